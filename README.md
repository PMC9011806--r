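# deseflow

Dynamic efficient sensory encoding for optic-flow heading models.

## What this is

A population of speed-tuned model neurons (like those in primate area MT)
has only a handful of distinct speed preferences, while the distribution of
optic-flow speeds an observer encounters shifts dramatically as self-motion
speed and scene depth change. `deseflow` implements a self-tuning rule that
keeps such a population matched to its input: the Gaussian tuning-curve
parameters are re-derived continually from the empirical distribution of
speeds observed over a rolling window of recent frames.

For a stimulus density *p(s)* and *N* speed cells, the neural density is
*d(s) = N p(s)*; the *n*-th tuning peak sits where the cumulative neural
density reaches *n* (the *n/N* quantile),

```
mu_n = s_n  where  D(s_n) = n,
FWHM_n = 1 / d(s_n),     sigma_n = FWHM_n / 2.355,
```

so each cell captures about 1/N of the stimulus probability mass: many
narrow curves where speeds are common, few broad ones where they are rare.

To measure the functional consequences, the package embeds the rule in a
two-stage heading-perception model — an MT-like grid of macrocolumns with
joint direction x speed tuning and Gaussian spatial pooling, feeding a
64 x 64 MSTd-like bank of radial-expansion templates with leaky recurrent
competition, decoded by the maximally active template — plus a synthetic
ego-motion stimulus generator (pinhole reprojection through parametric
depth scenes along seeded five-segment camera trajectories), Middlebury
`.flo` readers/writers, and an experiment harness that compares dynamic
tuning against static baselines on heading accuracy and convergence
latency.

Audience: computational neuroscientists and modelers studying adaptive
population codes and optic-flow processing, and anyone needing a seeded,
ground-truth dense flow generator with heading analytics.

## Worked example

Derive efficient tunings and run the pipeline on one synthetic trial:

```r
library(deseflow)

# closed-form check: uniform speeds on [0, 50], seven cells
derive_tuning(uniform_speed_distribution(50), 7)
#> tuning_curve_set: 7 Gaussian speed curves (dynamic, literal_eq2)
#>  index        mu     fwhm    sigma degenerate
#>      1  7.142857 7.142857 3.033060      FALSE
#>      2 14.285714 7.142857 3.033060      FALSE
#>      ...
#>      7 50.000000 7.142857 3.033060      FALSE
```

Peaks at 50·n/7 (equal 1/7 mass per cell) and constant width: a uniform
distribution earns a uniform tiling. On real flow the curves concentrate
where the speeds are:

```r
scene <- depth_scene("cluttered", depth_range = c(1.5, 12), seed = 3)
traj  <- make_trajectory(5, grid = 48, scene = scene)   # 162-frame protocol
flows <- render_trajectory_flow(scene, traj)

cfg   <- mt_config(grid = 48)          # 24 directions x 7 speeds = 168 units
bank  <- template_bank(32, cfg)        # 90/32 = 2.8 deg template spacing
trial <- run_condition_trial(flows, traj, condition("dynamic", 10),
                             cfg, bank)
segment_final_errors <- function(tr)   # error on each segment's last frame
  tapply(tr$error[!tr$is_transition], tr$segment[!tr$is_transition],
         function(y) y[length(y)])[-1]
round(segment_final_errors(trial), 2)
#>    2    3    4    5
#> 3.77 2.53 3.98 1.82
```

By the end of each constant-heading segment the decode has settled to
within a few degrees of the true heading (here 1.8–4 degrees, against a
2.8-degree template spacing), after spiking at each heading transition.
The per-frame data frame carries the decoded and true heading, total and
per-axis error, and a flag for frames on which the derived tuning collapsed
(all observed speeds identical — the known one-frame-horizon pathology).
The full comparison — dynamic vs a static-uniform tuning (0–5.3
degrees/frame) vs a static tuning from the whole stimulus set — is one
call:

```r
run <- run_experiment(n_trials = 10, seed = 1, mt_grid = 48,
                      mstd_grid = 32, noise_sigma = 0.1)
run    # per-condition converged error with bootstrap CIs,
       # logistic convergence frames, degenerate-frame counts
plot(run)
```

In this comparison the dynamic condition converges to lower heading error
than the static-uniform baseline — which suffers most on close-range/fast
segments whose speeds exceed its range, with the gap largest early in
each segment — while the in-sample static-aggregate tuning performs
comparably to dynamic at this stimulus diversity; every condition shows
the transition-frame error spike followed by gradual re-convergence. See the methods vignette
(`vignettes/dynamic-efficient-encoding.Rmd`) for the model, parameter and
generator details.

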