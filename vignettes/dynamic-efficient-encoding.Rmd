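---
title: "Dynamic efficient sensory encoding in a heading-perception model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamic efficient sensory encoding in a heading-perception model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

A population of speed-tuned visual neurons with a fixed, small number of
unique speed preferences can only encode a limited band of stimulus values
well. During self-motion the distribution of optic-flow speeds across the
visual field shifts dramatically — slow, narrow bands when approaching a
distant wall; broad, long-tailed gradients when skimming over a ground
plane; and abrupt changes whenever camera speed or scene depth changes. A
static attunement therefore wastes encoding capacity whenever the current
stimulus distribution departs from the one it was tuned for.

`deseflow` implements *dynamic efficient sensory encoding* (DESE): the
parameters of a bank of Gaussian speed-tuning curves are re-derived
continually from the empirical distribution of speeds observed over a
rolling window of recent frames, so the population stays matched to what
the observer is currently seeing. The mechanism is embedded in a two-stage
neural model of heading perception so its functional consequences can be
measured.

## The encoding rule

Let $p(s)$ be the probability density of the stimulus (flow speed, in
degrees/frame) and $N$ the number of distinct speed preferences. Define the
neural density

$$d(s) = N\,p(s),$$

whose integral over the support is $N$. Writing $D(s)$ for the cumulative
of $d$, the $n$-th tuning peak is placed where the cumulative density
reaches level $n$,

$$\mu_n = s_n \quad \text{with} \quad D(s_n) = n,$$

i.e. at the $n/N$ quantile of the stimulus distribution, and its width is
set inversely to the local neural density,

$$\mathrm{FWHM}_n = \frac{1}{d(s_n)}, \qquad
\sigma_n = \frac{\mathrm{FWHM}_n}{2.355}.$$

Each cell then captures approximately $1/N$ of the stimulus probability
mass: dense stimulus regions receive many narrow curves, sparse regions few
broad ones. The constant 2.355 is the conventional rounding of
$2\sqrt{2\ln 2}$; the package uses the rounded value throughout, so
"response at the half-maximum offset" equals 0.5 to about four decimal
places, not exactly.

```{r, eval = FALSE}
library(deseflow)
u <- uniform_speed_distribution(50)
derive_tuning(u, 7)   # peaks at 50 n / 7, every sigma = 50/7/2.355
```

### Numerical realization

* **Histograms.** Distributions are 128-bin histograms spanning
  `[0, max observed speed]`, pooled with equal weight per flow vector over
  whatever frames are in the window. 128 bins balances resolution against
  the per-frame cost of re-deriving the tuning on every frame.
* **Interpolated CDF.** The CDF is piecewise *linear* within bins (not a
  step function), and peaks are placed by its generalized inverse. With a
  step CDF, peaks would jump between bin edges from frame to frame,
  injecting artificial re-tuning noise into the dynamic condition.
  Densities are linearly interpolated between bin centers and clamped
  beyond the outermost centers.
* **Placement levels.** The placement rule evaluates the inverse CDF at
  levels $n/N$ (`literal_eq2`, the default), which puts the last peak
  exactly at the observed maximum. The efficient-coding literature often
  centers quantiles at $(n-\tfrac12)/N$; that variant is available as
  `placement = "half_offset"`. The default favors the form of the
  defining equation; nothing downstream depends on the choice beyond a
  half-bin shift of every peak.
* **Degenerate collapse.** When every speed in the window is identical
  (e.g. a one-frame horizon viewing near-uniform flow), the distribution
  is a point mass: all peaks collapse to the same value with zero width.
  This is deliberately *not* an error — the collapse and the erratic
  downstream activity it produces are part of the phenomenon being
  modeled. An optional bandwidth floor (`sigma_floor`, suggested 0.05
  degrees/frame) stabilizes the limit for users who want it; it is off by
  default.
* **Response cutoff.** Tuning responses are hard-clipped to zero beyond
  $\mu \pm 4\sigma$, realizing "drops to zero outside the sensitive
  range" while keeping more than 99.99% of the Gaussian mass. The cutoff
  is configurable.

## The two-stage heading model

**MT stage.** At every pixel of the flow grid sits a macrocolumn of units
jointly tuned to direction and speed (24 directions × 7 speeds = 168 units
at the defaults). Direction tuning is a von Mises curve (concentration
$\kappa = 10$); the direction curve's bandwidth and the joint combination
rule are not constrained by the modeled physiology, so both are explicit
free parameters — the package multiplies the two tuning factors, the
simplest joint rule. Each channel is pooled spatially with a normalized
Gaussian kernel ($\sigma = 1$ pixel, truncated at $4\sigma$, 9-pixel
support — about 3.15 degrees of visual angle on a 256-pixel, 90-degree
grid). Speed-channel indices carry *rank* (slowest to fastest), never an
absolute speed, so re-tuning preserves the downstream meaning of each
channel ordinally.

**MSTd stage.** A 64 × 64 bank of radial-expansion templates spans the
field of view (about 1.41 degrees between adjacent template headings).
Each template's drive is the sum over pixels and direction channels of MT
activity — summed over speed channels, because heading information lives
in flow *directions* — weighted by the rectified cosine between the
channel's preferred direction and the template's outward radial direction
at that pixel. Radial directions are evaluated as the exact motion-field
direction for translation toward the template's FoE — radial in pixel
coordinates and mapped through the gnomonic Jacobian into the angular
coordinates flow is measured in — which is depth-independent and keeps
templates aligned with noiseless radial flow at all eccentricities. Activity evolves as a leaky integrator with global
subtractive competition,

$$a_{t+1} = (1-\lambda)\,a_t + \lambda\,[\,\text{drive} -
\gamma\,\overline{a_t}\,]_+ ,$$

and the decoded heading is the preference of the maximally active
template (ties break to the lowest row-major index). This recurrence is a
deliberate simplification of fully recurrent competitive dynamics: it is
*not* the published competitive-dynamics circuit, and users should not
treat it as such. The leak rate is calibrated on a controlled abrupt
heading jump between equal-strength drives: $\lambda = 0.05$ (default)
makes the decoded heading take about 14 frames to switch, inside the
10–20 frame latency range of interest (0.2 would switch in 4 frames,
too fast to resolve latency differences); $\gamma = 1$ by default.

An implementation note: the template match is algebraically decomposed
over half-circle direction sets, which turns the per-frame cost into two
small matrix products plus a gather, instead of a cosine evaluation per
(pixel, direction, template) triple. A literal brute-force evaluation is
kept in the test suite as the oracle for this path.

## The synthetic stimulus generator

The generator emulates a five-segment ego-motion protocol: per trial, five
random heading pixels (uniform over the image), five speeds uniform in
1–20 m/s, a starting height of 1–5 m, 30 steady frames per segment and
3-frame linear transitions of heading pixel and speed — 162 frames at 30
frames/s. Flow is produced by exact pinhole reprojection: each pixel is
back-projected through the scene depth to a 3-D point, re-projected under
the next camera pose, and differenced in angular image coordinates
(azimuth positive rightward, elevation positive upward, per-axis gnomonic
angles $\mathrm{az} = \arctan(x/f)$). Trajectories that bring the camera
within 0.5 m of scene geometry are rejected and re-sampled — an automated
stand-in for manually reviewing stimuli for collisions.

The camera's *orientation is held fixed* throughout a trial, so the focus
of expansion sits at the sampled heading pixel and jumps between segments.
The alternative — re-aiming the camera at each new heading — would return
the focus of expansion to the image center after every transition,
collapsing the heading-shift structure that the segment-normalized
latency analyses measure. Rotational flow therefore appears only through
the translation direction changing mid-transition, not through camera
rotation; this is the one place the generator deliberately simplifies the
emulated protocol, and it is the package's own design choice.

Three scene families supply depth: an infinite ground plane (smooth speed
gradient, sky above the horizon), a frontoparallel wall (narrow speed
band), and a "cluttered" scene — a seeded random log-depth field over
viewing direction, combined with a ground floor — standing in for
naturalistic depth variation without modeling geometry. Because the
cluttered range field is evaluated per frame along current viewing rays,
its depth statistics are stationary over a trial; it emulates the
*statistics* of flying through clutter, not a persistent 3-D world, which
is exactly what the encoding stage consumes.

Estimation noise emulates the error profile of pixel-based flow
estimators: i.i.d. Gaussian perturbation of every vector plus sparse large
outliers on sky pixels (default rate 0.02), where real estimators latch
onto low-contrast junk.

What the generator does *not* emulate: rendered imagery and actual flow
estimation, independently moving objects, persistent scene geometry across
frames, eccentricity-dependent receptive fields. Passing tests therefore
demonstrate the encoding and decoding machinery on geometrically exact,
statistically realistic flow — not performance on estimated flow from
real video.

## The simulation experiments

The harness compares three tuning regimes on identical stimuli: *dynamic*
(rolling horizon, default 10 frames), *static-uniform* (tuning derived
once from a uniform speed distribution on 0–5.3 degrees/frame) and
*static-aggregate* (tuning derived once from the distribution pooled over
every frame of the whole stimulus set, computed in a pre-pass). A second
experiment compares dynamic horizons of 1, 10 and 30 frames.

Desk-scale study conditions (chosen once; all seeded): 10 trials, flow and
MT at 48 × 48, MSTd at 32 × 32, 24 directions × 7 speeds,
$\lambda = 0.05$, estimation noise 0.1 degrees/frame. Trials alternate
between two cluttered-scene flavors — an enclosed close-surface
environment (depth 1.5–12 m, the geometry of a warehouse corridor) and an
open deep-depth one (3–250 m, neighborhood-like) — emulating a 50/50
indoor/outdoor stimulus mix. The indoor flavor matters: at 1–20 m/s with
surfaces a few meters away, much of the field exceeds the static-uniform
range, which is precisely the regime in which a static attunement loses
sensitivity; with only deep scenes nearly all flow falls inside every
tuning's coverage and the regimes are indistinguishable. The reduced
grids keep a full two-experiment run in the minutes range; they lower the
heading-resolution floor to 90/32 ≈ 2.8 degrees between template centers,
which bounds how small a converged-error difference the desk scale can
resolve.

Metrics follow the logic of latency-and-accuracy analysis of a tracking
system. Per frame, heading error is the angle between the 3-D gaze
vectors of estimate and truth. The first segment is excluded (no prior
activity to overcome). Converged error is the final steady frame of each
remaining segment; each segment's steady-frame series is normalized by
its first-frame error and fit with a decreasing 4-parameter logistic by
least squares (parameters averaged over converged segment fits per
condition; non-convergent fits are counted and excluded). The latency
measure is the closed-form frame at which the averaged curve has dropped
by 98% of its range. The logistic's parameter count and loss are
recorded in output metadata because several reasonable variants exist
(3-parameter, robust loss); the 4-parameter least-squares choice is the
package's own. Group comparisons use seeded bootstrap confidence
intervals and paired one-sided bootstrap tests rather than
repeated-measures ANOVA machinery: the inferential apparatus is not the
scientific content, and the bootstrap avoids sphericity corrections at
these sample sizes.

```{r, eval = FALSE}
run <- run_experiment(n_trials = 10, seed = 1, mt_grid = 48,
                      mstd_grid = 32, noise_sigma = 0.1)
run
plot(run)
```

## Known limitations

* The recurrent stage is a leaky integrator with global competition, not
  the published competitive-dynamics circuit; absolute error magnitudes
  and latencies are therefore specific to this simplification.
* Radial templates only: laminar/spiral templates and
  rotation-compensating heading estimation are out of scope, so
  transition frames (which contain interpolated translation) are treated
  purely as error spikes, as the analyses assume.
* The dynamic condition adapts to whatever enters the pooled window —
  including estimation noise. With very high outlier rates the adapted
  distribution itself becomes contaminated; no robustification is
  attempted.
* Speeds are expressed in degrees/frame with a single global
  degrees-per-pixel conversion (field of view / grid width), a small-angle
  approximation that slightly compresses peripheral magnitudes relative
  to exact per-pixel scaling.
* Only the pooled, field-wide distribution drives the tuning;
  per-receptive-field local adaptation is an extension point, as are
  non-Gaussian tuning families (log-Gaussian, gamma).
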