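---
title: "Models and methods behind platesim"
author: "platesim maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind platesim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(platesim)
```

# Scope

platesim models the computational side of an automated perfusion
cell-culture platform: the liquid-handling routines that exchange medium in
multi-well plates, the pulse-width-modulation (PWM) formulator that mixes
up to six stocks into time-varying concentrations, and the downstream image
analysis that turns fluorescence time-lapses into concentration traces and
gastruloid reporter images into morphometric statistics. It deliberately
excludes hardware control, pressure–flow physics, evaporation, CO~2~ and
temperature, and cell growth or consumption kinetics: the simulator is a
bookkeeping model of volumes, solute masses and programmed times, which is
exactly the level at which exchange protocols are designed and audited.

# The fluidics model

Each well is a ledger `(volume, per-solute mass, clock)` under three
assumptions:

* **Instantaneous well mixing.** Concentration is always mass/volume.
  There is no spatial model of the liquid column.
* **Homogeneous removal.** Emptying and leveling remove liquid at the
  current mixed concentration, so neither changes any concentration; only
  dispensing events do.
* **Time-driven phases, volume-targeted fills.** The instrument is
  programmed with phase durations; the only flow-rate information available
  is "one set volume per programmed fill time", so a fill to any volume is
  charged `fill_s × added/set_volume` seconds (pro-rated).

An exchange cycle is EMPTY → FILL → LEVEL. Emptying retains the dead
volume `d` (0 for standard 24-well lids, 150 µL for Gri3D hydrogel
microwell arrays, where the residual protects the aggregates), so the
old-solute mass fraction after `n` cycles is `(d/V)^n` for set volume `V`.
A half-wash — fill to `1.5 V` with the new formulation, empty, refill,
level — reduces the per-switch carryover to `d/(1.5 V)`, strictly below a
plain exchange whenever `d > 0`.

**Fill overshoot.** The platform fills slightly past the level pin and
then levels. The overshoot amount is not part of the recorded settings, and
under homogeneous leveling any overshoot fraction `f > 1` would multiply
the carryover by `1/f`, breaking the clean `(d/V)^n` closed form that the
recorded volume ledgers follow. The package therefore defaults
`fill_overshoot_fraction` to 1.0 — fill to the level, with leveling a
time-cost-only trim — and exposes the fraction (up to 1.5) in
`well_config()` for users who want to model a real overshoot; the
`carryover_fraction()` closed form is exact only at the default.

**Units** are µL, seconds, and concentration values carried with a free
unit text (µM, ng/mL, …). No conversion between unit texts is attempted;
adding the same solute under a different unit text is an error, which
catches protocol bugs early.

**Sequential addressing.** One formulation/multiplexing path serves all
wells, so automated events execute one well at a time and `WAIT` events
model incubation gaps. Whether a real 8-plex run interleaves phases across
wells is not modeled; each routine completes on its well before the next
starts.

# PWM scheduling

Duty fractions solve `sum_i f_i stock_i(s) = target(s)` per solute with
`f ≥ 0`, `sum f = 1`. With two inputs this is a scalar least-squares
problem solved in closed form; with more inputs a nonnegative
least-squares mixture is used and the residual is checked against a
tolerance, since exact multi-solute targets may be unreachable. An
infeasible target reports the worst-matching solute.

Quantization maps fractions to pulses that are multiples of
`resolution_ms` (default 100 ms) summing to `cycle_ms` (default 1500 ms),
every nonzero pulse at least `min_pulse_ms` (100 ms). The quantization step
defaults to the minimum pulse because the programmable granularity of the
valve controller is not recorded; both are configurable. Among feasible
pulse vectors the one minimizing the Euclidean concentration error is
chosen by exhaustive enumeration over compositions, with ties broken toward
lower-index inputs so results are deterministic. The worst-case delivery
error is `stock_range × resolution_ms / cycle_ms` (0.5 µM for a 7.5 µM
stock at the defaults). The characterization literature reports duty
cycles from 0.1 to 0.9 while also stating a 100 ms minimum (fraction
1/15); the scheduler honors the 100 ms bound and treats the 0.1–0.9 range
as a characterization detail, not a constraint.

Ramps are discretized one target per PWM cycle, the finest step the cycle
structure supports; staircases split their window equally across levels,
any remainder cycles staying on the last level. A half-wash marker is
recorded at every discrete target switch (not at schedule start-up, and not
within ramps, which would thrash washes every cycle); markers can be
disabled. Multiplexer exclusivity is structural: each dispensing window
addresses exactly one well, and `validate_schedule()` re-checks every
constraint on any schedule.

Homogeneity of the pulse train after the formulator is summarized by the
resident-cycle count `tubing_volume / (flow × cycle time)`; the default
threshold of 5 resident cycles reflects the validated delivery geometry
(37.5 cm of 0.56 mm tubing, ~10 µL/s, 1.5 s cycle → 6.2 cycles, passing).
Flow is derived from the programmed fill time (set volume / fill seconds),
not from pressure, which the package does not model.

# Image quantification

The correction model is `(raw − darkfield) / (flatfield − darkfield)` with
the darkfield as pixelwise *mean* and the flatfield as pixelwise *median*
projection of their reference stacks (medians resist dust and transients in
the illumination references). Pixels whose dark-subtracted flatfield is not
positive cannot be normalized; they are masked and propagate as `NA`
rather than being interpolated. Corrected values are not clipped — noise
legitimately produces small negatives, and clipping would bias ROI
statistics. Even-count medians use the mean of the two middle values.

Per-well normalization divides ROI medians (default 100 × 100 px) by the
median intensity of a 0.5 µM reference solution imaged in the same well,
canceling well-to-well differences in liquid column height. The
calibration line is fitted by ordinary least squares in these
reference-normalized units (fitting in raw units is equally supported by
passing unnormalized intensities); inversion returns
`(I − intercept)/slope`, flagging below-zero results instead of truncating
them. With exactly two calibration points the residual standard error is
undefined and reported as 0 with a flag.

# Gastruloid morphometry

**Segmentation** uses Kapur's maximum-entropy criterion on a 256-bin
histogram over the image range (the convention of common image-analysis
toolkits), computed on the supplied channel; the largest connected
component is retained. The implementation is vectorized but the test suite
holds it equal, bin for bin, to an explicit brute-force maximization.

**Elongation index** = maximum Feret diameter / largest inscribed circle
diameter. "Length" is defined as the maximum Feret diameter (taken over
the convex hull of foreground pixel centers); the inscribed diameter is
twice the maximum of the Euclidean distance transform. The square → √2
example documents the length convention. On discrete masks both terms are
accurate to roughly one pixel, hence the 2 % tolerances used on analytic
shapes (disk 1.0, stadium 3.0, square √2).

**Axial profiles**: the operator-supplied posterior→anterior polyline is
partitioned into ten equal-arc segments; every pixel within 40 px
perpendicular distance (half the 80 px band, read as total width) is
assigned to the segment of its nearest axis point — a Voronoi partition
along the polyline, computed by exact projection onto the segments, so no
pixel is counted twice — and pixels projecting beyond the poles are
excluded. Per-segment sums are normalized to the gastruloid's own maximum
(peak = 1) and positions to its length (segment centers 0.05 … 0.95). The
per-gastruloid peak is taken from these raw normalized sums, not from any
fitted curve, reading the summary statistic literally as the recorded
maximum; ties resolve to the smallest position with a flag.

**Condition statistics**: polynomial fits are pooled across the
gastruloids of a condition (typically 4–7), matching how conditions are
summarized for display; per-gastruloid fits remain available by passing a
single profile. The polynomial degree is a required parameter with default
4 — the source analyses do not record the degree, and 4 is the lowest that
follows the observed one-peaked, shoulder-bearing profiles without chasing
segment noise. Fits serve visualization and residual inspection; the
hypothesis test runs on per-gastruloid peak positions, with unpaired
heteroscedastic (Welch) one-tailed *t*-tests via `stats::t.test`, checked
in the suite against the closed-form statistic, Welch–Satterthwaite
degrees of freedom, and the *t* distribution.

# Synthetic data: what it does and does not emulate

Every generator is seeded, restores the caller's RNG stream, and attaches a
`phantom_truth` record sufficient to regenerate its output bit-identically.

* `make_reference_stacks()` — Gaussian read noise around a camera offset
  (darkfields) plus a flat illumination level shaped by a radial vignette
  (flatfields), 100 frames each by default, matching the reference
  acquisition sizes.
* `make_dilution_series()` — one frame per known concentration with signal
  `intercept + slope·C` in corrected units, rendered through the shading
  model, including the 0.5 µM reference level.
* `make_pwm_trace()` — per-cycle delivered concentrations smoothed by a
  causal moving average of `dispersion_cycles` cycles (a first-order stand-in
  for tubing dispersion), sampled at the 0.5 s imaging interval, optionally
  rendered to frames.
* `make_gastruloid_phantom()` — a stadium-shaped body whose axial
  expression is a baseline plus a Gaussian bump (σ = 0.15 of the axis, a
  smooth unimodal shape chosen because no functional form is recorded for
  real posterior gradients) centered at the true peak; the straight
  centerline is the axis, posterior pole first. `make_condition_set()`
  draws per-gastruloid peaks (normal, truncated to [0.02, 0.98]) and
  elongations (uniform) to emulate a condition's 4–7 gastruloids.

These phantoms omit real-data features: curved axes, cell-scale texture,
photobleaching, autofluorescence gradients, optical blur, and 3-D
structure. Passing the recovery suites therefore shows the *measurement
chain* is correct and stable under noise — not that segmentation or axis
placement is robust on arbitrary real images. One consequence worth
knowing: Kapur thresholding of a strongly graded body (bright pole, dim
tail) places the threshold inside the expression range and clips the dim
tail, shortening the apparent mask — visible on phantoms whose bump
dominates the body baseline. The elongation recovery suite therefore
measures geometry on the phantom's true mask, while segmentation accuracy
is validated separately on flat-contrast objects (≥ 99 % pixel accuracy at
SNR 30); on real images the practical remedy is a dedicated,
more-uniformly-expressed segmentation channel.

# Numerical and testing choices

* Tolerances: mass conservation to 1e-9 relative; scheduler exactness to
  1e-12 on representable targets; threshold-oracle equivalence exact;
  analytic-shape elongation to 2 %; phantom recovery 5 % (elongation) and
  one segment, ±0.10 (peak) in ≥ 90 % of 20 randomized phantoms;
  calibration within 3 standard errors; end-to-end plateau recovery to 2 %;
  Welch power ≥ 90 % at p ≤ 0.05 over 100 seeded two-condition draws
  (peak means 0.55 vs 0.90, sd 0.05, n = 7 per condition).
* Problem sizes are kept desk-scale: reference stacks of 24–120 px frames,
  phantoms of 40–80 px width, staircases of 30–75 s; the whole suite runs
  in well under a minute on one CPU. These sizes were chosen so the
  statistical bounds above are meaningful while iteration stays fast.
* Degenerate inputs error loudly rather than guessing: constant images for
  thresholding, all-zero profiles for normalization, empty masks, zero
  calibration slopes, zero variance in both Welch groups, fills below the
  current volume, states below the dead volume.
* CSV is UTF-8, comma-separated, header row, no row names; JSON is written
  with unboxed scalars and full precision. Re-running any subcommand with
  the same configuration and seed reproduces byte-identical artifacts.

# Known limitations

The simulator's homogeneous-removal assumption makes leveling
concentration-neutral by construction; a stratified column (e.g.
immediately after a gentle top-up) is not represented. The dispersion model
is a moving average, not Taylor dispersion; it reproduces settling and
plateau homogeneity but not the true pulse-response shape. Elongation on
masks thinner than ~10 px becomes discretization-limited. Axis placement is
manual by design — the package does not attempt automatic axis detection —
so profile accuracy inherits the operator's axis quality.
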