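---
title: "Modelling capillary-driven plasma separation as cake filtration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling capillary-driven plasma separation as cake filtration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plasmaflow)
```

## The physical model and its assumptions

A passive plasma-separation device stacks a filtration membrane over a
shallow disc-shaped reservoir (height `h` ≈ 80 µm). Whole blood sits on the
membrane; the hydrophilic microchannel beneath pulls plasma through by
capillary pressure alone. Red blood cells retained on the membrane accumulate
as a filter cake whose hydraulic resistance grows in proportion to the
filtrate already collected. Three assumptions define the model:

1. **Constant driving pressure.** The meniscus in a thin slit supplies
   `ΔP = 2γcosθ/h` (Young–Laplace; the rectangular form
   `2γcosθ(1/h + 1/w)` is implemented too, and converges to the slit form as
   `w → ∞` — for a 37 mm wide, 80 µm high reservoir the difference is a part
   in 500). `capillary_pressure()` computes either form; with plasma-like
   surface tension (0.058 N/m) and a passivated surface (contact angle 27°)
   the channel develops ≈ 1292 Pa.
2. **Cake-dominated resistance, lumped linearly.** Total resistance is
   proportional to `V + Ve`, where the *equivalent filtrate volume* `Ve`
   (µL) expresses the clean membrane's resistance in cake-equivalent units.
3. **All material physics lumped into one constant.**
   `k = 2ΔP/(rμv)` (µL² mm⁻⁴ min⁻¹) absorbs pressure, plasma viscosity,
   specific cake resistance and cake-per-filtrate ratio. `k` and `Ve` are
   treated as empirical, to be fitted per blood sample and device treatment;
   the package deliberately does not model hematocrit-dependent viscosity,
   pore-scale clogging or hemolysis.

The rate balance and its exact integral from `V(0) = 0` are

$$\frac{dV}{d\tau} = \frac{kA^2}{2(V + V_e)}, \qquad
  V(\tau) = \sqrt{kA^2\tau + V_e^2} - V_e .$$

A point worth flagging for anyone re-deriving this: a tempting but wrong
integration yields `sqrt(kA²τ/2 + Ve²) − Ve`, which is off by a factor of two
under the root and is *not* the solution of the rate balance above. plasmaflow
uses the exact integral; the unit tests verify it against independent
adaptive ODE integration of `filtration_rate()` to within 10⁻⁴ µL across a
parameter grid spanning two orders of magnitude in `k` and `Ve`.

## Steady state and the per-minute convention

Collection never truly stops, so "complete" is defined by a threshold on the
relative growth rate `q = (dV/dτ)/V = kA²/(2V(V+Ve))`. The threshold `q_th`
needs a time unit that the defining inequality ("5 % or less") leaves open;
plasmaflow defines it **per minute** (default 0.05/min), the natural unit for
a process observed on a 30-s imaging grid over tens of minutes. `q_th` is a
field of `filtration_model()`, never a hard-coded constant, and the
steady-state volume is implemented for general thresholds:

$$V_q(A) = \sqrt{\frac{kA^2}{2q_{th}} + \frac{V_e^2}{4}} - \frac{V_e}{2},$$

which at `q_th = 0.05` gives the familiar `sqrt(10kA² + 0.25Ve²) − 0.5Ve`.
Two consequences of the self-consistent kinetics deserve emphasis:

- For any pure square-root law (`Ve = 0`), `q(τ) = 1/(2τ)` *independently of
  k and A*, so the threshold is crossed at exactly `1/(2 q_th)` = 10 min.
- With `Ve > 0` the steady-state time
  `τ_q = (V_q² + 2V_qV_e)/(kA²)` increases toward, but never reaches,
  `1/q_th` = 20 min. Separation under this model therefore always completes
  within 20 minutes at the default threshold, consistent with bench
  experience with such devices.

`Vq(A)` is strictly increasing and convex: `dVq/dA = cA/\sqrt{cA² + Ve²/4}`
and `d²Vq/dA² = (cVe²/4)/(cA² + Ve²/4)^{3/2}` with `c = k/(2q_th)` — the
second derivative's denominator carries exponent 3/2, as differentiation
requires (statements of this result sometimes print exponent 3; positivity,
the scientifically relevant claim, holds either way). Both are checked
against central finite differences (step 10⁻⁴ mm²) to relative 10⁻⁵.
Convexity means each extra mm² of membrane buys *more* plasma when `Ve`
matters — worth knowing when a fit returns a large `Ve`.

## Estimation: choices and tie-breaks

`fit_time_course()` and `fit_steady_state()` minimise unweighted least
squares on volumes (no error model is assumed for the measurements;
robust losses are out of scope) using Levenberg–Marquardt on
`(log k, log(Ve + 10⁻⁸))`, so positivity is structural rather than enforced
by constraints. Initialisation is fixed and documented — `Ve = 0` and `k`
from a through-origin linear fit (`V²` against `A²τ` for time courses, `Vq`
against `A` for calibrations) — making every fit deterministic. Convergence:
`ftol = ptol = 10⁻¹⁰`, at most 1000 iterations; non-convergence is flagged on
the returned object, never raised as an error. Degenerate inputs (all-zero
curves, fewer than two distinct areas, under-determined two-point curves)
are rejected with informative errors.

With a single 20-min curve, `k` is strongly identified but `Ve` only weakly
(it mostly shifts the first few minutes); calibrations across several areas
share the same asymmetry. This is why the package's accuracy claims are
about *design* rather than *parameters*: the design inversion
`A = sqrt(2 q_th V*(V* + Ve)/k)` re-uses the same fitted curve that predicts
`Vq`, so correlated errors in `(k, Ve)` largely cancel. In the repeated
simulation experiment (100 seeds, 4 areas × 3 replicates, 3 % noise) the
median error of `k̂` stays under 5 % while `V̂e` errors run ~3× larger, yet
designed devices deliver within 10 % of target in ≥ 95 % of runs.

`detect_steady_state()` discretises `q` with backward differences normalised
by the *current* volume `V_i` — the reference volume for a relative rate is
ambiguous in discrete time, and this choice keeps `q_i` defined whenever
`V_i > 0` (zero-volume intervals are skipped, neither hit nor reset). By
default three consecutive sub-threshold intervals are required before
declaring steady state, suppressing single-interval noise flukes; with
noise-free data and `consecutive = 1` the detection lands within one 30-s
sample of the analytic `τ_q`.

## What the synthetic data emulate — and what they do not

The generators reproduce the study conditions the pipeline is meant for:
sampling every 30 s for 20 min; calibration devices at 12.56, 19.63, 28.26
and 38.47 mm² (4–7 mm diameter membranes), three replicates; whole blood of
48 % hematocrit at 5×10⁶ red cells/µL; ~0.2 % residue in the plasma.
Measurement noise is multiplicative Gaussian (CV 3 % by default, truncated
at −3 CV to keep volumes positive), reflecting that image-segmentation area
error scales with the measured area; 3 % makes the devices' ±10 % error band
the binding constraint rather than an artifact of simulated noise. Reservoir
images render the plasma as a clean bright annulus (37 mm groove, 6 mm
central boss, additive pixel noise of 5 intensity units on 8-bit scale);
real wetting fronts are ragged and unevenly lit, but only total area enters
the pipeline, so segmentation difficulty is deliberately understated. Cell
counts are Poisson — no counting-chamber loading bias, no clumping.
Passing tests on these data therefore validate the *mathematics and code
paths*, not the device: they say nothing about membrane lot variation,
temperature, donor hematocrit or hemolysis, all of which fold silently into
the fitted `(k, Ve)`.

Problem sizes used by the test-suite: curves of 41 points, calibrations of
12 points, 100-seed recovery and design experiments, 740×740-pixel images at
50 µm/pixel — small enough to re-run interactively, large enough that the
Monte-Carlo checks (noise CV within 20 % of nominal; Poisson residue
estimator unbiased within 2 standard errors over 1000 draws) are sharp.

## Image quantification and purity metrics

Volume from an image is `V = S·h` (1 mm²·µm = 10⁻³ µL): segment
(Otsu's bimodal-histogram threshold by default, polarity configurable with
`invert`), count pixels, multiply. No illumination correction or
morphological cleanup is applied — high-contrast imagery is assumed. On
synthetic images at 50 µm/pixel the closed loop recovers the generating
volume within 2 % across fill fractions 0.05–0.95. One dimensional-analysis
note: a hemocytometer sampling point of 250 µm² under an 80 µm channel holds
2×10⁻⁵ µL, not 0.02 µL — counting statistics should be computed from the
former.

The residue rate is defined here as the plasma red-cell concentration as a
percentage of the *input whole-blood* concentration (default 5×10⁶
cells/µL, configurable); capture efficiency is its complement to 100 %. The
denominator convention matters only when working from raw counts — replicate
rates supplied directly (e.g. 0.202 %, 0.266 %, 0.248 % → 0.2 % mean,
99.8 % efficiency at one decimal) are convention-free. Reported figures are
rounded half-up at the stated precision so the residue/efficiency pair is
always mutually consistent.

## Design feasibility and limitations

`required_area()` flags, but still computes, targets outside the validated
5–30 µL range — extrapolation along a fitted convex curve is useful with an
explicit caveat. Areas below the minimum feasible bound (default 7 mm²,
a device/treatment property stored on `device_geometry()`, not a constant)
are marked infeasible: below it, inlet-wall capillarity stalls filtration
entirely, a regime the model does not attempt to describe. Remaining known
limitations: no uncertainty quantification beyond residual RMS, no
hierarchical multi-donor modelling, no meniscus or wetting-front modelling,
and no hemolysis quantification beyond what a user flags visually.
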