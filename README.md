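# plasmaflow

Point-of-care blood tests need a few microlitres of cell-free plasma, but
outside a laboratory there is no centrifuge to produce it. A passive
alternative draws whole blood through an asymmetric membrane using nothing but
the capillary pressure of a shallow (~80 µm) microchannel: red blood cells are
retained on the membrane, where they pile up as a *filter cake* that
progressively throttles the flow until collection effectively stops. Because
the plateau volume is set almost entirely by the membrane area open to flow,
the device itself meters the plasma — choose the area, get the volume.

plasmaflow is an R package for scientists modelling and designing such
devices. It implements the constant-pressure cake-filtration model of the
process and everything around it: parameter estimation, area design,
image-based volume quantification, purity metrics, and synthetic-data
generators with known ground truth.

## The model

With `V` the collected plasma volume (µL), `τ` time (min), `A` the effective
filtration area (mm²), the rate balance of cake filtration under a constant
capillary driving pressure `ΔP = 2γcosθ/h` (Young–Laplace, thin-slit limit)
is

    dV/dτ = k A² / (2 (V + Ve)),      k = 2ΔP/(rμv)

where `k` (µL² mm⁻⁴ min⁻¹) is the *filtering constant* and `Ve` (µL) the
*equivalent filtrate volume* — the volume at which cake resistance equals the
clean-membrane resistance. Integrating from `V(0) = 0`:

    V(τ) = sqrt(k A² τ + Ve²) − Ve

Separation is declared steady once the relative growth rate
`q = (dV/dτ)/V = k A²/(2V(V+Ve))` falls to a threshold `q_th` (5 %/min by
default), giving the steady-state volume and its area sensitivity

    Vq(A) = sqrt(k A²/(2 q_th) + Ve²/4) − Ve/2,      dVq/dA > 0,  d²Vq/dA² ≥ 0

Inverting `Vq(A)` yields the design rule: the area delivering a target volume
`V*` is `A = sqrt(2 q_th V* (V* + Ve) / k)`, subject to a minimum feasible
area (7 mm² by default) below which inlet capillarity stalls the flow.

## Worked example

Calibrate on noisy synthetic measurements, design areas for five target
volumes, and check the delivered volumes against the generating truth:

```r
library(plasmaflow)

truth <- filtration_model(k = 0.05, ve = 4)        # ground truth
cfg   <- sim_config(seed = 42, noise_cv = 0.03)    # 4 areas x 3 reps, 3% noise

cal <- gen_calibration_set(truth, cfg)
fit <- fit_steady_state(cal)
fit
#> <filtration_fit: steady_state, 12 points>
#>   k = 0.051088 uL^2 mm^-4 min^-1, Ve = 4.5844 uL (q_th = 0.05 /min)
#>   rms error = 0.3939 uL, converged = TRUE (32 iterations)

report <- design_report(c(5, 10, 15, 20, 30), fit$model, eval_model = truth)
report[, 1:5]
#>   target_uL  area_mm2 predicted_uL    rel_error feasible
#> 1         5  9.685181     5.134519  0.026903853     TRUE
#> 2        10 16.896024    10.113539  0.011353867     TRUE
#> 3        15 23.979548    15.073645  0.004909682     TRUE
#> 4        20 31.023088    20.027619  0.001380943     TRUE
#> 5        30 45.065164    29.928585 -0.002380510     TRUE
```

The fitted parameters land within ~15 % of the truth (the offset `Ve` is the
weakly identified one), yet every designed device delivers its target within
2.7 % — well inside the 10 % error band reported for the physical devices —
because design inversion and steady-state prediction use the *same* fitted
curve, so calibration errors largely cancel. Plasma purity follows the same
arithmetic as a hemocytometer count:

```r
capture_efficiency(c(0.202, 0.266, 0.248))
#>   n_replicates mean_residue_pct capture_efficiency_pct
#> 1            3              0.2                   99.8
```

`autoplot(fit)`, `autoplot(curve)` and `plot_design_report(report)` draw the
standard diagnostic figures; `tidy(fit)`/`glance(fit)` return the estimates
as tibbles. File-based workflows (simulate → quantify → fit → design →
quality) are exposed as `cli_*()` functions and a thin `Rscript` dispatcher
in `inst/cli/plasmaflow.R`.

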