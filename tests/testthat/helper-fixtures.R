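# Shared fixtures: small models and an independent ODE oracle for the
# closed-form kinetics (lsoda integration of the rate balance).

ref_model <- function(k = 0.1, ve = 2, q_th = 0.05) filtration_model(k, ve, q_th)

# Integrate dV/dtau = k A^2 / (2 (V + ve)) from V(0) = 0 with an adaptive
# solver; independent of volume_at_time()'s closed form.
ode_volume <- function(model, A, tau) {
  out <- deSolve::ode(
    y = c(V = 0), times = c(0, tau),
    func = function(t, y, p) list(model$k * A^2 / (2 * (y[1] + model$ve))),
    parms = NULL, method = "lsoda", rtol = 1e-10, atol = 1e-10
  )
  unname(out[nrow(out), "V"])
}

# Noise-free sampled curve straight from the closed form.
ideal_curve <- function(model, A, interval_s = 30, duration_min = 20) {
  t_s <- seq(0, duration_min * 60, by = interval_s)
  filtration_curve(t_s, volume_at_time(model, A, t_s / 60), area_mm2 = A)
}

# Bench-reported design pairs: area (mm^2) -> steady-state volume (uL).
bench_design_pairs <- function() {
  calibration_set(
    area_mm2 = c(15, 22.5, 25, 29, 32.5),
    vq_uL = c(5, 10, 15, 20, 30)
  )
}
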