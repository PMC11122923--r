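test_that("capillary pressure follows Young-Laplace in slit and rectangular forms", {
  # cos(90 deg) = 0: no wetting, no driving pressure
  expect_equal(
    capillary_pressure(fluid_properties(0.05, 90, 1e-3), device_geometry(h = 100)),
    0
  )
  # 2 * 0.05 / 1e-4 m = 1000 Pa
  expect_equal(
    capillary_pressure(fluid_properties(0.05, 0, 1e-3), device_geometry(h = 100)),
    1000
  )
  # albumin-passivated channel: 2 * 0.058 * cos(27 deg) / 8e-5
  expect_equal(
    capillary_pressure(fluid_properties(0.058, 27, 1.5e-3), device_geometry(h = 80)),
    2 * 0.058 * cos(27 * pi / 180) / 8e-5,
    tolerance = 1e-12
  )
  # de-wetting surface: negative pressure
  expect_lt(
    capillary_pressure(fluid_properties(0.05, 120, 1e-3), device_geometry(h = 100)),
    0
  )
  # thin-slit form is the w -> infinity limit of the rectangular form
  slit <- capillary_pressure(fluid_properties(0.058, 27, 1.5e-3), device_geometry(h = 80))
  rect <- capillary_pressure(
    fluid_properties(0.058, 27, 1.5e-3),
    device_geometry(h = 80, w = 80 * 1e7)
  )
  expect_lt(abs(rect - slit) / slit, 1e-6)
  expect_error(device_geometry(h = -1), "h")
})

test_that("filtering constant computes 2 dP/(r mu v) with the documented unit conversion", {
  # 2*1000 / (1e12 * 1.5e-3 * 0.5) = 2.6667e-6 m^2/s; x 6e7 = 160 canonical
  k <- filtering_constant(1000, cake_properties(1e12, 0.5), 1.5e-3)
  expect_equal(k, 2 * 1000 / (1e12 * 1.5e-3 * 0.5) * 6e7, tolerance = 1e-12)
  expect_equal(k, 160, tolerance = 1e-10)
  # proportionalities
  expect_equal(filtering_constant(2000, cake_properties(1e12, 0.5), 1.5e-3), 2 * k)
  expect_equal(filtering_constant(1000, cake_properties(2e12, 0.5), 1.5e-3), k / 2)
  # zero pressure is rejected here, and k = 0 is rejected by the model type
  expect_error(filtering_constant(0, cake_properties(1e12, 0.5), 1.5e-3))
  expect_error(filtration_model(k = 0, ve = 1))
})

test_that("filtration rate is the cake-throttled rate balance", {
  m <- ref_model(0.1, 2)
  expect_equal(filtration_rate(m, A = 5, V = 3), 0.25) # 0.1*25 / (2*5)
  expect_lt(filtration_rate(m, 5, 10), filtration_rate(m, 5, 1))
  expect_lt(filtration_rate(m, 5, 1e9), 1e-6) # rate -> 0 as V grows
  expect_error(filtration_rate(filtration_model(0.1, 0), 5, 0), "undefined")
})

test_that("closed-form volume-time law matches independent ODE integration", {
  skip_if_not_installed("deSolve")
  grid <- expand.grid(k = c(0.01, 0.1, 1), ve = c(0.05, 0.5, 5), A = c(5, 15, 40))
  for (i in seq_len(nrow(grid))) {
    m <- filtration_model(grid$k[i], grid$ve[i])
    for (tau in c(1, 10, 60)) {
      expect_lt(
        abs(volume_at_time(m, grid$A[i], tau) - ode_volume(m, grid$A[i], tau)),
        1e-4
      )
    }
  }
})

test_that("volume-time law starts at zero, grows concavely, and reduces to the root law", {
  m <- ref_model(0.1, 2)
  expect_equal(volume_at_time(m, 5, 0), 0)
  expect_equal(volume_at_time(m, 5, 20), sqrt(0.1 * 25 * 20 + 4) - 2) # sqrt(54) - 2
  tau <- seq(0, 60, by = 0.5)
  v <- volume_at_time(m, 5, tau)
  expect_true(all(diff(v) > 0))
  expect_true(all(diff(diff(v)) < 1e-12)) # concave
  m0 <- filtration_model(0.1, 0)
  expect_equal(volume_at_time(m0, 5, tau), 5 * sqrt(0.1 * tau))
  expect_error(volume_at_time(m, 5, -1), "tau")
})

test_that("relative rate q decreases in V and hits the threshold at the steady-state volume", {
  m0 <- filtration_model(0.1, 0)
  expect_equal(relative_rate_q(m0, A = 5, V = 5), 0.05) # V = A sqrt(10 k) here
  for (m in list(ref_model(0.1, 2), filtration_model(0.5, 0), filtration_model(0.02, 7, 0.02))) {
    for (A in c(7, 20, 38.47)) {
      vq <- steady_state_volume(m, A)
      expect_equal(relative_rate_q(m, A, vq), m$q_th, tolerance = 1e-12)
      # consistency: Vq (Vq + Ve) = k A^2 / (2 q_th)
      expect_equal(vq * (vq + m$ve), m$k * A^2 / (2 * m$q_th), tolerance = 1e-10)
    }
  }
  v <- seq(1, 30, by = 0.5)
  expect_true(all(diff(relative_rate_q(ref_model(), 10, v)) < 0))
  # q halves when V (V + Ve) doubles
  m <- filtration_model(0.3, 0)
  expect_equal(relative_rate_q(m, 5, sqrt(2) * 4), relative_rate_q(m, 5, 4) / 2)
  expect_error(relative_rate_q(ref_model(), 5, 0), "V")
})

test_that("steady-state volume is the generalized threshold solution", {
  m <- ref_model(0.1, 2)
  expect_equal(steady_state_volume(m, 0), 0)
  expect_equal(steady_state_volume(m, 5), sqrt(26) - 1) # sqrt(10*0.1*25 + 1) - 1
  expect_equal(steady_state_volume(filtration_model(0.1, 0), 10), 10) # A sqrt(10 k)
  # general q_th, not just the 5% specialization
  m2 <- filtration_model(0.1, 2, q_th = 0.02)
  expect_equal(steady_state_volume(m2, 5), sqrt(0.1 * 25 / 0.04 + 1) - 1)
  expect_error(steady_state_volume(m, -1), "A")
})

test_that("steady-state time inverts the kinetics and stays below 1/q_th", {
  # ve = 0: tau_q = 1/(2 q_th) exactly, for any k and A
  for (k in c(0.01, 0.3)) {
    for (A in c(9, 30)) {
      expect_equal(steady_state_time(filtration_model(k, 0), A), 10, tolerance = 1e-12)
    }
  }
  # ve -> infinity limit: tau_q -> 1/q_th (20 min at the default threshold)
  expect_equal(steady_state_time(filtration_model(0.1, 1e7), 10), 20, tolerance = 1e-4)
  # definitional round trip V(tau_q) = Vq, and bounds [1/(2 q_th), 1/q_th)
  for (m in list(ref_model(0.1, 2), filtration_model(0.05, 4), filtration_model(1, 0.1))) {
    for (A in c(10, 25, 38.47)) {
      tq <- steady_state_time(m, A)
      expect_equal(volume_at_time(m, A, tq), steady_state_volume(m, A), tolerance = 1e-9)
      expect_gte(tq, 1 / (2 * m$q_th))
      expect_lt(tq, 1 / m$q_th)
    }
  }
  # cross-check by root-finding on q(V(tau)) = q_th
  m <- filtration_model(0.05, 4)
  root <- uniroot(
    function(tau) relative_rate_q(m, 20, volume_at_time(m, 20, tau)) - m$q_th,
    c(0.1, 100), tol = 1e-12
  )$root
  expect_equal(steady_state_time(m, 20), root, tolerance = 1e-8)
  expect_error(steady_state_time(m, 0), "A")
})

test_that("area sensitivities are positive, convex, and match finite differences", {
  m0 <- filtration_model(0.1, 0)
  expect_equal(dVq_dA(m0, c(0, 5, 20)), rep(sqrt(1), 3)) # sqrt(10 k), constant
  expect_equal(d2Vq_dA2(m0, c(5, 20)), c(0, 0))
  m <- ref_model(0.1, 2)
  expect_equal(dVq_dA(m, 5), 5 / sqrt(26), tolerance = 1e-12)
  hh <- 1e-4
  for (mm in list(m, filtration_model(0.05, 4), filtration_model(0.9, 0.3))) {
    for (A in c(2, 10, 38.47)) {
      fd1 <- (steady_state_volume(mm, A + hh) - steady_state_volume(mm, A - hh)) / (2 * hh)
      fd2 <- (steady_state_volume(mm, A + hh) - 2 * steady_state_volume(mm, A) +
        steady_state_volume(mm, A - hh)) / hh^2
      expect_equal(dVq_dA(mm, A), fd1, tolerance = 1e-5)
      expect_equal(d2Vq_dA2(mm, A), fd2, tolerance = 1e-4)
      expect_gt(dVq_dA(mm, A), 0)
      expect_gte(d2Vq_dA2(mm, A), 0)
    }
  }
})
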