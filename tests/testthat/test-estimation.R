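test_that("steady-state detection applies the discrete relative-rate criterion", {
  # noise-free root-law curve: detection within one 30-s interval of the
  # analytic steady-state time
  m0 <- filtration_model(0.08, 0)
  d <- detect_steady_state(ideal_curve(m0, 28.26), q_th = 0.05, consecutive = 1)
  expect_true(d$achieved)
  expect_lt(abs(d$tau_q_s - 60 * steady_state_time(m0, 28.26)), 30 + 1e-6)
  expect_equal(d$v_q_uL, ideal_curve(m0, 28.26)$volume_uL[d$index])

  # constant positive volume: q = 0 everywhere, detected at the first interval
  flat <- filtration_curve(seq(0, 300, 30), rep(4, 11), area_mm2 = 20)
  d_flat <- detect_steady_state(flat, consecutive = 1)
  expect_true(d_flat$achieved)
  expect_equal(d_flat$index, 2L)

  # exponential growth: q ~ 1/min forever, never below 5%/min
  t_s <- seq(0, 600, 30)
  expo <- filtration_curve(t_s, exp(t_s / 60), area_mm2 = 20)
  d_exp <- detect_steady_state(expo, consecutive = 1)
  expect_false(d_exp$achieved)
  expect_equal(d_exp$index, length(t_s))

  # q is a relative rate: invariant to uniform volume rescaling
  m <- filtration_model(0.05, 4)
  cv <- ideal_curve(m, 19.63)
  scaled <- filtration_curve(cv$time_s, 17.3 * cv$volume_uL, area_mm2 = 19.63)
  expect_equal(
    detect_steady_state(cv, consecutive = 3)$index,
    detect_steady_state(scaled, consecutive = 3)$index
  )

  expect_error(
    detect_steady_state(filtration_curve(c(0, 30, 60), c(0, 1, 2), 10), consecutive = 3),
    "consecutive"
  )
})

test_that("time-course fitting recovers the generating parameters", {
  truth <- filtration_model(0.08, 3)
  curve <- gen_filtration_curve(truth, 28.26, sim_config(seed = 1, noise_cv = 0))
  fit <- fit_time_course(curve)
  expect_true(fit$converged)
  expect_equal(fit$model$k, truth$k, tolerance = 1e-4)
  expect_equal(fit$model$ve, truth$ve, tolerance = 1e-4)
  expect_lt(fit$rms_error, 1e-8)
  expect_equal(length(fit$residuals), nrow(curve))

  # three replicate curves at 3% noise: k recovered within 10%
  curves <- lapply(1:3, function(r) {
    gen_filtration_curve(truth, 28.26, sim_config(seed = 100 + r, noise_cv = 0.03))
  })
  fit_n <- fit_time_course(curves)
  expect_true(fit_n$converged)
  expect_lt(abs(fit_n$model$k - truth$k) / truth$k, 0.10)

  # under-determined and degenerate inputs
  expect_error(filtration_curve(c(0, 30), c(0, 1), 10), "3")
  expect_error(
    fit_time_course(filtration_curve(c(0, 30, 60), c(0, 0, 0), 10)),
    "zero"
  )
})

test_that("steady-state fitting recovers the generating parameters exactly from clean pairs", {
  truth <- filtration_model(0.05, 4)
  cal <- calibration_set(c(10, 20, 30, 40), steady_state_volume(truth, c(10, 20, 30, 40)))
  fit <- fit_steady_state(cal)
  expect_true(fit$converged)
  expect_equal(fit$model$k, truth$k, tolerance = 1e-4)
  expect_equal(fit$model$ve, truth$ve, tolerance = 1e-4)

  # identical volumes across areas are inconsistent with the model:
  # the fit cannot be flat, so residual error stays large
  flat <- calibration_set(c(10, 20, 30, 40), rep(10, 4))
  fit_flat <- fit_steady_state(flat)
  expect_gt(fit_flat$rms_error, 0.5)

  expect_error(fit_steady_state(calibration_set(c(10, 10), c(5, 5.1))), "distinct")
})

test_that("the bench design pairs admit a converged, increasing, convex fit", {
  fit <- fit_steady_state(bench_design_pairs())
  expect_true(fit$converged)
  expect_equal(length(fit$residuals), 5L)
  A <- seq(7, 40, by = 0.5)
  vq <- steady_state_volume(fit$model, A)
  expect_true(all(diff(vq) > 0))
  expect_true(all(diff(diff(vq)) >= -1e-10))
})

test_that("time-course and calibration fits agree on data from one model", {
  truth <- filtration_model(0.06, 2.5)
  cfg <- sim_config(seed = 5, noise_cv = 0)
  curves <- lapply(cfg$areas, function(a) gen_filtration_curve(truth, a, cfg))
  cal <- gen_calibration_set(truth, cfg)
  f_tc <- fit_time_course(curves)
  f_ss <- fit_steady_state(cal)
  expect_equal(f_tc$model$k, f_ss$model$k, tolerance = 1e-4)
  expect_equal(f_tc$model$ve, f_ss$model$ve, tolerance = 1e-3)
})

test_that("parameter recovery is accurate over repeated noisy calibrations", {
  truth <- filtration_model(0.05, 4)
  errs <- vapply(1:100, function(s) {
    cal <- gen_calibration_set(truth, sim_config(seed = s, noise_cv = 0.03))
    fit <- fit_steady_state(cal)
    c(
      abs(fit$model$k - truth$k) / truth$k,
      abs(fit$model$ve - truth$ve) / truth$ve
    )
  }, numeric(2))
  expect_lt(median(errs[1, ]), 0.05)
  expect_lt(median(errs[2, ]), 0.15)
})

test_that("fit objects expose tidy, glance and predict", {
  fit <- fit_steady_state(bench_design_pairs())
  td <- tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_equal(td$term, c("k", "ve", "q_th"))
  gl <- glance(fit)
  expect_equal(nrow(gl), 1L)
  expect_equal(gl$nobs, 5L)
  expect_equal(
    predict(fit, tibble::tibble(area_mm2 = 20)),
    steady_state_volume(fit$model, 20)
  )
})
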