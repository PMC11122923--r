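# Run `code` under a fixed RNG seed without disturbing the caller's stream.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Simulation configuration
#'
#' Bundles the bench conditions the generators emulate: imaging every 30 s
#' over a 20-min run, devices at the four calibration areas (4-7 mm diameter
#' circular membranes), three replicates, 3% multiplicative measurement noise,
#' and whole blood of 48% hematocrit at 5e6 red cells/uL.
#'
#' @param seed Integer RNG seed; must be set explicitly so every generated
#'   artifact is reproducible.
#' @param noise_cv Coefficient of variation of the multiplicative measurement
#'   noise. Default 0.03.
#' @param interval Sampling interval (seconds). Default 30.
#' @param duration Run duration (minutes). Default 20.
#' @param areas Effective filtration areas (mm^2).
#'   Default `c(12.56, 19.63, 28.26, 38.47)`.
#' @param replicates Replicates per condition. Default 3.
#' @param blood_conc Whole-blood red-cell concentration (cells/uL).
#'   Default 5e6.
#' @param hematocrit Red-cell volume fraction of the input blood.
#'   Default 0.48.
#'
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed,
                       noise_cv = 0.03,
                       interval = 30,
                       duration = 20,
                       areas = c(12.56, 19.63, 28.26, 38.47),
                       replicates = 3,
                       blood_conc = 5e6,
                       hematocrit = 0.48) {
  if (missing(seed) || !is.numeric(seed) || length(seed) != 1 || is.na(seed)) {
    abort("`seed` must be set explicitly (a single integer).")
  }
  if (noise_cv < 0) abort("`noise_cv` must be >= 0.")
  if (interval <= 0 || duration <= 0) abort("`interval` and `duration` must be > 0.")
  if (any(areas <= 0)) abort("`areas` must be > 0.")
  if (replicates < 1) abort("`replicates` must be >= 1.")
  structure(
    list(
      seed = as.integer(seed), noise_cv = noise_cv, interval = interval,
      duration = duration, areas = areas, replicates = replicates,
      blood_conc = blood_conc, hematocrit = hematocrit
    ),
    class = "sim_config"
  )
}

# Multiplicative measurement noise (1 + eps), eps ~ N(0, cv^2) with the lower
# tail truncated at -3 cv so volumes stay positive.
.mult_noise <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  1 + pmax(rnorm(n, 0, cv), -3 * cv)
}

#' Generate a noisy filtration curve
#'
#' Samples the closed-form volume-time law on the configured 30-s grid and
#' applies independent multiplicative Gaussian noise (truncated at -3 cv) to
#' each measurement, emulating image-based volume readout error.
#'
#' @param model A [filtration_model()] (the ground truth).
#' @param A Effective filtration area (mm^2).
#' @param cfg A [sim_config()].
#'
#' @return A [filtration_curve()]; deterministic given `cfg$seed`.
#' @export
gen_filtration_curve <- function(model, A, cfg) {
  stopifnot(inherits(model, "filtration_model"), inherits(cfg, "sim_config"))
  times <- seq(0, cfg$duration * 60, by = cfg$interval)
  ideal <- volume_at_time(model, A, times / 60)
  noisy <- with_seed(cfg$seed, ideal * .mult_noise(length(ideal), cfg$noise_cv))
  filtration_curve(times, noisy, area_mm2 = A, label = sprintf("sim seed %d", cfg$seed))
}

#' Generate a noisy area-volume calibration set
#'
#' For every configured area and replicate, emits the model's steady-state
#' volume perturbed by the same multiplicative noise model as
#' [gen_filtration_curve()]. Each replicate draws from a sub-stream derived
#' deterministically from the base seed.
#'
#' @param model Ground-truth [filtration_model()].
#' @param cfg A [sim_config()]; `areas`, `replicates`, `noise_cv`, `seed`
#'   are used.
#'
#' @return A [calibration_set()] with a `replicate` column and the generating
#'   model stored in the `"truth"` attribute.
#' @export
gen_calibration_set <- function(model, cfg) {
  stopifnot(inherits(model, "filtration_model"), inherits(cfg, "sim_config"))
  grid <- tidyr::expand_grid(replicate = seq_len(cfg$replicates), area_mm2 = cfg$areas)
  vq_true <- steady_state_volume(model, grid$area_mm2)
  noise <- unlist(lapply(seq_len(cfg$replicates), function(r) {
    with_seed(cfg$seed + r - 1L, .mult_noise(length(cfg$areas), cfg$noise_cv))
  }))
  out <- calibration_set(grid$area_mm2, vq_true * noise, replicate = grid$replicate)
  attr(out, "truth") <- model
  out
}

#' Render a synthetic reservoir image at a given plasma fill
#'
#' Emulates a top-down snapshot of the disc reservoir: a circular groove
#' (default 37 mm diameter) with a central boss (default 6 mm diameter).
#' Plasma of volume V occupies area `S = V/h` and is rendered as a bright
#' annulus growing outward from the boss on a dark background, with additive
#' Gaussian pixel noise (sd 5 intensity units). The exact analytic fill area
#' is returned alongside for use as ground truth.
#'
#' @param fill_volume Plasma volume to render (uL); must not exceed the
#'   annular capacity `pi (R_groove^2 - R_boss^2) h`.
#' @param geom A [device_geometry()]; `h` is used.
#' @param pixel_size Rendered pixel edge (micrometres). Default 50.
#' @param cfg A [sim_config()] (for the seed of the pixel noise).
#' @param groove_mm Groove diameter (mm). Default 37.
#' @param boss_mm Central boss diameter (mm). Default 6.
#'
#' @return A [reservoir_image()] with attributes `truth_area_mm2` (analytic
#'   S = V/h) and `truth_volume_uL`.
#' @export
gen_reservoir_image <- function(fill_volume, geom, pixel_size = 50, cfg,
                                groove_mm = 37, boss_mm = 6) {
  stopifnot(inherits(geom, "device_geometry"), inherits(cfg, "sim_config"))
  if (fill_volume < 0) abort("`fill_volume` must be >= 0.")
  r_out_max <- groove_mm / 2
  r_in <- boss_mm / 2
  capacity <- pi * (r_out_max^2 - r_in^2) * geom$h * 1e-3
  if (fill_volume > capacity) {
    abort(sprintf("Overfill: %.3g uL exceeds the %.3g uL reservoir capacity.", fill_volume, capacity))
  }
  S <- fill_volume / (geom$h * 1e-3) # mm^2
  r_fill <- sqrt(S / pi + r_in^2)
  px_mm <- pixel_size * 1e-3
  n <- ceiling(groove_mm / px_mm)
  centre <- (n + 1) / 2
  ax <- (seq_len(n) - centre) * px_mm # pixel-centre coordinates (mm)
  rr <- sqrt(outer(ax^2, ax^2, `+`))
  plasma <- rr >= r_in & rr < r_fill
  img <- matrix(30, n, n)
  img[plasma] <- 200
  img <- with_seed(cfg$seed, img + rnorm(length(img), 0, 5))
  img <- pmin(pmax(img, 0), 255)
  out <- reservoir_image(img, pixel_size)
  attr(out, "truth_area_mm2") <- S
  attr(out, "truth_volume_uL") <- fill_volume
  out
}

#' Simulate hemocytometer counts at a known residue rate
#'
#' Draws Poisson counts for `n_points` sampling positions in each replicate,
#' with per-sample mean `true_residue/100 * blood_conc * sample_volume`
#' (about 200 cells per 0.02-uL point at a 0.2% residue against 5e6 cells/uL
#' whole blood).
#'
#' @param true_residue Generating residue rate, percent, in \[0, 100\].
#' @param cfg A [sim_config()]; `blood_conc`, `replicates`, `seed` are used.
#' @param n_points Sampling points per replicate. Default 5.
#' @param sample_volume Volume per sampling point (uL). Default 0.02.
#'
#' @return A tibble with columns `replicate`, `sample_point`, `cells`,
#'   `volume_uL`; deterministic given `cfg$seed`.
#' @export
gen_cell_count_samples <- function(true_residue, cfg, n_points = 5, sample_volume = 0.02) {
  stopifnot(inherits(cfg, "sim_config"))
  if (true_residue < 0 || true_residue > 100) abort("`true_residue` must be in [0, 100].")
  if (n_points < 1 || sample_volume <= 0) abort("Invalid sampling design.")
  grid <- tidyr::expand_grid(
    replicate = seq_len(cfg$replicates),
    sample_point = seq_len(n_points)
  )
  lambda <- true_residue / 100 * cfg$blood_conc * sample_volume
  cells <- with_seed(cfg$seed, rpois(nrow(grid), lambda))
  tibble::tibble(
    replicate = grid$replicate,
    sample_point = grid$sample_point,
    cells = cells,
    volume_uL = sample_volume
  )
}
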