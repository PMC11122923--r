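#' Fluid properties of the filtrate
#'
#' Bundles the three fluid constants entering the capillary-pressure and
#' filtration-rate expressions: surface tension at the meniscus, contact angle
#' on the channel surface, and dynamic viscosity of the plasma.
#'
#' @param gamma Surface tension (N/m). Must be positive.
#' @param theta Contact angle (degrees), in \[0, 180\]. Hydrophilic surface
#'   treatment lowers this (e.g. 77.8 degrees untreated vs 27 degrees after
#'   albumin passivation), raising the capillary driving pressure.
#' @param mu Dynamic viscosity (Pa s). Must be positive.
#'
#' @return An object of class `fluid_properties`.
#' @examples
#' fluid_properties(gamma = 0.058, theta = 27, mu = 1.5e-3)
#' @export
fluid_properties <- function(gamma, theta, mu) {
  stopifnot(is.numeric(gamma), is.numeric(theta), is.numeric(mu))
  if (gamma <= 0) abort("`gamma` (surface tension) must be > 0.")
  if (theta < 0 || theta > 180) abort("`theta` (contact angle) must lie in [0, 180] degrees.")
  if (mu <= 0) abort("`mu` (viscosity) must be > 0.")
  structure(list(gamma = gamma, theta = theta, mu = mu), class = "fluid_properties")
}

#' Filter-cake properties
#'
#' @param r Specific cake resistance (m^-2). Must be positive.
#' @param v Cake volume deposited per unit filtrate volume (dimensionless).
#'   Must be positive.
#'
#' @return An object of class `cake_properties`.
#' @export
cake_properties <- function(r, v) {
  if (r <= 0) abort("`r` (specific cake resistance) must be > 0.")
  if (v <= 0) abort("`v` (cake volume per unit filtrate) must be > 0.")
  structure(list(r = r, v = v), class = "cake_properties")
}

#' Device geometry
#'
#' Geometry of the separation device: the shallow reservoir microchannel whose
#' height sets the capillary pressure and converts plasma area to volume, and
#' the effective filtration area open to flow through the membrane.
#'
#' @param h Microchannel height (micrometres). Default 80.
#' @param w Microchannel width (micrometres). `Inf` (the default) selects the
#'   thin-slit limit, appropriate when the channel is a wide disc whose lateral
#'   extent dwarfs its height.
#' @param A Effective filtration area (mm^2); may be `NA` when the geometry is
#'   used only for feasibility checks or volume conversion.
#' @param A_min Minimum feasible filtration area (mm^2). Below this bound
#'   capillary forces on the inlet wall stall the filtration; default 7.
#'
#' @return An object of class `device_geometry`.
#' @examples
#' device_geometry(h = 80, A = 28.26)
#' @export
device_geometry <- function(h = 80, w = Inf, A = NA_real_, A_min = 7) {
  if (h <= 0) abort("`h` (channel height) must be > 0.")
  if (is.finite(w) && w <= h) abort("`w` must exceed `h` when bounded.")
  if (!is.na(A) && A < 0) abort("`A` (effective filtration area) must be >= 0.")
  if (A_min < 0) abort("`A_min` must be >= 0.")
  structure(list(h = h, w = w, A = A, A_min = A_min), class = "device_geometry")
}

#' Filtration model parameters
#'
#' The two lumped parameters of the cake-filtration model plus the steady-state
#' threshold. `k` (the filtering constant, 2*dP/(r*mu*v)) sets how fast plasma
#' accumulates; `ve` (the equivalent filtrate volume) is the filtrate volume at
#' which the accumulated cake resistance equals the clean-membrane resistance,
#' and acts as an offset delaying the square-root regime.
#'
#' @param k Filtering constant (uL^2 mm^-4 min^-1). Must be positive.
#' @param ve Equivalent filtrate volume (uL). Must be non-negative.
#' @param q_th Relative-rate threshold (fraction per minute) below which the
#'   separation is declared steady. Default 0.05/min.
#'
#' @return An object of class `filtration_model`.
#' @examples
#' filtration_model(k = 0.05, ve = 4)
#' @export
filtration_model <- function(k, ve, q_th = 0.05) {
  if (!is.numeric(k) || k <= 0) abort("`k` (filtering constant) must be > 0.")
  if (!is.numeric(ve) || ve < 0) abort("`ve` (equivalent filtrate volume) must be >= 0.")
  if (q_th <= 0 || q_th >= 1) abort("`q_th` must lie in (0, 1) per minute.")
  structure(list(k = k, ve = ve, q_th = q_th), class = "filtration_model")
}

#' @export
print.filtration_model <- function(x, ...) {
  cat("<filtration_model>\n")
  cat(sprintf("  k    = %.6g uL^2 mm^-4 min^-1 (filtering constant)\n", x$k))
  cat(sprintf("  Ve   = %.6g uL (equivalent filtrate volume)\n", x$ve))
  cat(sprintf("  q_th = %.3g /min (steady-state threshold)\n", x$q_th))
  invisible(x)
}

#' Capillary driving pressure of a rectangular microchannel
#'
#' Young-Laplace pressure across the meniscus in a rectangular channel,
#' `2 gamma cos(theta) (1/h + 1/w)`. When the width is unbounded (`w = Inf`)
#' this reduces to the thin-slit form `2 gamma cos(theta) / h`, the relevant
#' limit for a wide disc reservoir whose width is thousands of times its
#' height. The sign follows `cos(theta)`: a contact angle above 90 degrees
#' gives a negative (opposing) pressure.
#'
#' @param fluid A [fluid_properties()] object.
#' @param geom A [device_geometry()] object; `h` and `w` are used.
#'
#' @return Capillary pressure in pascals (scalar).
#' @examples
#' # albumin-passivated channel: ~1292 Pa of passive driving pressure
#' capillary_pressure(fluid_properties(0.058, 27, 1.5e-3), device_geometry(h = 80))
#' @export
capillary_pressure <- function(fluid, geom) {
  stopifnot(inherits(fluid, "fluid_properties"), inherits(geom, "device_geometry"))
  h_m <- geom$h * 1e-6
  inv_w <- if (is.finite(geom$w)) 1 / (geom$w * 1e-6) else 0
  2 * fluid$gamma * cospi(fluid$theta / 180) * (1 / h_m + inv_w)
}

# 1 uL^2 mm^-4 = (1e-9 m^3)^2 / (1e-6 m^2)^2 = 1e-6 m^2, and 1/s = 60/min,
# so 1 m^2/s = 6e7 uL^2 mm^-4 min^-1.
.K_SI_TO_CANONICAL <- 6e7

#' Filtering constant from physical properties
#'
#' Computes `k = 2 dP / (r mu v)` in SI (m^2/s) and converts it to the
#' package's canonical unit, uL^2 mm^-4 min^-1 (1 m^2/s = 6e7 of those).
#'
#' @param delta_p Capillary driving pressure (Pa), positive.
#' @param cake A [cake_properties()] object.
#' @param mu Filtrate dynamic viscosity (Pa s), positive.
#'
#' @return Filtering constant k in uL^2 mm^-4 min^-1.
#' @export
filtering_constant <- function(delta_p, cake, mu) {
  stopifnot(inherits(cake, "cake_properties"))
  if (delta_p <= 0) abort("`delta_p` must be > 0 for a physically driven filtration.")
  if (mu <= 0) abort("`mu` must be > 0.")
  k_si <- 2 * delta_p / (cake$r * mu * cake$v)
  k_si * .K_SI_TO_CANONICAL
}

#' Instantaneous filtration rate
#'
#' Rate balance of constant-pressure cake filtration: the accumulated cake
#' (proportional to the filtrate already collected, offset by `ve`) throttles
#' the flow, giving `dV/dtau = k A^2 / (2 (V + Ve))`. Strictly decreasing in
#' the collected volume, vanishing as V grows.
#'
#' @param model A [filtration_model()].
#' @param A Effective filtration area (mm^2).
#' @param V Collected plasma volume (uL), vectorised. `V = 0` with `ve = 0` is
#'   a domain error (the cake-free rate is unbounded).
#'
#' @return Filtration rate in uL/min.
#' @examples
#' filtration_rate(filtration_model(k = 0.1, ve = 2), A = 5, V = 3) # 0.25
#' @export
filtration_rate <- function(model, A, V) {
  stopifnot(inherits(model, "filtration_model"))
  if (any(V < 0)) abort("`V` must be >= 0.")
  if (any(V + model$ve <= 0)) {
    abort("Rate undefined at V = 0 with ve = 0 (no cake, unbounded rate).")
  }
  model$k * A^2 / (2 * (V + model$ve))
}

#' Plasma volume as a function of filtration time
#'
#' Closed-form solution of the filtration rate balance:
#' `V(tau) = sqrt(k A^2 tau + Ve^2) - Ve`. Starts at zero, is nondecreasing
#' and concave in time, and for `ve = 0` reduces to the pure square-root law
#' `A sqrt(k tau)`.
#'
#' @param model A [filtration_model()].
#' @param A Effective filtration area (mm^2).
#' @param tau Filtration time (minutes), vectorised, non-negative.
#'
#' @return Plasma volume in uL.
#' @export
volume_at_time <- function(model, A, tau) {
  stopifnot(inherits(model, "filtration_model"))
  if (any(tau < 0)) abort("`tau` must be >= 0.")
  sqrt(model$k * A^2 * tau + model$ve^2) - model$ve
}

#' Relative volumetric growth rate q
#'
#' The separation is declared steady once the plasma volume grows by at most
#' a threshold fraction per minute: `q = (dV/dtau)/V = k A^2 / (2 V (V + Ve))`.
#' Strictly decreasing in V; equals `model$q_th` exactly at the steady-state
#' volume returned by [steady_state_volume()].
#'
#' @param model A [filtration_model()].
#' @param A Effective filtration area (mm^2).
#' @param V Collected plasma volume (uL), strictly positive, vectorised.
#'
#' @return Relative growth rate in fraction per minute.
#' @export
relative_rate_q <- function(model, A, V) {
  stopifnot(inherits(model, "filtration_model"))
  if (any(V <= 0)) abort("`V` must be > 0 (q is a relative rate).")
  model$k * A^2 / (2 * V * (V + model$ve))
}

#' Steady-state plasma volume for a given filtration area
#'
#' Solves `q(V) = q_th` for V: `Vq = sqrt(k A^2 / (2 q_th) + Ve^2/4) - Ve/2`.
#' At the default threshold 0.05/min this is `sqrt(10 k A^2 + 0.25 Ve^2) -
#' 0.5 Ve`. Strictly increasing and (for `ve > 0`) strictly convex in A; the
#' quantitative-design workhorse.
#'
#' @param model A [filtration_model()].
#' @param A Effective filtration area (mm^2), non-negative, vectorised.
#'
#' @return Steady-state plasma volume Vq in uL.
#' @examples
#' steady_state_volume(filtration_model(k = 0.1, ve = 2), A = 5) # sqrt(26) - 1
#' @export
steady_state_volume <- function(model, A) {
  stopifnot(inherits(model, "filtration_model"))
  if (any(A < 0)) abort("`A` must be >= 0.")
  sqrt(model$k * A^2 / (2 * model$q_th) + 0.25 * model$ve^2) - 0.5 * model$ve
}

#' Time to reach the steady state
#'
#' Inverts the volume-time law at `V = Vq`:
#' `tau_q = (Vq^2 + 2 Vq Ve) / (k A^2)`. For `ve = 0` this is exactly
#' `1/(2 q_th)` (10 min at the default threshold); it increases with `ve` but
#' is always below `1/q_th` (20 min at the default), so a separation obeying
#' this model completes within 20 minutes.
#'
#' @param model A [filtration_model()].
#' @param A Effective filtration area (mm^2), strictly positive.
#'
#' @return Steady-state time tau_q in minutes.
#' @export
steady_state_time <- function(model, A) {
  stopifnot(inherits(model, "filtration_model"))
  if (any(A <= 0)) abort("`A` must be > 0.")
  vq <- steady_state_volume(model, A)
  (vq^2 + 2 * vq * model$ve) / (model$k * A^2)
}

#' Sensitivity of the steady-state volume to the filtration area
#'
#' First and second derivatives of [steady_state_volume()] with respect to A:
#' `dVq/dA = c A / sqrt(c A^2 + Ve^2/4)` and
#' `d2Vq/dA2 = (c Ve^2/4) / (c A^2 + Ve^2/4)^(3/2)`, with `c = k/(2 q_th)`.
#' The first derivative is strictly positive (larger membranes always collect
#' more plasma) and the second is non-negative, vanishing only when `ve = 0`
#' (the linear regime `Vq = A sqrt(c)`).
#'
#' @param model A [filtration_model()].
#' @param A Effective filtration area (mm^2), non-negative, vectorised.
#'
#' @return `dVq_dA()`: derivative in uL/mm^2. `d2Vq_dA2()`: second derivative
#'   in uL/mm^4.
#' @export
dVq_dA <- function(model, A) {
  stopifnot(inherits(model, "filtration_model"))
  if (any(A < 0)) abort("`A` must be >= 0.")
  cc <- model$k / (2 * model$q_th)
  if (model$ve == 0) {
    # linear regime: Vq = A sqrt(c); right-derivative at A = 0 included
    return(rep_len(sqrt(cc), length(A)))
  }
  cc * A / sqrt(cc * A^2 + 0.25 * model$ve^2)
}

#' @rdname dVq_dA
#' @export
d2Vq_dA2 <- function(model, A) {
  stopifnot(inherits(model, "filtration_model"))
  if (any(A < 0)) abort("`A` must be >= 0.")
  cc <- model$k / (2 * model$q_th)
  cc * 0.25 * model$ve^2 / (cc * A^2 + 0.25 * model$ve^2)^1.5
}
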