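#' Flat-punch indenter geometry
#'
#' A cylindrical flat punch of diameter `d`; the contact area is
#' \eqn{A = \pi d^2 / 4}.
#'
#' @param diameter_m Punch diameter in meters (default 1.5 mm).
#' @return A list of class `indenter_geometry` with `diameter_m` and
#'   `area_m2`.
#' @export
indenter_geometry <- function(diameter_m = 1.5e-3) {
  d <- check_positive(diameter_m, "diameter_m")
  structure(list(diameter_m = d, area_m2 = pi * d^2 / 4),
            class = "indenter_geometry")
}

check_poisson <- function(poisson) {
  if (!is.numeric(poisson) || length(poisson) != 1L ||
      poisson <= -1 || poisson > 0.5) {
    stop("'poisson' must lie in (-1, 0.5]", call. = FALSE)
  }
  poisson
}

# common geometric factor sqrt(pi) / (2 sqrt(A)); equals 1/d for a flat
# punch with A = pi d^2 / 4
punch_factor <- function(geom) sqrt(pi) / (2 * sqrt(geom$area_m2))

#' Elastic shear modulus from quasi-static flat-punch indentation
#'
#' Converts the quasi-static contact stiffness \eqn{k_s} (the mean slope of
#' the loading curve at the test depth) into the elastic shear modulus
#' \deqn{G = \frac{1 - \nu^2}{2(1+\nu)}\, k_s \frac{\sqrt{\pi}}{2\sqrt{A}},}
#' which for an incompressible tissue (\eqn{\nu = 0.5}) and flat-punch area
#' \eqn{A = \pi d^2/4} reduces exactly to \eqn{G = k_s / (4d)}.
#'
#' @param contact_stiffness Quasi-static contact stiffness \eqn{k_s} in N/m
#'   (>= 0).
#' @param geom An [indenter_geometry()].
#' @param poisson Poisson ratio (default 0.5, incompressibility).
#' @param correction Optional multiplicative correction for finite sample
#'   thickness (default 1: uncorrected, matching thick-slice measurements
#'   with no-slip support where the correction was deliberately not applied).
#' @return Elastic shear modulus in kPa.
#' @export
elastic_shear_modulus <- function(contact_stiffness, geom = indenter_geometry(),
                                  poisson = 0.5, correction = 1) {
  if (any(contact_stiffness < 0)) stop("'contact_stiffness' must be >= 0", call. = FALSE)
  check_poisson(poisson)
  g_pa <- (1 - poisson^2) / (2 * (1 + poisson)) *
    contact_stiffness * punch_factor(geom) * correction
  g_pa / 1000
}

#' Storage and loss moduli from dynamic flat-punch indentation
#'
#' Converts the dynamic contact stiffness \eqn{k_d} and the damping term
#' \eqn{\omega C_d} into storage and loss shear moduli,
#' \deqn{G' = \frac{1}{2(1+\nu)} k_d \frac{\sqrt{\pi}}{2\sqrt{A}}, \qquad
#'       G'' = \frac{1}{2(1+\nu)} \omega C_d \frac{\sqrt{\pi}}{2\sqrt{A}},}
#' reducing to \eqn{k_d/(3d)} and \eqn{\omega C_d/(3d)} at \eqn{\nu = 0.5}.
#'
#' @param dynamic_stiffness \eqn{k_d} in N/m (>= 0).
#' @param damping_times_omega \eqn{\omega C_d} in N/m (>= 0).
#' @inheritParams elastic_shear_modulus
#' @return A data.frame with columns `storage_kpa`, `loss_kpa`.
#' @export
indentation_moduli <- function(dynamic_stiffness, damping_times_omega,
                               geom = indenter_geometry(), poisson = 0.5,
                               correction = 1) {
  if (any(dynamic_stiffness < 0) || any(damping_times_omega < 0)) {
    stop("stiffness terms must be >= 0", call. = FALSE)
  }
  check_poisson(poisson)
  fac <- punch_factor(geom) * correction / (2 * (1 + poisson))
  data.frame(storage_kpa = dynamic_stiffness * fac / 1000,
             loss_kpa = damping_times_omega * fac / 1000)
}

#' Contact stiffness as the mean loading-curve slope at a depth
#'
#' Least-squares slope of load versus displacement over a window centered on
#' the target depth, the quasi-static contact stiffness used by
#' [elastic_shear_modulus()].
#'
#' @param displacement_m Displacement samples in meters (monotone over the
#'   window).
#' @param load_n Load samples in newtons, same length.
#' @param at_depth Window center in meters.
#' @param window Window width in meters (default 10% of `at_depth`).
#' @return Slope \eqn{k_s} in N/m.
#' @export
contact_stiffness_from_curve <- function(displacement_m, load_n, at_depth,
                                         window = 0.1 * at_depth) {
  if (length(displacement_m) != length(load_n)) {
    stop("displacement and load must have equal length", call. = FALSE)
  }
  sel <- displacement_m >= at_depth - window / 2 &
    displacement_m <= at_depth + window / 2
  if (sum(sel) < 3L) {
    stop("fewer than 3 samples in the slope window", call. = FALSE)
  }
  x <- displacement_m[sel]
  if (is.unsorted(x) && is.unsorted(rev(x))) {
    stop("loading curve must be monotone over the window", call. = FALSE)
  }
  unname(stats::coef(stats::lm(load_n[sel] ~ x))[2L])
}

#' Average strain under a flat punch
#'
#' For a flat punch of diameter `d` indented to depth \eqn{\delta}, the
#' average strain is \eqn{4\delta / (\pi d)}; its inverse gives the depth for
#' a target strain (a 1% linear-regime strain with a 1.5 mm punch requires a
#' depth of about 11.8 micrometers).
#'
#' @param depth_m Indentation depth in meters (>= 0).
#' @param geom An [indenter_geometry()].
#' @return Dimensionless average strain.
#' @export
average_strain <- function(depth_m, geom = indenter_geometry()) {
  if (any(depth_m < 0)) stop("'depth_m' must be >= 0", call. = FALSE)
  4 * depth_m / (pi * geom$diameter_m)
}
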