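#' Rheological model constructors
#'
#' Build a parameter object for one of the four linear viscoelastic models
#' used to describe the frequency-dependent shear behavior of brain tissue:
#'
#' * **Maxwell** — spring and dashpot in series, \eqn{G(\omega) = i\omega\eta\mu /
#'   (\mu + i\omega\eta)}. Zero storage modulus in the quasi-static limit.
#' * **Voigt** (Kelvin–Voigt) — spring and dashpot in parallel,
#'   \eqn{G(\omega) = \mu + i\omega\eta}. Constant, frequency-independent
#'   storage modulus.
#' * **Springpot** — fractional-order element \eqn{G(\omega) = \kappa(i\omega)^\alpha},
#'   interpolating a spring (\eqn{\alpha = 0}) and a dashpot (\eqn{\alpha = 1}).
#' * **Standard linear solid** (Zener) — spring in parallel with a Maxwell
#'   branch, \eqn{G(\omega) = (\mu_1\mu_2 + i\omega\eta(\mu_1+\mu_2)) /
#'   (\mu_2 + i\omega\eta)}. Finite stiffness at both frequency limits:
#'   \eqn{\mu_1} quasi-statically, \eqn{\mu_1 + \mu_2} at infinite frequency.
#'
#' Stiffness parameters are in kPa, viscosities in kPa s, and the springpot
#' coefficient \eqn{\kappa} carries units kPa s\eqn{^\alpha}. All parameters
#' must be strictly positive; the springpot exponent must lie in \eqn{[0, 1]}.
#'
#' @param mu,mu1,mu2 Shear stiffness in kPa.
#' @param eta Viscosity in kPa s.
#' @param kappa Springpot stiffness-like coefficient in kPa s^alpha.
#' @param alpha Springpot fractional exponent, dimensionless in \[0, 1\].
#' @return An object of class `rheo_model` (subclass per model kind) holding
#'   the named parameters.
#' @examples
#' m <- maxwell(mu = 1.0, eta = 0.01)
#' dynamic_modulus(m, omega = 2 * pi * 80)
#' @name rheo_model
NULL

new_rheo_model <- function(kind, params) {
  structure(as.list(params), kind = kind, class = c(kind, "rheo_model"))
}

check_positive <- function(x, name) {
  if (length(x) != 1L || !is.numeric(x) || !is.finite(x) || x <= 0) {
    stop("'", name, "' must be a single finite value > 0", call. = FALSE)
  }
  as.numeric(x)
}

#' @rdname rheo_model
#' @export
maxwell <- function(mu, eta) {
  new_rheo_model("maxwell", list(mu = check_positive(mu, "mu"),
                                 eta = check_positive(eta, "eta")))
}

#' @rdname rheo_model
#' @export
voigt <- function(mu, eta) {
  new_rheo_model("voigt", list(mu = check_positive(mu, "mu"),
                               eta = check_positive(eta, "eta")))
}

#' @rdname rheo_model
#' @export
springpot <- function(kappa, alpha) {
  kappa <- check_positive(kappa, "kappa")
  if (length(alpha) != 1L || !is.finite(alpha) || alpha < 0 || alpha > 1) {
    stop("'alpha' must lie in [0, 1]", call. = FALSE)
  }
  new_rheo_model("springpot", list(kappa = kappa, alpha = as.numeric(alpha)))
}

#' @rdname rheo_model
#' @export
sls <- function(mu1, mu2, eta) {
  new_rheo_model("sls", list(mu1 = check_positive(mu1, "mu1"),
                             mu2 = check_positive(mu2, "mu2"),
                             eta = check_positive(eta, "eta")))
}

#' @export
print.rheo_model <- function(x, ...) {
  labels <- c(maxwell = "Maxwell (spring-dashpot series)",
              voigt = "Voigt (spring-dashpot parallel)",
              springpot = "Springpot (fractional element)",
              sls = "Standard linear solid (Zener)")
  cat(labels[[attr(x, "kind")]], "model\n")
  p <- unlist(x)
  cat(paste0("  ", names(p), " = ", format(p, digits = 6), collapse = "\n"), "\n")
  invisible(x)
}

model_kind <- function(params) attr(params, "kind")

#' Convert actuation frequency in Hz to angular frequency in rad/s
#'
#' All model formulas are written in angular frequency \eqn{\omega = 2\pi f};
#' measured sweeps report actuation frequency in Hz.
#'
#' @param f_hz Frequency in Hz.
#' @return Angular frequency in rad/s.
#' @export
hz_to_omega <- function(f_hz) 2 * pi * f_hz

#' Complex dynamic shear modulus of a rheological model
#'
#' Evaluates \eqn{G(\omega) = G'(\omega) + iG''(\omega)} for a model at the
#' given angular frequencies and splits it into storage and loss parts.
#' The springpot uses the principal branch \eqn{(i\omega)^\alpha =
#' \omega^\alpha e^{i\pi\alpha/2}}, which keeps both moduli non-negative for
#' \eqn{\alpha \in [0, 1]}.
#'
#' @param params A `rheo_model` object.
#' @param omega Angular frequency in rad/s (vectorized, each >= 0).
#' @return A data.frame with columns `omega`, `storage_kpa`, `loss_kpa`.
#' @export
dynamic_modulus <- function(params, omega) {
  UseMethod("dynamic_modulus")
}

check_omega <- function(omega) {
  if (!is.numeric(omega) || any(!is.finite(omega)) || any(omega < 0)) {
    stop("'omega' must be finite and >= 0", call. = FALSE)
  }
  as.numeric(omega)
}

modulus_frame <- function(omega, g) {
  data.frame(omega = omega, storage_kpa = Re(g), loss_kpa = Im(g))
}

#' @export
dynamic_modulus.maxwell <- function(params, omega) {
  omega <- check_omega(omega)
  we <- omega * params$eta
  # iwem/(m + iwe) decomposed; avoids 0/0 at omega = 0
  denom <- params$mu^2 + we^2
  modulus_frame(omega, complex(real = params$mu * we^2 / denom,
                               imaginary = params$mu^2 * we / denom))
}

#' @export
dynamic_modulus.voigt <- function(params, omega) {
  omega <- check_omega(omega)
  modulus_frame(omega, complex(real = rep(params$mu, length(omega)),
                               imaginary = omega * params$eta))
}

#' @export
dynamic_modulus.springpot <- function(params, omega) {
  omega <- check_omega(omega)
  mag <- params$kappa * omega^params$alpha
  modulus_frame(omega, complex(real = mag * cos(pi * params$alpha / 2),
                               imaginary = mag * sin(pi * params$alpha / 2)))
}

#' @export
dynamic_modulus.sls <- function(params, omega) {
  omega <- check_omega(omega)
  we <- omega * params$eta
  denom <- params$mu2^2 + we^2
  gp <- (params$mu1 * params$mu2^2 + we^2 * (params$mu1 + params$mu2)) / denom
  gpp <- we * params$mu2^2 / denom
  modulus_frame(omega, complex(real = gp, imaginary = gpp))
}

#' Effective shear stiffness
#'
#' The magnitude of the complex shear modulus,
#' \eqn{G^{eff} = [G'^2 + G''^2]^{1/2}}, a scalar stiffness summary used to
#' compare elastograms across conditions.
#'
#' @param storage_kpa Storage modulus G' in kPa.
#' @param loss_kpa Loss modulus G'' in kPa.
#' @return Effective shear stiffness in kPa (vectorized).
#' @export
effective_stiffness <- function(storage_kpa, loss_kpa) {
  if (any(!is.finite(storage_kpa)) || any(!is.finite(loss_kpa))) {
    stop("moduli must be finite", call. = FALSE)
  }
  sqrt(storage_kpa^2 + loss_kpa^2)
}

#' Frequency limits of the storage modulus
#'
#' `quasistatic_limit()` returns the storage modulus as \eqn{\omega \to 0};
#' `infinite_frequency_limit()` as \eqn{\omega \to \infty}. Maxwell and
#' springpot models predict a (non-physical, for solid tissue) zero
#' quasi-static storage modulus; Voigt and the standard linear solid predict
#' finite values at both limits. The springpot storage modulus grows without
#' bound at high frequency for \eqn{\alpha > 0}, in which case
#' `infinite_frequency_limit()` returns `Inf`.
#'
#' @param params A `rheo_model` object.
#' @return Storage modulus in kPa (possibly 0 or `Inf`).
#' @export
quasistatic_limit <- function(params) {
  switch(model_kind(params),
         maxwell = 0,
         voigt = params$mu,
         springpot = if (params$alpha > 0) 0 else params$kappa,
         sls = params$mu1)
}

#' @rdname quasistatic_limit
#' @export
infinite_frequency_limit <- function(params) {
  switch(model_kind(params),
         maxwell = params$mu,
         voigt = params$mu,
         springpot = if (params$alpha > 0) Inf else params$kappa,
         sls = params$mu1 + params$mu2)
}
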