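# Independent complex-arithmetic oracle for the model moduli: evaluate each
# model's G(omega) literally as written, never through the package's
# closed-form decompositions.
oracle_modulus <- function(params, omega) {
  p <- unlist(unclass(params))
  switch(class(params)[1L],
         maxwell = (1i * omega * p["eta"] * p["mu"]) /
           (p["mu"] + 1i * omega * p["eta"]),
         voigt = p["mu"] + 1i * omega * p["eta"],
         springpot = p["kappa"] * (1i * omega)^p["alpha"],
         sls = (p["mu1"] * p["mu2"] + 1i * omega * p["eta"] * (p["mu1"] + p["mu2"])) /
           (p["mu2"] + 1i * omega * p["eta"]))
}

# analytic plane-wave field on an n^3 grid, propagation along x
plane_wave_field <- function(gstar_kpa, n = 24, h_mm = 1, f = 80, rho = 1000) {
  k <- hz_to_omega(f) * sqrt(rho / (gstar_kpa * 1000))
  x <- (seq_len(n) - 1) * h_mm * 1e-3
  array(rep(exp(-1i * k * x), times = n * n), c(n, n, n))
}

random_model <- function(kind) {
  mu <- exp(stats::runif(2, log(0.1), log(4)))
  eta <- exp(stats::runif(1, log(0.01), log(1)))
  switch(kind,
         maxwell = maxwell(mu[1L], eta),
         voigt = voigt(mu[1L], eta),
         springpot = springpot(mu[1L], stats::runif(1, 0.05, 0.95)),
         sls = sls(mu[1L], mu[2L], eta))
}
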