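test_that("objective is zero iff the model matches the sweep exactly", {
  truth <- sls(0.8, 0.6, 0.002)
  sw <- make_sweep(truth, noise_sd = 0)
  expect_equal(objective_phi(sw, truth), 0)
  expect_gt(objective_phi(sw, sls(0.81, 0.6, 0.002)), 0)
})

test_that("objective matches a hand-evaluated two-frequency case", {
  # Voigt(1.1, 0.001): loss is omega*eta exactly; feed a sweep whose loss
  # equals the model's, and whose storage (1, 1) the model overshoots by
  # 10%: phi = (0.1^2 + 0.1^2) / (2 * 2) = 0.005
  eta <- 0.001
  sw <- frequency_sweep(c(40, 80), c(1, 1), hz_to_omega(c(40, 80)) * eta)
  expect_equal(objective_phi(sw, voigt(1.1, eta)), 0.005, tolerance = 1e-12)
  # single frequency, 10% relative error on storage only:
  # phi = 0.1^2 / 2 = 0.005, reported error 100 sqrt(phi) ~ 7.07%
  sw1 <- frequency_sweep(80, 1, hz_to_omega(80) * eta)
  phi1 <- objective_phi(sw1, voigt(1.1, eta))
  expect_equal(phi1, 0.005, tolerance = 1e-12)
  expect_equal(100 * sqrt(phi1), 7.0710678, tolerance = 1e-6)
})

test_that("objective is invariant under joint rescaling of data and model", {
  sw <- make_sweep(sls(0.9, 0.5, 0.003), noise_sd = 0)
  m <- maxwell(1.2, 0.01)
  phi1 <- objective_phi(sw, m)
  # scale both experimental and model moduli by 3: relative errors unchanged
  sw3 <- frequency_sweep(sw$frequency_hz, 3 * sw$storage_kpa, 3 * sw$loss_kpa)
  m3 <- maxwell(3 * 1.2, 3 * 0.01)
  expect_equal(objective_phi(sw3, m3), phi1, tolerance = 1e-12)
})

test_that("objective rejects zero moduli and mismatched input", {
  expect_error(frequency_sweep(40, 0, 0.5) |> objective_phi(maxwell(1, 0.1)),
               "positive")
})

test_that("single fits recover generating parameters from clean sweeps", {
  sw <- make_sweep(voigt(0.9, 0.002), noise_sd = 0)
  f <- fit_single(sw, "voigt", c(mu = 1.0, eta = 0.01))
  expect_lt(f$phi, 1e-10)
  expect_equal(coef_vec <- unlist(unclass(f$params)),
               c(mu = 0.9, eta = 0.002), tolerance = 1e-4)

  sw2 <- make_sweep(maxwell(1.0, 0.01), noise_sd = 0)
  f2 <- fit_single(sw2, "maxwell", c(mu = 0.1, eta = 1.0))
  expect_equal(unname(unlist(unclass(f2$params))), c(1.0, 0.01),
               tolerance = 1e-3)
  expect_equal(f2$error_pct, 100 * sqrt(f2$phi), tolerance = 1e-9)
})

test_that("springpot fit of nearly elastic data drives alpha to the boundary", {
  w <- hz_to_omega(c(40, 60, 80, 90, 100))
  sw <- frequency_sweep(c(40, 60, 80, 90, 100),
                        rep(1, 5), rep(1e-6, 5))
  f <- fit_single(sw, "springpot", c(kappa = 1, alpha = 0.5))
  expect_lt(f$params$alpha, 1e-3)
  expect_true(is.finite(f$phi))
})

test_that("multi-start fitting recovers SLS and reports sorted top-k", {
  truth <- sls(0.5, 0.5, 0.01)
  sw <- make_sweep(truth, noise_sd = 0)
  fit <- rheofit(sw, "sls", multistart_config(n_starts = 200))
  expect_lt(fit$phi, 1e-8)
  fc <- coef(fit)
  expect_equal(unname(fc["mu1"] + fc["mu2"]), 1.0, tolerance = 0.01)
  expect_equal(unname(fc["eta"]), 0.01, tolerance = 0.01)
  phis <- vapply(fit$top_k, `[[`, numeric(1), "phi")
  expect_true(all(diff(phis) >= 0))
  expect_identical(fit$top_k[[1]]$phi, fit$phi)
})

test_that("top_k has length one when only one start is requested", {
  sw <- make_sweep(maxwell(1, 0.01), noise_sd = 0)
  fit <- rheofit(sw, "maxwell", multistart_config(n_starts = 1))
  expect_length(fit$top_k, 1)
})

test_that("identical sweep and configuration give identical fits", {
  sw <- make_sweep(sls(0.83, 0.6, 0.0012), noise_sd = 0.01, seed = 7)
  f1 <- rheofit(sw, "sls", multistart_config(n_starts = 27, seed = 3))
  f2 <- rheofit(sw, "sls", multistart_config(n_starts = 27, seed = 3))
  expect_identical(coef(f1), coef(f2))
  expect_identical(f1$phi, f2$phi)
})

test_that("start lattice covers the configured ranges and respects n_starts", {
  cfg <- multistart_config(n_starts = 20, seed = 1)
  lat2 <- brainrheo:::start_lattice("maxwell", cfg)
  expect_lte(nrow(lat2), 20)
  expect_true(all(lat2[, "mu"] >= 0.1 & lat2[, "mu"] <= 4.0))
  expect_true(all(lat2[, "eta"] >= 0.01 & lat2[, "eta"] <= 1.0))
  lat3 <- brainrheo:::start_lattice("sls", multistart_config(n_starts = 27))
  expect_equal(nrow(lat3), 27)
  expect_error(multistart_config(n_starts = 0), "n_starts")
  expect_error(multistart_config(mu_range = c(2, 1)), "mu_range")
})

test_that("noisy sweeps give error_pct on the scale of the noise", {
  set.seed(21)
  errs <- vapply(1:5, function(i) {
    sw <- make_sweep(sls(0.83, 0.6, 0.0012), noise_sd = 0.01)
    rheofit(sw, "sls", multistart_config(n_starts = 27))$error_pct
  }, numeric(1))
  # 1% multiplicative noise -> O(1%) normalized RMS error, far below the
  # 6-28% misfit scale seen when a model class cannot follow the data
  expect_true(all(errs < 5))
  expect_true(mean(errs) > 0.1)
})

test_that("fit methods: predict, residuals, simulate, summary, report", {
  truth <- sls(0.83, 0.6, 0.0012)
  sw <- make_sweep(truth, noise_sd = 0)
  fit <- rheofit(sw, "sls", multistart_config(n_starts = 27))
  pred <- predict(fit)
  expect_equal(pred$storage_kpa, sw$storage_kpa, tolerance = 1e-6)
  res <- residuals(fit)
  expect_true(all(abs(res$storage) < 1e-6))
  sims <- simulate(fit, nsim = 2, seed = 5, noise_sd = 0.02)
  expect_length(sims, 2)
  expect_s3_class(sims[[1]], "frequency_sweep")
  s <- summary(fit)
  expect_s3_class(s, "summary.rheofit")
  expect_true(all(diff(s$top$phi) >= 0))
  path <- tempfile(fileext = ".json")
  write_fit_report(fit, path)
  rep <- jsonlite::read_json(path)
  expect_equal(rep$model_kind, "sls")
  expect_equal(rep$params$mu1, unname(coef(fit)["mu1"]), tolerance = 1e-8)
  expect_length(rep$top_k, 5)
})
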