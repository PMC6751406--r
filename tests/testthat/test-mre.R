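test_that("plane-wave wavenumber and attenuation behave physically", {
  # homogeneous stiffness: k = omega sqrt(rho/G) ~ 410 rad/m at 80 Hz,
  # G = 1.5 kPa, rho = 1000 -> wavelength ~ 15.3 mm
  k <- hz_to_omega(80) * sqrt(1000 / 1500)
  expect_equal(k, 410.4159, tolerance = 1e-4)
  expect_equal(2 * pi / k * 1000, 15.31, tolerance = 1e-3)

  params <- region_sls_defaults()
  phantom <- make_phantom(region_params = params)
  wf <- simulate_wave_field(phantom, 80)
  expect_s3_class(wf, "wave_field")
  expect_equal(dim(wf$snapshots)[4], 8)

  # amplitude zero -> identically zero field
  wf0 <- simulate_wave_field(phantom, 80, amplitude = 0)
  expect_true(all(Mod(wf0$complex_field) == 0))

  # lossy region: |u| strictly decreasing along propagation
  mid <- 16
  line <- Mod(wf$complex_field[, mid, mid])
  inside <- phantom$labels[, mid, mid] == 1
  expect_true(all(diff(line[inside]) < 0))
})

test_that("wave simulation validates inputs", {
  phantom <- make_phantom()
  expect_error(simulate_wave_field(phantom, -1), "frequency")
  expect_error(simulate_wave_field(phantom, 80, direction = c(1, 1, 0)),
               "unit")
})

test_that("demodulation is the exact DFT of a pure tone", {
  th <- 2 * pi * (0:7) / 8
  a <- 2.5
  phi0 <- pi / 3
  snaps <- array(a * cos(th + phi0), c(1, 1, 1, 8))
  u <- demodulate(snaps)
  expect_equal(as.complex(u), a * exp(1i * phi0), tolerance = 1e-12)

  # a pure second harmonic contributes nothing to the fundamental
  snaps2 <- array(cos(2 * th), c(1, 1, 1, 8))
  expect_equal(Mod(as.complex(demodulate(snaps2))), 0, tolerance = 1e-12)

  expect_error(demodulate(array(0, c(2, 2, 2, 7))), "8 phase")
})

test_that("demodulating the simulated snapshots recovers the complex field", {
  phantom <- make_phantom()
  wf <- simulate_wave_field(phantom, 80)
  rec <- demodulate(wf$snapshots)
  expect_equal(rec, wf$complex_field, tolerance = 1e-12)
})

test_that("Helmholtz inversion recovers the modulus of an analytic plane wave", {
  for (gstar in c(complex(real = 1.5, imaginary = 0),
                  complex(real = 1.2, imaginary = 0.4))) {
    field <- plane_wave_field(gstar, n = 24, h_mm = 1)
    e <- helmholtz_invert(field, 80, 1)
    expect_true(any(e$valid))
    # discretization bound: the 7-point stencil biases G by rho omega^2 h^2/12
    bound <- 1.3 * 1000 * hz_to_omega(80)^2 * (1e-3)^2 / 12 / 1000  # kPa
    expect_lt(max(abs(e$storage_kpa[e$valid] - Re(gstar))), bound)
    expect_lt(max(abs(e$loss_kpa[e$valid] - Im(gstar))), bound)
  }
})

test_that("halving the voxel spacing cuts the inversion error about 4x", {
  gstar <- complex(real = 1.2, imaginary = 0.4)
  err <- vapply(c(1, 0.5), function(h) {
    e <- helmholtz_invert(plane_wave_field(gstar, n = 24, h_mm = h), 80, h)
    max(abs(e$storage_kpa[e$valid] - Re(gstar)))
  }, numeric(1))
  expect_gt(err[1] / err[2], 3.2)
  expect_lt(err[1] / err[2], 4.8)
})

test_that("constant fields and grid boundaries are marked invalid", {
  field <- array(complex(real = 1, imaginary = 0), c(8, 8, 8))
  e <- helmholtz_invert(field, 80, 1)
  expect_false(any(e$valid))
  e2 <- helmholtz_invert(plane_wave_field(1.5, n = 10), 80, 1)
  expect_false(any(e2$valid[1, , ] | e2$valid[10, , ]))
})

test_that("region summary reproduces the hand-computed far-outlier example", {
  s <- region_statistics(c(1, 2, 3, 4, 100))
  expect_equal(s$q1, 2)
  expect_equal(s$q3, 4)
  expect_equal(s$iqr, 2)
  expect_equal(s$fence_low, -4)
  expect_equal(s$fence_high, 10)
  expect_identical(s$outliers, 100)
  expect_equal(region_statistics(c(1, 2, 3, 4))$median, 2.5)
  sc <- region_statistics(rep(1.13, 20))
  expect_true(all(c(sc$median, sc$q1, sc$q3, sc$min, sc$max) == 1.13))
  expect_length(sc$outliers, 0)
  expect_error(region_statistics(numeric(0)), "empty")
  expect_error(region_statistics(c(1, 2), mask = c(FALSE, FALSE)), "empty")
})

test_that("region summary ordering invariants hold on random inputs", {
  set.seed(31)
  for (i in 1:1000) {
    n <- sample(1:60, 1)
    x <- switch(sample(3, 1),
                rnorm(n), rlnorm(n, sdlog = 2), rt(n, df = 2))
    s <- region_statistics(x)
    expect_true(s$min <= s$q1 && s$q1 <= s$median &&
                  s$median <= s$q3 && s$q3 <= s$max)
    expect_true(all(s$outliers < s$fence_low | s$outliers > s$fence_high))
    expect_equal(s$iqr, s$q3 - s$q1)
  }
})

test_that("end-to-end: region medians recover the ground-truth moduli", {
  params <- region_sls_defaults()
  phantom <- make_phantom(region_params = params)
  wf <- simulate_wave_field(phantom, 80)
  elast <- helmholtz_invert(demodulate(wf$snapshots), 80, 1)
  gs <- summarize_regions(elast, phantom, "storage")
  gl <- summarize_regions(elast, phantom, "loss")
  for (i in seq_len(nrow(gs))) {
    truth <- dynamic_modulus(params[[gs$region[i]]], hz_to_omega(80))
    expect_equal(gs$median[i], truth$storage_kpa, tolerance = 0.05)
    expect_equal(gl$median[i], truth$loss_kpa, tolerance = 0.05)
  }
})

test_that("multiplicative stiffening of a region propagates to its median", {
  params <- region_sls_defaults()
  c_fac <- 1.6
  stiffer <- params
  p <- stiffer$thalamus
  stiffer$thalamus <- sls(c_fac * p$mu1, c_fac * p$mu2, c_fac * p$eta)
  med <- function(pars) {
    ph <- make_phantom(region_params = pars)
    e <- helmholtz_invert(simulate_wave_field(ph, 80), 80, 1)
    g <- summarize_regions(e, ph, "storage")
    g$median[g$region == "thalamus"]
  }
  # scaling all SLS parameters by c scales G' by c (eta scaling shifts the
  # relaxation frequency, so allow the discretization-level tolerance)
  expect_equal(med(stiffer) / med(params), c_fac, tolerance = 0.05)
})

test_that("percent change matches its reciprocal identity and examples", {
  expect_equal(percent_change(1.13, 1.42), 25.66372, tolerance = 1e-6)
  expect_equal(percent_change(0.30, 0.48), 60)
  expect_equal(percent_change(2.2, 2.2), 0)
  set.seed(32)
  a <- rlnorm(50)
  b <- rlnorm(50)
  lhs <- (1 + percent_change(a, b) / 100) * (1 + percent_change(b, a) / 100)
  expect_equal(lhs, rep(1, 50), tolerance = 1e-12)
  expect_error(percent_change(0, 1), "before")
})

test_that("volumes round-trip through NIfTI-1", {
  vol <- array(rnorm(16^3), c(16, 16, 16))
  path <- tempfile(fileext = ".nii")
  write_volume(vol, path, spacing_mm = 0.5)
  back <- read_volume(path)
  expect_equal(array(back, dim(back)), vol, tolerance = 1e-6)
  expect_equal(attr(back, "spacing_mm"), 0.5)
})
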