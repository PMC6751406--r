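test_that("packaged moduli table matches the printed values byte-for-byte", {
  tab <- brain_moduli_table()
  expect_equal(nrow(tab), 25)
  # 50 cells minus the 8 unmeasured ex vivo entries = 42 printed numbers
  expect_equal(sum(is.finite(tab$storage_kpa)) + sum(is.finite(tab$loss_kpa)),
               42)
  get <- function(reg, tp, what) {
    tab[tab$region == reg & tab$timepoint == tp, paste0(what, "_kpa")]
  }
  expect_identical(get("cerebrum", "in_vivo", "storage"), 1.13)
  expect_identical(get("cerebrum", "in_vivo", "loss"), 0.30)
  expect_identical(get("cerebrum", "pm_3min", "storage"), 1.42)
  expect_identical(get("cerebrum", "pm_45min", "loss"), 0.61)
  expect_identical(get("cerebrum", "ex_vivo_16h", "loss"), 2.36)
  expect_identical(get("corpus_callosum", "pm_45min", "storage"), 2.95)
  expect_identical(get("corpus_callosum", "pm_45min", "loss"), 1.14)
  expect_identical(get("corpus_callosum", "in_situ_16h", "storage"), 4.57)
  expect_identical(get("thalamus", "pm_3min", "storage"), 1.57)
  expect_identical(get("brainstem", "in_vivo", "loss"), 0.20)
  expect_true(is.na(get("cerebellum", "ex_vivo_16h", "storage")))
  # whole-table checksum freezes all 40 printed numbers at once
  vals <- c(tab$storage_kpa, tab$loss_kpa)
  # hand-summed: storage 36.29 + loss 16.66
  expect_equal(sum(vals, na.rm = TRUE), 52.95, tolerance = 1e-9)
  peaks <- peak_moduli_table()
  expect_identical(peaks$peak_storage_kpa, c(1.13, 1.00, 1.22, 1.14, 1.19))
  expect_identical(peaks$peak_loss_kpa, c(0.30, 0.32, 0.57, 0.48, 0.19))
})

test_that("region SLS defaults reproduce in vivo moduli at 80 Hz", {
  params <- region_sls_defaults()
  tab <- brain_moduli_table()
  vivo <- tab[tab$timepoint == "in_vivo", ]
  for (i in seq_len(nrow(vivo))) {
    g <- dynamic_modulus(params[[as.character(vivo$region[i])]],
                         hz_to_omega(80))
    expect_equal(g$storage_kpa, vivo$storage_kpa[i], tolerance = 1e-9)
    expect_equal(g$loss_kpa, vivo$loss_kpa[i], tolerance = 1e-9)
  }
})

test_that("synthetic sweeps are exact when noiseless and seeded when not", {
  p <- sls(0.95, 0.45, 0.004)
  sw <- make_sweep(p, noise_sd = 0)
  g <- dynamic_modulus(p, hz_to_omega(sw$frequency_hz))
  expect_identical(sw$storage_kpa, g$storage_kpa)
  expect_true(all(diff(sw$storage_kpa) >= 0))  # SLS storage non-decreasing
  s1 <- make_sweep(p, noise_sd = 0.05, seed = 9)
  s2 <- make_sweep(p, noise_sd = 0.05, seed = 9)
  expect_identical(s1, s2)
  s3 <- make_sweep(p, noise_sd = 0.05, seed = 10)
  expect_false(identical(s1, s3))
})

test_that("default phantom has all five labeled regions, ordered by volume", {
  ph <- make_phantom()
  counts <- table(ph$labels[ph$labels > 0])
  expect_length(counts, 5)
  expect_true(all(counts >= 10))
  # cerebrum dominates, cerebellum is the largest substructure
  expect_gt(counts[["1"]], counts[["2"]])
  expect_true(counts[["2"]] > max(counts[["3"]], counts[["4"]], counts[["5"]]))
  for (lab in 1:5) {
    expect_gte(sum(brainrheo:::erode_mask(ph$labels == lab)), 10)
  }
})

test_that("undersized phantom grids are rejected", {
  expect_error(make_phantom(c(4, 4, 4)), "16")
  expect_error(make_phantom(c(32, 32, 32), spacing_mm = -1), "spacing")
  expect_error(make_phantom(region_params = list()), "five regions")
})

test_that("post-mortem series preserves the fixture trajectory and gaps", {
  s <- make_postmortem_series("cerebrum")
  expect_equal(s$storage_kpa[1:3], c(1.13, 1.42, 1.58))
  b <- make_postmortem_series("brainstem")
  expect_equal(b$loss_kpa[1:3], c(0.20, 0.19, 0.30))
  expect_true(is.na(b$storage_kpa[b$timepoint == "ex_vivo_16h"]))
  expect_error(make_postmortem_series("hippocampus"), "unknown region")
})

test_that("indentation trace generator is seeded and noise-controlled", {
  t1 <- make_indentation_traces(noise_sd = 0.05, seed = 3)
  t2 <- make_indentation_traces(noise_sd = 0.05, seed = 3)
  expect_identical(t1, t2)
  expect_false(identical(t1$k_s, make_indentation_traces(noise_sd = 0.05,
                                                         seed = 4)$k_s))
  expect_error(make_indentation_traces(true_g_kpa = c(white = -1, gray = 1)),
               "> 0")
})

test_that("histology generator hits the target fraction and is seeded", {
  img <- make_histology_image(0.72, seed = 5)
  expect_equal(attr(img, "true_fraction"), 0.72, tolerance = 0.01)
  meas <- myelin_fraction(classify_pixels(img))$fraction
  expect_equal(meas, attr(img, "true_fraction"), tolerance = 0.02)
  all_blue <- make_histology_image(1.0, seed = 5)
  expect_equal(attr(all_blue, "true_fraction"), 1.0)
  expect_true(all(classify_pixels(all_blue)))
  i1 <- make_histology_image(0.5, seed = 8)
  i2 <- make_histology_image(0.5, seed = 8)
  expect_identical(i1, i2)
  expect_error(make_histology_image(1.2), "target_fraction")
})
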