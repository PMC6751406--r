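# Canonical region labels for the 5-region brain phantom.
REGION_NAMES <- c("cerebrum", "cerebellum", "corpus_callosum",
                  "thalamus", "brainstem")

region_name <- function(label) {
  if (any(label < 1L) || any(label > length(REGION_NAMES))) {
    stop("unknown region label ", paste(label, collapse = ", "), call. = FALSE)
  }
  REGION_NAMES[label]
}

#' Packaged regional storage/loss moduli table
#'
#' Regional storage and loss moduli at 80 Hz for five brain regions
#' (cerebrum, cerebellum, corpus callosum, thalamus, brainstem) across five
#' conditions: in vivo, in situ 3 and 45 minutes post mortem, ex vivo 16 h
#' post mortem (cerebrum only; measured by indentation on slices), and, from
#' a different comparison animal, in situ 16 h post mortem. Conditions with
#' no measurement are `NA`. This fixture drives the post-mortem stiffening
#' report and calibrates the synthetic generators.
#'
#' @return A data.frame with columns `region`, `timepoint`, `storage_kpa`,
#'   `loss_kpa`.
#' @export
brain_moduli_table <- function() {
  path <- system.file("extdata", "table1_moduli.csv", package = "brainrheo",
                      mustWork = TRUE)
  d <- utils::read.csv(path)
  d$region <- factor(d$region, levels = REGION_NAMES)
  d$timepoint <- factor(d$timepoint, levels = c("in_vivo", "pm_3min",
                                                "pm_45min", "ex_vivo_16h",
                                                "in_situ_16h"))
  d
}

#' Peak in vivo moduli per region across the frequency sweep
#'
#' The maxima of the in vivo storage and loss moduli over the five actuation
#' frequencies, per region; a plausibility envelope for synthetic sweeps.
#'
#' @return A data.frame with columns `region`, `peak_storage_kpa`,
#'   `peak_loss_kpa`.
#' @export
peak_moduli_table <- function() {
  path <- system.file("extdata", "fig2_peak_moduli.csv", package = "brainrheo",
                      mustWork = TRUE)
  utils::read.csv(path)
}

#' Default standard-linear-solid parameters per brain region
#'
#' Calibrated so that each region's model moduli at 80 Hz equal its packaged
#' in vivo storage and loss moduli exactly, with the loss peak placed at
#' 80 Hz (\eqn{\omega\eta = \mu_2}, i.e. the loss modulus peaks at an
#' intermediate frequency of the measured 40-100 Hz band). Under that
#' convention \eqn{\mu_2 = 2 G''}, \eqn{\mu_1 = G' - G''} and
#' \eqn{\eta = \mu_2 / \omega}. These are internal calibration values, not
#' measured parameters.
#'
#' @param frequency_hz Calibration frequency (default 80).
#' @return Named list of [sls()] objects, one per region.
#' @export
region_sls_defaults <- function(frequency_hz = 80) {
  tab <- brain_moduli_table()
  vivo <- tab[tab$timepoint == "in_vivo", ]
  omega <- hz_to_omega(frequency_hz)
  out <- lapply(seq_len(nrow(vivo)), function(i) {
    gp <- vivo$storage_kpa[i]
    gpp <- vivo$loss_kpa[i]
    sls(mu1 = gp - gpp, mu2 = 2 * gpp, eta = 2 * gpp / omega)
  })
  stats::setNames(out, as.character(vivo$region))
}

#' Generate a synthetic frequency sweep from a rheological model
#'
#' Evaluates the model's storage and loss moduli at the actuation
#' frequencies and applies optional multiplicative Gaussian measurement
#' noise (independent draws per modulus and frequency). The default
#' frequency set is the five-frequency acquisition band 40-100 Hz.
#'
#' @param params A `rheo_model` object (typically one of
#'   [region_sls_defaults()]).
#' @param frequencies_hz Actuation frequencies in Hz.
#' @param noise_sd Relative noise standard deviation (0 = exact moduli).
#' @param seed Optional integer seed.
#' @return A [frequency_sweep()].
#' @export
make_sweep <- function(params, frequencies_hz = c(40, 60, 80, 90, 100),
                       noise_sd = 0, seed = NULL) {
  stopifnot(inherits(params, "rheo_model"), noise_sd >= 0)
  g <- dynamic_modulus(params, hz_to_omega(frequencies_hz))
  gp <- g$storage_kpa
  gpp <- g$loss_kpa
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    gp <- gp * (1 + stats::rnorm(length(gp), sd = noise_sd))
    gpp <- gpp * (1 + stats::rnorm(length(gpp), sd = noise_sd))
  }
  frequency_sweep(frequencies_hz, gp, gpp)
}

#' Build a nested-ellipsoid five-region brain phantom
#'
#' A voxelized stand-in for a segmented brain: a large outer ellipsoid
#' (cerebrum, label 1) containing four embedded ellipsoidal structures —
#' cerebellum (2), corpus callosum (3), thalamus (4) and brainstem (5) —
#' each carrying its own standard-linear-solid parameters. Background is
#' label 0. Geometry is deterministic and scales with the grid.
#'
#' @param shape Grid dimensions in voxels (each >= 16; default 32^3).
#' @param spacing_mm Isotropic voxel spacing in mm.
#' @param region_params Named list of [sls()] parameters per region
#'   (default [region_sls_defaults()]).
#' @param density Tissue density in kg/m^3.
#' @return An object of class `labeled_phantom`: integer `labels` array,
#'   `spacing_mm`, `density`, `region_params`.
#' @export
make_phantom <- function(shape = c(32, 32, 32), spacing_mm = 1,
                         region_params = region_sls_defaults(),
                         density = 1000) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 16L)) {
    stop("phantom grid must be at least 16 voxels per dimension", call. = FALSE)
  }
  if (!all(REGION_NAMES %in% names(region_params))) {
    stop("region_params must name all five regions", call. = FALSE)
  }
  if (spacing_mm <= 0) stop("'spacing_mm' must be > 0", call. = FALSE)
  ctr <- (shape + 1) / 2
  co <- lapply(1:3, function(a) seq_len(shape[a]))
  inside <- function(center_frac, semi_frac) {
    cen <- ctr + center_frac * shape
    semi <- semi_frac * shape
    q1 <- ((co[[1L]] - cen[1L]) / semi[1L])^2
    q2 <- ((co[[2L]] - cen[2L]) / semi[2L])^2
    q3 <- ((co[[3L]] - cen[3L]) / semi[3L])^2
    outer(outer(q1, q2, `+`), q3, `+`) <= 1
  }
  outer_ell <- inside(c(0, 0, 0), c(0.44, 0.44, 0.42))
  labels <- array(0L, shape)
  labels[outer_ell] <- 1L
  sub <- list(cerebellum = list(c(0, 0.22, -0.19), c(0.17, 0.14, 0.12)),
              corpus_callosum = list(c(0, -0.06, 0.16), c(0.25, 0.09, 0.06)),
              thalamus = list(c(0, -0.03, 0), c(0.12, 0.12, 0.09)),
              brainstem = list(c(0, -0.16, -0.22), c(0.09, 0.09, 0.19)))
  for (i in seq_along(sub)) {
    sel <- inside(sub[[i]][[1L]], sub[[i]][[2L]]) & outer_ell
    labels[sel] <- i + 1L
  }
  for (lab in 1:5) {
    m <- labels == lab
    if (sum(m) < 10L || sum(erode_mask(m)) < 10L) {
      stop("region '", REGION_NAMES[lab],
           "' too small to survive boundary exclusion; enlarge the grid",
           call. = FALSE)
    }
  }
  structure(list(labels = labels, spacing_mm = spacing_mm,
                 density = density,
                 region_params = region_params[REGION_NAMES]),
            class = "labeled_phantom")
}

#' @export
print.labeled_phantom <- function(x, ...) {
  d <- dim(x$labels)
  cat("Labeled phantom:", paste(d, collapse = " x "), "voxels @",
      x$spacing_mm, "mm\n")
  counts <- table(factor(x$labels, levels = 0:5,
                         labels = c("background", REGION_NAMES)))
  print(counts)
  invisible(x)
}

#' Post-mortem modulus trajectory for one region
#'
#' Extracts a region's storage and loss moduli across the measured
#' timepoints from the packaged table, for feeding the stiffening report.
#' Conditions the region was not measured under remain `NA` (absent, not
#' zero).
#'
#' @param region One of `"cerebrum"`, `"cerebellum"`, `"corpus_callosum"`,
#'   `"thalamus"`, `"brainstem"`.
#' @param table Moduli table (default [brain_moduli_table()]).
#' @return A data.frame with columns `timepoint`, `storage_kpa`, `loss_kpa`
#'   in timepoint order.
#' @export
make_postmortem_series <- function(region, table = brain_moduli_table()) {
  if (!region %in% REGION_NAMES) {
    stop("unknown region '", region, "'", call. = FALSE)
  }
  d <- table[table$region == region, c("timepoint", "storage_kpa", "loss_kpa")]
  d[order(d$timepoint), , drop = FALSE]
}

#' Generate synthetic flat-punch indentation records
#'
#' Inverts the flat-punch conversion formulas to synthesize quasi-static and
#' dynamic indentation measurables from known ground-truth moduli:
#' \eqn{k_s = 4 d G}, \eqn{k_d = 3 d G'}, \eqn{\omega C_d = 3 d G''}
#' (incompressible tissue), with optional multiplicative Gaussian noise per
#' location. The default layout mirrors an 18-location protocol, ten in
#' white matter and eight in gray matter, with white matter slightly stiffer.
#'
#' @param true_g_kpa Ground-truth elastic shear modulus per matter type,
#'   named vector `c(white = ..., gray = ...)` in kPa.
#' @param true_storage_kpa,true_loss_kpa Ground-truth dynamic moduli in kPa
#'   (applied to both matter types).
#' @param frequency_hz Dynamic test frequency.
#' @param geom An [indenter_geometry()].
#' @param n_white,n_gray Number of locations per matter type.
#' @param noise_sd Relative measurement noise (0 = exact round trip).
#' @param seed Optional integer seed.
#' @return A data.frame with columns `location_id`, `matter_type`, `k_s`,
#'   `frequency_hz`, `k_d`, `omega_Cd` (N/m), with the ground truth attached
#'   as attribute `"truth"`.
#' @export
make_indentation_traces <- function(true_g_kpa = c(white = 0.30, gray = 0.27),
                                    true_storage_kpa = 1.52,
                                    true_loss_kpa = 2.36,
                                    frequency_hz = 80,
                                    geom = indenter_geometry(),
                                    n_white = 10, n_gray = 8,
                                    noise_sd = 0, seed = NULL) {
  if (any(true_g_kpa <= 0) || true_storage_kpa <= 0 || true_loss_kpa <= 0) {
    stop("ground-truth moduli must be > 0", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  d <- geom$diameter_m
  matter <- rep(c("white", "gray"), c(n_white, n_gray))
  n <- length(matter)
  g_pa <- true_g_kpa[matter] * 1000
  jitter <- function(k) if (noise_sd > 0) k * (1 + stats::rnorm(n, sd = noise_sd)) else k
  out <- data.frame(location_id = seq_len(n),
                    matter_type = matter,
                    k_s = jitter(unname(4 * d * g_pa)),
                    frequency_hz = frequency_hz,
                    k_d = jitter(rep(3 * d * true_storage_kpa * 1000, n)),
                    omega_Cd = jitter(rep(3 * d * true_loss_kpa * 1000, n)))
  attr(out, "truth") <- list(g_kpa = true_g_kpa,
                             storage_kpa = true_storage_kpa,
                             loss_kpa = true_loss_kpa,
                             geom = geom, noise_sd = noise_sd)
  out
}

#' Generate a synthetic stained-section image with known myelin fraction
#'
#' Builds a blue-blob-on-pink texture emulating a luxol-fast-blue stained
#' section: a Gaussian-smoothed random field is thresholded so that exactly
#' `round(target_fraction * n_pixels)` pixels are blue (myelin); the rest
#' are pink (neuropil). Mild per-pixel color jitter stays within the default
#' classifier thresholds. The realized fraction is attached as
#' `attr(, "true_fraction")` and is within 1/n_pixels of the target.
#'
#' @param target_fraction Desired blue-pixel fraction in \[0, 1\].
#' @param blob_scale Smoothing length in pixels controlling blob size.
#' @param size Image dimensions `c(height, width)`.
#' @param seed Integer seed (generation is deterministic given the seed).
#' @return Numeric RGB array `height x width x 3` in \[0, 1\].
#' @export
make_histology_image <- function(target_fraction, blob_scale = 8,
                                 size = c(96, 96), seed = 1L) {
  if (target_fraction < 0 || target_fraction > 1) {
    stop("'target_fraction' must lie in [0, 1]", call. = FALSE)
  }
  set.seed(seed)
  h <- size[1L]
  w <- size[2L]
  field <- matrix(stats::rnorm(h * w), h, w)
  # periodic Gaussian smoothing via FFT; blob_scale sets correlation length
  gx <- stats::dnorm(pmin(0:(h - 1), h - (0:(h - 1))), sd = blob_scale)
  gy <- stats::dnorm(pmin(0:(w - 1), w - (0:(w - 1))), sd = blob_scale)
  kern <- outer(gx, gy)
  kern <- kern / sum(kern)
  field <- Re(stats::fft(stats::fft(field) * stats::fft(kern), inverse = TRUE)) / (h * w)
  n <- h * w
  k <- round(target_fraction * n)
  mask <- matrix(FALSE, h, w)
  if (k > 0) mask[order(field, decreasing = TRUE)[seq_len(k)]] <- TRUE

  blue <- c(0.16, 0.28, 0.78)
  pink <- c(0.98, 0.62, 0.72)
  img <- array(0, c(h, w, 3))
  jit <- array(stats::rnorm(n * 3, sd = 0.02), c(h, w, 3))
  for (ch in 1:3) {
    base <- ifelse(mask, blue[ch], pink[ch])
    img[, , ch] <- pmin(pmax(base + jit[, , ch], 0), 1)
  }
  attr(img, "true_fraction") <- k / n
  attr(img, "seed") <- seed
  img
}
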