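#' Post-mortem stiffening report
#'
#' Computes, for every region and both moduli, the percent change of each
#' post-mortem timepoint relative to the in vivo baseline, via
#' [percent_change()]. Raw values are exact; reported integers round to the
#' nearest percent, ties away from zero. Timepoints without a measurement
#' are skipped (absent, not zero).
#'
#' @param table A moduli table with columns `region`, `timepoint`,
#'   `storage_kpa`, `loss_kpa`; defaults to the packaged
#'   [brain_moduli_table()].
#' @param baseline Timepoint used as reference (default `"in_vivo"`).
#' @return A data.frame of class `stiffening_report` with columns `region`,
#'   `modulus` (`"storage"` or `"loss"`), `timepoint`, `before_kpa`,
#'   `after_kpa`, `percent_raw`, `percent` (integer), and attribute
#'   `"provenance"`.
#' @examples
#' rep <- build_stiffening_report()
#' subset(rep, region == "corpus_callosum" & modulus == "storage")
#' @export
build_stiffening_report <- function(table = brain_moduli_table(),
                                    baseline = "in_vivo") {
  need <- c("region", "timepoint", "storage_kpa", "loss_kpa")
  if (!all(need %in% names(table))) {
    stop("table must have columns ", paste(need, collapse = ", "), call. = FALSE)
  }
  provenance <- if (missing(table)) "packaged fixture" else "user data"
  rows <- list()
  for (reg in unique(as.character(table$region))) {
    sub <- table[table$region == reg, ]
    base <- sub[sub$timepoint == baseline, ]
    if (nrow(base) != 1L) {
      stop("region '", reg, "' has no '", baseline, "' baseline", call. = FALSE)
    }
    later <- sub[sub$timepoint != baseline, ]
    for (mod in c("storage", "loss")) {
      col <- paste0(mod, "_kpa")
      before <- base[[col]]
      if (!is.finite(before)) {
        stop("region '", reg, "' baseline ", mod, " modulus is missing",
             call. = FALSE)
      }
      ok <- is.finite(later[[col]])
      if (!any(ok)) next
      raw <- percent_change(before, later[[col]][ok])
      rows[[length(rows) + 1L]] <- data.frame(
        region = reg, modulus = mod,
        timepoint = as.character(later$timepoint[ok]),
        before_kpa = before, after_kpa = later[[col]][ok],
        percent_raw = raw, percent = as.integer(round_half_away(raw)))
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "provenance") <- provenance
  class(out) <- c("stiffening_report", "data.frame")
  out
}

#' @export
print.stiffening_report <- function(x, ...) {
  cat("Post-mortem stiffening report (", attr(x, "provenance"),
      "; percent change vs in vivo)\n", sep = "")
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Look up one stiffening percentage
#'
#' Convenience accessor on a [build_stiffening_report()] result.
#'
#' @param report A `stiffening_report`.
#' @param region,modulus,timepoint Row selectors.
#' @param raw Return the unrounded percentage (default `FALSE`: integer).
#' @return A single percentage.
#' @export
stiffening_percent <- function(report, region, modulus, timepoint,
                               raw = FALSE) {
  row <- report[report$region == region & report$modulus == modulus &
                  report$timepoint == timepoint, ]
  if (nrow(row) != 1L) stop("no unique matching report row", call. = FALSE)
  if (raw) row$percent_raw else row$percent
}

#' Configuration for the end-to-end synthetic pipeline
#'
#' @param shape Phantom grid (default 32^3).
#' @param spacing_mm Voxel spacing in mm.
#' @param frequency Actuation frequency in Hz.
#' @param direction Shear-wave propagation direction.
#' @param amplitude Displacement amplitude in micrometers.
#' @param field_noise_sd Relative noise on the complex wave field.
#' @param sweep_noise_sd Relative noise on the synthetic sweeps fed to the
#'   model fits.
#' @param model Rheological model to fit per region.
#' @param n_starts Multi-start count for the fits.
#' @param seed Master integer seed for all randomized stages.
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(shape = c(32, 32, 32), spacing_mm = 1,
                            frequency = 80, direction = c(1, 0, 0),
                            amplitude = 1, field_noise_sd = 0,
                            sweep_noise_sd = 0,
                            model = c("sls", "maxwell", "voigt", "springpot"),
                            n_starts = 27, seed = 1L) {
  model <- match.arg(model)
  if (frequency <= 0) stop("'frequency' must be > 0", call. = FALSE)
  if (field_noise_sd < 0 || sweep_noise_sd < 0) {
    stop("noise levels must be >= 0", call. = FALSE)
  }
  structure(list(shape = shape, spacing_mm = spacing_mm,
                 frequency = frequency, direction = direction,
                 amplitude = amplitude, field_noise_sd = field_noise_sd,
                 sweep_noise_sd = sweep_noise_sd, model = model,
                 n_starts = as.integer(n_starts), seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full synthetic elastography pipeline
#'
#' Executes the whole chain with one seed: build the five-region phantom,
#' simulate the shear-wave field, demodulate the phase snapshots, invert to
#' an elastogram, summarize each region, generate per-region frequency
#' sweeps and fit the configured rheological model, and build the
#' post-mortem stiffening report from the packaged table. Each stage is
#' wrapped so a failure aborts with the stage name. The run is fully
#' reproducible given the seed.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Optional directory; when given, region summaries and the
#'   stiffening report are written as CSV, fit reports as JSON, and a run
#'   log (package version, seed, configuration) as text.
#' @return A list of class `pipeline_result`: `phantom`, `elastogram`,
#'   `region_storage`, `region_loss` (summary tables), `fits` (named list of
#'   [rheofit()] objects), `stiffening` (report), `config`, `log`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  set.seed(config$seed)
  phantom <- stage("phantom", make_phantom(config$shape, config$spacing_mm))
  wf <- stage("simulate", simulate_wave_field(
    phantom, config$frequency, config$direction, config$amplitude,
    noise_sd = config$field_noise_sd, seed = config$seed))
  harmonic <- stage("demodulate", demodulate(wf$snapshots))
  elast <- stage("invert", helmholtz_invert(harmonic, config$frequency,
                                            config$spacing_mm,
                                            phantom$density))
  region_storage <- stage("region-stats",
                          summarize_regions(elast, phantom, "storage"))
  region_loss <- stage("region-stats",
                       summarize_regions(elast, phantom, "loss"))
  fits <- stage("fit", {
    cfgs <- multistart_config(n_starts = config$n_starts, seed = config$seed)
    lapply(phantom$region_params, function(p) {
      sw <- make_sweep(p, noise_sd = config$sweep_noise_sd,
                       seed = config$seed)
      rheofit(sw, config$model, cfgs)
    })
  })
  stiffening <- stage("report", build_stiffening_report())
  log <- c(paste("brainrheo", as.character(utils::packageVersion("brainrheo"))),
           paste("seed", config$seed),
           paste("model", config$model),
           paste("frequency_hz", config$frequency),
           paste("grid", paste(config$shape, collapse = "x"),
                 "@", config$spacing_mm, "mm"))
  result <- structure(list(phantom = phantom, elastogram = elast,
                           region_storage = region_storage,
                           region_loss = region_loss,
                           fits = fits, stiffening = stiffening,
                           config = config, log = log),
                      class = "pipeline_result")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(region_storage, file.path(out_dir, "region_storage.csv"),
                     row.names = FALSE)
    utils::write.csv(region_loss, file.path(out_dir, "region_loss.csv"),
                     row.names = FALSE)
    utils::write.csv(as.data.frame(stiffening),
                     file.path(out_dir, "stiffening_report.csv"),
                     row.names = FALSE)
    for (reg in names(fits)) {
      write_fit_report(fits[[reg]],
                       file.path(out_dir, paste0("fit_", reg, ".json")))
    }
    writeLines(log, file.path(out_dir, "run_log.txt"))
  }
  result
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("Synthetic elastography pipeline run\n")
  cat(paste0("  ", x$log, collapse = "\n"), "\n")
  cat("  regions summarized:", nrow(x$region_storage), "\n")
  cat("  fits:", paste(names(x$fits), collapse = ", "), "\n")
  invisible(x)
}
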