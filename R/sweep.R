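#' Frequency sweep of storage and loss moduli
#'
#' Container for paired storage/loss moduli measured at a set of actuation
#' frequencies for one region and timepoint — the unit of data a viscoelastic
#' model is fitted to. Frequencies are in Hz (as reported by the scanner) and
#' converted to angular frequency internally.
#'
#' @param frequencies_hz Actuation frequencies in Hz; strictly positive and
#'   strictly increasing.
#' @param storage_kpa Storage modulus G' per frequency, kPa, finite and >= 0.
#' @param loss_kpa Loss modulus G'' per frequency, kPa, finite and >= 0.
#' @return A data.frame of class `frequency_sweep` with columns
#'   `frequency_hz`, `storage_kpa`, `loss_kpa`.
#' @examples
#' sw <- frequency_sweep(c(40, 60, 80, 90, 100),
#'                       storage_kpa = c(0.9, 1.0, 1.1, 1.12, 1.15),
#'                       loss_kpa = c(0.25, 0.3, 0.31, 0.3, 0.28))
#' @export
frequency_sweep <- function(frequencies_hz, storage_kpa, loss_kpa) {
  if (length(frequencies_hz) == 0L) stop("sweep must be non-empty", call. = FALSE)
  if (length(storage_kpa) != length(frequencies_hz) ||
      length(loss_kpa) != length(frequencies_hz)) {
    stop("frequencies, storage and loss moduli must have equal length",
         call. = FALSE)
  }
  if (any(!is.finite(frequencies_hz)) || any(frequencies_hz <= 0)) {
    stop("frequencies must be finite and > 0", call. = FALSE)
  }
  if (is.unsorted(frequencies_hz, strictly = TRUE)) {
    stop("frequencies must be strictly increasing", call. = FALSE)
  }
  moduli <- c(storage_kpa, loss_kpa)
  if (any(!is.finite(moduli)) || any(moduli < 0)) {
    stop("moduli must be finite and >= 0", call. = FALSE)
  }
  structure(data.frame(frequency_hz = as.numeric(frequencies_hz),
                       storage_kpa = as.numeric(storage_kpa),
                       loss_kpa = as.numeric(loss_kpa)),
            class = c("frequency_sweep", "data.frame"))
}

#' @export
print.frequency_sweep <- function(x, ...) {
  cat("Frequency sweep:", nrow(x), "frequencies,",
      min(x$frequency_hz), "-", max(x$frequency_hz), "Hz\n")
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

#' Read / write frequency sweeps as CSV
#'
#' Sweeps are exchanged as comma-separated text with a header line and
#' columns `frequency_hz`, `storage_kpa`, `loss_kpa`.
#'
#' @param path File path.
#' @param sweep A [frequency_sweep()] object.
#' @return `read_sweep()` returns a `frequency_sweep`; `write_sweep()`
#'   returns `path` invisibly.
#' @export
read_sweep <- function(path) {
  d <- utils::read.csv(path)
  need <- c("frequency_hz", "storage_kpa", "loss_kpa")
  if (!all(need %in% names(d))) {
    stop("sweep file must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  frequency_sweep(d$frequency_hz, d$storage_kpa, d$loss_kpa)
}

#' @rdname read_sweep
#' @export
write_sweep <- function(sweep, path) {
  stopifnot(inherits(sweep, "frequency_sweep"))
  utils::write.csv(as.data.frame(sweep), path, row.names = FALSE)
  invisible(path)
}
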