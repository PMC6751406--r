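#' Boxplot summary of a masked modulus map
#'
#' Every voxel inside a region's segmentation is one data point. The summary
#' reports the median, first and third quartiles (linear interpolation
#' between order statistics), minimum, maximum, the interquartile range, and
#' the data points lying beyond three interquartile ranges outside the
#' quartiles — the far-outlier fences \eqn{[q_1 - 3\,IQR,\ q_3 + 3\,IQR]}.
#'
#' @param map Numeric vector or array of per-voxel values (kPa).
#' @param mask Optional logical vector/array selecting the region; `NA`
#'   values in `map` are dropped after masking.
#' @param label Optional region label carried through to the result.
#' @return A list of class `region_summary`: `label`, `n_voxels`, `median`,
#'   `q1`, `q3`, `min`, `max`, `iqr`, `outliers` (values beyond the fences),
#'   `fence_low`, `fence_high`.
#' @examples
#' region_statistics(c(1, 2, 3, 4, 100))  # 100 is a far outlier
#' @export
region_statistics <- function(map, mask = NULL, label = NA) {
  x <- as.numeric(map)
  if (!is.null(mask)) {
    if (length(mask) != length(x)) stop("mask and map sizes differ", call. = FALSE)
    x <- x[as.logical(mask)]
  }
  x <- x[is.finite(x)]
  if (length(x) == 0L) stop("region is empty", call. = FALSE)
  q <- unname(stats::quantile(x, c(0.25, 0.5, 0.75), type = 7))
  iqr <- q[3L] - q[1L]
  lo <- q[1L] - 3 * iqr
  hi <- q[3L] + 3 * iqr
  structure(list(label = label,
                 n_voxels = length(x),
                 median = q[2L], q1 = q[1L], q3 = q[3L],
                 min = min(x), max = max(x), iqr = iqr,
                 outliers = x[x < lo | x > hi],
                 fence_low = lo, fence_high = hi),
            class = "region_summary")
}

#' @export
print.region_summary <- function(x, ...) {
  cat("Region", if (!is.na(x$label)) x$label else "", "summary (",
      x$n_voxels, "voxels ):\n")
  cat(sprintf("  median %.4g  [q1 %.4g, q3 %.4g]  range [%.4g, %.4g]\n",
              x$median, x$q1, x$q3, x$min, x$max))
  cat("  far outliers (3 IQR):", length(x$outliers), "\n")
  invisible(x)
}

# 6-connected erosion: TRUE where the voxel and all face neighbors are in
# the mask; used to drop label-boundary voxels where the local-homogeneity
# assumption of the inversion fails.
erode_mask <- function(mask) {
  d <- dim(mask)
  out <- mask
  pad <- function(a, by) {
    idx <- rep(list(quote(expr = )), 3L)
    n <- d[a]
    idx[[a]] <- if (by > 0) c(seq.int(1 + by, n), n) else c(1L, seq.int(1, n - 1))
    do.call(`[`, c(list(mask), idx))
  }
  for (a in 1:3) out <- out & pad(a, 1) & pad(a, -1)
  # grid-boundary voxels have incomplete neighborhoods
  out[c(1, d[1]), , ] <- FALSE
  out[, c(1, d[2]), ] <- FALSE
  out[, , c(1, d[3])] <- FALSE
  out
}

#' Regional summaries of an elastogram over a labeled phantom
#'
#' Applies [region_statistics()] to each labeled region of an elastogram.
#' By default each region mask is eroded by one voxel and intersected with
#' the elastogram's valid-voxel mask, excluding boundary voxels where the
#' inversion stencil mixes regions.
#'
#' @param elastogram An [helmholtz_invert()] result.
#' @param phantom The [make_phantom()] the field was simulated on.
#' @param what `"storage"` or `"loss"`.
#' @param erode Drop a one-voxel rind of each region (default `TRUE`).
#' @return A data.frame with one row per region: `label`, `region`,
#'   `n_voxels`, `median`, `q1`, `q3`, `min`, `max`, `n_outliers`.
#' @export
summarize_regions <- function(elastogram, phantom,
                              what = c("storage", "loss"), erode = TRUE) {
  what <- match.arg(what)
  stopifnot(inherits(elastogram, "elastogram"), inherits(phantom, "labeled_phantom"))
  map <- if (what == "storage") elastogram$storage_kpa else elastogram$loss_kpa
  labs <- setdiff(sort(unique(as.integer(phantom$labels))), 0L)
  rows <- lapply(labs, function(lab) {
    m <- phantom$labels == lab
    if (erode) m <- erode_mask(m)
    m <- m & elastogram$valid
    s <- region_statistics(map, m, label = lab)
    data.frame(label = lab, region = region_name(lab), n_voxels = s$n_voxels,
               median = s$median, q1 = s$q1, q3 = s$q3,
               min = s$min, max = s$max, n_outliers = length(s$outliers))
  })
  do.call(rbind, rows)
}

#' Percent change of a modulus relative to a baseline
#'
#' \eqn{100 (after - before)/before}. The reporting layer rounds to the
#' nearest integer percent, ties away from zero.
#'
#' @param before Baseline modulus (kPa), > 0.
#' @param after Modulus at the later timepoint (kPa).
#' @return Percent change (vectorized, unrounded).
#' @examples
#' percent_change(1.13, 1.42)  # 25.66... -> reported as 26%
#' @export
percent_change <- function(before, after) {
  if (any(!is.finite(before)) || any(before <= 0)) {
    stop("'before' must be finite and > 0", call. = FALSE)
  }
  100 * (after - before) / before
}

# nearest integer, ties away from zero (0.5 -> 1, -0.5 -> -1)
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)
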