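#' Simulate a shear-wave displacement field on a labeled phantom
#'
#' Produces the steady-state first-harmonic displacement of a continuous
#' mechanical actuation at one frequency. Within each homogeneous region the
#' field is a plane shear wave
#' \deqn{u(x) = A \exp(-i k\, x \cdot d), \qquad k = \omega\sqrt{\rho / G^*(\omega)},}
#' with the complex wavenumber taken on the principal branch so that a lossy
#' region (\eqn{G'' > 0}) attenuates the wave along the propagation direction
#' `d`. The region's complex modulus \eqn{G^*} comes from its standard linear
#' solid parameters. The field is returned both as the complex first harmonic
#' and as 8 real snapshots sampled at equally spaced phase offsets over one
#' period, mirroring how phase images are acquired.
#'
#' @param phantom A [make_phantom()] object.
#' @param frequency Actuation frequency in Hz (> 0).
#' @param direction Propagation direction, length-3 unit vector.
#' @param amplitude Displacement amplitude in micrometers.
#' @param noise_sd Relative standard deviation of multiplicative Gaussian
#'   noise applied to the complex field (0 = noiseless).
#' @param seed Optional integer seed for the noise.
#' @return An object of class `wave_field`: `complex_field` (complex array on
#'   the phantom grid, zero in background), `snapshots` (4-D array, last
#'   dimension the 8 phase offsets), `frequency`, `spacing_mm`.
#' @export
simulate_wave_field <- function(phantom, frequency, direction = c(1, 0, 0),
                                amplitude = 1, noise_sd = 0, seed = NULL) {
  stopifnot(inherits(phantom, "labeled_phantom"))
  if (!is.numeric(frequency) || length(frequency) != 1L || frequency <= 0) {
    stop("'frequency' must be a single value > 0", call. = FALSE)
  }
  if (length(direction) != 3L || abs(sqrt(sum(direction^2)) - 1) > 1e-8) {
    stop("'direction' must be a unit 3-vector", call. = FALSE)
  }
  omega <- hz_to_omega(frequency)
  dims <- dim(phantom$labels)
  h <- phantom$spacing_mm * 1e-3
  # projection of voxel-center world coordinates (m) onto the direction
  ax <- lapply(1:3, function(a) (seq_len(dims[a]) - 1) * h * direction[a])
  proj <- outer(outer(ax[[1L]], ax[[2L]], `+`), ax[[3L]], `+`)

  field <- array(complex(real = 0, imaginary = 0), dims)
  for (lab in sort(unique(as.integer(phantom$labels)))) {
    if (lab == 0L) next
    p <- phantom$region_params[[region_name(lab)]]
    g <- dynamic_modulus(p, omega)
    gstar_pa <- complex(real = g$storage_kpa, imaginary = g$loss_kpa) * 1000
    if (Mod(gstar_pa) == 0) stop("region ", lab, " has zero modulus", call. = FALSE)
    k <- omega * sqrt(phantom$density / gstar_pa)  # principal branch: Im(k) <= 0
    sel <- phantom$labels == lab
    field[sel] <- amplitude * exp(-1i * k * proj[sel])
  }
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    field <- field * (1 + stats::rnorm(length(field), sd = noise_sd))
  }
  phases <- 2 * pi * (0:7) / 8
  snaps <- vapply(phases, function(th) Re(field * exp(1i * th)),
                  array(0, dims))
  structure(list(complex_field = field, snapshots = snaps,
                 frequency = frequency, spacing_mm = phantom$spacing_mm),
            class = "wave_field")
}

#' Recover the complex first harmonic from phase snapshots
#'
#' Extracts the fundamental Fourier component from 8 real snapshots sampled
#' at uniform phase offsets over one period of motion. Exact for a pure
#' sinusoid: snapshots of \eqn{Re[U e^{i\theta_j}]} return \eqn{U}.
#'
#' @param snapshots Array whose last dimension has length 8 (the phase
#'   offsets \eqn{\theta_j = 2\pi j/8, j = 0..7}).
#' @return Complex array with the last dimension dropped.
#' @export
demodulate <- function(snapshots) {
  d <- dim(snapshots)
  if (is.null(d) || d[length(d)] != 8L) {
    stop("'snapshots' must have 8 phase offsets in the last dimension",
         call. = FALSE)
  }
  nd <- length(d)
  flat <- matrix(snapshots, ncol = 8L)
  w <- exp(-1i * 2 * pi * (0:7) / 8)
  u <- (flat %*% w) * (2 / 8)
  if (nd == 1L) as.vector(u) else array(u, d[-nd])
}

#' Algebraic Helmholtz inversion of a displacement field
#'
#' Estimates the per-voxel complex shear modulus from the first-harmonic
#' displacement \eqn{u} under the local-homogeneity assumption,
#' \deqn{G^*(\omega) = -\rho\,\omega^2\, u / \nabla^2 u,}
#' with a 7-point central-difference Laplacian (spacing in meters). Voxels
#' with an incomplete stencil (grid boundary) or with \eqn{|\nabla^2 u|}
#' below a floor (e.g. a locally constant field) are marked invalid rather
#' than inverted. Negative storage or loss values — possible under noise —
#' are flagged, never clipped.
#'
#' @param field A `wave_field` object, or a complex array (then `frequency`
#'   and `spacing_mm` are required).
#' @param frequency Actuation frequency in Hz.
#' @param spacing_mm Isotropic voxel spacing in mm.
#' @param density Tissue density in kg/m^3 (default 1000).
#' @param lap_floor Invalidity floor on \eqn{|\nabla^2 u|}, relative to the
#'   field's maximum amplitude over squared spacing.
#' @return An object of class `elastogram`: `storage_kpa` and `loss_kpa`
#'   arrays, logical `valid` and `negative` arrays, `frequency`,
#'   `spacing_mm`.
#' @export
helmholtz_invert <- function(field, frequency = NULL, spacing_mm = NULL,
                             density = 1000, lap_floor = 1e-8) {
  if (inherits(field, "wave_field")) {
    if (is.null(frequency)) frequency <- field$frequency
    if (is.null(spacing_mm)) spacing_mm <- field$spacing_mm
    field <- field$complex_field
  }
  if (is.null(frequency) || is.null(spacing_mm)) {
    stop("'frequency' and 'spacing_mm' are required for a bare array",
         call. = FALSE)
  }
  d <- dim(field)
  if (length(d) != 3L) stop("'field' must be a 3-D array", call. = FALSE)
  if (any(d < 3L)) stop("grid too small for the Laplacian stencil", call. = FALSE)
  h <- spacing_mm * 1e-3
  omega <- hz_to_omega(frequency)

  shift <- function(x, a, by) {
    idx <- rep(list(quote(expr = )), 3L)
    n <- d[a]
    idx[[a]] <- if (by > 0) c(seq.int(1 + by, n), rep(n, by)) else
      c(rep(1L, -by), seq.int(1, n + by))
    do.call(`[`, c(list(x), idx))
  }
  lap <- (shift(field, 1, 1) + shift(field, 1, -1) +
          shift(field, 2, 1) + shift(field, 2, -1) +
          shift(field, 3, 1) + shift(field, 3, -1) - 6 * field) / h^2

  interior <- array(FALSE, d)
  interior[2:(d[1] - 1), 2:(d[2] - 1), 2:(d[3] - 1)] <- TRUE
  floor_abs <- lap_floor * max(Mod(field)) / h^2
  valid <- interior & (Mod(lap) > floor_abs)

  g <- array(complex(real = NA_real_, imaginary = NA_real_), d)
  g[valid] <- -density * omega^2 * field[valid] / lap[valid]
  storage <- Re(g) / 1000
  loss <- Im(g) / 1000
  negative <- valid & ((storage < 0) | (loss < 0))
  structure(list(storage_kpa = storage, loss_kpa = loss,
                 valid = valid, negative = negative,
                 frequency = frequency, spacing_mm = spacing_mm),
            class = "elastogram")
}

#' Read and write volumes as NIfTI-1
#'
#' Thin wrappers for exchanging label masks, displacement components and
#' elastogram maps with other neuroimaging tools.
#'
#' @param vol Numeric 3-D array.
#' @param path File path (`.nii` is uncompressed NIfTI-1).
#' @param spacing_mm Isotropic voxel spacing in mm.
#' @return `read_volume()` returns a plain array with a `spacing_mm`
#'   attribute; `write_volume()` returns `path` invisibly.
#' @export
write_volume <- function(vol, path, spacing_mm = 1) {
  img <- RNifti::asNifti(vol)
  RNifti::pixdim(img) <- rep(spacing_mm, 3)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  out <- array(as.numeric(img), dim(img))
  attr(out, "spacing_mm") <- RNifti::pixdim(img)[1L]
  out
}
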