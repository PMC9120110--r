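#' Reconstructed volume container
#'
#' A non-negative (envelope-detected) 3D intensity grid for one frequency
#' band. Axes are `[x (fast), y (slow), z (depth)]`; voxel centres sit at
#' `origin + (i - 0.5) * voxel_size` micrometres, with z measured from the
#' detector plane unless re-referenced (e.g. after surface flattening).
#'
#' @param intensity numeric 3D array, finite.
#' @param voxel_size length-3 voxel edges in um (default `c(12, 12, 3)`).
#' @param band frequency band `c(f_lo, f_hi)` in MHz.
#' @param origin length-3 grid-corner offset in um.
#' @return object of class `recon_volume`.
#' @export
recon_volume <- function(intensity, voxel_size = c(12, 12, 3),
                         band = c(10, 40), origin = c(0, 0, 0)) {
  if (length(dim(intensity)) != 3L) stop("intensity must be a 3D array")
  if (!all(is.finite(intensity))) stop("intensity must be finite")
  if (any(voxel_size <= 0)) stop("voxel sizes must be > 0")
  structure(list(intensity = intensity, voxel_size = as.numeric(voxel_size),
                 band = as.numeric(band), origin = as.numeric(origin)),
            class = "recon_volume")
}

#' @export
print.recon_volume <- function(x, ...) {
  d <- dim(x$intensity)
  cat(sprintf("<recon_volume> %d x %d x %d voxels @ %g x %g x %g um, band %g-%g MHz\n",
              d[1], d[2], d[3], x$voxel_size[1], x$voxel_size[2],
              x$voxel_size[3], x$band[1], x$band[2]))
  invisible(x)
}

## voxel-centre coordinate vectors of a recon volume (um)
volume_axes <- function(v) {
  d <- dim(v$intensity)
  list(x = v$origin[1] + (seq_len(d[1]) - 0.5) * v$voxel_size[1],
       y = v$origin[2] + (seq_len(d[2]) - 0.5) * v$voxel_size[2],
       z = v$origin[3] + (seq_len(d[3]) - 0.5) * v$voxel_size[3])
}

#' Split a raw scan into frequency bands
#'
#' Applies a zero-phase 4th-order Butterworth band-pass to every A-line,
#' once per requested band. Defaults reproduce the low / high split of a
#' 10-120 MHz detection bandwidth: 10-40 MHz (large structures) and
#' 40-120 MHz (small structures).
#'
#' @param scan a [raw_scan()].
#' @param bands list of `c(f_lo, f_hi)` in MHz.
#' @return a list of [raw_scan()]s, one per band, each carrying a
#'   `band` attribute in MHz.
#' @export
bandpass_split <- function(scan, bands = list(c(10, 40), c(40, 120))) {
  stopifnot(inherits(scan, "raw_scan"))
  cfg <- scan$config
  nyq <- cfg$sample_rate / 2
  lapply(bands, function(b) {
    if (b[2] * 1e6 > nyq)
      stop(sprintf("band %g-%g MHz exceeds the Nyquist frequency (%g MHz)",
                   b[1], b[2], nyq / 1e6))
    bw <- signal::butter(4, b * 1e6 / nyq, type = "pass")
    m <- matrix(aperm(scan$signals, c(3, 1, 2)), nrow = cfg$n_samples)
    # remove the per-line mean first: filtfilt edge transients would
    # otherwise leak a DC offset through the band-pass
    m <- sweep(m, 2, colMeans(m))
    for (j in seq_len(ncol(m))) m[, j] <- signal::filtfilt(bw, m[, j])
    out <- raw_scan(cfg, array(aperm(array(m, c(cfg$n_samples, cfg$n_fast,
                                                cfg$n_slow)),
                                     c(2, 3, 1)),
                               c(cfg$n_fast, cfg$n_slow, cfg$n_samples)),
                    acquisition_order = scan$acquisition_order,
                    wavelength_index = scan$wavelength_index)
    attr(out, "band") <- b
    out
  })
}

#' Reconstruction grid specification
#'
#' @param dim integer length-3 voxel counts.
#' @param voxel_size voxel edges in um, default `c(12, 12, 3)`.
#' @param origin grid-corner offset in um (z from the detector plane).
#' @return a list usable as the `grid` argument of [beamform()].
#' @export
recon_grid <- function(dim, voxel_size = c(12, 12, 3), origin = c(0, 0, 0)) {
  list(dim = as.integer(dim), voxel_size = as.numeric(voxel_size),
       origin = as.numeric(origin))
}

#' Sensitivity-weighted delay-and-sum beamforming
#'
#' Reconstructs one frequency band onto a fixed voxel grid: each voxel
#' accumulates, over all scan positions within the detector's lateral
#' sensitivity support, the A-line sample at the one-way delay
#' `||voxel - position|| / c` (linear time interpolation), weighted by the
#' Gaussian sensitivity field, and normalized by the total weight. The
#' returned intensity is the envelope magnitude of the summed image taken
#' along depth; set `envelope = FALSE` to obtain the signed pre-envelope
#' image (beamforming is linear in the input signals up to that point).
#' Voxels with empty sensitivity support are zero and counted in the
#' `coverage` attribute.
#'
#' @param scan_band a (band-passed, motion-corrected) [raw_scan()].
#' @param grid a [recon_grid()].
#' @param speed_of_sound m/s; defaults to the scan's configured value.
#' @param sensitivity a [sensitivity_field()].
#' @param envelope apply envelope detection along depth (default TRUE).
#' @return a [recon_volume()]; attribute `coverage` holds the number of
#'   voxels with empty support.
#' @export
beamform <- function(scan_band, grid, speed_of_sound = NULL,
                     sensitivity = sensitivity_field(), envelope = TRUE) {
  stopifnot(inherits(scan_band, "raw_scan"))
  cfg <- scan_band$config
  c_ms <- speed_of_sound %||% cfg$speed_of_sound
  if (c_ms <= 0) stop("speed_of_sound must be > 0")
  pos <- scan_positions(cfg)
  gx <- grid$origin[1] + (seq_len(grid$dim[1]) - 0.5) * grid$voxel_size[1]
  gy <- grid$origin[2] + (seq_len(grid$dim[2]) - 0.5) * grid$voxel_size[2]
  gz <- grid$origin[3] + (seq_len(grid$dim[3]) - 0.5) * grid$voxel_size[3]
  fovx <- range(pos[, 1]); fovy <- range(pos[, 2])
  margin <- sensitivity$cutoff * sensitivity$waist
  if (min(gx) < fovx[1] - margin - grid$voxel_size[1] ||
      max(gx) > fovx[2] + margin + grid$voxel_size[1] ||
      min(gy) < fovy[1] - margin - grid$voxel_size[2] ||
      max(gy) > fovy[2] + margin + grid$voxel_size[2])
    warning("reconstruction grid extends beyond the scanned field of view")
  m <- matrix(aperm(scan_band$signals, c(3, 1, 2)), nrow = cfg$n_samples)
  bf <- beamform_cpp(m, pos[, 1], pos[, 2], gx, gy, gz,
                     cfg$sample_rate, c_ms * 1e6,
                     sensitivity$focal_depth, sensitivity$waist,
                     sensitivity$rayleigh, sensitivity$cutoff)
  img <- bf$image
  if (envelope) {
    d <- dim(img)
    flat <- matrix(aperm(img, c(3, 1, 2)), nrow = d[3])
    env <- signal_envelope(flat)
    img <- aperm(array(env, c(d[3], d[1], d[2])), c(2, 3, 1))
  }
  band <- attr(scan_band, "band") %||% c(NA_real_, NA_real_)
  out <- recon_volume(img, voxel_size = grid$voxel_size, band = band,
                      origin = grid$origin)
  attr(out, "coverage") <- bf$empty_voxels
  attr(out, "envelope") <- envelope
  out
}

#' Composite two frequency-band volumes into red/green channels
#'
#' Normalizes each band to `[0, 1]` by its own upper percentile (values
#' above clip to 1) and packs the low band as the red channel and the high
#' band as the green channel, the standard dual-band rendering in which
#' large vessels appear red and fine structures green.
#'
#' @param low,high [recon_volume()]s on identical grids.
#' @param prob normalization percentile (default 0.999).
#' @return object of class `dual_band_composite`: `red`, `green` (arrays in
#'   `[0,1]`), `normalization` (the divisors used), `voxel_size`.
#' @export
composite_dual_band <- function(low, high, prob = 0.999) {
  stopifnot(inherits(low, "recon_volume"), inherits(high, "recon_volume"))
  if (!identical(dim(low$intensity), dim(high$intensity)) ||
      !isTRUE(all.equal(low$voxel_size, high$voxel_size)) ||
      !isTRUE(all.equal(low$origin, high$origin)))
    stop("low and high band volumes must share one grid")
  normof <- function(v) {
    q <- stats::quantile(v, prob, names = FALSE)
    if (q <= 0) q <- 1
    q
  }
  ql <- normof(low$intensity); qh <- normof(high$intensity)
  structure(list(red = pmin(low$intensity / ql, 1),
                 green = pmin(high$intensity / qh, 1),
                 normalization = c(low = ql, high = qh, prob = prob),
                 voxel_size = low$voxel_size, origin = low$origin),
            class = "dual_band_composite")
}

#' Maximum intensity projection
#'
#' Per-pixel maximum along the depth axis (`"depth"`, giving a coronal x-y
#' view) or the slow axis (`"slow"`, giving a cross-sectional x-z view),
#' optionally restricted to a depth range — e.g. an epidermal or dermal
#' slab.
#'
#' @param volume a [recon_volume()].
#' @param axis `"depth"` or `"slow"`.
#' @param depth_range `c(z0, z1)` in um (half-open, voxel centres in
#'   `[z0, z1)`), or `NULL` for the full depth.
#' @return 2D matrix; attribute `axes` names the remaining axes.
#' @export
project_mip <- function(volume, axis = c("depth", "slow"),
                        depth_range = NULL) {
  stopifnot(inherits(volume, "recon_volume"))
  axis <- match.arg(axis)
  ax <- volume_axes(volume)
  zi <- seq_along(ax$z)
  if (!is.null(depth_range)) {
    zi <- which(ax$z >= depth_range[1] & ax$z < depth_range[2])
    if (!length(zi))
      stop(sprintf("depth range [%g, %g) um selects no voxels",
                   depth_range[1], depth_range[2]))
  }
  v <- volume$intensity[, , zi, drop = FALSE]
  out <- if (axis == "depth") apply(v, c(1, 2), max)
         else apply(v, c(1, 3), max)
  attr(out, "axes") <- if (axis == "depth") c("fast", "slow")
                       else c("fast", "depth")
  attr(out, "pixel_size") <- if (axis == "depth") volume$voxel_size[1:2]
                             else volume$voxel_size[c(1, 3)]
  out
}

#' Linear spectral unmixing of multiwavelength volumes
#'
#' Solves, per voxel, the non-negative least-squares problem
#' `spectra %*% fractions = measured` across wavelengths, separating the
#' chromophore contributions (typically melanin, oxy- and deoxyhemoglobin).
#' Voxels whose unconstrained solution is already non-negative are accepted
#' directly; the rest are refined with NNLS.
#'
#' @param volumes list of co-registered [recon_volume()]s (or plain arrays),
#'   one per wavelength, in the row order of `spectra`.
#' @param spectra numeric matrix, rows = wavelengths, columns = components;
#'   must have full column rank and at least as many rows as columns.
#' @return list with `components` (named list of arrays), `residual_norm`.
#' @export
unmix_spectra <- function(volumes, spectra) {
  spectra <- as.matrix(spectra)
  if (nrow(spectra) < ncol(spectra))
    stop("need at least as many wavelengths as components")
  if (qr(spectra)$rank < ncol(spectra))
    stop("spectra matrix is rank-deficient")
  if (length(volumes) != nrow(spectra))
    stop("one volume per spectra row required")
  arrs <- lapply(volumes, function(v)
    if (inherits(v, "recon_volume")) v$intensity else v)
  dm <- dim(arrs[[1]])
  if (!all(vapply(arrs, function(a) identical(dim(a), dm), logical(1))))
    stop("volumes must be co-registered (identical grids)")
  V <- vapply(arrs, as.numeric, numeric(prod(dm)))   # nvox x W
  # unconstrained LS, then NNLS only where constraints bind
  Xt <- solve(crossprod(spectra), t(spectra))
  F <- V %*% t(Xt)                                   # nvox x C
  neg <- which(apply(F < -1e-12, 1, any))
  for (i in neg) F[i, ] <- pracma::lsqnonneg(spectra, V[i, ])$x
  F[F < 0] <- 0
  R <- V - F %*% t(spectra)
  comps <- lapply(seq_len(ncol(spectra)), function(k) array(F[, k], dm))
  names(comps) <- colnames(spectra) %||%
    paste0("component", seq_len(ncol(spectra)))
  list(components = comps, residual_norm = sqrt(sum(R^2)))
}
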