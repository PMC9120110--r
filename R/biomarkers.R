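#' Container for the six vascular biomarkers
#'
#' @param tbv total blood volume: vessel voxel fraction, in `[0, 1]`.
#' @param vessel_density nonzero-pixel fraction of the vessel
#'   representation within the analysis region (a.u.).
#' @param avg_vessel_length total skeleton length over branch-point count
#'   (um).
#' @param tortuosity tortuosity index: mean (DM - 1), where DM = AL/SL.
#' @param mean_dm mean raw distance metric (>= 1).
#' @param fractal_number box-counting dimension of the vessel pattern.
#' @param lacunarity normalized second moment minus one.
#' @param n_branch_points branch-point count used as the vessel number.
#' @param provenance free-form list recording thresholds / choices.
#' @return object of class `biomarker_set`.
#' @export
biomarker_set <- function(tbv, vessel_density, avg_vessel_length,
                          tortuosity, mean_dm = NA_real_,
                          fractal_number = NA_real_,
                          lacunarity = NA_real_,
                          n_branch_points = NA_integer_,
                          provenance = list()) {
  if (is.finite(tbv) && (tbv < 0 || tbv > 1))
    stop("tbv must lie in [0, 1]")
  if (is.finite(avg_vessel_length) && avg_vessel_length < 0)
    stop("avg_vessel_length must be >= 0")
  if (is.finite(mean_dm) && mean_dm < 1 - 1e-9)
    stop("mean DM cannot be below 1")
  if (is.finite(fractal_number) &&
      (fractal_number < -0.05 || fractal_number > 3))
    stop("fractal number out of the plausible [0, 3] range")
  structure(list(tbv = tbv, vessel_density = vessel_density,
                 avg_vessel_length = avg_vessel_length,
                 tortuosity = tortuosity, mean_dm = mean_dm,
                 fractal_number = fractal_number, lacunarity = lacunarity,
                 n_branch_points = n_branch_points,
                 provenance = provenance),
            class = "biomarker_set")
}

#' @export
print.biomarker_set <- function(x, ...) {
  cat("<biomarker_set>\n")
  cat(sprintf("  TBV                 %.4f (%.2f%%)\n", x$tbv, 100 * x$tbv))
  cat(sprintf("  vessel density      %.4g\n", x$vessel_density))
  cat(sprintf("  avg vessel length   %.2f um\n", x$avg_vessel_length))
  cat(sprintf("  tortuosity (DM - 1) %.4f   [mean DM %.4f]\n",
              x$tortuosity, x$mean_dm))
  cat(sprintf("  fractal number      %.4f\n", x$fractal_number))
  cat(sprintf("  lacunarity          %.4f\n", x$lacunarity))
  invisible(x)
}

#' @export
as.data.frame.biomarker_set <- function(x, ...) {
  data.frame(tbv = x$tbv, vessel_density = x$vessel_density,
             avg_vessel_length_um = x$avg_vessel_length,
             tortuosity = x$tortuosity, fractal_number = x$fractal_number,
             lacunarity = x$lacunarity)
}

#' Total blood volume
#'
#' TBV = N / V: the number of nonzero voxels of the segmented vessel volume
#' within the region of interest divided by the ROI voxel count.
#'
#' @param vessel_volume binary (or nonzero-coded) array, any dimension.
#' @param roi logical array of the same shape, or `NULL` for everything.
#' @return fraction in `[0, 1]`.
#' @export
total_blood_volume <- function(vessel_volume, roi = NULL) {
  v <- if (inherits(vessel_volume, "recon_volume")) vessel_volume$intensity
       else vessel_volume
  if (is.null(roi)) roi <- array(TRUE, dim(v) %||% length(v))
  if (!any(roi)) stop("empty ROI")
  sum(v[roi] != 0) / sum(roi)
}

#' Vessel density
#'
#' Ratio between the nonzero pixels of the vessel representation and the
#' analysis-region pixel count. The default representation is the skeleton
#' (centerline pixels); `representation = "mask"` uses the full segmented
#' mask instead.
#'
#' @param network a [vessel_network()].
#' @param roi logical matrix; `NULL` uses the full image.
#' @param representation `"skeleton"` (default) or `"mask"`.
#' @return density in `[0, 1]` (a.u.).
#' @export
vessel_density <- function(network, roi = NULL,
                           representation = c("skeleton", "mask")) {
  stopifnot(inherits(network, "vessel_network"))
  representation <- match.arg(representation)
  img <- if (representation == "skeleton") network$skeleton
         else network$mask
  if (is.null(roi)) roi <- matrix(TRUE, nrow(img), ncol(img))
  if (!any(roi)) stop("empty ROI")
  sum(img & roi) / sum(roi)
}

#' Average vessel length
#'
#' Sum of all skeleton segment arc lengths divided by the number of branch
#' points (the vessel number); an unbranched network divides by 1.
#'
#' @param network a [vessel_network()].
#' @return length in um.
#' @export
average_vessel_length <- function(network) {
  stopifnot(inherits(network, "vessel_network"))
  if (!length(network$segments)) stop("network has no segments")
  al <- vapply(network$segments, function(s) s$al_um, numeric(1))
  nb <- if (is.null(network$branch_points)) 0L
        else nrow(network$branch_points)
  sum(al) / max(nb, 1L)
}

#' Vessel tortuosity (distance metric)
#'
#' Per segment, the distance metric DM = AL / SL — arc length over the
#' straight-line (chord) distance between its endpoints. Reported as the
#' tortuosity index mean(DM - 1) (0 for perfectly straight vessels) and the
#' raw mean DM; `weighted = TRUE` weights the mean by arc length.
#' Segments with zero chord length (closed loops are split upstream) are
#' skipped and counted.
#'
#' For skeleton-derived networks, `smooth_px > 0` recomputes AL and SL on
#' moving-average-smoothed pixel paths, suppressing the upward bias that
#' staircase centerlines impose on short arcs; `min_path_px` and
#' `min_sl_um` drop fragments too short to carry shape information (both
#' off by default, so stored AL/SL are used as-is).
#'
#' @param network a [vessel_network()] (or a bare list of segments).
#' @param weighted arc-length-weighted mean instead of the plain mean.
#' @param smooth_px moving-average window (px) applied to segment pixel
#'   paths before measuring lengths (0 = use stored AL/SL).
#' @param min_path_px drop segments with fewer path pixels.
#' @param min_sl_um drop segments with a shorter chord.
#' @return list: `tortuosity` (mean DM - 1), `mean_dm`, `dm` (per segment),
#'   `skipped` (dropped segments).
#' @export
tortuosity <- function(network, weighted = FALSE, smooth_px = 0,
                       min_path_px = 0, min_sl_um = 0) {
  is_net <- inherits(network, "vessel_network")
  segs <- if (is_net) network$segments else network
  if (!length(segs)) stop("network has no segments")
  px <- if (is_net) network$pixel_size else 1
  meas <- vapply(segs, function(s) {
    al <- s$al_um; sl <- s$sl_um
    n_px <- if (!is.null(s$path)) nrow(s$path) else Inf
    if (smooth_px > 1 && !is.null(s$path) && nrow(s$path) > smooth_px + 2) {
      k <- rep(1 / smooth_px, smooth_px)
      sm <- cbind(stats::filter(s$path[, 1], k, sides = 2),
                  stats::filter(s$path[, 2], k, sides = 2))
      bad <- is.na(sm[, 1]); sm[bad, ] <- s$path[bad, ]
      al <- sum(sqrt(rowSums((sm[-1, , drop = FALSE] -
                              sm[-nrow(sm), , drop = FALSE])^2))) * px
      sl <- sqrt(sum((sm[nrow(sm), ] - sm[1, ])^2)) * px
    }
    c(al, sl, n_px)
  }, numeric(3))
  ok <- meas[2, ] > 0 & meas[2, ] >= min_sl_um & meas[3, ] >= min_path_px
  if (!any(ok)) stop("no segment passes the chord-length filters")
  al <- meas[1, ok]; sl <- meas[2, ok]
  dm <- al / sl
  w <- if (weighted) al / sum(al) else rep(1 / sum(ok), sum(ok))
  list(tortuosity = sum(w * (dm - 1)), mean_dm = sum(w * dm), dm = dm,
       skipped = sum(!ok))
}

#' Box-counting fractal dimension
#'
#' Covers the nonzero pattern with square boxes of dyadic side lengths
#' `r = 2, 4, 8, ...` (grid anchored at the image origin) and returns the
#' least-squares slope of `log N(r)` against `log(1/r)`; at least four
#' dyadic scales are required. The 1-px box is excluded: at that scale the
#' count measures pixelization rather than structure and biases the slope
#' low for patterns whose native subdivision is not dyadic.
#'
#' @param img binary (or nonzero-coded) 2D image.
#' @param min_scales minimum number of dyadic scales.
#' @return the fractal number (slope), typically in `[0, 2]` for planar
#'   patterns.
#' @export
fractal_number <- function(img, min_scales = 4L) {
  img <- as.matrix(img) != 0
  if (!any(img)) stop("image is empty")
  M <- nrow(img); N <- ncol(img)
  kmax <- floor(log2(min(M, N) / 2))
  if (kmax < min_scales)
    stop(sprintf("image too small for %d dyadic scales", min_scales))
  r <- 2^(1:kmax)
  counts <- vapply(r, function(rr) {
    gi <- (seq_len(M) - 1L) %/% rr
    gj <- (seq_len(N) - 1L) %/% rr
    b <- rowsum(img * 1, gi)
    b <- t(rowsum(t(b), gj))
    sum(b > 0)
  }, numeric(1))
  unname(stats::coef(stats::lm(log(counts) ~ log(1 / r)))[2])
}

#' Lacunarity
#'
#' Normalized second moment of the image minus one:
#' `mean(I^2) / mean(I)^2 - 1` — the "lumpiness" of the pattern, 0 for a
#' constant image and `1/p - 1` for a binary image with fill fraction `p`.
#' `box_size` switches to the gliding-box variant, applying the same
#' statistic to box-summed occupancy.
#'
#' @param img 2D image with nonzero mean.
#' @param box_size optional gliding-box side length (px).
#' @return lacunarity (>= 0 for non-negative images).
#' @export
lacunarity <- function(img, box_size = NULL) {
  img <- as.matrix(img)
  if (!is.null(box_size)) {
    b <- as.integer(box_size)
    if (b < 1 || b > min(dim(img)))
      stop("box_size must lie within the image")
    # gliding-box sums via cumulative sums
    cs <- apply(apply(img, 2, cumsum), 1, cumsum)  # transposed integral
    cs <- t(cs)
    pad <- rbind(0, cbind(0, cs))
    M <- nrow(img); N <- ncol(img)
    i <- seq_len(M - b + 1L); j <- seq_len(N - b + 1L)
    S <- pad[i + b, j + b, drop = FALSE] + pad[i, j, drop = FALSE] -
      pad[i + b, j, drop = FALSE] - pad[i, j + b, drop = FALSE]
    img <- S
  }
  mu <- mean(img)
  if (mu == 0) stop("lacunarity undefined for a zero-mean image")
  mean(img^2) / mu^2 - 1
}

#' Compute all six biomarkers for one lesion region
#'
#' Runs the full biomarker panel on a segmented region: TBV from the binary
#' dermal vessel volume within the 3D ROI, and the 2D markers (density,
#' average length, tortuosity, fractal number, lacunarity) from the vessel
#' network within the STV (or lesion-center) mask. Fractal number and
#' lacunarity are evaluated on the binary segmented vessel image restricted
#' to the region, the same image used for box counting.
#'
#' @param vessel_volume binary 3D vessel volume (e.g. from
#'   [segment_vessels_3d()]), or `NULL` to skip TBV.
#' @param roi_3d logical array matching `vessel_volume`.
#' @param network a [vessel_network()] on the 2D analysis image.
#' @param roi_2d logical matrix (e.g. the STV mask).
#' @param density_representation passed to [vessel_density()].
#' @return a [biomarker_set()] with provenance.
#' @export
compute_biomarkers <- function(vessel_volume = NULL, roi_3d = NULL,
                               network, roi_2d = NULL,
                               density_representation = "skeleton") {
  stopifnot(inherits(network, "vessel_network"))
  tbv <- if (!is.null(vessel_volume))
    total_blood_volume(vessel_volume, roi_3d) else NA_real_
  dens <- vessel_density(network, roi_2d,
                         representation = density_representation)
  avl <- average_vessel_length(network)
  tor <- tortuosity(network)
  vimg <- network$mask
  if (!is.null(roi_2d)) vimg <- vimg & roi_2d
  fn <- if (any(vimg) && min(dim(vimg)) >= 32) fractal_number(vimg)
        else NA_real_
  lac <- if (any(vimg)) lacunarity(vimg) else NA_real_
  biomarker_set(
    tbv = tbv, vessel_density = dens, avg_vessel_length = avl,
    tortuosity = tor$tortuosity, mean_dm = tor$mean_dm,
    fractal_number = fn, lacunarity = lac,
    n_branch_points = if (is.null(network$branch_points)) 0L
                      else nrow(network$branch_points),
    provenance = list(density_representation = density_representation,
                      pixel_size = network$pixel_size,
                      skipped_segments = tor$skipped))
}
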