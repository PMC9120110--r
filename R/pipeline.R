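#' Run the full vascular-quantification pipeline on a raw scan
#'
#' Chains the analysis stages the way a lesion scan is processed:
#' optional motion estimation and correction, dual-band split,
#' sensitivity-weighted beamforming, a dermal region of interest, 3D
#' vessel segmentation for total blood volume, and 2D vessel network
#' analysis on the dermal coronal MIP of the high band (it resolves the
#' fine structure the skeleton metrics need), yielding the six biomarkers.
#'
#' TBV uses a dual-estimate bracket: a half-maximum mask of the low-band
#' volume (blur-broadened filled vessels — an upper bound on vessel
#' volume) and of the full-bandwidth volume (boundary-emphasizing sharp
#' rendering — a lower bound), combined as their geometric mean.
#'
#' @param scan a [raw_scan()].
#' @param grid a [recon_grid()] covering the scanned field (z from the
#'   detector plane).
#' @param dermis_range depth range `c(z0, z1)` in um (detector frame) of
#'   the dermal slab to quantify.
#' @param sensitivity a [sensitivity_field()].
#' @param bands the two frequency bands in MHz.
#' @param motion_correct estimate and correct breathing motion first.
#' @param motion_window correlation half-window (samples) for motion
#'   estimation.
#' @param roi_2d optional logical matrix (e.g. an STV mask) restricting the
#'   2D analysis.
#' @param tort_smooth_px centerline smoothing window for tortuosity (px).
#' @param vessel_args extra arguments passed to [segment_vessels()].
#' @return list: `biomarkers` (a [biomarker_set()]), `network`,
#'   `volume_low`, `volume_high`, `vessel_mask_3d`, `mip`, `motion`
#'   (the [estimate_displacement()] trace, when corrected).
#' @export
run_pipeline <- function(scan, grid, dermis_range,
                         sensitivity = sensitivity_field(),
                         bands = list(c(10, 40), c(40, 120)),
                         motion_correct = FALSE, motion_window = 150L,
                         roi_2d = NULL, tort_smooth_px = 5,
                         vessel_args = list(threshold = "halfmax",
                                            high = 0.65, low = 0.5,
                                            bg_sigma = 0)) {
  stopifnot(inherits(scan, "raw_scan"))
  trace <- NULL
  if (motion_correct) {
    trace <- estimate_displacement(scan, window = motion_window)
    scan <- correct_motion(scan, trace)
  }
  full_band <- c(bands[[1]][1], bands[[2]][2])
  split <- bandpass_split(scan, c(bands, list(full_band)))
  vol_lo <- beamform(split[[1]], grid, sensitivity = sensitivity)
  vol_hi <- beamform(split[[2]], grid, sensitivity = sensitivity)
  vol_full <- beamform(split[[3]], grid, sensitivity = sensitivity)
  ax <- volume_axes(vol_lo)
  roi3 <- array(FALSE, dim(vol_lo$intensity))
  roi3[, , ax$z >= dermis_range[1] & ax$z <= dermis_range[2]] <- TRUE
  if (!any(roi3)) stop("dermis_range selects no voxels of the grid")
  mask3 <- segment_vessels_3d(vol_lo, roi3)
  mask3_full <- segment_vessels_3d(vol_full, roi3)
  tbv <- sqrt(total_blood_volume(mask3, roi3) *
                total_blood_volume(mask3_full, roi3))
  mip <- project_mip(vol_hi, "depth", depth_range = dermis_range)
  net <- do.call(segment_vessels,
                 c(list(img = mip, roi = roi_2d,
                        pixel_size = grid$voxel_size[1]), vessel_args))
  px <- grid$voxel_size[1]
  no_tort <- list(tortuosity = NA_real_, mean_dm = NA_real_, skipped = 0L)
  if (length(net$segments)) {
    tor <- tryCatch(
      tortuosity(net, smooth_px = tort_smooth_px,
                 min_path_px = 8, min_sl_um = 4 * px),
      error = function(e) no_tort)        # all fragments below the filters
    avl <- average_vessel_length(net)
  } else {
    tor <- no_tort
    avl <- NA_real_
  }
  dens <- if (any(net$skeleton))
    vessel_density(net, roi_2d) else 0
  vimg <- net$mask
  if (!is.null(roi_2d)) vimg <- vimg & roi_2d
  fn <- if (any(vimg) && min(dim(vimg)) >= 32) fractal_number(vimg)
        else NA_real_
  lac <- if (any(vimg)) lacunarity(vimg) else NA_real_
  bm <- biomarker_set(
    tbv = tbv, vessel_density = dens, avg_vessel_length = avl,
    tortuosity = tor$tortuosity, mean_dm = tor$mean_dm,
    fractal_number = fn, lacunarity = lac,
    n_branch_points = if (is.null(net$branch_points)) 0L
                      else nrow(net$branch_points),
    provenance = list(bands = bands, dermis_range = dermis_range,
                      tort_smooth_px = tort_smooth_px,
                      motion_corrected = motion_correct,
                      vessel_args = vessel_args))
  list(biomarkers = bm, network = net, volume_low = vol_lo,
       volume_high = vol_hi, volume_full = vol_full,
       vessel_mask_3d = mask3, vessel_mask_3d_wide = mask3_full,
       mip = mip, motion = trace)
}
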