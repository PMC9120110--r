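#' Breathing-motion parameters
#'
#' Rigid vertical displacement of the imaged tissue as a function of
#' acquisition time: `amplitude * sin(2*pi*t/period + phase) + drift * t`
#' (micrometres).
#'
#' @param amplitude sinusoid amplitude, um (>= 0).
#' @param period breathing period, s (> 0).
#' @param drift linear drift, um/s.
#' @param phase phase offset, radians.
#' @return object of class `motion_params`.
#' @export
motion_params <- function(amplitude = 0, period = 4, drift = 0, phase = 0) {
  if (amplitude < 0) stop("amplitude must be >= 0")
  if (period <= 0) stop("period must be > 0")
  structure(list(amplitude = amplitude, period = period, drift = drift,
                 phase = phase), class = "motion_params")
}

#' Evaluate a motion model at given times
#' @param motion a [motion_params()].
#' @param t times in seconds.
#' @return displacement in um (positive = deeper).
#' @export
motion_displacement <- function(motion, t) {
  motion$amplitude * sin(2 * pi * t / motion$period + motion$phase) +
    motion$drift * t
}

#' Detector sensitivity field
#'
#' Depth-dependent Gaussian lateral sensitivity of the focused detector:
#' at depth z the lateral weight is `exp(-r^2 / (2 sigma(z)^2))` with
#' `sigma(z) = waist * sqrt(1 + ((z - focal_depth)/rayleigh)^2)`, a
#' Gaussian-beam-like cone with its waist at the focal depth. Support is
#' truncated at `cutoff` sigmas.
#'
#' @param focal_depth focal depth below the detector plane, um.
#' @param waist lateral sigma at focus, um.
#' @param rayleigh depth scale of the defocus cone, um.
#' @param cutoff support truncation, in sigmas.
#' @return object of class `sensitivity_field`.
#' @export
sensitivity_field <- function(focal_depth = 1000, waist = 30,
                              rayleigh = 300, cutoff = 3) {
  stopifnot(waist > 0, rayleigh > 0, cutoff > 0)
  structure(list(focal_depth = focal_depth, waist = waist,
                 rayleigh = rayleigh, cutoff = cutoff),
            class = "sensitivity_field")
}

## Bipolar (N-shaped) pressure pulse: derivative of a Gaussian, band-limited
## to [f_lo, f_hi] by a zero-phase 4th-order Butterworth. Returned
## oversampled by `os` for sub-sample placement in the forward model.
pulse_kernel <- function(sample_rate, f_lo = 10e6, f_hi = 120e6,
                         f_peak = 55e6, os = 8L) {
  fso <- sample_rate * os
  sigma <- 1 / (2 * pi * f_peak)
  half <- ceiling(6 * sigma * fso)
  t <- (-half:half) / fso
  k <- -t / sigma^2 * exp(-t^2 / (2 * sigma^2))
  b <- signal::butter(4, c(f_lo, f_hi) / (fso / 2), type = "pass")
  k <- signal::filtfilt(b, c(numeric(4 * os), k, numeric(4 * os)))
  k <- k[(4 * os + 1):(length(k) - 4 * os)]
  k <- k / max(abs(k))
  # t0_index: 0-based index of t = 0 in the oversampled kernel
  list(kernel = k, os = as.integer(os), t0_index = half)
}

#' Simulate a raster-scan optoacoustic acquisition of a phantom
#'
#' Single-scattering, fluence-flat forward model: every absorbing voxel
#' emits a band-limited bipolar pulse that arrives after the one-way travel
#' time `distance / speed_of_sound`, weighted by the detector's lateral
#' Gaussian sensitivity and 1/distance spreading. The phantom (z = 0 at the
#' skin surface) sits `standoff` um below the detector plane. Breathing is
#' modelled as a rigid vertical translation evaluated at each A-line's
#' acquisition time; white Gaussian noise of standard deviation `noise_sd`
#' (relative to the maximum clean amplitude) is added last.
#'
#' @param phantom a `phantom_truth`.
#' @param config a [scan_config()]; the scan field of view must be covered
#'   by the phantom grid.
#' @param motion a [motion_params()].
#' @param noise_sd additive white-noise SD as a fraction of the peak clean
#'   signal (0 for noiseless).
#' @param seed integer seed for the noise draw.
#' @param standoff detector-to-skin-surface distance, um.
#' @param sensitivity a [sensitivity_field()] (depths relative to the
#'   detector plane).
#' @param band pulse band limits in Hz, c(lo, hi).
#' @return a [raw_scan()].
#' @export
simulate_scan <- function(phantom, config, motion = motion_params(),
                          noise_sd = 0, seed = 1L, standoff = 400,
                          sensitivity = sensitivity_field(),
                          band = c(10e6, 120e6)) {
  stopifnot(inherits(phantom, "phantom_truth"),
            inherits(config, "scan_config"))
  grid <- phantom$grid
  ext <- grid_extent(grid)
  fov <- c((config$n_fast - 1) * config$step_fast,
           (config$n_slow - 1) * config$step_slow)
  if (fov[1] > ext[1] - grid$origin[1] + 1e-9 ||
      fov[2] > ext[2] - grid$origin[2] + 1e-9)
    stop("scan field of view extends beyond the phantom grid")
  idx <- which(phantom$absorption > 0, arr.ind = TRUE)
  pos <- scan_positions(config)
  tall <- acquisition_times(scan_dummy(config))
  sig <- array(0, c(config$n_fast, config$n_slow, config$n_samples))
  if (nrow(idx) > 0) {
    vox <- cbind(grid$origin[1] + (idx[, 1] - 0.5) * grid$voxel_size[1],
                 grid$origin[2] + (idx[, 2] - 0.5) * grid$voxel_size[2],
                 grid$origin[3] + (idx[, 3] - 0.5) * grid$voxel_size[3] +
                   standoff)
    amp <- phantom$absorption[idx]
    kern <- pulse_kernel(config$sample_rate, band[1], band[2])
    m <- forward_simulate_cpp(
      vox, amp, pos[, 1], pos[, 2], tall, config$n_samples,
      config$sample_rate, config$speed_of_sound * 1e6,
      kern$kernel, kern$os, kern$t0_index,
      motion$amplitude, motion$period, motion$drift, motion$phase,
      sensitivity$focal_depth, sensitivity$waist, sensitivity$rayleigh,
      sensitivity$cutoff)
    sig <- array(t(m), c(config$n_fast, config$n_slow, config$n_samples))
  }
  if (noise_sd > 0) {
    set.seed(as.integer(seed))
    sig <- sig + stats::rnorm(length(sig), 0, noise_sd * max(abs(sig), 1))
  }
  raw_scan(config, sig)
}

## raw_scan skeleton used only to derive acquisition times before signals
## exist (default fast-axis-major order)
scan_dummy <- function(config) {
  list(config = config,
       acquisition_order = cbind(rep(seq_len(config$n_fast), config$n_slow),
                                 rep(seq_len(config$n_slow),
                                     each = config$n_fast)))
}
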