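#' Acquisition geometry of a raster scan
#'
#' Describes the raster grid, sampling and acoustic parameters of one
#' optoacoustic mesoscopy acquisition. Defaults correspond to a 4 x 2 mm
#' field scanned at 201 x 101 points, digitized at 1 GS/s with a 1.4 kHz
#' pulse repetition rate.
#'
#' @param n_fast,n_slow number of scan positions along the fast and slow axes.
#' @param step_fast,step_slow scan step sizes in micrometres.
#' @param n_samples samples per A-line.
#' @param sample_rate digitizer rate in Hz.
#' @param speed_of_sound assumed speed of sound in m/s.
#' @param wavelengths illumination wavelengths in nm.
#' @param rep_rate laser pulse repetition rate in Hz; one A-line is acquired
#'   per pulse, so this sets the time base of the acquisition order.
#' @return an object of class `scan_config`.
#' @export
scan_config <- function(n_fast = 201L, n_slow = 101L,
                        step_fast = 20, step_slow = 20,
                        n_samples = 2048L, sample_rate = 1e9,
                        speed_of_sound = 1500, wavelengths = 532,
                        rep_rate = 1400) {
  n_fast <- as.integer(n_fast); n_slow <- as.integer(n_slow)
  n_samples <- as.integer(n_samples)
  if (n_fast < 1L || n_slow < 1L || n_samples < 1L)
    stop("n_fast, n_slow and n_samples must all be >= 1")
  if (step_fast <= 0 || step_slow <= 0) stop("scan step sizes must be > 0")
  if (sample_rate <= 0) stop("sample_rate must be > 0")
  if (speed_of_sound <= 0) stop("speed_of_sound must be > 0")
  if (rep_rate <= 0) stop("rep_rate must be > 0")
  structure(list(n_fast = n_fast, n_slow = n_slow,
                 step_fast = step_fast, step_slow = step_slow,
                 n_samples = n_samples, sample_rate = sample_rate,
                 speed_of_sound = speed_of_sound,
                 wavelengths = as.numeric(wavelengths),
                 rep_rate = rep_rate),
            class = "scan_config")
}

#' @export
print.scan_config <- function(x, ...) {
  cat(sprintf("<scan_config> %d x %d points, step %g x %g um (%g x %g mm)\n",
              x$n_fast, x$n_slow, x$step_fast, x$step_slow,
              x$n_fast * x$step_fast / 1000, x$n_slow * x$step_slow / 1000))
  cat(sprintf("  %d samples/A-line @ %g GS/s, c = %g m/s, rep rate %g Hz\n",
              x$n_samples, x$sample_rate / 1e9, x$speed_of_sound, x$rep_rate))
  invisible(x)
}

#' Raw raster-scan A-line container
#'
#' Bundles the time-resolved pressure signals recorded on the raster grid
#' with the acquisition geometry. `signals` is indexed
#' `[fast, slow, sample]`. `acquisition_order` gives the 1-based
#' `(fast, slow)` index of each A-line in the order it was recorded; the
#' default is fast-axis-major (all fast positions of slow row 1, then row 2,
#' ...), matching a raster scan whose fast stage sweeps within each slow
#' step.
#'
#' @param config a [scan_config()].
#' @param signals numeric array `[n_fast, n_slow, n_samples]`, finite.
#' @param acquisition_order integer matrix `n_fast*n_slow x 2`, a permutation
#'   of the grid.
#' @param wavelength_index integer index into `config$wavelengths` for each
#'   A-line (length 1 is recycled).
#' @return object of class `raw_scan`.
#' @export
raw_scan <- function(config, signals, acquisition_order = NULL,
                     wavelength_index = 1L) {
  stopifnot(inherits(config, "scan_config"))
  dm <- dim(signals)
  if (length(dm) != 3L ||
      !all(dm == c(config$n_fast, config$n_slow, config$n_samples)))
    stop(sprintf("signals shape [%s] does not match config [%d, %d, %d]",
                 paste(dm, collapse = ", "),
                 config$n_fast, config$n_slow, config$n_samples))
  if (!all(is.finite(signals))) stop("signals must be finite")
  np <- config$n_fast * config$n_slow
  if (is.null(acquisition_order))
    acquisition_order <- cbind(rep(seq_len(config$n_fast), config$n_slow),
                               rep(seq_len(config$n_slow),
                                   each = config$n_fast))
  acquisition_order <- matrix(as.integer(acquisition_order), ncol = 2L)
  lin <- (acquisition_order[, 2L] - 1L) * config$n_fast +
    acquisition_order[, 1L]
  if (nrow(acquisition_order) != np || !identical(sort(lin), seq_len(np)))
    stop("acquisition_order must be a permutation of the scan grid")
  wavelength_index <- as.integer(rep_len(wavelength_index, np))
  if (any(wavelength_index < 1L) ||
      any(wavelength_index > length(config$wavelengths)))
    stop("wavelength_index out of range of config$wavelengths")
  structure(list(config = config, signals = signals,
                 acquisition_order = acquisition_order,
                 wavelength_index = wavelength_index),
            class = "raw_scan")
}

#' @export
print.raw_scan <- function(x, ...) {
  cat("<raw_scan>\n"); print(x$config)
  cat(sprintf("  signal range [%.3g, %.3g]\n",
              min(x$signals), max(x$signals)))
  invisible(x)
}

#' Lateral scan positions in micrometres
#'
#' @param config a [scan_config()].
#' @return matrix `n_fast*n_slow x 2` of (x, y) positions, fast-axis-major,
#'   with position (1,1) at the origin.
#' @export
scan_positions <- function(config) {
  cbind(x = rep((seq_len(config$n_fast) - 1) * config$step_fast,
                config$n_slow),
        y = rep((seq_len(config$n_slow) - 1) * config$step_slow,
                each = config$n_fast))
}

#' Acquisition time of each A-line
#'
#' @param scan a [raw_scan()].
#' @return numeric vector: for the A-line at grid index `(fast, slow)`
#'   (fast-axis-major linear order), the time in seconds at which it was
#'   recorded, derived from its rank in `acquisition_order` and the pulse
#'   repetition rate.
#' @export
acquisition_times <- function(scan) {
  cfg <- scan$config
  lin <- (scan$acquisition_order[, 2L] - 1L) * cfg$n_fast +
    scan$acquisition_order[, 1L]
  t <- numeric(length(lin))
  t[lin] <- (seq_along(lin) - 1) / cfg$rep_rate
  t
}
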