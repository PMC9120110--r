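#' Detect the skin surface in every A-line
#'
#' Per A-line, the surface is the first sample whose signal envelope
#' (magnitude of the analytic signal) exceeds `threshold_frac` times that
#' line's envelope maximum. Lines without a detectable echo — zero envelope,
#' or a peak-to-median envelope ratio below `snr_min` (pure noise) — are
#' flagged with the `NA` sentinel rather than raising an error.
#'
#' @param scan a [raw_scan()].
#' @param threshold_frac fraction of the per-line envelope maximum.
#' @param snr_min minimum peak/median envelope ratio for a line to count as
#'   containing an echo.
#' @return integer matrix `[n_fast, n_slow]` of 1-based sample indices
#'   (`NA` = missing).
#' @export
detect_surface <- function(scan, threshold_frac = 0.5, snr_min = 6) {
  stopifnot(inherits(scan, "raw_scan"))
  cfg <- scan$config
  m <- matrix(aperm(scan$signals, c(3, 1, 2)),
              nrow = cfg$n_samples)           # samples x lines
  env <- signal_envelope(m)
  mx <- apply(env, 2, max)
  med <- apply(env, 2, stats::median)
  idx <- integer(ncol(env))
  for (j in seq_len(ncol(env))) {
    if (mx[j] <= 0 || (med[j] > 0 && mx[j] / med[j] < snr_min)) {
      idx[j] <- NA_integer_
    } else {
      idx[j] <- which(env[, j] > threshold_frac * mx[j])[1]
    }
  }
  matrix(idx, cfg$n_fast, cfg$n_slow)
}

#' Estimate per-position vertical displacement by cross-correlation
#'
#' The first A-line in acquisition order is the reference. For every other
#' A-line the lag of the cross-correlation maximum between the two signal
#' envelopes — restricted to a window around the reference's detected
#' surface — is refined to sub-sample precision by a 3-point parabolic fit
#' and converted to micrometres via the one-way relation
#' `displacement = lag * speed_of_sound / sample_rate`. Positive
#' displacement means the tissue moved deeper (away from the detector).
#' Lines flagged missing by [detect_surface()] get their displacement
#' linearly interpolated from acquisition-order neighbours.
#'
#' @param scan a [raw_scan()].
#' @param window half-width (samples) of the correlation window around the
#'   reference surface.
#' @param max_lag largest admissible lag in samples (default `window`).
#' @param on correlate `"envelope"` (default) or `"signal"`.
#' @return object of class `motion_trace`: `displacement` (um, acquisition
#'   order), `displacement_matrix` (`[fast, slow]`), `max_abs`,
#'   `reference_index`, `missing` (linear indices of interpolated lines).
#' @export
estimate_displacement <- function(scan, window = 100L, max_lag = NULL,
                                  on = c("envelope", "signal")) {
  stopifnot(inherits(scan, "raw_scan"))
  on <- match.arg(on)
  cfg <- scan$config
  ns <- cfg$n_samples
  np <- cfg$n_fast * cfg$n_slow
  if (np < 2) stop("need at least 2 A-lines")
  surf <- detect_surface(scan)
  ord <- scan$acquisition_order
  lin_order <- (ord[, 2L] - 1L) * cfg$n_fast + ord[, 1L]
  ref_lin <- lin_order[1L]
  if (is.na(surf[ref_lin]))
    stop("reference A-line (first in acquisition order) has no detectable surface")
  m <- matrix(aperm(scan$signals, c(3, 1, 2)), nrow = ns)
  x <- if (on == "envelope") signal_envelope(m) else m
  s0 <- surf[ref_lin]
  w0 <- max(1L, s0 - window); w1 <- min(ns, s0 + window)
  win <- w0:w1
  L <- length(win)
  max_lag <- as.integer(max_lag %||% min(window, floor(L / 2) - 1L))
  nfft <- 2^ceiling(log2(2L * L))
  pad <- function(v) c(v, numeric(nfft - L))
  Fref <- stats::fft(pad(x[win, ref_lin]))
  W <- rbind(x[win, , drop = FALSE],
             matrix(0, nfft - L, ncol(x)))
  CC <- Re(stats::mvfft(stats::mvfft(W) * Conj(Fref), inverse = TRUE)) / nfft
  lags <- c(0:(nfft / 2 - 1), -(nfft / 2):-1)
  keep <- which(abs(lags) <= max_lag)
  # order candidates by |lag| so that ties pick the smallest magnitude
  keep <- keep[order(abs(lags[keep]))]
  disp_samples <- numeric(np)
  for (j in seq_len(np)) {
    cc <- CC[keep, j]
    b <- keep[which.max(cc)]
    lag <- lags[b]
    # parabolic sub-sample refinement on the circular neighbours
    im <- which(lags == lag)
    ip <- im %% nfft + 1L
    in_ <- (im - 2L) %% nfft + 1L
    y0 <- CC[im, j]; ym <- CC[in_, j]; yp <- CC[ip, j]
    den <- ym - 2 * y0 + yp
    delta <- if (den < 0) 0.5 * (ym - yp) / den else 0
    delta <- max(min(delta, 0.5), -0.5)
    disp_samples[j] <- lag + delta
  }
  disp_um <- disp_samples * cfg$speed_of_sound / cfg$sample_rate * 1e6
  missing <- which(is.na(surf))
  if (length(missing)) {
    # interpolate missing lines along acquisition order
    pos_in_order <- match(seq_len(np), lin_order)
    t_ord <- pos_in_order
    good <- setdiff(seq_len(np), missing)
    disp_um[missing] <- stats::approx(t_ord[good], disp_um[good],
                                      xout = t_ord[missing], rule = 2)$y
  }
  dm <- matrix(disp_um, cfg$n_fast, cfg$n_slow)
  trace <- disp_um[lin_order]
  structure(list(displacement = trace, displacement_matrix = dm,
                 max_abs = max(abs(trace)), reference_index = ref_lin,
                 missing = missing),
            class = "motion_trace")
}

#' @export
print.motion_trace <- function(x, ...) {
  cat(sprintf("<motion_trace> %d positions, max |displacement| %.1f um, %d interpolated\n",
              length(x$displacement), x$max_abs, length(x$missing)))
  invisible(x)
}

#' Correct a raw scan for estimated vertical motion
#'
#' Shifts every A-line in time by minus its estimated displacement
#' (converted to samples), with sub-sample linear interpolation; samples
#' shifted in from outside the record are zero. Positions whose displacement
#' was interpolated (missing surface) are shifted too and listed in the
#' `corrected_missing` attribute of the result.
#'
#' @param scan a [raw_scan()].
#' @param trace a [estimate_displacement()] result on the same grid.
#' @return a corrected [raw_scan()].
#' @export
correct_motion <- function(scan, trace) {
  stopifnot(inherits(scan, "raw_scan"), inherits(trace, "motion_trace"))
  cfg <- scan$config
  if (!all(dim(trace$displacement_matrix) == c(cfg$n_fast, cfg$n_slow)))
    stop("motion trace grid does not match the scan grid")
  ns <- cfg$n_samples
  shift <- trace$displacement_matrix * cfg$sample_rate /
    (cfg$speed_of_sound * 1e6)              # samples, positive = deeper
  sig <- scan$signals
  out <- array(0, dim(sig))
  tgrid <- seq_len(ns)
  for (j in seq_len(cfg$n_slow)) for (i in seq_len(cfg$n_fast)) {
    s <- shift[i, j]
    if (s == 0) { out[i, j, ] <- sig[i, j, ]; next }
    out[i, j, ] <- stats::approx(tgrid, sig[i, j, ], xout = tgrid + s,
                                 yleft = 0, yright = 0)$y
  }
  res <- raw_scan(cfg, out, acquisition_order = scan$acquisition_order,
                  wavelength_index = scan$wavelength_index)
  attr(res, "corrected_missing") <- trace$missing
  res
}

#' Grade scan quality from the amount of motion
#'
#' Pure function of the maximum absolute displacement: `Q1` (usable as-is)
#' if `max_abs <= q1`, `Q2` (correctable) if `<= q2`, `Q3` (reject)
#' otherwise. Boundaries are inclusive. The defaults anchor Q1 at the 70 um
#' displacement typical of a held breath; scans at the 350 um level seen
#' under free breathing fall in Q3, beyond what correction can fix.
#'
#' @param trace a `motion_trace` (or a number, taken as `max_abs` in um).
#' @param thresholds named vector `c(q1 = , q2 = )` in um.
#' @return object of class `qc_grade` with fields `grade`, `max_abs`,
#'   `thresholds`.
#' @export
classify_quality <- function(trace, thresholds = c(q1 = 70, q2 = 300)) {
  max_abs <- if (inherits(trace, "motion_trace")) trace$max_abs
             else as.numeric(trace)
  stopifnot(is.finite(max_abs), thresholds["q1"] <= thresholds["q2"])
  grade <- if (max_abs <= thresholds[["q1"]]) "Q1"
           else if (max_abs <= thresholds[["q2"]]) "Q2" else "Q3"
  structure(list(grade = grade, max_abs = max_abs,
                 thresholds = thresholds), class = "qc_grade")
}

#' @export
print.qc_grade <- function(x, ...) {
  lab <- c(Q1 = "usable as-is", Q2 = "correctable", Q3 = "reject")
  cat(sprintf("<qc_grade> %s (%s): max |displacement| %.1f um (q1 = %g, q2 = %g)\n",
              x$grade, lab[[x$grade]], x$max_abs,
              x$thresholds[["q1"]], x$thresholds[["q2"]]))
  invisible(x)
}
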