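#' Signal envelope via the analytic signal
#'
#' Magnitude of the analytic signal computed with the FFT (positive
#' frequencies doubled, negative zeroed). For a matrix the transform runs
#' down each column.
#'
#' @param x numeric vector or matrix (columns are signals).
#' @return non-negative envelope, same shape as `x`.
#' @export
signal_envelope <- function(x) {
  vec <- is.null(dim(x))
  if (vec) x <- matrix(x, ncol = 1L)
  n <- nrow(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1L, n / 2 + 1L)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1L] <- 1
    if (n > 1) h[2:((n + 1) / 2)] <- 2
  }
  a <- stats::mvfft(stats::mvfft(x) * h, inverse = TRUE) / n
  e <- Mod(a)
  if (vec) e <- e[, 1L]
  e
}

## 2D median filter with an odd k x k window (edge-replicated).
medfilt2 <- function(m, k = 3L) {
  if (k < 2L) return(m)
  r <- (k - 1L) %/% 2L
  nr <- nrow(m); nc <- ncol(m)
  ri <- pmin(pmax(rep(seq_len(nr), nc), 1L), nr)
  stack <- array(NA_real_, dim = c(nr, nc, k * k))
  s <- 1L
  for (dx in -r:r) for (dy in -r:r) {
    stack[, , s] <- m[pmin(pmax(seq_len(nr) + dx, 1L), nr),
                      pmin(pmax(seq_len(nc) + dy, 1L), nc)]
    s <- s + 1L
  }
  apply(stack, c(1, 2), stats::median)
}

## Otsu threshold of a numeric vector (256-bin histogram); returns the
## threshold and the between-class / total variance ratio (separability).
otsu_threshold <- function(x, nbins = 256L) {
  x <- x[is.finite(x)]
  rng <- range(x)
  if (diff(rng) == 0) return(list(threshold = rng[1], separability = 0))
  br <- seq(rng[1], rng[2], length.out = nbins + 1L)
  h <- tabulate(findInterval(x, br, rightmost.closed = TRUE), nbins)
  p <- h / sum(h)
  mids <- (br[-1] + br[-length(br)]) / 2
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  mut <- mu[nbins]
  sb <- (mut * w0 - mu)^2 / (w0 * (1 - w0))
  sb[!is.finite(sb)] <- 0
  k <- which.max(sb)
  list(threshold = mids[k], separability = sb[k] / stats::var(x) /
         (length(x) - 1) * length(x))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
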