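tone_scan <- function(freqs) {
  n <- 1024
  cfg <- scan_config(n_fast = length(freqs), n_slow = 1, n_samples = n)
  t <- (seq_len(n) - 1) / 1e9
  sig <- array(0, c(length(freqs), 1, n))
  for (i in seq_along(freqs))
    sig[i, 1, ] <- sin(2 * pi * freqs[i] * t) *
      exp(-((t - 5e-7) / 1.5e-7)^2)
  raw_scan(cfg, sig)
}

test_that("the band split separates tone bursts by >= 95% of their energy", {
  sc <- tone_scan(c(30e6, 80e6))
  bands <- bandpass_split(sc)
  en <- function(x) sum(x^2)
  e30 <- en(sc$signals[1, 1, ]); e80 <- en(sc$signals[2, 1, ])
  expect_gt(en(bands[[1]]$signals[1, 1, ]) / e30, 0.95)
  expect_lt(en(bands[[2]]$signals[1, 1, ]) / e30, 0.05)
  expect_gt(en(bands[[2]]$signals[2, 1, ]) / e80, 0.95)
  expect_lt(en(bands[[1]]$signals[2, 1, ]) / e80, 0.05)
})

test_that("DC is rejected, in-band energy is conserved, Nyquist enforced", {
  cfg <- scan_config(n_fast = 1, n_slow = 1, n_samples = 512)
  dc <- raw_scan(cfg, array(1, c(1, 1, 512)))
  bands <- bandpass_split(dc)
  expect_lt(max(abs(bands[[1]]$signals)), 1e-6)
  expect_lt(max(abs(bands[[2]]$signals)), 1e-6)

  # broadband in-band pulse: low + high energy >= 90% of the input
  k <- rsomvasc:::pulse_kernel(1e9)$kernel
  k <- k[seq(1, length(k), by = 8)]
  sig <- array(0, c(1, 1, 512)); sig[1, 1, 200 + seq_along(k)] <- k
  sc <- raw_scan(cfg, sig)
  bb <- bandpass_split(sc)
  etot <- sum(sig^2)
  expect_gt((sum(bb[[1]]$signals^2) + sum(bb[[2]]$signals^2)) / etot, 0.9)

  slow <- scan_config(n_fast = 1, n_slow = 1, n_samples = 64,
                      sample_rate = 2e8)
  expect_error(bandpass_split(raw_scan(slow, array(0, c(1, 1, 64)))),
               "Nyquist")
})

test_that("beamforming is linear before envelope detection", {
  ph <- small_phantom()
  cfg <- scan_config(n_fast = 12, n_slow = 8, step_fast = 60,
                     step_slow = 60, n_samples = 800)
  sens <- test_sensitivity()
  sc <- simulate_scan(ph, cfg, standoff = 400, sensitivity = sens)
  grid <- recon_grid(dim = c(12, 8, 20), voxel_size = c(55, 50, 20),
                     origin = c(0, 0, 600))
  s2 <- sc; s2$signals <- 2 * sc$signals + 100 * 0
  mix <- sc; mix$signals <- 1.5 * sc$signals + 0.5 * s2$signals
  b  <- beamform(sc,  grid, sensitivity = sens, envelope = FALSE)
  b2 <- beamform(s2,  grid, sensitivity = sens, envelope = FALSE)
  bm <- beamform(mix, grid, sensitivity = sens, envelope = FALSE)
  expect_equal(bm$intensity, 1.5 * b$intensity + 0.5 * b2$intensity,
               tolerance = 1e-10)
})

test_that("a simulated point absorber is localized within one voxel", {
  g <- phantom_grid(dim = c(40, 40, 60), voxel_size = c(20, 20, 10))
  ap <- array(0, g$dim); ap[20, 24, 30] <- 1   # truth (390, 470, 695) um
  ph <- structure(list(absorption = ap, grid = g, depth_range = c(0, 600)),
                  class = "phantom_truth")
  cfg <- scan_config(n_fast = 20, n_slow = 20, step_fast = 40,
                     step_slow = 40, n_samples = 900)
  sens <- test_sensitivity()
  sc <- simulate_scan(ph, cfg, standoff = 400, sensitivity = sens)
  grid <- recon_grid(dim = c(38, 38, 60), voxel_size = c(20, 20, 10),
                     origin = c(0, 0, 500))
  vol <- beamform(sc, grid, sensitivity = sens)
  am <- which(vol$intensity == max(vol$intensity), arr.ind = TRUE)[1, ]
  ax <- rsomvasc:::volume_axes(vol)
  truth <- c(390, 470, 695)
  err <- abs(c(ax$x[am[1]], ax$y[am[2]], ax$z[am[3]]) - truth)
  expect_true(all(err <= c(20, 20, 10)))
})

test_that("all-zero signals beamform to an all-zero volume", {
  cfg <- scan_config(n_fast = 6, n_slow = 4, step_fast = 60,
                     step_slow = 60, n_samples = 256)
  sc <- raw_scan(cfg, array(0, c(6, 4, 256)))
  vol <- beamform(sc, recon_grid(dim = c(6, 4, 10),
                                 voxel_size = c(50, 45, 20)),
                  sensitivity = test_sensitivity())
  expect_true(all(vol$intensity == 0))
})

test_that("dual-band compositing normalizes per band and checks grids", {
  set.seed(6)
  a <- array(abs(rnorm(4 * 4 * 4)), c(4, 4, 4))
  lo <- recon_volume(a, band = c(10, 40))
  hi <- recon_volume(a, band = c(40, 120))
  cp <- composite_dual_band(lo, hi)
  expect_equal(cp$red, cp$green)           # identical inputs
  zero <- recon_volume(array(0, c(4, 4, 4)), band = c(40, 120))
  cp0 <- composite_dual_band(lo, zero)
  expect_true(all(cp0$green == 0))
  expect_lte(max(cp$red), 1)
  other <- recon_volume(array(1, c(5, 4, 4)))
  expect_error(composite_dual_band(lo, other), "grid")
})

test_that("MIPs take maxima over the right axes and ranges", {
  v <- array(0, c(6, 5, 8))
  v[2, 3, 4] <- 7
  vol <- recon_volume(v, voxel_size = c(10, 10, 10))
  mip <- project_mip(vol, "depth")
  expect_equal(sum(mip == 7), 1)
  expect_equal(mip[2, 3], 7)
  expect_equal(sum(mip), 7)
  # slab decomposition: max of slab MIPs equals the full MIP
  m1 <- project_mip(vol, "depth", c(0, 40))
  m2 <- project_mip(vol, "depth", c(40, 80))
  expect_equal(pmax(m1, m2), matrix(mip, 6, 5), ignore_attr = TRUE)
  # cross-sectional axis
  ms <- project_mip(vol, "slow")
  expect_equal(dim(ms), c(6, 8))
  expect_equal(ms[2, 4], 7)
  expect_error(project_mip(vol, "depth", c(100, 120)), "no voxels")
})

test_that("spectral unmixing inverts exact mixtures and guards rank", {
  # melanin / HbO2 / Hb style spectra at four wavelengths
  S <- matrix(c(1.0, 0.7, 0.5, 0.35,
                0.30, 0.45, 0.30, 0.85,
                0.55, 0.35, 0.60, 0.40), ncol = 3)
  colnames(S) <- c("melanin", "hbo2", "hb")
  set.seed(7)
  dm <- c(5, 4, 3)
  F_true <- lapply(1:3, function(k) array(runif(prod(dm)), dm))
  vols <- lapply(seq_len(nrow(S)), function(w)
    S[w, 1] * F_true[[1]] + S[w, 2] * F_true[[2]] + S[w, 3] * F_true[[3]])
  um <- unmix_spectra(vols, S)
  for (k in 1:3)
    expect_equal(um$components[[k]], F_true[[k]], tolerance = 1e-6)
  expect_lt(um$residual_norm, 1e-8)

  # a pure-melanin voxel yields zero hemoglobin
  pure <- lapply(seq_len(nrow(S)), function(w) array(S[w, 1], c(2, 2, 1)))
  ump <- unmix_spectra(pure, S)
  expect_equal(max(ump$components$hbo2), 0, tolerance = 1e-8)
  expect_equal(max(ump$components$hb), 0, tolerance = 1e-8)

  # 1% noise keeps the mean absolute fraction error under 0.05
  set.seed(8)
  noisy <- lapply(vols, function(v) v + rnorm(length(v), 0, 0.01))
  umn <- unmix_spectra(noisy, S)
  err <- mean(abs(unlist(umn$components) - unlist(F_true)))
  expect_lt(err, 0.05)

  Sr <- S; Sr[, 3] <- Sr[, 1] * 2
  expect_error(unmix_spectra(vols, Sr), "rank")
})
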