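test_that("total blood volume is the nonzero-voxel fraction of the ROI", {
  v <- array(0, c(10, 10, 10))
  v[1:10, 1, 1] <- 1
  expect_equal(total_blood_volume(v), 0.01)
  expect_equal(total_blood_volume(array(0, c(5, 5, 5))), 0)
  # counting oracle on a random mask and ROI
  set.seed(12)
  m <- array(runif(8^3) < 0.3, c(8, 8, 8))
  roi <- array(runif(8^3) < 0.6, c(8, 8, 8))
  expect_equal(total_blood_volume(m, roi), sum(m & roi) / sum(roi))
  expect_error(total_blood_volume(m, array(FALSE, c(8, 8, 8))), "ROI")
  # invariance to intensity rescaling of a nonzero-coded volume
  expect_equal(total_blood_volume(m * 7.3, roi),
               total_blood_volume(m, roi))
})

test_that("vessel density counts the chosen representation per ROI area", {
  sk <- matrix(FALSE, 100, 100); sk[50, 1:100] <- TRUE
  mask <- matrix(FALSE, 100, 100); mask[48:52, 1:100] <- TRUE
  net <- vessel_network(mask, sk, NULL, list(), pixel_size = 12)
  expect_equal(vessel_density(net), 0.01)
  expect_equal(vessel_density(net, representation = "mask"), 0.05)
  roi <- matrix(FALSE, 100, 100); roi[, 1:50] <- TRUE
  expect_equal(vessel_density(net, roi), 50 / 5000)
  empty <- vessel_network(matrix(FALSE, 10, 10), matrix(FALSE, 10, 10),
                          NULL, list(), 12)
  expect_equal(vessel_density(empty), 0)
  # density is monotone in the number of phantom tubes
  dens <- vapply(1:5, function(k) {
    m <- matrix(FALSE, 60, 60)
    for (r in seq_len(k) * 10) m[r, 5:55] <- TRUE
    vessel_density(vessel_network(m, m, NULL, list(), 12))
  }, numeric(1))
  expect_true(all(diff(dens) > 0))
})

test_that("average vessel length divides total length by branch count", {
  net <- vessel_network(
    matrix(TRUE, 2, 2), matrix(FALSE, 2, 2),
    branch_points = rbind(c(1, 1), c(2, 2)),
    segments = list(list(al_um = 100, sl_um = 90),
                    list(al_um = 200, sl_um = 150),
                    list(al_um = 300, sl_um = 250)),
    pixel_size = 12)
  expect_equal(average_vessel_length(net), 300)  # 600 / 2
  solo <- vessel_network(matrix(TRUE, 2, 2), matrix(FALSE, 2, 2), NULL,
                         list(list(al_um = 500, sl_um = 480)), 12)
  expect_equal(average_vessel_length(solo), 500) # fallback divisor 1
  empty <- vessel_network(matrix(FALSE, 2, 2), matrix(FALSE, 2, 2), NULL,
                          list(), 12)
  expect_error(average_vessel_length(empty), "segments")
})

test_that("tortuosity reproduces analytic distance metrics", {
  straight <- list(list(al_um = 400, sl_um = 400))
  ts <- tortuosity(straight)
  expect_equal(ts$mean_dm, 1, tolerance = 1e-12)
  expect_equal(ts$tortuosity, 0, tolerance = 1e-12)

  # semicircle: AL = pi * r, SL = 2 r -> DM = pi/2
  th <- seq(0, pi, length.out = 4001)
  arc <- cbind(cos(th), sin(th)) * 500
  al <- sum(sqrt(rowSums(diff(arc)^2)))
  semi <- list(list(al_um = al, sl_um = 1000))
  expect_equal(tortuosity(semi)$mean_dm, pi / 2, tolerance = 1e-3)

  # random polylines: DM matches a brute-force oracle to 1e-9
  set.seed(13)
  segs <- lapply(1:20, function(i) {
    p <- apply(matrix(rnorm(40), ncol = 2), 2, cumsum)
    list(path = p,
         al_um = sum(sqrt(rowSums(diff(p)^2))),
         sl_um = sqrt(sum((p[nrow(p), ] - p[1, ])^2)))
  })
  tor <- tortuosity(segs)
  oracle <- mean(vapply(segs, function(s) {
    d <- diff(s$path)
    sum(sqrt(rowSums(d^2))) / sqrt(sum((s$path[nrow(s$path), ] -
                                        s$path[1, ])^2))
  }, numeric(1)))
  expect_equal(tor$mean_dm, oracle, tolerance = 1e-9)

  # zero-chord segments are skipped and reported
  loop <- c(segs, list(list(al_um = 50, sl_um = 0)))
  expect_equal(tortuosity(loop)$skipped, 1L)
  expect_error(tortuosity(list(list(al_um = 1, sl_um = 0))), "chord")
})

test_that("box counting recovers the dimension of lines, planes, fractals", {
  line <- matrix(0, 512, 512); line[256, ] <- 1
  expect_lt(abs(fractal_number(line) - 1), 0.05)
  expect_lt(abs(fractal_number(matrix(1, 512, 512)) - 2), 0.05)
  expect_lt(abs(fractal_number(diag(512)) - 1), 0.05)
  carpet <- sierpinski_carpet(5)
  expect_lt(abs(fractal_number(carpet) - log(8) / log(3)), 0.05)
  expect_error(fractal_number(matrix(1, 16, 16)), "scales")
  expect_error(fractal_number(matrix(0, 64, 64)), "empty")
})

test_that("the fractal number is stable under sub-box translations", {
  set.seed(14)
  img <- matrix(0, 256, 256)
  img[64:192, 64] <- 1; img[128, 32:224] <- 1; img[64:192, 160] <- 1
  f0 <- fractal_number(img)
  for (sh in list(c(1, 0), c(0, 1), c(1, 1))) {
    shifted <- matrix(0, 256, 256)
    shifted[(65:193) - 1 + sh[1], 64 + sh[2]] <- 1
    shifted[128 + sh[1], (33:225) - 1 + sh[2]] <- 1
    shifted[(65:193) - 1 + sh[1], 160 + sh[2]] <- 1
    expect_lt(abs(fractal_number(shifted) - f0), 0.02)
  }
})

test_that("lacunarity follows its closed forms", {
  expect_equal(lacunarity(matrix(5, 10, 10)), 0)
  half <- matrix(c(rep(0, 50), rep(3, 50)), 10)
  expect_equal(lacunarity(half), 1)
  expect_equal(lacunarity(matrix(c(1, 0, 0, 0), 2)), 3)
  expect_error(lacunarity(matrix(0, 4, 4)), "zero-mean")
  # property: binary image with fill fraction p has L = 1/p - 1
  set.seed(15)
  for (p in c(0.1, 0.25, 0.5, 0.8)) {
    b <- matrix(runif(400) < p, 20)
    expect_equal(lacunarity(b), 1 / mean(b) - 1, tolerance = 1e-12)
  }
  # gliding-box variant: constant image still has zero lacunarity
  expect_equal(lacunarity(matrix(2, 16, 16), box_size = 4), 0)
})

test_that("compute_biomarkers assembles all six markers deterministically", {
  set.seed(16)
  sk <- matrix(FALSE, 64, 64)
  sk[20, 10:50] <- TRUE; sk[40, 10:50] <- TRUE; sk[10:50, 32] <- TRUE
  mask <- sk
  net <- segment_vessels(EBImage::gblur(mask * 1, 1.5), pixel_size = 12,
                         bg_sigma = 0)
  v3 <- array(FALSE, c(64, 64, 8)); v3[, , 4] <- mask
  bm1 <- compute_biomarkers(v3, NULL, net)
  bm2 <- compute_biomarkers(v3, NULL, net)
  expect_identical(as.data.frame(bm1), as.data.frame(bm2))
  expect_equal(bm1$tbv, sum(v3) / length(v3))
  expect_true(bm1$mean_dm >= 1)
  expect_true(bm1$fractal_number > 0.8 && bm1$fractal_number < 2)
  expect_gte(bm1$lacunarity, 0)
})
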