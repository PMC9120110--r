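test_that("the DP boundary tracer equals a Dijkstra oracle on 100 instances", {
  set.seed(42)
  for (i in 1:100) {
    cost <- matrix(runif(64), 8, 8)
    dp <- trace_boundary_dp(cost, 2L)
    expect_equal(dp$cost, dijkstra_cost(cost), tolerance = 1e-12)
    # the returned path reproduces its own cost and respects the jump bound
    expect_equal(sum(cost[cbind(dp$path, 1:8)]), dp$cost,
                 tolerance = 1e-12)
    expect_true(all(abs(diff(dp$path)) <= 2))
  }
})

test_that("DP ties resolve to the topmost path and degenerate input errors", {
  dp <- trace_boundary_dp(matrix(0, 6, 5), 2L)
  expect_equal(dp$path, rep(1L, 5))
  zc <- matrix(1, 4, 4); zc[, 2] <- Inf
  expect_error(trace_boundary_dp(zc), "infinite")
  expect_error(trace_boundary_dp(matrix(1, 3, 1)), "2 columns")
  one_row <- matrix(c(5, 1, 5, 5, 1, 5), 3, 2)
  expect_equal(trace_boundary_dp(one_row)$path, c(2L, 2L))
})

test_that("surface flattening centres the surface and inverts cleanly", {
  # smooth volume: linear interpolation round-trips with small error
  v <- array(0, c(20, 10, 40))
  for (k in 1:40) v[, , k] <- outer(sin((1:20) / 3), cos((1:10) / 2)) +
    sin(k / 5) + 2
  vol <- recon_volume(v, voxel_size = c(10, 10, 5))
  flat0 <- flatten_surface(vol, matrix(0, 20, 10))
  expect_equal(flat0$intensity, v)         # zero surface = identity
  surf <- matrix(rep(seq(0, 30, length.out = 20), 10), 20, 10)
  flat <- flatten_surface(vol, surf)
  back <- unflatten_surface(flat)
  interior <- back$intensity[, , 10:30]
  expect_lt(mean(abs(interior - v[, , 10:30])), 0.06)
  expect_error(flatten_surface(vol, matrix(1e4, 20, 10)), "outside")
})

test_that("a tilted surface flattens to within one depth voxel", {
  vol <- layered_volume(250)
  # tilt the whole volume by shifting columns, then flatten it back
  tilt <- matrix(rep(seq(0, 60, length.out = 40), 20), 40, 20)
  tilted <- unflatten_surface(structure(vol,
                                        surface_shift_um = -tilt))
  surf <- detect_surface_map(tilted)
  flat <- flatten_surface(tilted, surf)
  resurf <- detect_surface_map(flat)
  expect_lt(stats::sd(resurf), 6 + 1e-9)   # <= 1 z-voxel spread
})

test_that("layer segmentation finds the band bottom and orders thicknesses", {
  ly1 <- segment_layers(layered_volume(220), exclusion_um = 60)
  ly2 <- segment_layers(layered_volume(320), exclusion_um = 60)
  expect_true(all(ly1$ep_top == 0))
  # the falling edge sits at the band bottom (half-envelope tolerance)
  expect_lt(abs(median(ly1$ep_bottom) - 220), 30)
  expect_lt(abs(median(ly2$ep_bottom) - 320), 30)
  expect_gt(median(ly2$ep_bottom), median(ly1$ep_bottom))
  # vessels-only volume: the coherence guard rejects and suggests override
  expect_error(segment_layers(layered_volume(250, band = FALSE),
                              exclusion_um = 60), "fixed_thickness")
  fixed <- segment_layers(layered_volume(250, band = FALSE),
                          fixed_thickness_um = 150)
  expect_true(all(fixed$ep_bottom == 150))
})

test_that("a bright disk is segmented with small mean radial error", {
  im <- matrix(0.1, 260, 220)
  px <- matrix(rep(1:260, 220), 260)
  py <- matrix(rep(1:220, each = 260), 260)
  im[(px - 130)^2 + (py - 110)^2 <= 60^2] <- 1
  reg <- segment_lesion_boundary(im, pixel_size = 12)
  rad <- sqrt((reg$boundary_path[, 1] - 130)^2 +
              (reg$boundary_path[, 2] - 110)^2)
  expect_lt(mean(abs(rad - 60)), 2)
  expect_error(segment_lesion_boundary(matrix(1, 64, 64)), "contrast")
  # two disks: the larger one is kept
  im2 <- matrix(0.1, 260, 220)
  im2[(px - 80)^2 + (py - 110)^2 <= 50^2] <- 1
  im2[(px - 210)^2 + (py - 170)^2 <= 20^2] <- 1
  reg2 <- segment_lesion_boundary(im2, pixel_size = 12)
  expect_true(reg2$lesion_mask[80, 110])
  expect_false(reg2$lesion_mask[210, 170])
})

test_that("the STV band has the prescribed width and area", {
  # straight vertical boundary: ceil(500/12) = 42 columns of band
  les <- matrix(FALSE, 100, 120); les[, 1:40] <- TRUE
  reg <- structure(list(lesion_mask = les, pixel_size = 12,
                        stv_mask = NULL, band_width = NA),
                   class = "lesion_regions")
  reg <- suppressWarnings(extract_stv_band(reg, 500, 12))
  cols <- which(apply(reg$stv_mask, 2, any))
  expect_equal(range(cols), c(41, 82))
  expect_false(any(reg$stv_mask & reg$lesion_mask))

  # circular lesion: area of the annulus within 5%
  im <- matrix(0.1, 300, 300)
  px <- matrix(rep(1:300, 300), 300); py <- t(px)
  im[(px - 150)^2 + (py - 150)^2 <= 50^2] <- 1
  reg2 <- extract_stv_band(segment_lesion_boundary(im, pixel_size = 12),
                           500, 12)
  expect_lt(abs(sum(reg2$stv_mask) / (pi * (92^2 - 50^2)) - 1), 0.05)

  # area grows linearly with band width on a straight boundary
  areas <- vapply(c(250, 500, 750), function(bw)
    sum(suppressWarnings(extract_stv_band(reg, bw, 12))$stv_mask),
    numeric(1))
  expect_equal(areas / areas[1], c(1, 2, 3), tolerance = 0.05)

  empty <- structure(list(lesion_mask = matrix(FALSE, 10, 10),
                          pixel_size = 12, stv_mask = NULL,
                          band_width = NA), class = "lesion_regions")
  expect_error(extract_stv_band(empty), "empty")
})

test_that("vessel segmentation recovers tubes, crossings and empties", {
  blur <- function(m) EBImage::gblur(m, 2)
  img <- matrix(0, 120, 120); img[60, 20:100] <- 1
  net <- segment_vessels(blur(img), pixel_size = 12, bg_sigma = 0)
  expect_equal(length(net$segments), 1L)
  expect_true(is.null(net$branch_points) || nrow(net$branch_points) == 0)
  sk <- which(net$skeleton, arr.ind = TRUE)
  expect_lt(mean(abs(sk[, 1] - 60)), 1)    # skeleton on the centerline
  expect_lt(abs(net$segments[[1]]$al_um / 12 - 81) / 81, 0.1)

  img2 <- matrix(0, 120, 120)
  img2[60, 10:110] <- 1; img2[10:110, 60] <- 1
  net2 <- segment_vessels(blur(img2), pixel_size = 12, bg_sigma = 0)
  expect_gte(nrow(net2$branch_points), 1)

  net0 <- suppressWarnings(segment_vessels(matrix(0, 50, 50),
                                           pixel_size = 12))
  expect_equal(length(net0$segments), 0L)
  expect_false(any(net0$mask))
  expect_error(segment_vessels(img, roi = matrix(FALSE, 120, 120)),
               "ROI")
})

test_that("phantom tube rasters are skeletonized near their centerlines", {
  # three parallel tubes -> three segments, total length within 15%
  img <- matrix(0, 150, 100)
  for (r in c(30, 75, 120)) img[r + (-2:2), 15:85] <- 1
  net <- segment_vessels(EBImage::gblur(img, 1.5), pixel_size = 10,
                         bg_sigma = 0)
  expect_equal(length(net$segments), 3L)
  total <- sum(vapply(net$segments, function(s) s$al_um, numeric(1)))
  expect_lt(abs(total / (3 * 71 * 10) - 1), 0.15)
})

test_that("the 3D vessel mask respects the ROI and empty inputs", {
  set.seed(10)
  v <- array(abs(rnorm(20 * 20 * 20, 0, 0.01)), c(20, 20, 20))
  v[8:12, 8:12, 5:15] <- 1
  roi <- array(TRUE, dim(v))
  mask <- segment_vessels_3d(v, roi)
  expect_true(all(mask[9:11, 9:11, 8:12]))
  expect_lt(mean(mask), 0.1)
  expect_error(segment_vessels_3d(v, array(FALSE, dim(v))), "ROI")
  expect_false(any(segment_vessels_3d(array(0, c(8, 8, 8)))))
})
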