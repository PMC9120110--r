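#' Detect the skin surface on a reconstructed volume
#'
#' Per (x, y) column, the surface is the first depth voxel whose intensity
#' exceeds `threshold_frac` times the column maximum; the map is smoothed
#' with a 3x3 median filter. Columns without signal get the median surface
#' of their neighbours.
#'
#' @param volume a [recon_volume()].
#' @param threshold_frac fraction of the per-column maximum.
#' @return a surface map: matrix `[x, y]` of depths in um (volume z
#'   coordinates).
#' @export
detect_surface_map <- function(volume, threshold_frac = 0.5) {
  stopifnot(inherits(volume, "recon_volume"))
  v <- volume$intensity
  d <- dim(v)
  ax <- volume_axes(volume)
  idx <- matrix(NA_real_, d[1], d[2])
  for (j in seq_len(d[2])) for (i in seq_len(d[1])) {
    col <- v[i, j, ]
    mx <- max(col)
    if (mx > 0) idx[i, j] <- ax$z[which(col > threshold_frac * mx)[1]]
  }
  if (anyNA(idx)) idx[is.na(idx)] <- stats::median(idx, na.rm = TRUE)
  medfilt2(idx, 3L)
}

#' Flatten the skin surface of a volume
#'
#' Shifts every (x, y) depth column so that the detected surface sits at
#' depth 0 (linear interpolation between voxels; samples shifted in from
#' outside are zero). The applied shifts are stored so the operation can be
#' inverted with [unflatten_surface()]. After flattening, z is depth below
#' the skin surface.
#'
#' @param volume a [recon_volume()].
#' @param surface matrix `[x, y]` of surface depths in um (volume z
#'   coordinates), e.g. from [detect_surface_map()].
#' @return a flattened [recon_volume()] (origin z = 0) with attribute
#'   `surface_shift_um`.
#' @export
flatten_surface <- function(volume, surface) {
  stopifnot(inherits(volume, "recon_volume"))
  v <- volume$intensity
  d <- dim(v)
  if (!all(dim(surface) == d[1:2]))
    stop("surface map does not match the volume grid")
  ax <- volume_axes(volume)
  if (any(surface < min(ax$z) - volume$voxel_size[3] |
          surface > max(ax$z) + volume$voxel_size[3]))
    stop("surface lies outside the volume depth range")
  dz <- volume$voxel_size[3]
  out <- array(0, d)
  zi <- seq_len(d[3])
  for (j in seq_len(d[2])) for (i in seq_len(d[1])) {
    s <- (surface[i, j] - volume$origin[3]) / dz   # shift in voxels
    if (abs(s) < 1e-12) { out[i, j, ] <- v[i, j, ]; next }
    out[i, j, ] <- stats::approx(zi, v[i, j, ], xout = zi + s,
                                 yleft = 0, yright = 0)$y
  }
  res <- recon_volume(out, voxel_size = volume$voxel_size,
                      band = volume$band,
                      origin = c(volume$origin[1:2], 0))
  attr(res, "surface_shift_um") <- surface
  res
}

#' Undo [flatten_surface()]
#' @param volume a flattened [recon_volume()] carrying `surface_shift_um`.
#' @param original_origin the z origin of the unflattened volume (um).
#' @return the unflattened [recon_volume()] (up to interpolation error).
#' @export
unflatten_surface <- function(volume, original_origin = 0) {
  surface <- attr(volume, "surface_shift_um")
  if (is.null(surface)) stop("volume carries no surface shifts to invert")
  v <- volume$intensity; d <- dim(v)
  dz <- volume$voxel_size[3]
  out <- array(0, d)
  zi <- seq_len(d[3])
  for (j in seq_len(d[2])) for (i in seq_len(d[1])) {
    s <- (surface[i, j] - original_origin) / dz
    out[i, j, ] <- stats::approx(zi, v[i, j, ], xout = zi - s,
                                 yleft = 0, yright = 0)$y
  }
  recon_volume(out, voxel_size = volume$voxel_size, band = volume$band,
               origin = c(volume$origin[1:2], original_origin))
}

#' Minimal-cost column-monotone path by dynamic programming
#'
#' Finds the path that visits exactly one row per column, moves at most
#' `jump` rows between adjacent columns, and minimizes the summed cost —
#' the layer-boundary tracer used for epidermis and lesion segmentation.
#' The optimum is global for this neighbourhood; ties resolve to the
#' smallest row index.
#'
#' @param cost numeric matrix (rows x columns); `Inf` masks nodes, at least
#'   2 columns, no NA.
#' @param jump maximum vertical step between adjacent columns (px).
#' @return list: `path` (row index per column), `cost` (total).
#' @export
trace_boundary_dp <- function(cost, jump = 2L) {
  cost <- as.matrix(cost)
  nr <- nrow(cost); nc <- ncol(cost)
  if (nc < 2L) stop("cost image needs at least 2 columns")
  if (anyNA(cost)) stop("cost image must not contain NA")
  bad <- which(!apply(is.finite(cost), 2, any))
  if (length(bad))
    stop(sprintf("column %d of the cost image is entirely infinite", bad[1]))
  jump <- as.integer(jump)
  D <- matrix(Inf, nr, nc)
  P <- matrix(0L, nr, nc)
  D[, 1] <- cost[, 1]
  rows <- seq_len(nr)
  for (cc in 2:nc) {
    best <- rep(Inf, nr); barg <- integer(nr)
    for (off in -jump:jump) {
      pr <- rows + off
      ok <- pr >= 1L & pr <= nr
      cand <- rep(Inf, nr)
      cand[ok] <- D[pr[ok], cc - 1L]
      # strict < keeps the earliest (smallest) predecessor row on ties,
      # because off runs in ascending predecessor order for each row
      upd <- cand < best
      best[upd] <- cand[upd]
      barg[upd] <- pr[upd]
    }
    D[, cc] <- cost[, cc] + best
    P[, cc] <- barg
  }
  end <- which.min(D[, nc])          # which.min: smallest row on ties
  path <- integer(nc)
  path[nc] <- end
  for (cc in nc:2) path[cc - 1L] <- P[path[cc], cc]
  list(path = path, cost = D[end, nc])
}

#' Segment the epidermis layer of a flattened volume
#'
#' The epidermal top is the flattened surface (depth 0). The epidermal
#' bottom — the melanin-to-dermis transition — is traced per B-scan with
#' [trace_boundary_dp()] on a falling-edge cost (negative depth gradient of
#' intensity), excluding a superficial margin, and smoothed with a 3x3
#' median filter across the scan grid.
#'
#' @param volume a flattened [recon_volume()].
#' @param exclusion_um superficial margin excluded from the search (um).
#' @param min_coherence minimum coherence of the traced edge: the mean
#'   falling-edge strength along the DP paths divided by the 99.9th
#'   percentile of all falling-edge values. A melanin band presents a
#'   strong edge in every column (ratio near 1); scattered vessels force
#'   the path through near-zero edges (ratio near 0). Below the threshold
#'   the layer is declared unresolvable and an error suggests a fixed
#'   thickness.
#' @param fixed_thickness_um optional manual override: skip the search and
#'   place the epidermal bottom at this depth everywhere.
#' @param jump DP vertical step bound (voxels).
#' @return object of class `layer_boundaries`: matrices `ep_top`,
#'   `ep_bottom` (um below the flattened surface), plus the measured
#'   `coherence`.
#' @export
segment_layers <- function(volume, exclusion_um = 50, min_coherence = 0.5,
                           fixed_thickness_um = NULL, jump = 2L) {
  stopifnot(inherits(volume, "recon_volume"))
  d <- dim(volume$intensity)
  dz <- volume$voxel_size[3]
  if (!is.null(fixed_thickness_um)) {
    eb <- matrix(fixed_thickness_um, d[1], d[2])
    return(structure(list(ep_top = matrix(0, d[1], d[2]), ep_bottom = eb,
                          voxel_size = volume$voxel_size),
                     class = "layer_boundaries"))
  }
  z0 <- max(2L, ceiling(exclusion_um / dz) + 1L)
  if (z0 >= d[3] - 1L) stop("exclusion margin leaves no depth to search")
  eb <- matrix(NA_real_, d[1], d[2])
  path_edges <- numeric(0)
  edge_all <- numeric(0)
  for (j in seq_len(d[2])) {
    b <- volume$intensity[, j, ]                 # x by z
    g <- b[, -1, drop = FALSE] - b[, -ncol(b), drop = FALSE]  # dI/dz
    edge <- pmax(-g, 0)                          # falling edges only
    edge <- edge[, (z0 - 1L):ncol(edge), drop = FALSE]
    cost <- max(edge) - edge
    dp <- trace_boundary_dp(t(cost), jump = jump)  # rows = z, cols = x
    eb[, j] <- (dp$path + z0 - 1L) * dz            # depth of the edge
    path_edges <- c(path_edges, edge[cbind(seq_len(d[1]), dp$path)])
    edge_all <- c(edge_all, edge)
  }
  ref <- stats::quantile(edge_all, 0.999, names = FALSE)
  coherence <- if (ref > 0) mean(path_edges) / ref else 0
  if (coherence < min_coherence)
    stop(sprintf(
      "no gradient contrast for the epidermal boundary (coherence %.3f < %.2f); supply fixed_thickness_um to override",
      coherence, min_coherence))
  structure(list(ep_top = matrix(0, d[1], d[2]),
                 ep_bottom = medfilt2(eb, 3L),
                 coherence = coherence,
                 voxel_size = volume$voxel_size),
            class = "layer_boundaries")
}

## bilinear interpolation at continuous 1-based coordinates (clamped)
bilinear <- function(img, x, y) {
  nr <- nrow(img); nc <- ncol(img)
  x <- pmin(pmax(x, 1), nr); y <- pmin(pmax(y, 1), nc)
  x0 <- pmin(floor(x), nr - 1L); y0 <- pmin(floor(y), nc - 1L)
  fx <- x - x0; fy <- y - y0
  img[cbind(x0, y0)] * (1 - fx) * (1 - fy) +
    img[cbind(x0 + 1, y0)] * fx * (1 - fy) +
    img[cbind(x0, y0 + 1)] * (1 - fx) * fy +
    img[cbind(x0 + 1, y0 + 1)] * fx * fy
}

#' Segment the pigmented-lesion boundary on an epidermal MIP
#'
#' The lesion is the high-intensity connected region of the epidermal-layer
#' coronal MIP (pigment generates the strongest signal). An Otsu threshold
#' locates the candidate region — rejected with a "no lesion contrast" error
#' when the threshold separates the histogram poorly — the largest connected
#' component is kept, and the boundary is refined as the DP-optimal falling
#' radial edge in polar coordinates around the component centroid
#' ([trace_boundary_dp()] over angle columns).
#'
#' @param ep_mip 2D coronal MIP of the epidermal layer.
#' @param pixel_size pixel edge in um (isotropic).
#' @param min_separability minimum Otsu between-class / total variance
#'   ratio.
#' @param n_angles angular sampling of the polar unwrapping.
#' @param jump DP radial step bound (px per angle step).
#' @return object of class `lesion_regions`: `lesion_mask` (logical
#'   matrix), `boundary_path` (n x 2 pixel coordinates), `stv_mask`
#'   (`NULL` until [extract_stv_band()]), `pixel_size`, `band_width`.
#' @export
segment_lesion_boundary <- function(ep_mip, pixel_size = 12,
                                    min_separability = 0.2,
                                    n_angles = 360L, jump = 2L) {
  im <- as.matrix(ep_mip)
  rng <- range(im)
  if (diff(rng) == 0) stop("no lesion contrast: uniform image")
  nim <- (im - rng[1]) / diff(rng)
  ot <- otsu_threshold(as.numeric(nim))
  if (ot$separability < min_separability)
    stop(sprintf("no lesion contrast (separability %.3f < %.2f)",
                 ot$separability, min_separability))
  mask0 <- nim > ot$threshold
  lab <- EBImage::bwlabel(mask0)
  sizes <- tabulate(lab[lab > 0])
  if (!length(sizes)) stop("no lesion contrast: nothing above threshold")
  mask0 <- lab == which.max(sizes)
  ctr <- colMeans(which(mask0, arr.ind = TRUE))
  rr <- which(mask0, arr.ind = TRUE)
  rmax <- max(sqrt((rr[, 1] - ctr[1])^2 + (rr[, 2] - ctr[2])^2)) * 1.5 + 5
  theta <- seq(0, 2 * pi, length.out = n_angles + 1L)[-(n_angles + 1L)]
  rho <- seq(1, rmax, by = 1)
  polar <- outer(rho, theta, function(r, th)
    bilinear(nim, ctr[1] + r * cos(th), ctr[2] + r * sin(th)))
  g <- polar[-1, , drop = FALSE] - polar[-nrow(polar), , drop = FALSE]
  edge <- pmax(-g, 0)                     # falling edge moving outward
  cost1 <- max(edge) - edge
  # tile three revolutions so the path can close on itself; keep the middle
  dp <- trace_boundary_dp(cbind(cost1, cost1, cost1), jump = jump)
  ridx <- dp$path[(n_angles + 1L):(2L * n_angles)] + 1L  # edge row -> rho
  rad <- rho[pmin(ridx, length(rho))]
  bx <- ctr[1] + rad * cos(theta)
  by <- ctr[2] + rad * sin(theta)
  # rasterize the closed polar contour into a mask
  nr <- nrow(im); nc <- ncol(im)
  px <- matrix(rep(seq_len(nr), nc), nr, nc)
  py <- matrix(rep(seq_len(nc), each = nr), nr, nc)
  pth <- atan2(py - ctr[2], px - ctr[1]) %% (2 * pi)
  prho <- sqrt((px - ctr[1])^2 + (py - ctr[2])^2)
  radf <- stats::approx(c(theta, 2 * pi), c(rad, rad[1]), xout = pth,
                        rule = 2)$y
  lesion <- prho <= radf
  structure(list(lesion_mask = lesion,
                 boundary_path = cbind(x = bx, y = by),
                 stv_mask = NULL, band_width = NA_real_,
                 pixel_size = pixel_size, center = ctr),
            class = "lesion_regions")
}

#' Extract the surrounding-tissue-vessel (STV) band
#'
#' The STV band is the set of pixels outside the lesion within `band_width`
#' micrometres of its boundary — the 0.5 mm extension toward healthy skin
#' in which dermal vessels are quantified. Computed with a Euclidean
#' distance transform; the band width converts to pixels as
#' `ceiling(band_width / pixel_size)`.
#'
#' @param regions a [segment_lesion_boundary()] result.
#' @param band_width band width in um (default 500).
#' @param pixel_size pixel edge in um; defaults to the value stored in
#'   `regions`.
#' @return `regions` with `stv_mask` and `band_width` filled. A warning is
#'   recorded when the band is clipped by the image border.
#' @export
extract_stv_band <- function(regions, band_width = 500,
                             pixel_size = NULL) {
  stopifnot(inherits(regions, "lesion_regions"))
  pixel_size <- pixel_size %||% regions$pixel_size
  lesion <- regions$lesion_mask
  if (!any(lesion)) stop("lesion mask is empty")
  band_px <- ceiling(band_width / pixel_size)
  d <- EBImage::distmap(1 - lesion)     # distance of outside px to lesion
  stv <- d > 0 & d <= band_px
  if (any(stv[1, ]) || any(stv[nrow(stv), ]) ||
      any(stv[, 1]) || any(stv[, ncol(stv)]))
    warning("STV band clipped at the image border")
  regions$stv_mask <- stv & !lesion
  regions$band_width <- band_width
  regions$pixel_size <- pixel_size
  regions
}

## ---- vessel segmentation -------------------------------------------------

shift01 <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(0L, nr, nc)
  rs <- max(1, 1 + dr):min(nr, nr + dr)
  cs <- max(1, 1 + dc):min(nc, nc + dc)
  out[rs, cs] <- m[rs - dr, cs - dc]
  out
}

## Topology-preserving 2D thinning (Zhang-Suen), vectorized on 0/1 matrices.
zhang_suen_thin <- function(mask) {
  m <- matrix(as.integer(mask), nrow(mask), ncol(mask))
  nbr <- function(m) list(p2 = shift01(m, -1, 0), p3 = shift01(m, -1, 1),
                          p4 = shift01(m, 0, 1), p5 = shift01(m, 1, 1),
                          p6 = shift01(m, 1, 0), p7 = shift01(m, 1, -1),
                          p8 = shift01(m, 0, -1), p9 = shift01(m, -1, -1))
  repeat {
    changed <- FALSE
    for (sub in 1:2) {
      n <- nbr(m)
      B <- n$p2 + n$p3 + n$p4 + n$p5 + n$p6 + n$p7 + n$p8 + n$p9
      seqs <- list(n$p2, n$p3, n$p4, n$p5, n$p6, n$p7, n$p8, n$p9, n$p2)
      A <- matrix(0L, nrow(m), ncol(m))
      for (k in 1:8) A <- A + (seqs[[k]] == 0L & seqs[[k + 1L]] == 1L)
      if (sub == 1) {
        c1 <- n$p2 * n$p4 * n$p6 == 0L
        c2 <- n$p4 * n$p6 * n$p8 == 0L
      } else {
        c1 <- n$p2 * n$p4 * n$p8 == 0L
        c2 <- n$p2 * n$p6 * n$p8 == 0L
      }
      del <- m == 1L & B >= 2L & B <= 6L & A == 1L & c1 & c2
      if (any(del)) { m[del] <- 0L; changed <- TRUE }
    }
    if (!changed) break
  }
  m == 1L
}

neigh_offsets <- cbind(dr = c(-1, -1, -1, 0, 0, 1, 1, 1),
                       dc = c(-1, 0, 1, -1, 1, -1, 0, 1))

skel_degree <- function(sk) {
  deg <- matrix(0L, nrow(sk), ncol(sk))
  for (k in seq_len(nrow(neigh_offsets)))
    deg <- deg + shift01(matrix(as.integer(sk), nrow(sk)),
                         -neigh_offsets[k, 1], -neigh_offsets[k, 2])
  deg
}

## Trace a skeleton into node pixels (endpoints + merged junction clusters)
## and degree-2 chains between them. Returns list(segments, branch_points).
trace_skeleton <- function(sk, pixel_size) {
  nr <- nrow(sk); nc <- ncol(sk)
  deg <- skel_degree(sk); deg[!sk] <- 0L
  junction <- sk & deg >= 3L
  endpoint <- sk & deg == 1L
  # merge 8-connected junction clusters into single branch points
  branch_points <- NULL
  jlab <- if (any(junction)) EBImage::bwlabel(junction) else junction * 0
  njc <- max(jlab)
  if (njc > 0) {
    branch_points <- t(vapply(seq_len(njc), function(l) {
      px <- which(jlab == l, arr.ind = TRUE)
      ctr <- colMeans(px)
      px[which.min((px[, 1] - ctr[1])^2 + (px[, 2] - ctr[2])^2), ]
    }, numeric(2)))
    colnames(branch_points) <- c("row", "col")
  }
  is_node <- junction | endpoint
  visited <- matrix(FALSE, nr, nc)       # visited degree-2 chain pixels
  segments <- list()
  nodes <- which(is_node, arr.ind = TRUE)
  nbrs_of <- function(r, c) {
    rr <- r + neigh_offsets[, 1]; cc <- c + neigh_offsets[, 2]
    ok <- rr >= 1 & rr <= nr & cc >= 1 & cc <= nc
    cbind(rr[ok], cc[ok])[sk[cbind(rr[ok], cc[ok])], , drop = FALSE]
  }
  add_segment <- function(path) {
    if (nrow(path) < 2) return()
    steps <- sqrt(rowSums((path[-1, , drop = FALSE] -
                           path[-nrow(path), , drop = FALSE])^2))
    al <- sum(steps) * pixel_size
    sl <- sqrt(sum((path[nrow(path), ] - path[1, ])^2)) * pixel_size
    segments[[length(segments) + 1L]] <<-
      list(path = path, al_um = al, sl_um = sl)
  }
  if (nrow(nodes)) for (ni in seq_len(nrow(nodes))) {
    r0 <- nodes[ni, 1]; c0 <- nodes[ni, 2]
    for (nb in seq_len(nrow(nn <- nbrs_of(r0, c0)))) {
      r <- nn[nb, 1]; c <- nn[nb, 2]
      if (is_node[r, c]) {
        # adjacent junction pixels belong to one merged branch point;
        # other direct node-node contacts keep one orientation only
        if (!(junction[r0, c0] && junction[r, c]) &&
            r0 * nc + c0 < r * nc + c)
          add_segment(rbind(c(r0, c0), c(r, c)))
        next
      }
      if (visited[r, c]) next
      path <- rbind(c(r0, c0))
      prev <- c(r0, c0)
      repeat {
        path <- rbind(path, c(r, c))
        if (is_node[r, c]) break
        visited[r, c] <- TRUE
        nxt <- nbrs_of(r, c)
        nxt <- nxt[!(nxt[, 1] == prev[1] & nxt[, 2] == prev[2]) &
                     !visited[nxt], , drop = FALSE]
        if (!nrow(nxt)) break
        prev <- c(r, c)
        r <- nxt[1, 1]; c <- nxt[1, 2]
      }
      add_segment(path)
    }
  }
  # pure cycles: remaining unvisited degree-2 pixels with no node contact
  left <- sk & !visited & !is_node
  if (any(left)) {
    ij <- which(left, arr.ind = TRUE)
    for (s in seq_len(nrow(ij))) {
      r0 <- ij[s, 1]; c0 <- ij[s, 2]
      if (visited[r0, c0]) next
      path <- rbind(c(r0, c0)); visited[r0, c0] <- TRUE
      prev <- c(NA, NA); r <- r0; c <- c0
      repeat {
        nxt <- nbrs_of(r, c)
        nxt <- nxt[!visited[nxt], , drop = FALSE]
        if (!nrow(nxt)) break
        prev <- c(r, c); r <- nxt[1, 1]; c <- nxt[1, 2]
        path <- rbind(path, c(r, c)); visited[r, c] <- TRUE
      }
      if (nrow(path) >= 4) {
        # split the loop at its start and at the farthest pixel so both
        # halves have nonzero chord length
        far <- which.max((path[, 1] - r0)^2 + (path[, 2] - c0)^2)
        add_segment(path[1:far, , drop = FALSE])
        add_segment(path[far:nrow(path), , drop = FALSE])
      }
    }
  }
  list(segments = segments,
       branch_points = branch_points,
       endpoints = which(endpoint, arr.ind = TRUE))
}

#' Vessel network container
#'
#' @param mask logical matrix, segmented vessel pixels.
#' @param skeleton logical matrix, centerline pixels (subset of `mask`).
#' @param branch_points k x 2 matrix of skeleton junction coordinates.
#' @param segments list of `list(path, al_um, sl_um)` — skeleton paths
#'   between branch points / endpoints with their arc (AL) and chord (SL)
#'   lengths in um.
#' @param pixel_size pixel edge in um.
#' @return object of class `vessel_network`.
#' @export
vessel_network <- function(mask, skeleton, branch_points, segments,
                           pixel_size) {
  if (any(skeleton & !mask)) stop("skeleton must be a subset of the mask")
  for (s in segments)
    if (!(s$al_um >= s$sl_um - 1e-9) || s$sl_um <= 0)
      stop("every segment must satisfy AL >= SL > 0")
  structure(list(mask = mask, skeleton = skeleton,
                 branch_points = branch_points, segments = segments,
                 pixel_size = pixel_size),
            class = "vessel_network")
}

#' @export
print.vessel_network <- function(x, ...) {
  cat(sprintf("<vessel_network> %d mask px, %d skeleton px, %d segments, %d branch points\n",
              sum(x$mask), sum(x$skeleton), length(x$segments),
              if (is.null(x$branch_points)) 0L else nrow(x$branch_points)))
  invisible(x)
}

#' Segment vessels into mask, skeleton and branch points
#'
#' AngioQuant-style 2D vessel segmentation of a dermal-layer image:
#' large-scale background subtraction, hysteresis thresholding (percentile
#' `high` seeds grown through percentile `low`), removal of components
#' smaller than `a_min` pixels, morphological closing, topology-preserving
#' thinning to a skeleton, pruning of spurs shorter than `l_min` pixels, and
#' branch-point detection (skeleton pixels with >= 3 skeleton neighbours;
#' adjacent junction pixels merged). Skeleton paths between branch points
#' and endpoints become segments with arc length AL (summed pixel-to-pixel
#' Euclidean steps x pixel size) and chord length SL (endpoint distance).
#'
#' @param img 2D dermal-layer image (e.g. a DR-band MIP).
#' @param roi logical matrix restricting the analysis (default: all).
#' @param pixel_size pixel edge in um.
#' @param high,low hysteresis levels within the ROI. With
#'   `threshold = "quantile"` (default) they are intensity percentiles
#'   (0.97 / 0.90); with `threshold = "halfmax"` they are fractions of the
#'   robust maximum (the 99.9th-percentile intensity), the width-faithful
#'   choice for well-resolved structures (e.g. 0.65 / 0.5).
#' @param a_min minimum component area (px).
#' @param l_min minimum spur length (px).
#' @param bg_sigma background-subtraction Gaussian sigma (px; 0 disables).
#' @param threshold thresholding mode, see `high`.
#' @return a [vessel_network()]; empty (with a warning) when nothing
#'   exceeds the thresholds.
#' @export
segment_vessels <- function(img, roi = NULL, pixel_size = 12,
                            high = 0.97, low = 0.90, a_min = 5L,
                            l_min = 3L, bg_sigma = 20,
                            threshold = c("quantile", "halfmax")) {
  threshold <- match.arg(threshold)
  img <- as.matrix(img)
  if (is.null(roi)) roi <- matrix(TRUE, nrow(img), ncol(img))
  if (!any(roi)) stop("empty ROI")
  empty_net <- function() {
    warning("no vessels found in ROI")
    vessel_network(mask = matrix(FALSE, nrow(img), ncol(img)),
                   skeleton = matrix(FALSE, nrow(img), ncol(img)),
                   branch_points = NULL, segments = list(),
                   pixel_size = pixel_size)
  }
  if (max(img[roi]) <= 0) return(empty_net())
  work <- img
  # gblur needs its brush to fit inside the image
  if (bg_sigma > 0 && 2 * ceiling(3 * bg_sigma) + 1 >= min(dim(img)))
    bg_sigma <- 0
  if (bg_sigma > 0) {
    sm <- EBImage::gblur(img / max(img), sigma = bg_sigma) * max(img)
    work <- pmax(img - sm, 0)
  }
  vals <- work[roi]
  if (threshold == "quantile") {
    th <- stats::quantile(vals, high, names = FALSE)
    tl <- stats::quantile(vals, low, names = FALSE)
  } else {
    ref <- stats::quantile(vals, 0.999, names = FALSE)
    th <- high * ref
    tl <- low * ref
  }
  if (th <= 0) return(empty_net())
  strong <- work >= th & roi
  weak <- work >= tl & roi
  lab <- EBImage::bwlabel(weak)
  keep <- unique(lab[strong & lab > 0])
  mask <- matrix(lab %in% keep & lab > 0, nrow(img))
  # area filter
  lab2 <- EBImage::bwlabel(mask)
  sizes <- tabulate(lab2[lab2 > 0])
  small <- which(sizes < a_min)
  if (length(small)) mask[matrix(lab2 %in% small, nrow(img))] <- FALSE
  if (!any(mask)) return(empty_net())
  mask <- EBImage::closing(mask * 1, EBImage::makeBrush(3, "diamond")) > 0
  mask <- mask & roi
  sk <- zhang_suen_thin(mask)
  tr <- trace_skeleton(sk, pixel_size)
  # prune spurs: segments with a free end shorter than l_min pixels
  if (length(tr$segments)) {
    spur <- vapply(tr$segments, function(s) {
      ends_free <- !is_junction_px(tr, s$path[1, ]) ||
        !is_junction_px(tr, s$path[nrow(s$path), ])
      ends_free && (s$al_um / pixel_size) < l_min
    }, logical(1))
    if (any(spur)) {
      for (s in tr$segments[spur]) {
        p <- s$path
        # keep junction-end pixels, drop the rest of the spur
        for (k in seq_len(nrow(p)))
          if (!is_junction_px(tr, p[k, ])) sk[p[k, 1], p[k, 2]] <- FALSE
      }
      tr <- trace_skeleton(sk, pixel_size)
    }
  }
  segs <- Filter(function(s) s$sl_um > 0, tr$segments)
  vessel_network(mask = mask, skeleton = sk,
                 branch_points = tr$branch_points, segments = segs,
                 pixel_size = pixel_size)
}

is_junction_px <- function(tr, p) {
  if (is.null(tr$branch_points)) return(FALSE)
  any(abs(tr$branch_points[, 1] - p[1]) <= 1 &
        abs(tr$branch_points[, 2] - p[2]) <= 1)
}

#' Binary vessel mask of a dermal volume (3D)
#'
#' Thresholds a reconstructed dermal volume into the binary vessel volume
#' used for total-blood-volume computation, using a full-width-half-maximum
#' criterion: blur spreads a structure symmetrically about its half-peak
#' contour, so thresholding there recovers its true volume. The default
#' `"halfmax"` method applies one global threshold at `frac` of a robust
#' intensity maximum (the `ref_prob` quantile within the ROI).
#' `"adaptive"` applies the criterion per connected structure — candidate
#' regions above `seed_frac` of the robust maximum are labelled in 3D
#' (26-connectivity) and each is cut at `frac` of its own peak — and
#' `"otsu"` uses Otsu's histogram criterion.
#'
#' @param volume a [recon_volume()] or 3D array (envelope intensities).
#' @param roi logical array of the same shape (default: everything).
#' @param method `"halfmax"` (default), `"adaptive"` or `"otsu"`.
#' @param frac half-maximum fraction.
#' @param seed_frac candidate-region floor as a fraction of the robust
#'   maximum (adaptive method).
#' @param ref_prob quantile defining the robust maximum.
#' @return logical 3D array (vessel voxels inside the ROI).
#' @export
segment_vessels_3d <- function(volume, roi = NULL,
                               method = c("halfmax", "adaptive", "otsu"),
                               frac = 0.5, seed_frac = 0.25,
                               ref_prob = 0.999) {
  method <- match.arg(method)
  v <- if (inherits(volume, "recon_volume")) volume$intensity else volume
  if (is.null(roi)) roi <- array(TRUE, dim(v))
  if (!any(roi)) stop("empty ROI")
  vals <- v[roi]
  if (max(vals) <= 0) return(array(FALSE, dim(v)))
  ref <- stats::quantile(vals, ref_prob, names = FALSE)
  if (method == "adaptive") {
    cand <- v >= seed_frac * ref & roi
    if (!any(cand)) return(array(FALSE, dim(v)))
    lab <- label_components_3d(cand)
    peaks <- tapply(v[cand], lab[cand], max)
    cut <- numeric(max(lab) + 1L)          # cut[label + 1]
    cut[as.integer(names(peaks)) + 1L] <- frac * as.numeric(peaks)
    out <- array(FALSE, dim(v))
    out[cand] <- v[cand] > cut[lab[cand] + 1L]
    return(out)
  }
  thr <- if (method == "halfmax") frac * ref
         else otsu_threshold(vals)$threshold
  v > thr & roi
}
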