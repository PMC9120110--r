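#' Phantom voxel grid
#'
#' Regular voxel grid for ground-truth phantoms. Coordinates are in
#' micrometres; voxel centres sit at `origin + (i - 0.5) * voxel_size`.
#' `z` is depth, increasing into the skin, with the skin surface at z = 0.
#'
#' @param dim integer length-3 voxel counts (x = fast, y = slow, z = depth).
#' @param voxel_size length-3 voxel edge lengths in micrometres.
#' @param origin length-3 offset of the grid corner in micrometres.
#' @return object of class `phantom_grid`.
#' @export
phantom_grid <- function(dim = c(256L, 128L, 128L),
                         voxel_size = c(16, 16, 16),
                         origin = c(0, 0, 0)) {
  dim <- as.integer(dim)
  stopifnot(length(dim) == 3L, all(dim >= 1L),
            length(voxel_size) == 3L, all(voxel_size > 0))
  structure(list(dim = dim, voxel_size = as.numeric(voxel_size),
                 origin = as.numeric(origin)),
            class = "phantom_grid")
}

grid_extent <- function(grid) grid$origin + grid$dim * grid$voxel_size

## One vessel tree grown as a smoothly meandering walk with branching.
## Each vessel keeps a base heading and oscillates around it sinusoidally
## with amplitude `curvature` (radians) and a configurable wavelength —
## tortuosity at scales an imaging system can resolve (white-noise jitter
## would put all injected curvature below the acoustic resolution limit).
## curvature = 0 yields perfectly straight segments; vessels terminate at
## the slab / field walls. Returns list(segments = list of
## list(path (n x 3 um), radius), branch_points = k x 3 matrix).
grow_tree <- function(grid, depth_range, mean_segment_length, curvature,
                      branching_prob, radius, step = 20, max_tips = 16L,
                      fixed_length = NULL, wavelength = c(300, 600)) {
  ext <- grid_extent(grid)
  lo <- grid$origin
  start <- c(stats::runif(1, lo[1], ext[1]), stats::runif(1, lo[2], ext[2]),
             stats::runif(1, depth_range[1], depth_range[2]))
  draw_budget <- function() {
    if (!is.null(fixed_length)) fixed_length
    else max(50, stats::rnorm(1, mean_segment_length,
                              0.3 * mean_segment_length))
  }
  new_tip <- function(p, psi0) list(
    p = p, psi0 = psi0,
    lambda = stats::runif(1, wavelength[1], wavelength[2]),
    phi = stats::runif(1, 0, 2 * pi),
    pitch = stats::rnorm(1, 0, 0.1),         # out-of-plane slope (rad)
    s = 0,                                    # arc length along the vessel
    budget = draw_budget(), path = matrix(p, 1))
  segments <- list()
  branch_points <- NULL
  tips <- list(new_tip(start, stats::runif(1, 0, 2 * pi)))
  n_spawned <- 1L
  while (length(tips)) {
    tip <- tips[[1L]]; tips <- tips[-1L]
    repeat {
      tip$s <- tip$s + step
      psi <- tip$psi0 +
        curvature * sin(2 * pi * tip$s / tip$lambda + tip$phi)
      d <- c(cos(psi) * cos(tip$pitch), sin(psi) * cos(tip$pitch),
             sin(tip$pitch))
      p <- tip$p + step * d
      hit_wall <- p[3] < depth_range[1] || p[3] > depth_range[2] ||
        p[1] < lo[1] || p[1] > ext[1] || p[2] < lo[2] || p[2] > ext[2]
      if (!hit_wall) {
        tip$p <- p
        tip$path <- rbind(tip$path, p)
        tip$budget <- tip$budget - step
      }
      if (hit_wall || tip$budget <= 0) {
        if (nrow(tip$path) >= 2)
          segments[[length(segments) + 1L]] <-
            list(path = tip$path, radius = radius)
        break
      }
      if (stats::runif(1) < branching_prob && n_spawned < max_tips) {
        # close the current segment at the branch point, continue two children
        segments[[length(segments) + 1L]] <-
          list(path = tip$path, radius = radius)
        branch_points <- rbind(branch_points, tip$p)
        for (child in 1:2) {
          dpsi <- (if (child == 1) 1 else -1) * stats::runif(1, 0.3, 0.9)
          tips[[length(tips) + 1L]] <- new_tip(tip$p, psi + dpsi)
        }
        n_spawned <- n_spawned + 2L
        break
      }
    }
  }
  list(segments = segments, branch_points = branch_points)
}

#' Generate a ground-truth dermal vessel phantom
#'
#' Grows vessel trees as smoothly meandering polylines with stochastic
#' branching inside a depth slab, rasterizes them at the given radius, and
#' records the continuous geometry (centerlines, branch points) alongside
#' the voxel masks so that every downstream measurement has an exact truth.
#' Trees are added until the rasterized vessel fraction inside the slab
#' reaches `target_tbv`.
#'
#' @param target_tbv target vessel volume fraction within the depth slab,
#'   in (0, 0.5].
#' @param grid a [phantom_grid()]; >= 64^3 voxels recommended.
#' @param mean_segment_length mean branch-to-branch centerline length (um).
#' @param curvature amplitude (radians) of the sinusoidal heading meander
#'   around each vessel's base direction; 0 gives perfectly straight
#'   vessels, ~1 gives the strongly tortuous vessels seen around malignant
#'   lesions. The meander wavelength (`meander_wavelength`, default
#'   300-600 um) is resolvable by design.
#' @param branching_prob probability per 20 um step of bifurcating.
#' @param depth_range depth slab (um from the skin surface) holding vessels.
#' @param radius vessel radius (um).
#' @param meander_wavelength range (um) of the sinusoidal meander
#'   wavelength; keep well above the imaging resolution so injected
#'   tortuosity is observable.
#' @param seed integer seed; the same seed and parameters reproduce the
#'   phantom exactly.
#' @param max_trees give up (with an error reporting the achieved fraction)
#'   after this many trees.
#' @return object of class `phantom_truth` with fields `absorption`,
#'   `vessel_mask`, `melanin_mask`, `vessel_segments`, `branch_points`,
#'   `grid`, `depth_range`, `true_biomarkers`, `seed`.
#' @export
generate_vessel_phantom <- function(target_tbv = 0.02,
                                    grid = phantom_grid(),
                                    mean_segment_length = 300,
                                    curvature = 0.3,
                                    branching_prob = 0.04,
                                    depth_range = c(400, 1500),
                                    radius = 40,
                                    meander_wavelength = c(300, 600),
                                    seed = 1L,
                                    max_trees = 2000L) {
  if (target_tbv <= 0 || target_tbv > 0.5)
    stop("target_tbv must lie in (0, 0.5]")
  ext <- grid_extent(grid)
  depth_range <- c(max(depth_range[1], grid$origin[3]),
                   min(depth_range[2], ext[3]))
  if (depth_range[2] <= depth_range[1])
    stop("depth_range does not intersect the phantom grid")
  set.seed(as.integer(seed))
  mask <- array(FALSE, grid$dim)
  slab_z <- which((seq_len(grid$dim[3]) - 0.5) * grid$voxel_size[3] +
                    grid$origin[3] >= depth_range[1] &
                  (seq_len(grid$dim[3]) - 0.5) * grid$voxel_size[3] +
                    grid$origin[3] <= depth_range[2])
  slab_vox <- prod(grid$dim[1:2]) * length(slab_z)
  segments <- list(); branch_points <- NULL
  realized <- 0
  # voxel cost of one mean-length segment, for the stopping rule
  seg_vox <- mean_segment_length * pi * radius^2 / prod(grid$voxel_size)
  for (i in seq_len(max_trees)) {
    remaining <- (target_tbv - realized) * slab_vox
    if (remaining <= 0.02 * target_tbv * slab_vox) break
    if (remaining < 2 * seg_vox) {
      # close the gap with single unbranched segments of matched volume
      fill_len <- max(50, remaining * prod(grid$voxel_size) /
                        (pi * radius^2))
      tr <- grow_tree(grid, depth_range,
                      mean_segment_length = fill_len, curvature,
                      branching_prob = 0, radius, fixed_length = fill_len,
                      wavelength = meander_wavelength)
    } else {
      # cap the tree size (~1 segment per tip) by the remaining budget
      tips <- max(2L, min(16L, as.integer(remaining / (1.5 * seg_vox))))
      tr <- grow_tree(grid, depth_range, mean_segment_length, curvature,
                      branching_prob, radius, max_tips = tips,
                      wavelength = meander_wavelength)
    }
    segments <- c(segments, tr$segments)
    branch_points <- rbind(branch_points, tr$branch_points)
    pts <- do.call(rbind, lapply(tr$segments, function(s)
      densify_path(s$path, grid$voxel_size)))
    mask <- mask | rasterize_balls(pts, radius, grid$dim, grid$voxel_size,
                                   grid$origin)
    realized <- sum(mask[, , slab_z]) / slab_vox
  }
  if (realized < 0.8 * target_tbv)
    stop(sprintf(
      "target_tbv %.4g unreachable within %d trees (achieved %.4g)",
      target_tbv, max_trees, realized))
  ph <- structure(list(
    absorption = mask * 1.0, vessel_mask = mask,
    melanin_mask = array(FALSE, grid$dim),
    vessel_segments = segments, branch_points = branch_points,
    lesion_disk = NULL, grid = grid, depth_range = depth_range,
    realized_tbv = realized, seed = as.integer(seed)),
    class = "phantom_truth")
  ph$true_biomarkers <- true_biomarkers(ph)
  ph
}

## resample a polyline to spacing <= half the smallest voxel edge
densify_path <- function(path, voxel_size) {
  if (nrow(path) < 2) return(path)
  seglen <- sqrt(rowSums((path[-1, , drop = FALSE] -
                          path[-nrow(path), , drop = FALSE])^2))
  s <- c(0, cumsum(seglen))
  h <- min(voxel_size) / 2
  si <- seq(0, s[length(s)], by = h)
  cbind(stats::approx(s, path[, 1], si)$y,
        stats::approx(s, path[, 2], si)$y,
        stats::approx(s, path[, 3], si)$y)
}

## mark all voxels whose centre lies within `radius` of any sample point
rasterize_balls <- function(pts, radius, dim, voxel, origin) {
  mask <- array(FALSE, dim)
  if (is.null(pts) || nrow(pts) == 0) return(mask)
  rv <- ceiling(radius / voxel)
  for (i in seq_len(nrow(pts))) {
    c0 <- (pts[i, ] - origin) / voxel + 0.5   # fractional voxel index
    i0 <- pmax(1L, floor(c0 - rv)); i1 <- pmin(dim, ceiling(c0 + rv))
    if (any(i0 > i1)) next
    xs <- i0[1]:i1[1]; ys <- i0[2]:i1[2]; zs <- i0[3]:i1[3]
    dx2 <- ((xs - c0[1]) * voxel[1])^2
    dy2 <- ((ys - c0[2]) * voxel[2])^2
    dz2 <- ((zs - c0[3]) * voxel[3])^2
    d2 <- outer(outer(dx2, dy2, "+"), dz2, "+")
    mask[xs, ys, zs] <- mask[xs, ys, zs] | (d2 <= radius^2)
  }
  mask
}

#' Add a melanin layer and pigmented lesion to a vessel phantom
#'
#' Places a uniform melanin slab (the epidermal band) above the vessel slab
#' and an elevated-absorption disk (the pigmented lesion) within it.
#' Absorption is the sum of the vessel and melanin contributions; vessels
#' have unit absorption, the slab `contrast` times that, and the lesion disk
#' `contrast * lesion_contrast`.
#'
#' @param phantom a vessel [generate_vessel_phantom()] truth.
#' @param melanin_depth_range depth slab (um) of the melanin band; must lie
#'   entirely above the vessel slab.
#' @param lesion_disk `list(center = c(x, y), radius)` in um, or `NULL` /
#'   radius 0 for a uniform band.
#' @param contrast melanin : vessel absorption ratio (the slab mean).
#' @param lesion_contrast extra factor applied inside the lesion disk.
#' @param texture relative amplitude of the multiplicative speckle applied
#'   to the slab (uniform in `1 +/- texture`, mean preserved). Epidermal
#'   melanin is granular; a perfectly uniform slab would band-pass away to
#'   its two boundary sheets in the reconstruction.
#' @return the phantom with `absorption`, `melanin_mask`, `lesion_disk`
#'   updated.
#' @export
generate_skin_phantom <- function(phantom,
                                  melanin_depth_range = c(100, 250),
                                  lesion_disk = NULL,
                                  contrast = 3,
                                  lesion_contrast = 2,
                                  texture = 0.5) {
  stopifnot(inherits(phantom, "phantom_truth"))
  if (melanin_depth_range[2] > phantom$depth_range[1])
    stop("melanin band must lie entirely above the vessel depth range")
  grid <- phantom$grid
  zc <- grid$origin[3] + (seq_len(grid$dim[3]) - 0.5) * grid$voxel_size[3]
  zin <- zc >= melanin_depth_range[1] & zc <= melanin_depth_range[2]
  slab <- array(FALSE, grid$dim)
  slab[, , zin] <- TRUE
  lev <- array(0, grid$dim)
  set.seed(phantom$seed + 1000L)
  tex <- if (texture > 0)
    stats::runif(sum(slab), 1 - texture, 1 + texture) else 1
  lev[slab] <- contrast * tex
  if (!is.null(lesion_disk) && lesion_disk$radius > 0) {
    xc <- grid$origin[1] + (seq_len(grid$dim[1]) - 0.5) * grid$voxel_size[1]
    yc <- grid$origin[2] + (seq_len(grid$dim[2]) - 0.5) * grid$voxel_size[2]
    in_disk <- outer((xc - lesion_disk$center[1])^2,
                     (yc - lesion_disk$center[2])^2, "+") <=
      lesion_disk$radius^2
    for (k in which(zin)) lev[, , k][in_disk] <- contrast * lesion_contrast
  }
  phantom$absorption <- phantom$vessel_mask * 1.0 + lev
  phantom$melanin_mask <- slab
  phantom$melanin_depth_range <- melanin_depth_range
  phantom$lesion_disk <- lesion_disk
  phantom
}

#' Ground-truth biomarkers from phantom geometry
#'
#' Computes the six vascular biomarkers from the continuous centerline
#' geometry (and, for TBV / fractal number / lacunarity, the rasterized
#' vessel mask), using the same definitions as the image-based biomarker
#' functions: TBV = vessel voxel fraction in the depth slab, tortuosity from
#' per-segment arc/chord ratios, average vessel length = total centerline
#' length over branch-point count.
#'
#' @param phantom a `phantom_truth`.
#' @return a [biomarker_set()].
#' @export
true_biomarkers <- function(phantom) {
  stopifnot(inherits(phantom, "phantom_truth"))
  segs <- phantom$vessel_segments
  if (!length(segs)) stop("phantom has no vessel segments")
  al <- vapply(segs, function(s) {
    p <- s$path
    if (nrow(p) < 2) return(0)
    sum(sqrt(rowSums((p[-1, , drop = FALSE] -
                      p[-nrow(p), , drop = FALSE])^2)))
  }, numeric(1))
  sl <- vapply(segs, function(s)
    sqrt(sum((s$path[nrow(s$path), ] - s$path[1, ])^2)), numeric(1))
  ok <- sl > 1e-9 & al > 0
  dm <- al[ok] / sl[ok]
  nb <- if (is.null(phantom$branch_points)) 0L
        else nrow(phantom$branch_points)
  grid <- phantom$grid
  zc <- grid$origin[3] + (seq_len(grid$dim[3]) - 0.5) * grid$voxel_size[3]
  slab_z <- which(zc >= phantom$depth_range[1] & zc <= phantom$depth_range[2])
  tbv <- sum(phantom$vessel_mask[, , slab_z]) /
    (prod(grid$dim[1:2]) * length(slab_z))
  proj <- apply(phantom$vessel_mask[, , slab_z, drop = FALSE], c(1, 2), max)
  # geometric density: centerline length per unit area, in pixels of the
  # coronal grid (same scale as skeleton-pixel counting downstream)
  dens <- sum(al) / min(grid$voxel_size[1:2]) / prod(grid$dim[1:2])
  biomarker_set(
    tbv = tbv,
    vessel_density = dens,
    avg_vessel_length = sum(al) / max(nb, 1),
    tortuosity = mean(dm - 1),
    mean_dm = mean(dm),
    fractal_number = if (min(dim(proj)) >= 32 && any(proj > 0))
      fractal_number(proj) else NA_real_,
    lacunarity = if (any(proj > 0)) lacunarity(proj) else NA_real_,
    n_branch_points = nb,
    provenance = list(source = "phantom geometry"))
}
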