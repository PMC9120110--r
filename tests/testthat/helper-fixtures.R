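# Shared fixture builders. Everything is generated in code at test time;
# heavier simulated objects are built once per session and cached.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_env))
    assign(name, builder(), envir = .fixture_env)
  get(name, envir = .fixture_env)
}

# A tiny raster scan whose A-lines carry one bipolar echo at a controllable
# per-line sample shift — the workhorse for motion tests.
echo_scan <- function(shift_samples, n_fast = 24L, n_slow = 12L,
                      n_samples = 512L, t0 = 256, width = 4,
                      rep_rate = 1000) {
  cfg <- scan_config(n_fast = n_fast, n_slow = n_slow, step_fast = 40,
                     step_slow = 40, n_samples = n_samples,
                     sample_rate = 1e9, rep_rate = rep_rate)
  shift_samples <- rep_len(shift_samples, n_fast * n_slow)
  pulse <- function(ctr) {
    t <- seq_len(n_samples) - ctr
    -t / width^2 * exp(-t^2 / (2 * width^2))
  }
  sig <- array(0, c(n_fast, n_slow, n_samples))
  k <- 0L
  for (j in seq_len(n_slow)) for (i in seq_len(n_fast)) {
    k <- k + 1L
    sig[i, j, ] <- pulse(t0 + shift_samples[k])
  }
  raw_scan(cfg, sig)
}

# Small dermal vessel phantom shared by simulation/reconstruction tests.
small_phantom <- function() fixture("small_phantom", function() {
  generate_vessel_phantom(
    target_tbv = 0.03,
    grid = phantom_grid(dim = c(60, 30, 60), voxel_size = c(20, 20, 10)),
    depth_range = c(300, 550), mean_segment_length = 250,
    curvature = 0.3, radius = 40, seed = 5)
})

small_scan_config <- function() {
  scan_config(n_fast = 30, n_slow = 15, step_fast = 40, step_slow = 40,
              n_samples = 1000, sample_rate = 1e9)
}

test_sensitivity <- function() sensitivity_field(focal_depth = 700)

# Depth-5 Sierpinski carpet (243 x 243), analytic dimension log(8)/log(3).
sierpinski_carpet <- function(depth = 5L) {
  m <- matrix(1L, 1, 1)
  for (i in seq_len(depth)) {
    z <- matrix(0L, nrow(m), ncol(m))
    m <- rbind(cbind(m, m, m), cbind(m, z, m), cbind(m, m, m))
  }
  m
}

# Exact two-tailed Mann-Whitney p by full enumeration of group labelings.
enumerate_mwu_p <- function(a, b) {
  x <- c(a, b); na <- length(a)
  U <- function(aa, bb) sum(outer(aa, bb, ">")) +
    0.5 * sum(outer(aa, bb, "=="))
  u0 <- U(a, b)
  mu <- na * length(b) / 2
  idx <- utils::combn(length(x), na)
  us <- apply(matrix(idx, nrow = na), 2, function(k) U(x[k], x[-k]))
  mean(abs(us - mu) >= abs(u0 - mu) - 1e-12)
}

# Dijkstra oracle for the column-monotone path problem (igraph).
dijkstra_cost <- function(cost, jump = 2L) {
  nr <- nrow(cost); nc <- ncol(cost)
  id <- function(r, c) (c - 1L) * nr + r
  from <- integer(0); to <- integer(0); w <- numeric(0)
  for (cc in 2:nc) for (r in seq_len(nr)) {
    pr <- (r - jump):(r + jump)
    pr <- pr[pr >= 1 & pr <= nr]
    from <- c(from, id(pr, cc - 1L))
    to <- c(to, rep(id(r, cc), length(pr)))
    w <- c(w, rep(cost[r, cc], length(pr)))
  }
  S <- nr * nc + 1L; T2 <- nr * nc + 2L
  from <- c(from, rep(S, nr), id(seq_len(nr), nc))
  to <- c(to, id(seq_len(nr), 1L), rep(T2, nr))
  w <- c(w, cost[, 1L], rep(0, nr))
  gr <- igraph::graph_from_edgelist(cbind(from, to))
  igraph::E(gr)$weight <- w
  igraph::distances(gr, S, T2, mode = "out")[1, 1]
}

# Layered skin volume built directly on the reconstruction grid: a bright
# speckled epidermal band with a sharp bottom edge above sparse vessel
# blobs. Exercises layer segmentation without a full acoustic simulation.
layered_volume <- function(band_bottom_um = 250, seed = 1,
                           dim = c(40, 20, 100), voxel = c(12, 12, 6),
                           vessels = TRUE, band = TRUE) {
  set.seed(seed)
  v <- array(0, dim)
  zc <- (seq_len(dim[3]) - 0.5) * voxel[3]
  zin <- zc >= 40 & zc <= band_bottom_um
  if (band)
    v[, , zin] <- 3 * matrix(stats::runif(prod(dim[1:2]) * sum(zin),
                                          0.6, 1.4),
                             prod(dim[1:2]))
  if (vessels) {
    for (k in 1:25) {
      c0 <- c(sample(3:(dim[1] - 2), 1), sample(2:(dim[2] - 1), 1),
              sample(which(zc > band_bottom_um + 120 & zc < max(zc) - 30), 1))
      v[c0[1] + (-1:1), c0[2] + (-1:0), c0[3] + (-2:2)] <- 1.2
    }
  }
  recon_volume(v, voxel_size = voxel, band = c(40, 120))
}
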