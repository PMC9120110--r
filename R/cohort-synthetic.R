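## Published group-level statistics of the melanoma-vs-nevus lesion-edge
## cohort (n = 16 regions per group): mean and sample SD per biomarker.
## TBV is stored as a fraction.
published_cohort_moments <- function() {
  list(
    melanoma = data.frame(
      marker = c("tbv", "vessel_density", "avg_vessel_length_um",
                 "tortuosity", "fractal_number", "lacunarity"),
      mean = c(0.3594, 0.017, 139.60, 0.47, 1.26, 0.170),
      sd = c(0.0622, 0.004, 46.63, 0.083, 0.18, 0.083)),
    nevus = data.frame(
      marker = c("tbv", "vessel_density", "avg_vessel_length_um",
                 "tortuosity", "fractal_number", "lacunarity"),
      mean = c(0.2362, 0.010, 260.39, 0.27, 1.12, 0.088),
      sd = c(0.0561, 0.0035, 62.49, 0.082, 0.062, 0.050)))
}

#' Synthetic stand-in cohort with the published group moments
#'
#' Generates a synthetic per-lesion biomarker table (16 melanoma + 16 nevus
#' edge regions) whose per-group sample means and SDs match the published
#' group-level statistics of the melanoma/nevus cohort exactly: correlated
#' normal draws are standardized per group and marker and rescaled to the
#' target moments. This is a synthetic stand-in for the study's per-lesion
#' source data, which is not redistributed here; within-group correlation
#' (`rho`) between markers is a modelling choice, so joint statistics such
#' as multivariate AUCs are indicative only.
#'
#' @param seed integer seed.
#' @param n_per_group regions per group.
#' @param rho latent within-group correlation between markers.
#' @return a [cohort_table()].
#' @export
synthetic_cohort <- function(seed = 1L, n_per_group = 16L, rho = 0.4) {
  set.seed(as.integer(seed))
  mom <- published_cohort_moments()
  p <- nrow(mom$melanoma)
  Sigma <- matrix(rho, p, p); diag(Sigma) <- 1
  L <- chol(Sigma)
  one_group <- function(group) {
    Z <- matrix(stats::rnorm(n_per_group * p), n_per_group, p) %*% L
    Z <- scale(Z)                       # exact zero mean / unit sample SD
    tgt <- mom[[group]]
    X <- sweep(sweep(Z, 2, tgt$sd, "*"), 2, tgt$mean, "+")
    colnames(X) <- tgt$marker
    df <- as.data.frame(X)
    df$lesion_id <- sprintf("%s_%02d", group, seq_len(n_per_group))
    df$group <- group
    df$region <- "edge"
    df
  }
  df <- rbind(one_group("melanoma"), one_group("nevus"))
  cohort_table(df)
}
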