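#' Two-tailed Mann-Whitney U test
#'
#' Rank-sum test with midrank ties. The p-value is exact (by enumeration of
#' the permutation distribution) when the pooled sample size is at most 16
#' and there are no ties, and otherwise uses the normal approximation with
#' tie correction and continuity correction — the behaviour of common
#' commercial statistics packages.
#'
#' @param a,b numeric vectors, both nonempty.
#' @param exact_max largest pooled size for the exact branch.
#' @return list: `U` (U statistic of `a`, i.e. the number of (a, b) pairs
#'   with a > b, ties counting 1/2), `p` (two-tailed), `exact`.
#' @export
mann_whitney_u <- function(a, b, exact_max = 16L) {
  if (!length(a) || !length(b)) stop("both groups must be nonempty")
  if (stats::sd(c(a, b)) == 0)             # every observation identical
    return(list(U = length(a) * length(b) / 2, p = 1, exact = FALSE))
  ties <- anyDuplicated(c(a, b)) > 0
  exact <- (length(a) + length(b) <= exact_max) && !ties
  ht <- suppressWarnings(
    stats::wilcox.test(a, b, alternative = "two.sided", exact = exact,
                       correct = TRUE))
  list(U = unname(ht$statistic), p = ht$p.value, exact = exact)
}

#' Empirical ROC curve and AUC
#'
#' Sweeps all observed score thresholds (ties grouped, so tied scores
#' contribute diagonal ROC steps and the trapezoidal area equals the
#' midrank Mann-Whitney statistic `U / (nA * nB)`).
#'
#' @param scores numeric classifier scores, higher = more positive.
#' @param labels logical (or coercible) positives.
#' @return list: `fpr`, `tpr` (including the (0,0) and (1,1) endpoints),
#'   `thresholds`, `auc`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  if (length(scores) != length(labels)) stop("scores/labels length mismatch")
  np <- sum(labels); nn <- sum(!labels)
  if (np == 0 || nn == 0) stop("both classes must be present")
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; y <- labels[o]
  grp <- cumsum(!duplicated(s))
  tp <- cumsum(y); fp <- cumsum(!y)
  last <- !duplicated(grp, fromLast = TRUE)
  tpr <- c(0, tp[last] / np)
  fpr <- c(0, fp[last] / nn)
  auc <- sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
  list(fpr = fpr, tpr = tpr, thresholds = c(Inf, s[last]), auc = auc)
}

#' Multivariate logistic regression with separation guard
#'
#' Maximum-likelihood fit (IRLS, intercept included). Complete or
#' quasi-complete separation — flagged by diverging fitted probabilities —
#' triggers a small ridge penalty (`ridge`, not applied to the intercept) so
#' that finite coefficients are always returned, with the `separation` flag
#' set.
#'
#' @param features numeric matrix or data.frame, one row per sample.
#' @param labels logical (or 0/1) outcome, both classes present.
#' @param ridge penalty used only on separation.
#' @param max_iter,tol IRLS iteration cap and coefficient-change tolerance.
#' @return list: `coefficients` (named, intercept first), `fitted`
#'   (probabilities), `separation`, `converged`.
#' @export
fit_logistic <- function(features, labels, ridge = 1e-4,
                         max_iter = 100L, tol = 1e-8) {
  X <- as.matrix(features)
  if (!all(is.finite(X))) stop("features must be finite")
  y <- as.numeric(as.logical(labels))
  if (length(unique(y)) < 2) stop("labels contain a single class")
  if (min(table(y)) < 2) stop("need at least 2 samples per class")
  cn <- colnames(X) %||% paste0("x", seq_len(ncol(X)))
  Xd <- cbind(`(Intercept)` = 1, X)
  irls <- function(lambda) {
    beta <- numeric(ncol(Xd))
    pen <- diag(c(0, rep(lambda, ncol(X))), ncol(Xd))
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      eta <- drop(Xd %*% beta)
      p <- 1 / (1 + exp(-eta))
      w <- pmax(p * (1 - p), 1e-10)
      z <- eta + (y - p) / w
      new <- tryCatch(
        solve(crossprod(Xd, Xd * w) + pen, crossprod(Xd, w * z)),
        error = function(e) NULL)
      if (is.null(new)) break
      new <- drop(new)
      if (max(abs(new - beta)) < tol) { beta <- new; converged <- TRUE; break }
      beta <- new
    }
    p <- 1 / (1 + exp(-drop(Xd %*% beta)))
    list(beta = beta, p = p, converged = converged)
  }
  fit <- irls(0)
  separation <- !fit$converged || any(fit$p > 1 - 1e-8 | fit$p < 1e-8) ||
    max(abs(fit$beta)) > 1e6
  if (separation) fit <- irls(ridge)
  names(fit$beta) <- c("(Intercept)", cn)
  list(coefficients = fit$beta, fitted = fit$p, separation = separation,
       converged = fit$converged)
}

## orientation of each marker: does a higher value indicate melanoma?
marker_orientation <- c(tbv = 1, vessel_density = 1,
                        avg_vessel_length_um = -1, tortuosity = 1,
                        fractal_number = 1, lacunarity = 1)

#' Cohort comparison report
#'
#' For every biomarker: group means and sample SDs (n - 1 denominator), the
#' two-tailed Mann-Whitney U test, and the ROC/AUC for discriminating
#' melanoma with a fixed marker orientation (higher value indicates
#' melanoma for TBV, vessel density, tortuosity, fractal number and
#' lacunarity; lower average vessel length indicates melanoma). A combined
#' model — in-sample multivariate logistic regression on the markers in
#' `combine` — contributes its predicted-probability ROC.
#'
#' @param table a [cohort_table()] with both groups present.
#' @param markers biomarker columns to report.
#' @param combine markers entering the combined logistic model.
#' @return object of class `cohort_report`: `markers` (per-marker stats),
#'   `roc` (per-marker ROC), `combined` (coefficients, ROC, AUC), `n`.
#' @export
cohort_report <- function(table,
                          markers = c("tbv", "vessel_density",
                                      "avg_vessel_length_um", "tortuosity",
                                      "fractal_number", "lacunarity"),
                          combine = c("tbv", "tortuosity")) {
  table <- cohort_table(as.data.frame(table))
  n_by <- table(table$group)
  if (any(n_by == 0)) stop("both groups must be present in the cohort")
  is_mel <- table$group == "melanoma"
  rows <- lapply(markers, function(mk) {
    x <- table[[mk]]
    mel <- x[is_mel]; nev <- x[!is_mel]
    mw <- mann_whitney_u(mel, nev)
    orient <- marker_orientation[[mk]]
    roc <- roc_auc(orient * x, is_mel)
    data.frame(marker = mk,
               melanoma_mean = mean(mel), melanoma_sd = stats::sd(mel),
               nevus_mean = mean(nev), nevus_sd = stats::sd(nev),
               U = mw$U, p = mw$p, auc = roc$auc)
  })
  stats_df <- do.call(rbind, rows)
  rocs <- lapply(markers, function(mk)
    roc_auc(marker_orientation[[mk]] * table[[mk]], is_mel))
  names(rocs) <- markers
  combined <- NULL
  if (length(combine) >= 1) {
    X <- scale(as.matrix(table[combine]))
    fit <- fit_logistic(X, is_mel)
    croc <- roc_auc(fit$fitted, is_mel)
    combined <- list(markers = combine, coefficients = fit$coefficients,
                     separation = fit$separation, roc = croc,
                     auc = croc$auc)
  }
  structure(list(markers = stats_df, roc = rocs, combined = combined,
                 n = c(nevus = unname(n_by["nevus"]),
                       melanoma = unname(n_by["melanoma"]))),
            class = "cohort_report")
}

#' @export
print.cohort_report <- function(x, digits = 4, ...) {
  cat(sprintf("<cohort_report> nevus n = %d, melanoma n = %d\n",
              x$n["nevus"], x$n["melanoma"]))
  df <- x$markers
  df$p <- format.pval(df$p, digits = 3)
  print(format(df, digits = digits), row.names = FALSE)
  if (!is.null(x$combined))
    cat(sprintf("combined (%s): AUC = %.3f%s\n",
                paste(x$combined$markers, collapse = " + "),
                x$combined$auc,
                if (x$combined$separation) " [separation, ridge]" else ""))
  invisible(x)
}

#' @export
summary.cohort_report <- function(object, ...) object$markers
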