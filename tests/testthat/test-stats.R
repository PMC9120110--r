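test_that("Mann-Whitney U and exact p match enumeration on small groups", {
  mw <- mann_whitney_u(1:3, 4:6)
  expect_equal(mw$U, 0)
  expect_equal(mw$p, 0.1)                  # 2/20 labelings as extreme
  expect_true(mw$exact)
  expect_equal(mann_whitney_u(c(5, 5, 5), c(5, 5, 5))$p, 1)
  set.seed(17)
  for (i in 1:25) {
    na <- sample(2:5, 1); nb <- sample(2:5, 1)
    a <- rnorm(na); b <- rnorm(nb)
    expect_equal(mann_whitney_u(a, b)$p, enumerate_mwu_p(a, b),
                 tolerance = 1e-12)
  }
  expect_error(mann_whitney_u(numeric(0), 1:3), "nonempty")
})

test_that("large or tied samples use the corrected normal approximation", {
  set.seed(18)
  a <- rnorm(20); b <- rnorm(20) + 0.5
  mw <- mann_whitney_u(a, b)
  expect_false(mw$exact)
  ref <- stats::wilcox.test(a, b, exact = FALSE, correct = TRUE)
  expect_equal(mw$p, ref$p.value)
  tied <- mann_whitney_u(c(1, 2, 2, 3), c(2, 3, 3, 4))
  expect_false(tied$exact)
  expect_true(tied$p > 0 && tied$p <= 1)
})

test_that("the ROC curve is monotone and AUC equals U/(nA*nB)", {
  scores <- c(5, 4, 3, 2, 1)
  labels <- c(TRUE, TRUE, TRUE, FALSE, FALSE)
  r <- roc_auc(scores, labels)
  expect_equal(r$auc, 1)
  expect_true(all(diff(r$tpr) >= 0) && all(diff(r$fpr) >= 0))
  expect_equal(roc_auc(rep(1, 10), rep(c(TRUE, FALSE), 5))$auc, 0.5)
  # rank-statistic identity, with and without ties
  set.seed(19)
  for (i in 1:20) {
    n <- 30
    sc <- if (i %% 2) rnorm(n) else sample(1:6, n, replace = TRUE)
    lb <- rep(c(TRUE, FALSE), n / 2)
    u <- mann_whitney_u(sc[lb], sc[!lb])$U
    expect_equal(roc_auc(sc, lb)$auc, u / (sum(lb) * sum(!lb)),
                 tolerance = 1e-12)
  }
  expect_error(roc_auc(1:4, rep(TRUE, 4)), "classes")
})

test_that("ROC/AUC agrees with an independent reference implementation", {
  skip_if_not_installed("pROC")
  set.seed(20)
  sc <- rnorm(40); lb <- rep(c(TRUE, FALSE), 20)
  ref <- as.numeric(pROC::auc(pROC::roc(lb, sc, quiet = TRUE,
                                        direction = "<")))
  expect_equal(roc_auc(sc, lb)$auc, ref, tolerance = 1e-12)
})

test_that("logistic fitting finds signal, ignores noise, guards separation", {
  set.seed(21)
  n <- 60
  x1 <- c(rnorm(n / 2), rnorm(n / 2) + 2)
  x2 <- rnorm(n)
  y <- rep(c(FALSE, TRUE), each = n / 2)
  fit <- fit_logistic(cbind(a = x1, b = x2), y)
  expect_false(fit$separation)
  expect_gt(fit$coefficients[["a"]], 0)
  expect_lt(abs(fit$coefficients[["b"]]),
            abs(fit$coefficients[["a"]]))
  ref <- stats::glm(y ~ x1 + x2, family = stats::binomial())
  expect_equal(unname(fit$coefficients), unname(stats::coef(ref)),
               tolerance = 1e-5)
  # perfectly separated toy data: flagged, finite coefficients
  xs <- c(1, 2, 3, 10, 11, 12)
  ys <- c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE)
  sep <- fit_logistic(matrix(xs, ncol = 1), ys)
  expect_true(sep$separation)
  expect_true(all(is.finite(sep$coefficients)))
  expect_error(fit_logistic(matrix(1:4, ncol = 1), rep(TRUE, 4)),
               "class")
})

test_that("cohort_report computes group stats with fixed orientation", {
  tab <- synthetic_cohort(seed = 22)
  rep1 <- cohort_report(tab)
  df <- rep1$markers
  mom <- rsomvasc:::published_cohort_moments()
  # group means and SDs reproduce the generator's target moments exactly
  for (k in seq_len(nrow(df))) {
    mk <- df$marker[k]
    expect_equal(df$melanoma_mean[k],
                 mom$melanoma$mean[mom$melanoma$marker == mk],
                 tolerance = 1e-9)
    expect_equal(df$nevus_sd[k],
                 mom$nevus$sd[mom$nevus$marker == mk], tolerance = 1e-9)
  }
  expect_true(all(df$p > 0 & df$p <= 1))
  expect_true(all(df$auc >= 0 & df$auc <= 1))
  # melanoma has lower average vessel length; orientation keeps AUC > 0.5
  expect_gt(df$auc[df$marker == "avg_vessel_length_um"], 0.5)
  expect_equal(rep1$combined$markers, c("tbv", "tortuosity"))
  expect_true(rep1$combined$auc >= 0 && rep1$combined$auc <= 1)

  # invariant to row order and lesion_id relabeling
  tab2 <- tab[sample(nrow(tab)), ]
  tab2$lesion_id <- paste0("x", seq_len(nrow(tab2)))
  rep2 <- cohort_report(tab2)
  expect_equal(rep2$markers$melanoma_mean, df$melanoma_mean)
  expect_equal(rep2$markers$p, df$p)
  expect_equal(rep2$combined$auc, rep1$combined$auc)
})

test_that("null cohorts rarely reach significance", {
  set.seed(23)
  hits <- 0L
  for (i in 1:40) {
    df <- data.frame(
      lesion_id = sprintf("l%02d", 1:20),
      group = rep(c("nevus", "melanoma"), each = 10),
      region = "edge",
      tbv = runif(20, 0.2, 0.4), vessel_density = runif(20, 0.005, 0.02),
      avg_vessel_length_um = runif(20, 100, 300),
      tortuosity = runif(20, 0.2, 0.5), fractal_number = runif(20, 1, 1.4),
      lacunarity = runif(20, 0.05, 0.2))
    p <- cohort_report(cohort_table(df))$markers$p
    hits <- hits + (min(p) < 0.05)
  }
  # six markers tested, so some spurious hits are expected, but most null
  # draws stay clear of significance on any single marker
  expect_lt(hits / 40, 0.5)
})

test_that("the synthetic cohort generator matches its target moments", {
  tab <- synthetic_cohort(seed = 24)
  expect_equal(nrow(tab), 32L)
  mom <- rsomvasc:::published_cohort_moments()
  mel <- tab[tab$group == "melanoma", ]
  expect_equal(mean(mel$tbv), 0.3594, tolerance = 1e-9)
  expect_equal(sd(mel$tortuosity), 0.083, tolerance = 1e-9)
  nev <- tab[tab$group == "nevus", ]
  expect_equal(mean(nev$avg_vessel_length_um), 260.39, tolerance = 1e-9)
  expect_equal(mean(nev$lacunarity), 0.088, tolerance = 1e-9)
  # different seeds give different tables with identical moments
  tab2 <- synthetic_cohort(seed = 25)
  expect_false(isTRUE(all.equal(tab$tbv, tab2$tbv)))
  expect_equal(mean(tab2$tbv[tab2$group == "melanoma"]), 0.3594,
               tolerance = 1e-9)
})
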