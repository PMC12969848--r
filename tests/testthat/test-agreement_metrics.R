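test_that("absolute-error summary uses inclusive tolerance bands", {
  s <- abs_error_summary(c(1, 2, 3), c(1, 2, 3))
  expect_equal(unlist(s[c("mean_abs_error", "median_abs_error", "within_3pp", "within_5pp")]),
               c(mean_abs_error = 0, median_abs_error = 0, within_3pp = 1, within_5pp = 1))

  s2 <- abs_error_summary(c(1, 2, 3), c(0, 0, 0))
  expect_equal(s2$mean_abs_error, 2)
  expect_equal(s2$median_abs_error, 2)
  expect_equal(s2$within_3pp, 1)

  # boundary: an error of exactly 3 counts as within 3
  s3 <- abs_error_summary(c(0, 3, 6), c(0, 0, 0))
  expect_equal(s3$within_3pp, 2 / 3)
  expect_equal(s3$within_5pp, 2 / 3)
})

test_that("Lin's CCC matches hand computations with 1/n moments", {
  x <- c(0, 1, 2)
  expect_equal(lin_ccc(x, x), 1)
  expect_equal(lin_ccc(x, c(1, 2, 3)), 4 / 7)
  expect_equal(lin_ccc(c(-1, 0, 1), c(1, 0, -1)), -1)
  expect_warning(expect_true(is.na(lin_ccc(c(2, 2), c(2, 2)))), "undefined")
})

test_that("CCC is bounded by the Pearson correlation in absolute value", {
  set.seed(31)
  for (i in 1:50) {
    x <- rnorm(20); y <- 2 * x + rnorm(20, sd = 0.5) + runif(1, -2, 2)
    expect_lte(abs(lin_ccc(x, y)), abs(cor(x, y)) + 1e-12)
  }
  # equality iff means and variances match
  x <- rnorm(50)
  y <- x[sample(50)]
  expect_equal(abs(lin_ccc(x, y)) < abs(cor(x, y)), TRUE)
  expect_equal(lin_ccc(x, x), cor(x, x))
})

test_that("Bland-Altman limits use the sample SD around the mean difference", {
  ba <- bland_altman(c(2, 4, 6), c(1, 2, 3))  # d = 1,2,3; sd = 1
  expect_equal(ba$bias, 2)
  expect_equal(ba$loa_low, 2 - 1.96)
  expect_equal(ba$loa_high, 2 + 1.96)

  x <- rnorm(10)
  ba2 <- bland_altman(x, x)
  expect_equal(c(ba2$bias, ba2$loa_low, ba2$loa_high), c(0, 0, 0))
  ba3 <- bland_altman(x, x - 1.5)
  expect_equal(c(ba3$bias, ba3$loa_low, ba3$loa_high), c(1.5, 1.5, 1.5))
})

test_that("confusion matrices count reference rows against comparator columns", {
  m <- confusion_matrix3(c(1, 2, 3), c(1, 2, 3))
  expect_equal(diag(unclass(m)), setNames(rep(1L, 3), NULL), ignore_attr = TRUE)
  expect_equal(sum(m), 3)

  m2 <- confusion_matrix3(rep(1, 4), rep(2, 4))
  expect_equal(unclass(m2)[1, 2], 4L)
  expect_equal(sum(m2), 4)
  expect_error(confusion_matrix3(c(1, 4), c(1, 1)), "depth")
})

test_that("margin reconstruction finds the unique matrix or reports the failure mode", {
  m <- reconstruct_confusion_from_margins(c(47, 16, 1), c(59, 5, 0), 48)
  expect_equal(unclass(m), matrix(c(45, 2, 0, 13, 3, 0, 1, 0, 0), 3, 3, byrow = TRUE),
               ignore_attr = TRUE)

  forced <- reconstruct_confusion_from_margins(c(2, 1, 0), c(2, 1, 0), 3)
  expect_equal(unclass(forced), diag(c(2, 1, 0)), ignore_attr = TRUE)

  expect_error(reconstruct_confusion_from_margins(c(1, 0, 0), c(0, 1, 0), 1), "infeasible")
  # uniform margins with zero diagonal admit both 3-cycles: ambiguous
  expect_error(reconstruct_confusion_from_margins(c(1, 1, 1), c(1, 1, 1), 0), "ambiguous")
})

test_that("reconstructed matrices satisfy their constraints and round-trip", {
  set.seed(41)
  for (i in 1:30) {
    m <- random_confusion3()
    rec <- tryCatch(
      reconstruct_confusion_from_margins(rowSums(m), colSums(m), sum(diag(m))),
      error = function(e) e
    )
    if (inherits(rec, "error")) {
      expect_match(conditionMessage(rec), "ambiguous|infeasible")
    } else {
      expect_equal(rowSums(rec), rowSums(m), ignore_attr = TRUE)
      expect_equal(colSums(rec), colSums(m), ignore_attr = TRUE)
      expect_equal(sum(diag(rec)), sum(diag(m)))
      # uniqueness implies the reconstruction equals the generating matrix
      expect_equal(unclass(rec), m, ignore_attr = TRUE)
      # labels regenerated from the matrix rebuild the same matrix
      ref <- rep(rep(1:3, each = 3), as.vector(t(rec)))
      cmp <- rep(rep(1:3, times = 3), as.vector(t(rec)))
      if (length(ref) > 0) {
        expect_equal(unclass(confusion_matrix3(ref, cmp)), unclass(rec), ignore_attr = TRUE)
      }
    }
  }
})

test_that("weighted kappa matches an independent double-sum oracle", {
  kappa_oracle <- function(m, scheme) {
    k <- nrow(m); n <- sum(m)
    po <- 0; pe <- 0
    for (i in 1:k) for (j in 1:k) {
      w <- switch(scheme,
        quadratic = 1 - (i - j)^2 / (k - 1)^2,
        linear = 1 - abs(i - j) / (k - 1),
        unweighted = as.numeric(i == j))
      po <- po + w * m[i, j] / n
      pe <- pe + w * (sum(m[i, ]) / n) * (sum(m[, j]) / n)
    }
    (po - pe) / (1 - pe)
  }
  set.seed(51)
  for (i in 1:100) {
    m <- random_confusion3()
    for (scheme in c("quadratic", "linear", "unweighted")) {
      ko <- kappa_oracle(m, scheme)
      if (is.finite(ko)) {
        expect_equal(weighted_kappa(m, scheme), ko, tolerance = 1e-12)
      }
    }
  }
})

test_that("unweighted kappa equals Cohen's kappa and diagonal matrices give 1", {
  cohen <- function(m) {
    n <- sum(m); po <- sum(diag(m)) / n
    pe <- sum(rowSums(m) * colSums(m)) / n^2
    (po - pe) / (1 - pe)
  }
  set.seed(61)
  for (i in 1:100) {
    m <- random_confusion3()
    if (sum(rowSums(m) * colSums(m)) / sum(m)^2 < 1) {
      expect_equal(weighted_kappa(m, "unweighted"), cohen(m), tolerance = 1e-12)
    }
  }
  expect_equal(weighted_kappa(diag(c(5, 3, 0))), 1)
  expect_warning(expect_true(is.na(weighted_kappa(diag(c(7, 0, 0))))), "undefined")
})

test_that("ICC(2,1) behaves at the agreement extremes and recovers known components", {
  cases <- matrix(rep(c(1, 3, 5, 9), 4), ncol = 4)  # identical raters
  expect_equal(icc_2way_random_single(cases), 1)

  # constant cases + noisy raters: nothing to agree on, ICC at or below ~0
  set.seed(71)
  flat_icc <- icc_2way_random_single(
    outer(rep(5, 8), rep(1, 4)) + outer(rep(1, 8), rnorm(4, sd = 2)) +
      matrix(rnorm(32, sd = 0.5), 8, 4))
  expect_lte(flat_icc, 0.1)

  # recovery: two-way model with known variance components
  sigma_case <- 2; sigma_rater <- 0.7; sigma_resid <- 1
  theo <- sigma_case^2 / (sigma_case^2 + sigma_rater^2 + sigma_resid^2)
  reps <- sapply(1:100, function(i) {
    set.seed(100 + i)
    n <- 40; k <- 6
    m <- outer(rnorm(n, sd = sigma_case), rep(1, k)) +
      outer(rep(1, n), rnorm(k, sd = sigma_rater)) +
      matrix(rnorm(n * k, sd = sigma_resid), n, k)
    icc_2way_random_single(m)
  })
  mc_se <- sd(reps) / sqrt(length(reps))
  expect_lt(abs(mean(reps) - theo), 2 * mc_se + 0.02)
})

test_that("calibration fit recovers the identity and degenerate lines", {
  x <- c(1, 2, 3, 4, 5)
  f <- calibration_fit(x, x)
  expect_equal(c(f$intercept, f$slope, f$r_squared), c(0, 1, 1))

  flat <- calibration_fit(rep(2, 5), x)
  expect_equal(flat$slope, 0)
  expect_equal(flat$r_squared, 0)
  expect_error(calibration_fit(x, rep(1, 5)), "zero variance")

  td <- tidy(f); gl <- glance(f)
  expect_equal(td$estimate, c(0, 1))
  expect_equal(gl$n, 5)
})

test_that("spearman_rho handles monotone, tied and constant inputs", {
  a <- c(1, 2, 3, 4)
  expect_equal(spearman_rho(a, exp(a)), 1)
  expect_equal(spearman_rho(a, -a^3), -1)
  expect_warning(expect_true(is.na(spearman_rho(a, rep(1, 4)))), "constant")

  # midrank ties against the direct rank-formula oracle
  set.seed(81)
  for (i in 1:20) {
    x <- sample(1:5, 12, replace = TRUE)
    y <- sample(1:5, 12, replace = TRUE)
    if (var(x) == 0 || var(y) == 0) next
    oracle <- cor(rank(x, ties.method = "average"), rank(y, ties.method = "average"))
    expect_equal(spearman_rho(x, y), oracle, tolerance = 1e-12)
  }
})

test_that("midrank AUC equals exhaustive pair counting and pROC agrees", {
  pair_auc <- function(scores, labels) {
    pos <- scores[labels]; neg <- scores[!labels]
    s <- 0
    for (p in pos) for (q in neg) s <- s + (p > q) + 0.5 * (p == q)
    s / (length(pos) * length(neg))
  }
  set.seed(91)
  for (i in 1:40) {
    n <- sample(4:12, 1)
    labels <- c(TRUE, FALSE, runif(n - 2) > 0.5)
    scores <- sample(seq(0, 1, 0.1), n, replace = TRUE)
    r <- roc_auc_delong(scores, scores, labels)
    expect_equal(r$roc_a$auc, pair_auc(scores, labels), tolerance = 1e-12)
    expect_equal(r$z, 0)
    expect_equal(r$p_value, 1)
  }

  # perfectly separating scores
  r <- roc_auc_delong(c(3, 4, 1, 2), c(3, 4, 1, 2), c(TRUE, TRUE, FALSE, FALSE),
                      threshold = 2.5)
  expect_equal(r$roc_a$auc, 1)
  expect_equal(r$roc_a$sensitivity, 1)
  expect_equal(r$roc_a$specificity, 1)

  # worked example: pos (0.9, 0.8), neg (0.7, 0.85)
  r2 <- roc_auc_delong(c(0.9, 0.8, 0.7, 0.85), c(0.9, 0.8, 0.7, 0.85),
                       c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(r2$roc_a$auc, 0.75)

  skip_if_not_installed("pROC")
  set.seed(92)
  labels <- rep(c(TRUE, FALSE), each = 15)
  sa <- rnorm(30, mean = labels * 1.2)
  sb <- rnorm(30, mean = labels * 0.6)
  ours <- roc_auc_delong(sa, sb, labels)
  ra <- pROC::roc(labels, sa, quiet = TRUE, direction = "<")
  rb <- pROC::roc(labels, sb, quiet = TRUE, direction = "<")
  expect_equal(ours$roc_a$auc, as.numeric(pROC::auc(ra)), tolerance = 1e-12)
  ref <- pROC::roc.test(ra, rb, method = "delong", paired = TRUE)
  expect_equal(ours$p_value, ref$p.value, tolerance = 1e-8)
})
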