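test_that("Hodges-Lehmann matches the Walsh-average oracle and small-n medians", {
  expect_equal(hodges_lehmann(5), 5)
  expect_equal(hodges_lehmann(c(1, 2, 6)), 2.75)  # Walsh set {1,1.5,2,3.5,4,6}
  expect_equal(hodges_lehmann(c(-1, 0, 1)), 0)

  walsh_oracle <- function(x) {
    w <- c()
    for (i in seq_along(x)) for (j in i:length(x)) w <- c(w, (x[i] + x[j]) / 2)
    median(w)
  }
  set.seed(101)
  for (i in 1:50) {
    x <- round(rnorm(sample(1:8, 1), sd = 3), 2)
    expect_equal(hodges_lehmann(x), walsh_oracle(x))
    if (length(x) <= 2) expect_equal(hodges_lehmann(x), median(x))
    # translation equivariance
    expect_equal(hodges_lehmann(x + 7.5), hodges_lehmann(x) + 7.5)
  }
  expect_error(hodges_lehmann(numeric(0)), "empty")
})

test_that("degenerate cluster structures collapse the bootstrap as expected", {
  # single cluster: every replicate is the full sample
  b <- cluster_bootstrap(c(1, 2, 3), c("p", "p", "p"), mean,
                         boot_config(n_resamples = 50, seed = 1))
  expect_equal(b$ci_low, 2)
  expect_equal(b$ci_high, 2)
  expect_true(all(b$replicates == 2))

  # constant statistic
  b2 <- cluster_bootstrap(rnorm(10), rep(1:5, 2), function(x) 42,
                          boot_config(n_resamples = 50, seed = 1))
  expect_true(all(b2$replicates == 42))
})

test_that("size-1 clusters reduce to the ordinary nonparametric bootstrap", {
  set.seed(7)
  x <- rnorm(15)
  ids <- sprintf("c%02d", 1:15)
  cfg <- boot_config(n_resamples = 200, seed = 99)
  b <- cluster_bootstrap(x, ids, mean, cfg)

  # direct ordinary bootstrap with the same canonical ordering + seed stream
  xs <- x[order(ids, x)]
  reps <- withr::with_seed(99, {
    draw <- matrix(sample.int(15, 15 * 200, replace = TRUE), nrow = 15)
    apply(draw, 2, function(ix) mean(xs[ix]))
  })
  expect_equal(b$replicates, reps)
})

test_that("replicates are invariant to input row order under the same seed", {
  set.seed(8)
  x <- rnorm(20)
  ids <- rep(sprintf("p%02d", 1:8), length.out = 20)
  cfg <- boot_config(n_resamples = 100, seed = 123)
  b1 <- cluster_bootstrap(x, ids, median, cfg)
  perm <- sample(20)
  b2 <- cluster_bootstrap(x[perm], ids[perm], median, cfg)
  expect_equal(b1$replicates, b2$replicates)
})

test_that("the one-sided upper bound is monotone in the confidence level", {
  set.seed(9)
  x <- rnorm(30)
  ids <- sprintf("p%02d", 1:30)
  ub <- sapply(c(0.10, 0.05, 0.01), function(a) {
    cluster_bootstrap(x, ids, mean,
                      boot_config(n_resamples = 500, alpha = a,
                                  side = "upper_one_sided", seed = 5))$ci_high
  })
  expect_true(ub[1] <= ub[2] && ub[2] <= ub[3])
  b <- cluster_bootstrap(x, ids, mean,
                         boot_config(n_resamples = 100, side = "upper_one_sided", seed = 5))
  expect_equal(b$ci_low, -Inf)
})

test_that("undefined replicates are recorded up to the cap, then abort with diagnostics", {
  x <- c(1, 2, 3, 4)
  ids <- c("a", "b", "c", "d")
  # defined on the full sample but failing on (most) degenerate resamples
  needs_all <- function(v) if (length(unique(v)) < 4) stop("degenerate") else mean(v)
  expect_error(
    cluster_bootstrap(x, ids, needs_all, boot_config(n_resamples = 100, seed = 1)),
    "undefined on"
  )
  # statistic undefined on a minority of replicates: recorded, CI still computed
  flaky <- function(v) if (max(v) == 4) NA_real_ else mean(v)
  b <- cluster_bootstrap(x, ids, flaky,
                         boot_config(n_resamples = 100, seed = 2,
                                     max_undefined_frac = 1))
  expect_gt(b$n_undefined, 0)
  expect_true(is.finite(b$ci_high))
  expect_equal(length(b$replicates), 100)
})

test_that("metric-level cluster bootstrap collapses for perfect agreement and handles degeneracy", {
  d <- tibble::tibble(
    region_case_id = sprintf("C%d", 1:8),
    patient_id = rep(sprintf("P%d", 1:4), each = 2),
    x = c(1, 2, 3, 4, 5, 6, 7, 8)
  )
  d$y <- d$x
  b <- cluster_bootstrap_ci_for_metric(
    d, function(df) lin_ccc(df$x, df$y),
    boot_config(n_resamples = 100, seed = 3))
  expect_equal(b$ci_low, 1)
  expect_equal(b$ci_high, 1)

  # kappa on a nearly-degenerate depth table: undefined replicates recorded
  d2 <- tibble::tibble(
    region_case_id = sprintf("C%d", 1:6),
    patient_id = sprintf("P%d", 1:6),
    ref = c(1, 1, 1, 1, 1, 2),
    cmp = c(1, 1, 1, 1, 1, 2)
  )
  b2 <- cluster_bootstrap_ci_for_metric(
    d2, function(df) weighted_kappa(confusion_matrix3(df$ref, df$cmp)),
    boot_config(n_resamples = 200, seed = 4, max_undefined_frac = 1))
  expect_gt(b2$n_undefined, 0)   # resamples that drop patient P6 are degenerate
  expect_true(is.finite(b2$point_estimate))
})
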