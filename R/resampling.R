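#' Hodges-Lehmann estimator
#'
#' The median of all Walsh averages \eqn{(x_i + x_j)/2} over pairs
#' \eqn{i \le j} (self-pairs included): a robust location estimate for the
#' paired per-case differences in the non-inferiority analysis.
#'
#' @param x numeric vector, length >= 1, no `NA`.
#' @return a single numeric value.
#' @examples
#' hodges_lehmann(c(1, 2, 6)) # 2.75
#' @export
hodges_lehmann <- function(x) {
  if (length(x) < 1) abort("hodges_lehmann: empty input")
  if (anyNA(x)) abort("hodges_lehmann: NA values not allowed")
  w <- outer(x, x, "+") / 2
  median(w[upper.tri(w, diag = TRUE)])
}

#' Bootstrap configuration
#'
#' @param n_resamples number of bootstrap replicates. The study design uses
#'   5000 for the primary endpoint and 2000 for agreement-metric intervals.
#' @param alpha type-I level (default 0.05).
#' @param side `"two_sided"` for a percentile interval at `alpha/2` and
#'   `1 - alpha/2`, or `"upper_one_sided"` for a one-sided upper bound at
#'   `1 - alpha` (the non-inferiority bound); the lower limit is then `-Inf`.
#' @param seed integer seed; every resampling function is reproducible from
#'   it and restores the caller's RNG state.
#' @param max_undefined_frac largest tolerated fraction of replicates on
#'   which the statistic is undefined (degenerate resamples can make e.g.
#'   kappa undefined); beyond it the bootstrap aborts with diagnostics.
#' @return a list of class `boot_config`.
#' @export
boot_config <- function(n_resamples = 5000, alpha = 0.05,
                        side = c("two_sided", "upper_one_sided"),
                        seed = NULL, max_undefined_frac = 0.01) {
  side <- match.arg(side)
  stopifnot(n_resamples >= 1, alpha > 0, alpha < 1)
  structure(
    list(n_resamples = as.integer(n_resamples), alpha = alpha, side = side,
         seed = seed, max_undefined_frac = max_undefined_frac),
    class = "boot_config"
  )
}

#' Patient-level cluster bootstrap
#'
#' Resamples whole clusters (patients) with replacement: each replicate draws
#' `n_clusters` cluster ids with replacement and concatenates all member
#' values, so a cluster drawn m times contributes m copies of all its
#' members and replicate sample sizes vary with the resampled cluster sizes.
#' Confidence limits are percentile quantiles of the replicate statistics
#' (inclusive, type-7 convention). Clusters are sorted canonically (by id,
#' then by value within cluster) before sampling, so the replicate vector is
#' invariant to input row order given the same seed.
#'
#' A replicate on which `statistic` errors or returns a non-finite value is
#' recorded as undefined; if more than `max_undefined_frac` of replicates are
#' undefined the bootstrap aborts with diagnostics, otherwise quantiles are
#' taken over the defined replicates.
#'
#' @param values numeric vector of observations.
#' @param clusters vector of cluster (patient) ids parallel to `values`.
#' @param statistic function mapping a numeric vector to a single number.
#' @param config a [boot_config()].
#' @return an object of class `bootstrap_result`: `point_estimate`,
#'   `replicates`, `ci_low`, `ci_high`, `n_undefined`, `n_clusters`, `config`.
#' @examples
#' b <- cluster_bootstrap(rnorm(20), rep(1:10, each = 2), mean,
#'                        boot_config(n_resamples = 200, seed = 1))
#' b$ci_low; b$ci_high
#' @export
cluster_bootstrap <- function(values, clusters, statistic, config = boot_config()) {
  if (length(values) != length(clusters)) abort("values and clusters must have equal length")
  if (length(values) == 0) abort("empty input")
  # canonical order: cluster id, then value, for row-order invariance
  ord <- order(as.character(clusters), values)
  values <- values[ord]; clusters <- clusters[ord]
  idx_by_cluster <- split(seq_along(values), as.character(clusters))
  idx_by_cluster <- idx_by_cluster[order(names(idx_by_cluster))]
  K <- length(idx_by_cluster)

  point <- statistic(values)
  B <- config$n_resamples
  seed_locally(config$seed)
  draw <- matrix(sample.int(K, K * B, replace = TRUE), nrow = K, ncol = B)

  reps <- vapply(seq_len(B), function(b) {
    members <- unlist(idx_by_cluster[draw[, b]], use.names = FALSE)
    out <- tryCatch(statistic(values[members]), error = function(e) NA_real_)
    if (!is.numeric(out) || length(out) != 1 || !is.finite(out)) NA_real_ else out
  }, numeric(1))

  finish_bootstrap(point, reps, K, config)
}

finish_bootstrap <- function(point, reps, n_clusters, config) {
  n_undef <- sum(is.na(reps))
  if (n_undef / length(reps) > config$max_undefined_frac) {
    abort(sprintf(
      "cluster bootstrap: statistic undefined on %d of %d replicates (> %.1f%% allowed)",
      n_undef, length(reps), 100 * config$max_undefined_frac
    ))
  }
  ok <- reps[!is.na(reps)]
  if (config$side == "two_sided") {
    ci <- unname(quantile(ok, c(config$alpha / 2, 1 - config$alpha / 2), type = 7))
  } else {
    ci <- c(-Inf, unname(quantile(ok, 1 - config$alpha, type = 7)))
  }
  structure(
    list(point_estimate = point, replicates = reps,
         ci_low = ci[1], ci_high = ci[2],
         n_undefined = n_undef, n_clusters = n_clusters, config = config),
    class = "bootstrap_result"
  )
}

#' @export
print.bootstrap_result <- function(x, ...) {
  lab <- if (x$config$side == "two_sided") {
    sprintf("%.1f%% CI [%.4g, %.4g]", 100 * (1 - x$config$alpha), x$ci_low, x$ci_high)
  } else {
    sprintf("one-sided %.1f%% upper bound %.4g", 100 * (1 - x$config$alpha), x$ci_high)
  }
  cat(sprintf(
    "Cluster bootstrap (%d clusters, B = %d): estimate %.4g, %s\n",
    x$n_clusters, x$config$n_resamples, x$point_estimate, lab
  ))
  if (x$n_undefined > 0) cat(sprintf("  (%d undefined replicates)\n", x$n_undefined))
  invisible(x)
}

#' Cluster-bootstrap confidence interval for a data-frame metric
#'
#' Wraps [cluster_bootstrap()] for agreement metrics that need whole rows
#' of paired data per region-case (e.g. weighted kappa, CCC): each replicate
#' resamples patients with replacement and re-evaluates the metric on the
#' concatenated rows.
#'
#' @param data a data frame with one row per region-case, containing a
#'   `patient_id` column (and `region_case_id` if present, used for canonical
#'   row ordering).
#' @param metric function taking the resampled data frame and returning a
#'   single number; must be defined on the full sample.
#' @param config a [boot_config()] (the study design uses
#'   `n_resamples = 2000` for agreement metrics).
#' @return a `bootstrap_result`.
#' @export
cluster_bootstrap_ci_for_metric <- function(data, metric, config = boot_config(n_resamples = 2000)) {
  if (!"patient_id" %in% names(data)) abort("data must contain a patient_id column")
  ord <- if ("region_case_id" %in% names(data)) {
    order(data$patient_id, data$region_case_id)
  } else {
    order(data$patient_id)
  }
  data <- data[ord, , drop = FALSE]
  point <- metric(data)
  if (!is.finite(point)) abort("metric undefined on the full sample")

  idx_by_cluster <- split(seq_len(nrow(data)), as.character(data$patient_id))
  idx_by_cluster <- idx_by_cluster[order(names(idx_by_cluster))]
  K <- length(idx_by_cluster)
  B <- config$n_resamples
  seed_locally(config$seed)
  draw <- matrix(sample.int(K, K * B, replace = TRUE), nrow = K, ncol = B)
  reps <- vapply(seq_len(B), function(b) {
    members <- unlist(idx_by_cluster[draw[, b]], use.names = FALSE)
    out <- tryCatch(suppressWarnings(metric(data[members, , drop = FALSE])),
                    error = function(e) NA_real_)
    if (!is.numeric(out) || length(out) != 1 || !is.finite(out)) NA_real_ else out
  }, numeric(1))
  finish_bootstrap(point, reps, K, config)
}

#' @export
tidy.bootstrap_result <- function(x, ...) {
  tibble::tibble(
    estimate = x$point_estimate,
    ci_low = x$ci_low,
    ci_high = x$ci_high,
    n_resamples = x$config$n_resamples,
    n_undefined = x$n_undefined,
    n_clusters = x$n_clusters,
    alpha = x$config$alpha,
    side = x$config$side
  )
}
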