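#' Absolute-error summary with clinical tolerance bands
#'
#' Summarises region-level TBSA error of a method against a reference:
#' mean and median absolute error in percentage points, and the proportion of
#' cases whose absolute error falls within each tolerance band. Bands are
#' inclusive: an error of exactly 3 pp counts as "within 3 pp".
#'
#' @param estimate numeric vector of method TBSA values (percentage points).
#' @param reference numeric vector of reference TBSA values, same length.
#' @param tolerances numeric vector of tolerance band half-widths in
#'   percentage points (default `c(3, 5)`, the bands used in clinical
#'   reporting of regional TBSA error).
#' @return A one-row tibble with columns `n`, `mean_abs_error`,
#'   `median_abs_error`, and one `within_<t>pp` proportion per tolerance.
#' @examples
#' abs_error_summary(c(1, 5, 9), c(0, 2, 3))
#' @export
abs_error_summary <- function(estimate, reference, tolerances = c(3, 5)) {
  check_paired(estimate, reference, min_n = 1)
  err <- abs(estimate - reference)
  out <- tibble::tibble(
    n = length(err),
    mean_abs_error = mean(err),
    median_abs_error = median(err)
  )
  for (t in tolerances) {
    out[[sprintf("within_%gpp", t)]] <- mean(err <= t)
  }
  out
}

#' Lin's concordance correlation coefficient
#'
#' Agreement of two paired continuous measurements with the identity line:
#' \deqn{CCC = 2 s_{xy} / (s_x^2 + s_y^2 + (\bar x - \bar y)^2)}
#' using population (1/n) moments, as in the original definition. The choice
#' of 1/n rather than 1/(n-1) moments changes the third decimal at n around
#' 64 and is therefore fixed and documented.
#'
#' @param x,y numeric vectors of equal length (>= 2), finite values.
#' @return a single numeric value in \[-1, 1\]; `NA` with a warning when both
#'   inputs are constant with equal means (agreement undefined).
#' @examples
#' lin_ccc(c(0, 1, 2), c(1, 2, 3)) # 4/7
#' @export
lin_ccc <- function(x, y) {
  check_paired(x, y, min_n = 2)
  n <- length(x)
  mx <- mean(x); my <- mean(y)
  vx <- mean((x - mx)^2); vy <- mean((y - my)^2)
  sxy <- mean((x - mx) * (y - my))
  denom <- vx + vy + (mx - my)^2
  if (denom == 0) {
    warn("lin_ccc undefined: both vectors constant with equal means")
    return(NA_real_)
  }
  2 * sxy / denom
}

#' Bland-Altman bias and 95% limits of agreement
#'
#' Differences are taken as `x - y`; the limits of agreement are
#' `bias +/- 1.96 * sd(d)` with the sample (n-1) standard deviation.
#'
#' @param x,y numeric vectors of equal length (>= 2).
#' @return one-row tibble: `bias`, `loa_low`, `loa_high`, `sd_diff`, `n`.
#' @examples
#' bland_altman(c(2, 4, 6), c(1, 2, 3))
#' @export
bland_altman <- function(x, y) {
  check_paired(x, y, min_n = 2)
  d <- x - y
  s <- sd(d)
  tibble::tibble(
    bias = mean(d),
    loa_low = mean(d) - 1.96 * s,
    loa_high = mean(d) + 1.96 * s,
    sd_diff = s,
    n = length(d)
  )
}

#' Three-class confusion matrix for the burn depth ontology
#'
#' Rows are the reference class, columns the comparator class, both on the
#' fixed ordinal ontology SP < DP < FT.
#'
#' @param ref,cmp vectors of depth classes (labels or integer codes 1..3),
#'   equal length; `NA` / non-assessable entries are not allowed here.
#' @return a 3x3 integer matrix of class `confusion_matrix3` with depth
#'   labels as dimnames.
#' @export
confusion_matrix3 <- function(ref, cmp) {
  r <- depth_code(ref); c <- depth_code(cmp)
  if (length(r) != length(c)) abort("ref and cmp must have equal length")
  if (anyNA(r) || anyNA(c)) abort("confusion_matrix3 requires assessable classes (no NA)")
  m <- matrix(0L, 3, 3, dimnames = list(reference = DEPTH_LEVELS, comparator = DEPTH_LEVELS))
  for (i in seq_along(r)) m[r[i], c[i]] <- m[r[i], c[i]] + 1L
  class(m) <- c("confusion_matrix3", class(m))
  m
}

as_confusion3 <- function(m) {
  if (inherits(m, "confusion_matrix3")) return(unclass(m))
  m <- as.matrix(m)
  if (!all(dim(m) == c(3, 3))) abort("expected a 3x3 matrix")
  if (any(m < 0)) abort("confusion counts must be non-negative")
  m
}

#' Reconstruct a 3x3 confusion matrix from its margins and diagonal total
#'
#' Published agreement tables often print only the marginal class counts of
#' the reference and the comparator plus the number of exact agreements.
#' For a 3-class table these constraints frequently determine the full matrix.
#' This routine enumerates all non-negative integer 3x3 matrices with the
#' given row totals, column totals and diagonal sum, and returns the matrix
#' iff it is unique.
#'
#' @param row_totals integer vector length 3: reference class counts (SP, DP, FT).
#' @param col_totals integer vector length 3: comparator class counts; must
#'   sum to `sum(row_totals)`.
#' @param diagonal_total integer: number of exactly agreeing cases.
#' @return a `confusion_matrix3`; errors if the constraints are infeasible or
#'   admit more than one solution (the error reports the solution count).
#' @examples
#' reconstruct_confusion_from_margins(c(47, 16, 1), c(59, 5, 0), 48)
#' @export
reconstruct_confusion_from_margins <- function(row_totals, col_totals, diagonal_total) {
  row_totals <- as.integer(row_totals); col_totals <- as.integer(col_totals)
  diagonal_total <- as.integer(diagonal_total)
  stopifnot(length(row_totals) == 3, length(col_totals) == 3, length(diagonal_total) == 1)
  if (any(row_totals < 0) || any(col_totals < 0)) abort("margins must be non-negative")
  if (sum(row_totals) != sum(col_totals)) abort("row and column totals must have equal sums")
  total <- sum(row_totals)
  if (diagonal_total < 0 || diagonal_total > total) abort("diagonal_total outside [0, total]")

  solutions <- list()
  # Four free cells (a11, a12, a21, a22); the rest follow from the margins.
  for (a11 in 0:min(row_totals[1], col_totals[1])) {
    for (a12 in 0:min(row_totals[1] - a11, col_totals[2])) {
      a13 <- row_totals[1] - a11 - a12
      if (a13 > col_totals[3]) next
      for (a21 in 0:min(row_totals[2], col_totals[1] - a11)) {
        for (a22 in 0:min(row_totals[2] - a21, col_totals[2] - a12)) {
          a23 <- row_totals[2] - a21 - a22
          if (a23 > col_totals[3] - a13) next
          a31 <- col_totals[1] - a11 - a21
          a32 <- col_totals[2] - a12 - a22
          a33 <- col_totals[3] - a13 - a23
          if (a31 < 0 || a32 < 0 || a33 < 0) next
          if (a31 + a32 + a33 != row_totals[3]) next
          if (a11 + a22 + a33 != diagonal_total) next
          solutions[[length(solutions) + 1L]] <-
            matrix(c(a11, a12, a13, a21, a22, a23, a31, a32, a33), 3, 3, byrow = TRUE)
        }
      }
    }
  }
  if (length(solutions) == 0) abort("infeasible margins: no matrix satisfies the constraints")
  if (length(solutions) > 1) {
    abort(sprintf("ambiguous margins: %d matrices satisfy the constraints", length(solutions)))
  }
  m <- solutions[[1]]
  storage.mode(m) <- "integer"
  dimnames(m) <- list(reference = DEPTH_LEVELS, comparator = DEPTH_LEVELS)
  class(m) <- c("confusion_matrix3", class(m))
  m
}

#' Cohen's kappa with quadratic, linear or no weights
#'
#' Chance-corrected agreement for a k-class ordinal confusion matrix.
#' With agreement weights \eqn{w_{ij} = 1 - (i-j)^2/(k-1)^2} (quadratic;
#' linear uses \eqn{|i-j|/(k-1)}, unweighted uses the identity weights),
#' \deqn{\kappa_w = (P_o - P_e) / (1 - P_e)}
#' where \eqn{P_o} is the weighted observed proportion and \eqn{P_e} the
#' weighted proportion expected from the matrix margins.
#'
#' @param m a square non-negative count matrix (rows = reference,
#'   columns = comparator), e.g. from [confusion_matrix3()].
#' @param weight_scheme one of `"quadratic"` (default), `"linear"`,
#'   `"unweighted"`.
#' @return a single numeric value; `NA` with a warning if the chance
#'   agreement equals 1 (all mass in one cell of both margins).
#' @examples
#' m <- reconstruct_confusion_from_margins(c(47, 16, 1), c(59, 5, 0), 48)
#' weighted_kappa(m) # 0.144 at 3 decimals
#' @export
weighted_kappa <- function(m, weight_scheme = c("quadratic", "linear", "unweighted")) {
  weight_scheme <- match.arg(weight_scheme)
  m <- as.matrix(unclass(m))
  if (nrow(m) != ncol(m)) abort("confusion matrix must be square")
  k <- nrow(m)
  total <- sum(m)
  if (total < 1) abort("confusion matrix total must be >= 1")
  p <- m / total
  d <- abs(outer(seq_len(k), seq_len(k), "-"))
  w <- switch(weight_scheme,
    quadratic = 1 - d^2 / (k - 1)^2,
    linear = 1 - d / (k - 1),
    unweighted = (d == 0) * 1
  )
  pe_mat <- outer(rowSums(p), colSums(p))
  po <- sum(w * p)
  pe <- sum(w * pe_mat)
  if (abs(1 - pe) < .Machine$double.eps * 8) {
    warn("weighted_kappa undefined: chance agreement equals 1")
    return(NA_real_)
  }
  (po - pe) / (1 - pe)
}

#' Exact-agreement proportion of a confusion matrix
#'
#' @param m a square count matrix.
#' @return diagonal sum divided by the total.
#' @export
exact_agreement <- function(m) {
  m <- as.matrix(unclass(m))
  sum(diag(m)) / sum(m)
}

#' Two-way random-effects intraclass correlation, ICC(2,1)
#'
#' Absolute-agreement, single-rater ICC from the two-way random-effects
#' ANOVA decomposition of a complete cases-by-raters matrix:
#' \deqn{ICC(2,1) = \frac{MS_R - MS_E}{MS_R + (k-1) MS_E + k (MS_C - MS_E)/n}}
#' with \eqn{MS_R} the between-case, \eqn{MS_C} the between-rater and
#' \eqn{MS_E} the residual mean square.
#'
#' @param ratings numeric matrix, rows = cases (n >= 2), columns =
#'   raters (k >= 2); must be complete (no `NA`) — restrict to complete
#'   cases before calling.
#' @return a single numeric value (can be <= 0 when raters disagree more
#'   than cases differ).
#' @export
icc_2way_random_single <- function(ratings) {
  ratings <- as.matrix(ratings)
  if (anyNA(ratings)) abort("icc_2way_random_single requires a complete matrix; restrict to complete cases first")
  n <- nrow(ratings); k <- ncol(ratings)
  if (n < 2 || k < 2) abort("need >= 2 cases and >= 2 raters")
  grand <- mean(ratings)
  row_m <- rowMeans(ratings)
  col_m <- colMeans(ratings)
  ss_r <- k * sum((row_m - grand)^2)
  ss_c <- n * sum((col_m - grand)^2)
  ss_tot <- sum((ratings - grand)^2)
  ss_e <- ss_tot - ss_r - ss_c
  ms_r <- ss_r / (n - 1)
  ms_c <- ss_c / (k - 1)
  ms_e <- ss_e / ((n - 1) * (k - 1))
  denom <- ms_r + (k - 1) * ms_e + k * (ms_c - ms_e) / n
  if (denom == 0) {
    warn("ICC undefined: zero total variance")
    return(NA_real_)
  }
  (ms_r - ms_e) / denom
}

#' Calibration regression of method estimates on reference values
#'
#' Ordinary least squares of `estimate` on `reference`. A slope below 1
#' indicates compression of extremes (estimates pulled toward the centre of
#' the distribution); intercept and slope of (0, 1) indicate identity
#' calibration.
#'
#' @param estimate,reference numeric vectors, length >= 3; `reference` must
#'   have non-zero variance.
#' @return an object of class `calibration_fit` with elements `intercept`,
#'   `slope`, `r_squared`, `n`, and the underlying data; supports [tidy()],
#'   [glance()] and [autoplot()][ggplot2::autoplot].
#' @export
calibration_fit <- function(estimate, reference) {
  check_paired(estimate, reference, min_n = 3)
  if (var(reference) == 0) abort("calibration_fit: reference has zero variance")
  fit <- lm(estimate ~ reference)
  # direct R^2: summary.lm warns on exact fits
  sst <- sum((estimate - mean(estimate))^2)
  r2 <- if (sst == 0) 0 else 1 - sum(fit$residuals^2) / sst
  structure(
    list(
      intercept = unname(coef(fit)[1]),
      slope = unname(coef(fit)[2]),
      r_squared = r2,
      n = length(estimate),
      data = tibble::tibble(estimate = estimate, reference = reference)
    ),
    class = "calibration_fit"
  )
}

#' @export
print.calibration_fit <- function(x, ...) {
  cat(sprintf(
    "Calibration fit (n = %d): estimate = %.3f + %.3f * reference, R^2 = %.3f\n",
    x$n, x$intercept, x$slope, x$r_squared
  ))
  invisible(x)
}

#' Spearman rank correlation with midrank ties
#'
#' @param a,b numeric vectors, length >= 3.
#' @return a single numeric value; `NA` with a warning when either input is
#'   constant (ranks undefined).
#' @export
spearman_rho <- function(a, b) {
  check_paired(a, b, min_n = 3)
  if (var(a) == 0 || var(b) == 0) {
    warn("spearman_rho undefined: constant input")
    return(NA_real_)
  }
  stats::cor(a, b, method = "spearman")
}

# Placement values for one classifier: V10 over positives, V01 over negatives.
delong_placements <- function(scores, labels) {
  x <- scores[labels]      # positives
  y <- scores[!labels]     # negatives
  m <- length(x); n <- length(y)
  psi <- outer(x, y, function(xi, yj) (xi > yj) + 0.5 * (xi == yj))
  list(v10 = rowMeans(psi), v01 = 1 - colMeans(psi), auc = mean(psi), m = m, n = n)
}

#' ROC AUC for two paired classifiers with the DeLong comparison
#'
#' AUC is the midrank (ties = half credit) estimate; the paired DeLong
#' covariance is computed from placement values, giving a z statistic and
#' two-sided p-value for the difference in AUCs of two score vectors
#' evaluated on the same cases.
#'
#' @param scores_a,scores_b numeric score vectors on the same cases.
#' @param labels logical (or 0/1) vector of true class; both classes must be
#'   present.
#' @param threshold optional decision threshold: predictions are
#'   `score >= threshold`, from which sensitivity and specificity are
#'   computed for each classifier.
#' @return list with `roc_a` and `roc_b` (one-row tibbles: `auc`,
#'   `auc_variance`, and at a threshold `sensitivity`, `specificity`),
#'   `z` and `p_value` for the paired AUC difference.
#' @examples
#' roc_auc_delong(c(.9, .8, .7, .85), c(.9, .8, .7, .85), c(TRUE, TRUE, FALSE, FALSE))
#' @export
roc_auc_delong <- function(scores_a, scores_b, labels, threshold = NULL) {
  labels <- as.logical(labels)
  if (length(scores_a) != length(labels) || length(scores_b) != length(labels)) {
    abort("scores and labels must have equal length")
  }
  if (!any(labels) || all(labels)) abort("both classes must be present in labels")
  pa <- delong_placements(scores_a, labels)
  pb <- delong_placements(scores_b, labels)

  # a class with a single member contributes no estimable covariance
  safe_cov <- function(m) if (nrow(m) < 2) matrix(0, 2, 2) else stats::cov(m)
  s10 <- safe_cov(cbind(pa$v10, pb$v10))
  s01 <- safe_cov(cbind(pa$v01, pb$v01))
  var_a <- s10[1, 1] / pa$m + s01[1, 1] / pa$n
  var_b <- s10[2, 2] / pb$m + s01[2, 2] / pb$n
  var_diff <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / pa$m +
    (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / pa$n
  if (var_diff <= .Machine$double.eps) {
    z <- 0; p <- 1
  } else {
    z <- (pa$auc - pb$auc) / sqrt(var_diff)
    p <- 2 * pnorm(-abs(z))
  }

  mk <- function(pl, v, scores) {
    out <- tibble::tibble(auc = pl$auc, auc_variance = max(0, v))
    if (!is.null(threshold)) {
      pred <- scores >= threshold
      out$sensitivity <- mean(pred[labels])
      out$specificity <- mean(!pred[!labels])
    }
    out
  }
  list(
    roc_a = mk(pa, var_a, scores_a),
    roc_b = mk(pb, var_b, scores_b),
    z = z, p_value = p
  )
}

check_paired <- function(x, y, min_n = 1) {
  if (length(x) != length(y)) abort("inputs must have equal length")
  if (length(x) < min_n) abort(sprintf("need at least %d paired values", min_n))
  if (anyNA(x) || anyNA(y)) abort("inputs must not contain NA; filter flagged/missing values first")
  invisible(TRUE)
}
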