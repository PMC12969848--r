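#' Expert-panel consensus for one region-case
#'
#' Implements the panel adjudication rule: consensus TBSA is the median of
#' the panelists' estimates and consensus depth the majority class, with a
#' three-way tie defaulting to deep partial absent unanimity (a two-way tie
#' is broken toward the deeper class). The case is auto-accepted when the
#' TBSA range (max - min) is at most 2 percentage points AND a strict
#' majority (> n/2 votes) depth class exists; otherwise it is flagged
#' `needs_adjudication` — the consensus is still computed (the human
#' re-score round cannot be executed by software) and the flag lets users
#' audit which cases would have gone to adjudication.
#'
#' @param tbsa numeric vector of panelist TBSA values (entry errors and
#'   non-assessable ratings removed upstream); length >= 1.
#' @param depth depth classes (labels or codes 1..3) of the same panelists;
#'   `NA` (non-assessable) votes are dropped from the depth vote.
#' @param tbsa_range_max auto-acceptance TBSA range threshold in pp
#'   (default 2).
#' @return one-row tibble: `consensus_tbsa`, `consensus_depth` (integer
#'   code), `adjudication_flag` (`auto_accepted` / `needs_adjudication`),
#'   `n_raters_used`, `depth_tie` (logical: was a tie-break used).
#' @examples
#' panel_consensus(c(4, 5, 6), c("superficial_partial", "superficial_partial", "deep_partial"))
#' @export
panel_consensus <- function(tbsa, depth, tbsa_range_max = 2) {
  depth <- depth_code(depth)
  if (length(tbsa) != length(depth)) abort("tbsa and depth must have equal length")
  keep_t <- !is.na(tbsa)
  votes <- depth[!is.na(depth)]
  if (!any(keep_t) || length(votes) == 0) {
    abort("no assessable panelist ratings for this case")
  }
  tbsa <- tbsa[keep_t]
  md <- modal_depth(votes)
  strict <- max(tabulate(votes, 3)) > length(votes) / 2
  auto <- (max(tbsa) - min(tbsa)) <= tbsa_range_max && strict
  tibble::tibble(
    consensus_tbsa = median(tbsa),
    consensus_depth = md$class,
    adjudication_flag = if (auto) "auto_accepted" else "needs_adjudication",
    n_raters_used = length(tbsa),
    depth_tie = md$tie
  )
}

# Majority depth with ordinal tie-breaks: a full three-way tie defaults to
# deep partial; a two-way tie is broken toward the deeper class. For a
# 3-member panel this rule is monotone in each vote; with larger groups a
# raised non-modal vote can break a tie toward the lower class.
modal_depth <- function(votes) {
  counts <- tabulate(votes, 3)
  modal <- which(counts == max(counts) & counts > 0)
  if (length(modal) == 1) return(list(class = modal, tie = FALSE))
  if (length(modal) == 3) return(list(class = 2L, tie = TRUE))
  list(class = max(modal), tie = TRUE)
}

#' Physician-group consensus for one region-case
#'
#' Consensus TBSA is the median of the physicians' estimates (midpoint
#' convention for even counts, as with 18 raters) and consensus depth the
#' modal class, with ties broken toward the deeper class (by analogy with
#' the panel's tie default).
#'
#' @inheritParams panel_consensus
#' @return one-row tibble: `consensus_tbsa`, `consensus_depth`,
#'   `n_raters_used`, `depth_tie`.
#' @examples
#' physician_consensus(c(1, 2, 3, 10), c(1, 1, 2, 2))
#' @export
physician_consensus <- function(tbsa, depth) {
  depth <- depth_code(depth)
  if (length(tbsa) != length(depth)) abort("tbsa and depth must have equal length")
  keep_t <- !is.na(tbsa)
  votes <- depth[!is.na(depth)]
  if (!any(keep_t) || length(votes) == 0) abort("no assessable physician ratings for this case")
  md <- modal_depth(votes)
  tibble::tibble(
    consensus_tbsa = median(tbsa[keep_t]),
    consensus_depth = md$class,
    n_raters_used = sum(keep_t),
    depth_tie = md$tie
  )
}

#' Consensus values for every region-case
#'
#' Applies [panel_consensus()] or [physician_consensus()] to each
#' region-case of a `study_tables` object. Entry-error TBSA values and
#' non-assessable depth votes are excluded before aggregation; cases with no
#' assessable rating of the requested kind are omitted (they are excluded
#' from the analysis sets upstream).
#'
#' @param tables a `study_tables` object.
#' @param source `"panel"` (rater kind `panelist`) or `"physician"`.
#' @param tbsa_range_max passed to [panel_consensus()].
#' @return tibble with one row per region-case: `region_case_id`,
#'   `consensus_source`, `consensus_tbsa`, `consensus_depth`,
#'   `adjudication_flag` (`NA` for physicians), `n_raters_used`, `depth_tie`.
#' @export
consensus_table <- function(tables, source = c("panel", "physician"),
                            tbsa_range_max = 2) {
  stopifnot(inherits(tables, "study_tables"))
  source <- match.arg(source)
  kind <- if (source == "panel") "panelist" else "physician"
  r <- tables$ratings[tables$ratings$rater_kind == kind, ]
  r$tbsa_use <- ifelse(usable(r), r$tbsa_percent, NA_real_)

  r |>
    dplyr::group_by(.data$region_case_id) |>
    dplyr::group_modify(function(g, key) {
      if (!any(!is.na(g$tbsa_use)) || !any(!is.na(g$depth_ord))) {
        return(tibble::tibble(
          consensus_tbsa = NA_real_, consensus_depth = NA_integer_,
          adjudication_flag = NA_character_, n_raters_used = 0L,
          depth_tie = NA))
      }
      if (source == "panel") {
        panel_consensus(g$tbsa_use, g$depth_ord, tbsa_range_max = tbsa_range_max)
      } else {
        out <- physician_consensus(g$tbsa_use, g$depth_ord)
        out$adjudication_flag <- NA_character_
        out[c("consensus_tbsa", "consensus_depth", "adjudication_flag",
              "n_raters_used", "depth_tie")]
      }
    }) |>
    dplyr::ungroup() |>
    dplyr::mutate(consensus_source = source, .after = "region_case_id") |>
    dplyr::filter(.data$n_raters_used > 0)
}

#' Pre-consensus agreement among panelists (or any rater group)
#'
#' Summarises agreement before adjudication: two-way random-effects
#' single-rater ICC for TBSA (on the complete cases-by-raters matrix) and
#' the mean pairwise quadratically weighted kappa for depth. Cases with any
#' missing rating are dropped from the ICC matrix; rater pairs whose kappa
#' is undefined (degenerate margins) are dropped from the mean with a
#' warning rather than crashing.
#'
#' @param tables a `study_tables` object.
#' @param kind rater kind to summarise (default `"panelist"`).
#' @return one-row tibble: `tbsa_icc`, `depth_kappa_w`, `n_cases_icc`,
#'   `n_raters`.
#' @export
preconsensus_agreement <- function(tables, kind = "panelist") {
  stopifnot(inherits(tables, "study_tables"))
  r <- tables$ratings[tables$ratings$rater_kind == kind, ]
  if (nrow(r) == 0) abort(paste0("no ratings of kind ", kind))
  r$tbsa_use <- ifelse(usable(r), r$tbsa_percent, NA_real_)

  wide <- r |>
    dplyr::select("region_case_id", "rater_id", "tbsa_use") |>
    tidyr::pivot_wider(names_from = "rater_id", values_from = "tbsa_use")
  mat <- as.matrix(wide[-1])
  if (ncol(mat) < 2) abort("need >= 2 raters for pre-consensus agreement")
  complete <- stats::complete.cases(mat)
  icc <- if (sum(complete) >= 2) icc_2way_random_single(mat[complete, , drop = FALSE]) else NA_real_

  dwide <- r |>
    dplyr::select("region_case_id", "rater_id", "depth_ord") |>
    tidyr::pivot_wider(names_from = "rater_id", values_from = "depth_ord")
  dm <- as.matrix(dwide[-1])
  pairs <- utils::combn(ncol(dm), 2)
  kappas <- apply(pairs, 2, function(p) {
    ok <- !is.na(dm[, p[1]]) & !is.na(dm[, p[2]])
    if (sum(ok) < 2) return(NA_real_)
    suppressWarnings(weighted_kappa(confusion_matrix3(dm[ok, p[1]], dm[ok, p[2]])))
  })
  if (anyNA(kappas)) warn("some rater pairs had undefined weighted kappa; dropped from the pairwise mean")
  kw <- if (all(is.na(kappas))) NA_real_ else mean(kappas, na.rm = TRUE)

  tibble::tibble(
    tbsa_icc = icc,
    depth_kappa_w = kw,
    n_cases_icc = sum(complete),
    n_raters = ncol(mat)
  )
}
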