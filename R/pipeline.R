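#' Paired per-case error differences
#'
#' For each region-case in the analysis set, computes the model's absolute
#' TBSA error and the physician-median absolute TBSA error against the
#' panel consensus, and their difference
#' `delta = model_abs_error - physician_abs_error` (positive values mean
#' the model is worse). Each delta carries its `patient_id` for the cluster
#' bootstrap.
#'
#' @param tables a `study_tables` object.
#' @param panel panel consensus tibble from
#'   `consensus_table(tables, "panel")`.
#' @param physicians physician consensus tibble from
#'   `consensus_table(tables, "physician")`.
#' @param case_ids region-case ids to include (default: the Full Analysis
#'   Set from [build_analysis_sets()]).
#' @return tibble with one row per case: `region_case_id`, `patient_id`,
#'   `model_tbsa`, `physician_tbsa`, `panel_tbsa`, `model_abs_error`,
#'   `physician_abs_error`, `delta`.
#' @export
compute_paired_deltas <- function(tables, panel = consensus_table(tables, "panel"),
                                  physicians = consensus_table(tables, "physician"),
                                  case_ids = NULL) {
  stopifnot(inherits(tables, "study_tables"))
  if (is.null(case_ids)) case_ids <- build_analysis_sets(tables)$full_analysis
  model <- tables$ratings[tables$ratings$rater_kind == "model" & usable(tables$ratings), ]

  out <- tibble::tibble(region_case_id = case_ids) |>
    dplyr::left_join(tables$cases[c("region_case_id", "patient_id")], by = "region_case_id") |>
    dplyr::left_join(
      dplyr::select(model, "region_case_id", model_tbsa = "tbsa_percent"),
      by = "region_case_id") |>
    dplyr::left_join(
      dplyr::select(physicians, "region_case_id", physician_tbsa = "consensus_tbsa"),
      by = "region_case_id") |>
    dplyr::left_join(
      dplyr::select(panel, "region_case_id", panel_tbsa = "consensus_tbsa"),
      by = "region_case_id")
  missing <- out$region_case_id[!stats::complete.cases(
    out[c("model_tbsa", "physician_tbsa", "panel_tbsa")])]
  if (length(missing)) {
    abort(paste0("missing rating or consensus for included case(s): ",
                 paste(missing, collapse = ", ")))
  }
  out |>
    dplyr::mutate(
      model_abs_error = abs(.data$model_tbsa - .data$panel_tbsa),
      physician_abs_error = abs(.data$physician_tbsa - .data$panel_tbsa),
      delta = .data$model_abs_error - .data$physician_abs_error
    )
}

#' Primary non-inferiority analysis
#'
#' Tests whether the model's region-level TBSA error is not meaningfully
#' worse than the physicians': the Hodges–Lehmann median of the paired
#' deltas is estimated, and its one-sided upper 95% confidence bound is
#' obtained by a patient-level cluster bootstrap of the HL statistic.
#' Non-inferiority is declared when the upper bound is at most the margin
#' Δ*; superiority when the upper bound is below 0 (superiority implies
#' non-inferiority and the strongest label is reported).
#'
#' @param deltas tibble from [compute_paired_deltas()].
#' @param margin non-inferiority margin Δ* in percentage points (default 3).
#' @param n_resamples bootstrap replicates (study design: 5000).
#' @param alpha one-sided level (default 0.05).
#' @param seed integer seed for the bootstrap.
#' @return object of class `noninf_result`: `hl_estimate`,
#'   `upper_bound`, `margin`, `decision`
#'   (`superior` / `non_inferior` / `not_demonstrated`), `n_cases`,
#'   `n_patients`, and the underlying `bootstrap` result.
#' @export
primary_analysis <- function(deltas, margin = 3, n_resamples = 5000,
                             alpha = 0.05, seed = NULL) {
  if (nrow(deltas) == 0) abort("no paired deltas")
  if (margin <= 0) abort("margin must be positive")
  boot <- cluster_bootstrap(
    deltas$delta, deltas$patient_id, hodges_lehmann,
    boot_config(n_resamples = n_resamples, alpha = alpha,
                side = "upper_one_sided", seed = seed)
  )
  ub <- boot$ci_high
  decision <- if (ub < 0) "superior" else if (ub <= margin) "non_inferior" else "not_demonstrated"
  structure(
    list(hl_estimate = boot$point_estimate, upper_bound = ub,
         margin = margin, decision = decision,
         n_cases = nrow(deltas),
         n_patients = dplyr::n_distinct(deltas$patient_id),
         alpha = alpha, n_resamples = n_resamples, seed = seed,
         bootstrap = boot),
    class = "noninf_result"
  )
}

#' @export
print.noninf_result <- function(x, ...) {
  cat(sprintf(
    paste0("Paired non-inferiority of TBSA error (n = %d region-cases, %d patients)\n",
           "  Hodges-Lehmann median delta: %.3f pp\n",
           "  one-sided %.0f%% upper bound: %.3f pp (margin %.2g pp)\n",
           "  decision: %s\n"),
    x$n_cases, x$n_patients, x$hl_estimate, 100 * (1 - x$alpha),
    x$upper_bound, x$margin, x$decision
  ))
  invisible(x)
}

#' One-region-per-patient sensitivity analysis
#'
#' Repeats the primary analysis on subsets with one randomly selected
#' region-case per patient (clusters become singletons), and summarises the
#' stability of the conclusion across repeats.
#'
#' @param deltas tibble from [compute_paired_deltas()].
#' @param margin non-inferiority margin (default 3 pp).
#' @param n_repeats number of random selections (default 200).
#' @param n_resamples bootstrap replicates per repeat (default 1000; smaller
#'   than the primary endpoint's 5000 because 200 full-size bootstraps are
#'   run).
#' @param alpha one-sided level.
#' @param seed integer seed.
#' @return list of class `sensitivity_result`: tibble `repeats`
#'   (`repeat_id`, `hl_estimate`, `upper_bound`, `decision`), plus
#'   `max_upper_bound`, `median_upper_bound`, `prop_non_inferior` (fraction
#'   of repeats with upper bound <= margin, counting superior repeats).
#' @export
sensitivity_one_region_per_patient <- function(deltas, margin = 3, n_repeats = 200,
                                               n_resamples = 1000, alpha = 0.05,
                                               seed = NULL) {
  seeds <- derive_seeds(seed, n_repeats + 1)
  pick_seed <- seeds[[n_repeats + 1]]
  by_patient <- split(seq_len(nrow(deltas)), deltas$patient_id)
  picks <- withr::with_seed(pick_seed %||% sample.int(1e6, 1), {
    lapply(seq_len(n_repeats), function(i) {
      vapply(by_patient, function(ix) if (length(ix) == 1) ix else sample(ix, 1), integer(1))
    })
  })
  rows <- lapply(seq_len(n_repeats), function(i) {
    sub <- deltas[picks[[i]], , drop = FALSE]
    res <- primary_analysis(sub, margin = margin, n_resamples = n_resamples,
                            alpha = alpha, seed = seeds[[i]])
    tibble::tibble(repeat_id = i, hl_estimate = res$hl_estimate,
                   upper_bound = res$upper_bound, decision = res$decision)
  })
  repeats <- dplyr::bind_rows(rows)
  structure(
    list(repeats = repeats,
         max_upper_bound = max(repeats$upper_bound),
         median_upper_bound = median(repeats$upper_bound),
         prop_non_inferior = mean(repeats$upper_bound <= margin),
         margin = margin, n_repeats = n_repeats),
    class = "sensitivity_result"
  )
}

#' @export
print.sensitivity_result <- function(x, ...) {
  cat(sprintf(
    paste0("One-region-per-patient sensitivity (%d repeats):\n",
           "  upper bound median %.3f, max %.3f (margin %.2g pp)\n",
           "  non-inferiority upheld in %.1f%% of repeats\n"),
    x$n_repeats, x$median_upper_bound, x$max_upper_bound, x$margin,
    100 * x$prop_non_inferior
  ))
  invisible(x)
}

#' Descriptive subgroup summaries of absolute error
#'
#' Per-stratum (age group and/or anatomical region) mean and median absolute
#' TBSA error for the model and the physician median. Purely descriptive;
#' empty strata are emitted with `n = 0` and `NA` statistics.
#'
#' @param deltas tibble from [compute_paired_deltas()].
#' @param cases the `cases` tibble of the `study_tables` (for stratum labels).
#' @param strata character vector of stratifying columns (default
#'   `c("age_group", "anatomical_region")`).
#' @return tibble, one row per stratum level and method.
#' @export
subgroup_analysis <- function(deltas, cases,
                              strata = c("age_group", "anatomical_region")) {
  stopifnot(all(strata %in% names(cases)))
  joined <- dplyr::left_join(
    deltas, cases[c("region_case_id", strata)], by = "region_case_id")
  out <- lapply(strata, function(s) {
    joined |>
      dplyr::group_by(stratum_value = .data[[s]]) |>
      dplyr::summarise(
        n = dplyr::n(),
        model_mean_abs_error = mean(.data$model_abs_error),
        model_median_abs_error = median(.data$model_abs_error),
        physician_mean_abs_error = mean(.data$physician_abs_error),
        physician_median_abs_error = median(.data$physician_abs_error),
        .groups = "drop"
      ) |>
      dplyr::mutate(stratum = s, .before = 1)
  })
  dplyr::bind_rows(out)
}

#' Threshold-based clinical discrimination
#'
#' Whole-body clinical cut-points (adults >= `adult_threshold`% TBSA,
#' pediatrics >= `pediatric_threshold`%) are applied at the patient level by
#' summing each patient's region-level TBSA per method; the panel sum
#' defines the binary truth. Because the threshold differs by age group,
#' scores are shifted by the patient-specific threshold before the ROC
#' (decision rule: score >= threshold, i.e. shifted score >= 0). Region-level
#' evaluation (each region against its own threshold) is selectable.
#'
#' If either class is absent (e.g. no patient above threshold),
#' discrimination is undefined: the result carries `undefined = TRUE` with
#' class-count diagnostics instead of statistics.
#'
#' @param tables a `study_tables` object.
#' @param panel,physicians consensus tibbles (see [consensus_table()]).
#' @param adult_threshold,pediatric_threshold cut-points in %TBSA
#'   (defaults 20 and 10).
#' @param level `"patient"` (default; sums regions within patient) or
#'   `"region"`.
#' @param case_ids analysis-set ids (default FAS).
#' @return list of class `discrimination_result`: `undefined`, class counts,
#'   and when defined the [roc_auc_delong()] output for model vs
#'   physician-median plus the per-unit score table.
#' @export
threshold_discrimination <- function(tables, panel = consensus_table(tables, "panel"),
                                     physicians = consensus_table(tables, "physician"),
                                     adult_threshold = 20, pediatric_threshold = 10,
                                     level = c("patient", "region"),
                                     case_ids = NULL) {
  level <- match.arg(level)
  deltas <- compute_paired_deltas(tables, panel, physicians, case_ids = case_ids)
  scored <- dplyr::left_join(
    deltas, tables$cases[c("region_case_id", "age_group")], by = "region_case_id")
  if (level == "patient") {
    scored <- scored |>
      dplyr::group_by(.data$patient_id) |>
      dplyr::summarise(
        model = sum(.data$model_tbsa),
        physician = sum(.data$physician_tbsa),
        panel = sum(.data$panel_tbsa),
        age_group = .data$age_group[1],
        .groups = "drop"
      )
  } else {
    scored <- scored |>
      dplyr::transmute(unit_id = .data$region_case_id,
                       model = .data$model_tbsa,
                       physician = .data$physician_tbsa,
                       panel = .data$panel_tbsa,
                       age_group = .data$age_group)
  }
  thr <- ifelse(scored$age_group == "adult", adult_threshold, pediatric_threshold)
  labels <- scored$panel >= thr
  counts <- c(positive = sum(labels), negative = sum(!labels))
  if (counts["positive"] == 0 || counts["negative"] == 0) {
    return(structure(
      list(undefined = TRUE, class_counts = counts, level = level,
           message = "discrimination undefined: a threshold class is absent"),
      class = "discrimination_result"))
  }
  roc <- roc_auc_delong(scored$model - thr, scored$physician - thr, labels, threshold = 0)
  structure(
    list(undefined = FALSE, class_counts = counts, level = level,
         model = roc$roc_a, physician = roc$roc_b,
         delong_z = roc$z, delong_p = roc$p_value, scores = scored),
    class = "discrimination_result"
  )
}

#' @export
print.discrimination_result <- function(x, ...) {
  if (x$undefined) {
    cat(sprintf("Threshold discrimination undefined (%d positive, %d negative)\n",
                x$class_counts["positive"], x$class_counts["negative"]))
    return(invisible(x))
  }
  cat(sprintf(
    paste0("Threshold discrimination (%s level; %d positive, %d negative):\n",
           "  model AUC %.3f (sens %.2f, spec %.2f)\n",
           "  physician AUC %.3f (sens %.2f, spec %.2f)\n",
           "  DeLong z = %.3f, p = %.3g\n"),
    x$level, x$class_counts["positive"], x$class_counts["negative"],
    x$model$auc, x$model$sensitivity, x$model$specificity,
    x$physician$auc, x$physician$sensitivity, x$physician$specificity,
    x$delong_z, x$delong_p
  ))
  invisible(x)
}

#' Image-quality sensitivity analysis
#'
#' Spearman correlation between the physician-rated image-quality score and
#' each method's absolute TBSA error, plus a re-run of the error summaries
#' excluding region-cases below the quality cutoff. Cases with missing
#' quality are excluded pairwise.
#'
#' @param deltas tibble from [compute_paired_deltas()].
#' @param cases the `cases` tibble (for `image_quality`).
#' @param quality_cutoff cases with `image_quality < quality_cutoff` are
#'   dropped in the filtered re-run (default 8).
#' @return list of class `quality_sensitivity`: `rho` (tibble with a row per
#'   method), `filtered_summary` (tibble of [abs_error_summary()] rows on
#'   the quality-filtered subset), `n_excluded`.
#' @export
image_quality_sensitivity <- function(deltas, cases, quality_cutoff = 8) {
  joined <- dplyr::left_join(
    deltas, cases[c("region_case_id", "image_quality")], by = "region_case_id") |>
    dplyr::filter(!is.na(.data$image_quality))
  if (nrow(joined) < 3) abort("need quality scores for >= 3 cases")
  rho <- tibble::tibble(
    method = c("model", "physician"),
    spearman_rho = c(
      suppressWarnings(spearman_rho(joined$image_quality, joined$model_abs_error)),
      suppressWarnings(spearman_rho(joined$image_quality, joined$physician_abs_error))
    )
  )
  keep <- joined$image_quality >= quality_cutoff
  filtered <- dplyr::bind_rows(
    dplyr::mutate(abs_error_summary(joined$model_tbsa[keep], joined$panel_tbsa[keep]),
                  method = "model", .before = 1),
    dplyr::mutate(abs_error_summary(joined$physician_tbsa[keep], joined$panel_tbsa[keep]),
                  method = "physician", .before = 1)
  )
  structure(
    list(rho = rho, filtered_summary = filtered,
         n_excluded = sum(!keep), quality_cutoff = quality_cutoff),
    class = "quality_sensitivity"
  )
}
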