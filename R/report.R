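#' TBSA accuracy and agreement report (Table 2 analogue)
#'
#' One row per comparison (model vs panel, physician median vs panel):
#' mean/median absolute error, inclusive 3 pp and 5 pp tolerance-band
#' proportions, Lin's CCC, Bland-Altman bias and 95% limits of agreement.
#' Cluster-bootstrap CIs for CCC are added when `ccc_ci = TRUE`.
#'
#' @param deltas tibble from [compute_paired_deltas()].
#' @param ccc_ci logical: add patient-level cluster-bootstrap CIs for CCC.
#' @param boot a [boot_config()] for the CCC intervals (study design:
#'   2000 replicates).
#' @return tibble with one row per method.
#' @export
tbsa_agreement_report <- function(deltas, ccc_ci = FALSE,
                                  boot = boot_config(n_resamples = 2000)) {
  one <- function(method, est, ref) {
    s <- abs_error_summary(est, ref)
    ba <- bland_altman(est, ref)
    out <- tibble::tibble(
      method = method,
      n = s$n,
      mean_abs_error = s$mean_abs_error,
      median_abs_error = s$median_abs_error,
      within_3pp = s$within_3pp,
      within_5pp = s$within_5pp,
      ccc = lin_ccc(est, ref),
      bias = ba$bias,
      loa_low = ba$loa_low,
      loa_high = ba$loa_high
    )
    if (ccc_ci) {
      col <- paste0(method, "_tbsa")
      b <- cluster_bootstrap_ci_for_metric(
        deltas, function(d) lin_ccc(d[[col]], d$panel_tbsa), boot)
      out$ccc_ci_low <- b$ci_low
      out$ccc_ci_high <- b$ci_high
    }
    out
  }
  dplyr::bind_rows(
    one("model", deltas$model_tbsa, deltas$panel_tbsa),
    one("physician", deltas$physician_tbsa, deltas$panel_tbsa)
  )
}

#' Burn-depth distribution and agreement report (Table 3 analogue)
#'
#' Depth class distributions for the panel, the model and the physician
#' consensus, plus exact agreement and quadratically weighted kappa of the
#' model and the physician consensus against the panel.
#'
#' @param tables a `study_tables` object.
#' @param panel,physicians consensus tibbles (see [consensus_table()]).
#' @param case_ids analysis-set ids (default FAS).
#' @param kappa_ci logical: add patient-level cluster-bootstrap CIs for the
#'   weighted kappas.
#' @param boot a [boot_config()] for the kappa intervals.
#' @return list of class `depth_report`: `distribution` (tibble of class
#'   counts per source), `agreement` (tibble per comparator:
#'   `exact_agreement`, `kappa_w`, optional CI), and the two confusion
#'   matrices (`model_vs_panel`, `physician_vs_panel`).
#' @export
depth_agreement_report <- function(tables, panel = consensus_table(tables, "panel"),
                                   physicians = consensus_table(tables, "physician"),
                                   case_ids = NULL, kappa_ci = FALSE,
                                   boot = boot_config(n_resamples = 2000)) {
  stopifnot(inherits(tables, "study_tables"))
  if (is.null(case_ids)) case_ids <- build_analysis_sets(tables)$full_analysis

  model <- tables$ratings[tables$ratings$rater_kind == "model", ]
  depth <- tibble::tibble(region_case_id = case_ids) |>
    dplyr::left_join(tables$cases[c("region_case_id", "patient_id")], by = "region_case_id") |>
    dplyr::left_join(dplyr::select(model, "region_case_id", model_depth = "depth_ord"),
                     by = "region_case_id") |>
    dplyr::left_join(dplyr::select(panel, "region_case_id", panel_depth = "consensus_depth"),
                     by = "region_case_id") |>
    dplyr::left_join(dplyr::select(physicians, "region_case_id", physician_depth = "consensus_depth"),
                     by = "region_case_id")
  if (anyNA(depth[c("model_depth", "panel_depth", "physician_depth")])) {
    abort("missing depth class for an included case")
  }

  dist_of <- function(v, source) {
    tibble::tibble(
      source = source,
      depth_class = DEPTH_LEVELS,
      n = tabulate(v, 3),
      prop = tabulate(v, 3) / length(v)
    )
  }
  distribution <- dplyr::bind_rows(
    dist_of(depth$panel_depth, "panel"),
    dist_of(depth$model_depth, "model"),
    dist_of(depth$physician_depth, "physician_consensus")
  )

  cm_model <- confusion_matrix3(depth$panel_depth, depth$model_depth)
  cm_phys <- confusion_matrix3(depth$panel_depth, depth$physician_depth)
  agreement <- tibble::tibble(
    comparator = c("model", "physician_consensus"),
    exact_agreement = c(exact_agreement(cm_model), exact_agreement(cm_phys)),
    kappa_w = c(weighted_kappa(cm_model), weighted_kappa(cm_phys))
  )
  if (kappa_ci) {
    ci <- lapply(c("model_depth", "physician_depth"), function(col) {
      b <- cluster_bootstrap_ci_for_metric(depth, function(d) {
        weighted_kappa(confusion_matrix3(d$panel_depth, d[[col]]))
      }, boot)
      c(b$ci_low, b$ci_high)
    })
    agreement$kappa_ci_low <- c(ci[[1]][1], ci[[2]][1])
    agreement$kappa_ci_high <- c(ci[[1]][2], ci[[2]][2])
  }
  structure(
    list(distribution = distribution, agreement = agreement,
         model_vs_panel = cm_model, physician_vs_panel = cm_phys,
         depth_table = depth),
    class = "depth_report"
  )
}

#' Cohort characteristics (Table 1 analogue)
#'
#' @param tables a `study_tables` object.
#' @param panel panel consensus tibble (for the depth distribution).
#' @return tibble of characteristic / value rows.
#' @export
cohort_characteristics <- function(tables, panel = consensus_table(tables, "panel")) {
  cases <- tables$cases
  n <- nrow(cases)
  row <- function(char, value) tibble::tibble(characteristic = char, value = value)
  q <- cases$image_quality[!is.na(cases$image_quality)]
  depth_counts <- tabulate(panel$consensus_depth, 3)
  dplyr::bind_rows(
    row("n_region_cases", n),
    row("n_patients", dplyr::n_distinct(cases$patient_id)),
    row("n_pediatric", sum(cases$age_group == "pediatric")),
    row("n_adult", sum(cases$age_group == "adult")),
    row("age_median", median(cases$age_years)),
    row("image_quality_median", if (length(q)) median(q) else NA_real_),
    dplyr::bind_rows(lapply(REGIONS, function(rg) {
      row(paste0("region_", rg), sum(cases$anatomical_region == rg))
    })),
    dplyr::bind_rows(lapply(1:3, function(d) {
      row(paste0("panel_depth_", DEPTH_LEVELS[d]), depth_counts[d])
    }))
  )
}

#' Run the full study analysis
#'
#' Orchestrates the pipeline end to end: validation, analysis sets, panel
#' and physician consensus, TBSA and depth agreement reports, calibration,
#' the primary non-inferiority analysis, the one-region-per-patient
#' sensitivity analysis, subgroup summaries, threshold discrimination, and
#' the image-quality sensitivity analysis. With `out_dir` set, report files
#' are written via [write_report_tables()]. Deterministic given `seed`.
#'
#' @param tables a `study_tables` object (from [read_study()] or
#'   [simulate_study()]).
#' @param margin non-inferiority margin Δ* (default: `tables$margin_pp`).
#' @param n_resamples primary-endpoint bootstrap replicates (default 5000).
#' @param agreement_resamples replicates for agreement-metric CIs
#'   (default 2000).
#' @param sensitivity_repeats repeats of the one-region-per-patient
#'   analysis (default 200; each uses 1000 bootstrap replicates).
#' @param adult_threshold,pediatric_threshold clinical TBSA cut-points.
#' @param quality_cutoff image-quality cutoff for the filtered re-run.
#' @param seed integer seed governing all resampling.
#' @param out_dir optional output directory for report files.
#' @return object of class `burn_study_report` (a named list of all stage
#'   results); supports [glance()].
#' @export
run_study <- function(tables, margin = NULL, n_resamples = 5000,
                      agreement_resamples = 2000, sensitivity_repeats = 200,
                      adult_threshold = 20, pediatric_threshold = 10,
                      quality_cutoff = 8, seed = NULL, out_dir = NULL) {
  stopifnot(inherits(tables, "study_tables"))
  margin <- margin %||% tables$margin_pp
  seeds <- derive_seeds(seed, 4)

  sets <- build_analysis_sets(tables)
  panel <- consensus_table(tables, "panel")
  physicians <- consensus_table(tables, "physician")
  panel_agreement <- preconsensus_agreement(tables, "panelist")
  physician_icc <- tryCatch(
    preconsensus_agreement(tables, "physician"),
    error = function(e) NULL)

  deltas <- compute_paired_deltas(tables, panel, physicians,
                                  case_ids = sets$full_analysis)
  tbsa_report <- tbsa_agreement_report(
    deltas, ccc_ci = TRUE,
    boot = boot_config(n_resamples = agreement_resamples, seed = seeds[[2]]))
  depth_report <- depth_agreement_report(
    tables, panel, physicians, case_ids = sets$full_analysis, kappa_ci = TRUE,
    boot = boot_config(n_resamples = agreement_resamples, seed = seeds[[2]]))
  calibration <- list(
    model = calibration_fit(deltas$model_tbsa, deltas$panel_tbsa),
    physician = calibration_fit(deltas$physician_tbsa, deltas$panel_tbsa)
  )
  primary <- primary_analysis(deltas, margin = margin,
                              n_resamples = n_resamples, seed = seeds[[1]])
  sensitivity <- sensitivity_one_region_per_patient(
    deltas, margin = margin, n_repeats = sensitivity_repeats, seed = seeds[[3]])
  subgroups <- subgroup_analysis(deltas, tables$cases)
  discrimination <- threshold_discrimination(
    tables, panel, physicians,
    adult_threshold = adult_threshold, pediatric_threshold = pediatric_threshold,
    case_ids = sets$full_analysis)
  quality <- image_quality_sensitivity(deltas, tables$cases,
                                       quality_cutoff = quality_cutoff)

  report <- structure(
    list(tables = tables, analysis_sets = sets,
         panel = panel, physicians = physicians,
         panel_agreement = panel_agreement, physician_icc = physician_icc,
         deltas = deltas, tbsa_report = tbsa_report, depth_report = depth_report,
         calibration = calibration, primary = primary, sensitivity = sensitivity,
         subgroups = subgroups, discrimination = discrimination, quality = quality,
         config = list(margin = margin, n_resamples = n_resamples,
                       agreement_resamples = agreement_resamples,
                       sensitivity_repeats = sensitivity_repeats,
                       adult_threshold = adult_threshold,
                       pediatric_threshold = pediatric_threshold,
                       quality_cutoff = quality_cutoff, seed = seed)),
    class = "burn_study_report"
  )
  if (!is.null(out_dir)) write_report_tables(report, out_dir)
  report
}

#' @export
print.burn_study_report <- function(x, ...) {
  cat("== Burn assessment study report ==\n")
  print(x$tables)
  print(x$analysis_sets)
  print(x$primary)
  cat(sprintf("  model vs panel: MAE %.2f pp, CCC %.3f, kappa_w %.3f\n",
              x$tbsa_report$mean_abs_error[1], x$tbsa_report$ccc[1],
              x$depth_report$agreement$kappa_w[1]))
  cat(sprintf("  physician vs panel: MAE %.2f pp, CCC %.3f, kappa_w %.3f\n",
              x$tbsa_report$mean_abs_error[2], x$tbsa_report$ccc[2],
              x$depth_report$agreement$kappa_w[2]))
  invisible(x)
}

fmt_num <- function(x, digits = 3) {
  ifelse(is.na(x), "", formatC(x, digits = digits, format = "f"))
}

#' Write the report tables to CSV
#'
#' Writes deterministic-byte CSV analogues of the study's tables plus the
#' primary result and bootstrap replicates:
#' `table1_analogue.csv` (cohort characteristics), `table2_analogue.csv`
#' (TBSA accuracy/agreement), `table3_analogue.csv` (depth distribution and
#' agreement), `subgroups.csv`, `primary_result.json`,
#' `replicates/primary_replicates.csv` and `run_log.txt`. Numbers are
#' formatted to 1-3 decimals; reruns with the same seed and configuration
#' produce byte-identical files.
#'
#' @param report a `burn_study_report`.
#' @param out_dir output directory (created if needed).
#' @return invisibly, the written file paths.
#' @export
write_report_tables <- function(report, out_dir) {
  stopifnot(inherits(report, "burn_study_report"))
  dir.create(file.path(out_dir, "replicates"), showWarnings = FALSE, recursive = TRUE)

  t1 <- cohort_characteristics(report$tables, report$panel)
  t1$value <- fmt_num(t1$value, 1)
  p1 <- file.path(out_dir, "table1_analogue.csv")
  readr::write_csv(t1, p1)

  t2 <- report$tbsa_report
  num <- vapply(t2, is.numeric, logical(1)) & names(t2) != "n"
  t2[num] <- lapply(t2[num], fmt_num, digits = 3)
  p2 <- file.path(out_dir, "table2_analogue.csv")
  readr::write_csv(t2, p2)

  dist <- report$depth_report$distribution
  dist$prop <- fmt_num(dist$prop, 3)
  agr <- report$depth_report$agreement
  numa <- vapply(agr, is.numeric, logical(1))
  agr[numa] <- lapply(agr[numa], fmt_num, digits = 3)
  t3 <- dplyr::bind_rows(
    dplyr::mutate(dist, block = "distribution", .before = 1),
    tibble::tibble(block = "agreement", source = agr$comparator,
                   depth_class = NA_character_, n = NA_integer_, prop = NA_character_) |>
      dplyr::bind_cols(agr[setdiff(names(agr), "comparator")])
  )
  p3 <- file.path(out_dir, "table3_analogue.csv")
  readr::write_csv(t3, p3)

  sg <- report$subgroups
  nums <- vapply(sg, is.numeric, logical(1)) & names(sg) != "n"
  sg[nums] <- lapply(sg[nums], fmt_num, digits = 3)
  p4 <- file.path(out_dir, "subgroups.csv")
  readr::write_csv(sg, p4)

  pr <- report$primary
  p5 <- file.path(out_dir, "primary_result.json")
  jsonlite::write_json(
    list(hl_estimate = pr$hl_estimate, upper_bound = pr$upper_bound,
         margin = pr$margin, decision = pr$decision,
         n_cases = pr$n_cases, n_patients = pr$n_patients,
         n_resamples = pr$n_resamples, alpha = pr$alpha),
    p5, auto_unbox = TRUE, digits = NA, pretty = TRUE)

  p6 <- file.path(out_dir, "replicates", "primary_replicates.csv")
  readr::write_csv(tibble::tibble(replicate = seq_along(pr$bootstrap$replicates),
                                  hl = pr$bootstrap$replicates), p6)

  p7 <- file.path(out_dir, "run_log.txt")
  cfg <- report$config
  writeLines(c(
    "burnagree run log",
    sprintf("region-cases (FAS/PP): %d/%d", length(report$analysis_sets$full_analysis),
            length(report$analysis_sets$per_protocol)),
    sprintf("exclusions logged: %d", nrow(report$analysis_sets$exclusion_log)),
    sprintf("margin: %g pp; bootstrap B = %d (primary), %d (agreement)",
            cfg$margin, cfg$n_resamples, cfg$agreement_resamples),
    sprintf("seed: %s", if (is.null(cfg$seed)) "none" else cfg$seed),
    sprintf("decision: %s", report$primary$decision)
  ), p7)

  invisible(c(p1, p2, p3, p4, p5, p6, p7))
}

#' @export
glance.burn_study_report <- function(x, ...) {
  tibble::tibble(
    n_cases = x$primary$n_cases,
    n_patients = x$primary$n_patients,
    hl_estimate = x$primary$hl_estimate,
    upper_bound = x$primary$upper_bound,
    margin = x$primary$margin,
    decision = x$primary$decision,
    model_mae = x$tbsa_report$mean_abs_error[1],
    physician_mae = x$tbsa_report$mean_abs_error[2],
    model_ccc = x$tbsa_report$ccc[1],
    physician_ccc = x$tbsa_report$ccc[2],
    model_kappa_w = x$depth_report$agreement$kappa_w[1],
    physician_kappa_w = x$depth_report$agreement$kappa_w[2]
  )
}
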