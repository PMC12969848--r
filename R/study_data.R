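#' Construct and validate the study tables
#'
#' Bundles the region-case metadata and the long-format ratings table into a
#' validated `study_tables` object, the input to every downstream stage.
#'
#' Validation enforces referential integrity (every rating refers to a known
#' region-case), uniqueness of `region_case_id` and of
#' `(region_case_id, rater_id)` pairs, exactly one model rating per
#' region-case, and the controlled vocabularies for sex, anatomical region,
#' rater kind and depth class. TBSA values outside \[0, 100\] are never used
#' silently: they are retained with `entry_error = TRUE` and excluded from
#' all computations.
#'
#' @param cases data frame with columns `region_case_id`, `patient_id`,
#'   `age_years`, `sex` (`male`/`female`), `anatomical_region`
#'   (`face_head`, `torso`, `upper_extremity`, `lower_extremity`),
#'   `image_quality` (integer 1–10 or `NA`).
#' @param ratings data frame with columns `region_case_id`, `rater_id`,
#'   `rater_kind` (`model`/`physician`/`panelist`), `tbsa_percent`,
#'   `depth_class` (ontology labels or `non_assessable`).
#' @param margin_pp non-inferiority margin Δ* in percentage points
#'   (default 3, the prespecified clinical margin).
#' @return an object of class `study_tables`: list with tibbles `cases`
#'   (gains derived column `age_group`) and `ratings` (gains `depth_ord`,
#'   the integer depth code, and `entry_error`), plus `margin_pp`.
#' @export
study_tables <- function(cases, ratings, margin_pp = 3) {
  if (!is.numeric(margin_pp) || length(margin_pp) != 1 || margin_pp <= 0) {
    abort("margin_pp must be a positive scalar")
  }
  cases <- tibble::as_tibble(cases)
  ratings <- tibble::as_tibble(ratings)

  need_cases <- c("region_case_id", "patient_id", "age_years", "sex",
                  "anatomical_region", "image_quality")
  need_ratings <- c("region_case_id", "rater_id", "rater_kind",
                    "tbsa_percent", "depth_class")
  miss <- setdiff(need_cases, names(cases))
  if (length(miss)) abort(paste0("cases is missing columns: ", paste(miss, collapse = ", ")))
  miss <- setdiff(need_ratings, names(ratings))
  if (length(miss)) abort(paste0("ratings is missing columns: ", paste(miss, collapse = ", ")))

  dup <- cases$region_case_id[duplicated(cases$region_case_id)]
  if (length(dup)) abort(paste0("duplicate region_case_id in cases: ", paste(unique(dup), collapse = ", ")))
  if (any(is.na(cases$age_years) | cases$age_years < 0)) {
    abort(report_rows("cases", which(is.na(cases$age_years) | cases$age_years < 0), "age_years must be non-negative"))
  }
  bad <- !cases$sex %in% c("male", "female")
  if (any(bad)) abort(report_rows("cases", which(bad), "sex must be 'male' or 'female'"))
  bad <- !cases$anatomical_region %in% REGIONS
  if (any(bad)) abort(report_rows("cases", which(bad), paste0("anatomical_region must be one of ", paste(REGIONS, collapse = ", "))))
  bad <- !is.na(cases$image_quality) &
    (cases$image_quality < 1 | cases$image_quality > 10 | cases$image_quality != round(cases$image_quality))
  if (any(bad)) abort(report_rows("cases", which(bad), "image_quality must be an integer in [1,10] or NA"))

  bad <- !ratings$rater_kind %in% RATER_KINDS
  if (any(bad)) abort(report_rows("ratings", which(bad), paste0("rater_kind must be one of ", paste(RATER_KINDS, collapse = ", "))))
  unknown <- setdiff(ratings$region_case_id, cases$region_case_id)
  if (length(unknown)) {
    abort(paste0("ratings reference unknown region_case_id: ", paste(unknown, collapse = ", ")))
  }
  key <- paste(ratings$region_case_id, ratings$rater_id, sep = "\r")
  if (anyDuplicated(key)) {
    d <- ratings[duplicated(key), c("region_case_id", "rater_id")]
    abort(paste0("duplicate (region_case_id, rater_id): ",
                 paste(paste(d$region_case_id, d$rater_id, sep = "/"), collapse = ", ")))
  }
  n_model <- table(ratings$region_case_id[ratings$rater_kind == "model"])
  if (any(n_model > 1)) {
    abort(paste0("more than one model rating for region_case_id: ",
                 paste(names(n_model)[n_model > 1], collapse = ", ")))
  }

  cases$age_group <- ifelse(cases$age_years < 18, "pediatric", "adult")
  ratings$depth_ord <- depth_code(ratings$depth_class)  # errors on unknown labels
  ratings$entry_error <- !is.na(ratings$tbsa_percent) &
    (ratings$tbsa_percent < 0 | ratings$tbsa_percent > 100)
  if (any(ratings$entry_error)) {
    warn(paste0(
      sum(ratings$entry_error), " TBSA value(s) outside [0,100] flagged as entry errors ",
      "(rows ", paste(which(ratings$entry_error), collapse = ", "),
      "); they are retained with entry_error = TRUE and excluded from all computations"
    ))
  }

  structure(
    list(cases = cases, ratings = ratings, margin_pp = margin_pp),
    class = "study_tables"
  )
}

report_rows <- function(tbl, rows, msg) {
  sprintf("%s row(s) %s: %s", tbl, paste(rows, collapse = ", "), msg)
}

#' @export
print.study_tables <- function(x, ...) {
  cat(sprintf(
    "Study tables: %d region-cases in %d patients; %d ratings (%d model, %d physician, %d panelist); margin %g pp\n",
    nrow(x$cases), dplyr::n_distinct(x$cases$patient_id), nrow(x$ratings),
    sum(x$ratings$rater_kind == "model"),
    sum(x$ratings$rater_kind == "physician"),
    sum(x$ratings$rater_kind == "panelist"),
    x$margin_pp
  ))
  invisible(x)
}

#' Read a study from CSV files
#'
#' Reads the region-case metadata and long-format ratings CSVs (one rating
#' per row) and validates them via [study_tables()]. Malformed rows are
#' reported with their line numbers; TBSA values outside \[0, 100\] are
#' retained with an entry-error flag, not dropped silently.
#'
#' @param cases_path path to `cases.csv` (columns
#'   `region_case_id,patient_id,age_years,sex,anatomical_region,image_quality`).
#' @param ratings_path path to `ratings.csv` (columns
#'   `region_case_id,rater_id,rater_kind,tbsa_percent,depth_class`).
#' @param margin_pp non-inferiority margin in percentage points (default 3).
#' @return a validated `study_tables` object.
#' @export
read_study <- function(cases_path, ratings_path, margin_pp = 3) {
  for (p in c(cases_path, ratings_path)) {
    if (!file.exists(p)) abort(paste0("file not found: ", p))
  }
  cases <- readr::read_csv(
    cases_path,
    col_types = readr::cols(
      region_case_id = readr::col_character(),
      patient_id = readr::col_character(),
      age_years = readr::col_double(),
      sex = readr::col_character(),
      anatomical_region = readr::col_character(),
      image_quality = readr::col_double()
    )
  )
  ratings <- readr::read_csv(
    ratings_path,
    col_types = readr::cols(
      region_case_id = readr::col_character(),
      rater_id = readr::col_character(),
      rater_kind = readr::col_character(),
      tbsa_percent = readr::col_double(),
      depth_class = readr::col_character()
    )
  )
  for (tb in list(cases, ratings)) {
    pr <- readr::problems(tb)
    if (nrow(pr) > 0) {
      abort(paste0(
        "malformed CSV rows (line numbers): ",
        paste(unique(pr$row), collapse = ", ")
      ))
    }
  }
  study_tables(cases, ratings, margin_pp = margin_pp)
}

#' Write study tables back to CSV
#'
#' Inverse of [read_study()]: writes `cases.csv` and `ratings.csv` in the
#' documented schema (derived columns are dropped). Lossless for all
#' non-flagged fields.
#'
#' @param tables a `study_tables` object.
#' @param dir output directory (created if needed).
#' @return invisibly, the two file paths.
#' @export
write_study <- function(tables, dir) {
  stopifnot(inherits(tables, "study_tables"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cp <- file.path(dir, "cases.csv")
  rp <- file.path(dir, "ratings.csv")
  readr::write_csv(
    tables$cases[c("region_case_id", "patient_id", "age_years", "sex",
                   "anatomical_region", "image_quality")], cp)
  readr::write_csv(
    tables$ratings[c("region_case_id", "rater_id", "rater_kind",
                     "tbsa_percent", "depth_class")], rp)
  invisible(c(cases = cp, ratings = rp))
}

# A rating is usable when its TBSA is present and not an entry error.
usable <- function(ratings) {
  !is.na(ratings$tbsa_percent) & !ratings$entry_error
}

#' Build the Full Analysis and Per-Protocol sets
#'
#' The Full Analysis Set (FAS) contains region-cases with a usable model
#' rating (TBSA in range and an assessable depth class), at least one usable
#' physician rating, and at least one assessable panelist rating. The
#' Per-Protocol (PP) set additionally excludes region-cases rated
#' non-assessable by two or more panelists. Every excluded case is logged
#' with a reason code; cases excluded from FAS are by construction excluded
#' from PP as well (PP is a subset of FAS).
#'
#' @param tables a `study_tables` object.
#' @return an object of class `analysis_sets`: list with character vectors
#'   `full_analysis` and `per_protocol` (sorted region-case ids) and tibble
#'   `exclusion_log` (`region_case_id`, `set_kind`, `reason`).
#' @export
build_analysis_sets <- function(tables) {
  stopifnot(inherits(tables, "study_tables"))
  r <- tables$ratings
  ids <- sort(tables$cases$region_case_id)

  model_ok <- vapply(ids, function(id) {
    m <- r[r$region_case_id == id & r$rater_kind == "model", ]
    nrow(m) == 1 && usable(m) && !is.na(m$depth_ord)
  }, logical(1))
  phys_ok <- vapply(ids, function(id) {
    p <- r[r$region_case_id == id & r$rater_kind == "physician", ]
    nrow(p) >= 1 && any(usable(p))
  }, logical(1))
  panel_assessable <- vapply(ids, function(id) {
    p <- r[r$region_case_id == id & r$rater_kind == "panelist", ]
    sum(usable(p) & !is.na(p$depth_ord))
  }, integer(1))
  panel_na_count <- vapply(ids, function(id) {
    p <- r[r$region_case_id == id & r$rater_kind == "panelist", ]
    sum(p$depth_class == NON_ASSESSABLE, na.rm = TRUE)
  }, integer(1))

  log <- list()
  add <- function(id, set_kind, reason) {
    log[[length(log) + 1L]] <<- tibble::tibble(
      region_case_id = id, set_kind = set_kind, reason = reason)
  }
  fas <- character()
  pp <- character()
  for (i in seq_along(ids)) {
    id <- ids[i]
    if (!model_ok[i]) { add(id, "full_analysis", "missing_or_invalid_model_rating"); next }
    if (!phys_ok[i]) { add(id, "full_analysis", "missing_physician_rating"); next }
    if (panel_assessable[i] < 1) { add(id, "full_analysis", "missing_panel_rating"); next }
    fas <- c(fas, id)
    if (panel_na_count[i] >= 2) { add(id, "per_protocol", "panel_non_assessable_ge2"); next }
    pp <- c(pp, id)
  }
  exclusion_log <- if (length(log)) dplyr::bind_rows(log) else {
    tibble::tibble(region_case_id = character(), set_kind = character(), reason = character())
  }
  structure(
    list(full_analysis = fas, per_protocol = pp, exclusion_log = exclusion_log),
    class = "analysis_sets"
  )
}

#' @export
print.analysis_sets <- function(x, ...) {
  cat(sprintf(
    "Analysis sets: %d region-cases in FAS, %d in PP; %d exclusion(s) logged\n",
    length(x$full_analysis), length(x$per_protocol), nrow(x$exclusion_log)
  ))
  invisible(x)
}
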