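# Hand-built fixtures used across tests; constructed in code, no files.

# Minimal valid study: 2 region-cases on 2 patients, one rater of each kind.
tiny_cases <- function() {
  tibble::tibble(
    region_case_id = c("C1", "C2"),
    patient_id = c("PA", "PB"),
    age_years = c(5, 30),
    sex = c("male", "female"),
    anatomical_region = c("torso", "upper_extremity"),
    image_quality = c(9L, 8L)
  )
}

tiny_ratings <- function() {
  tibble::tibble(
    region_case_id = rep(c("C1", "C2"), each = 3),
    rater_id = rep(c("model_1", "phys_01", "panel_1"), 2),
    rater_kind = rep(c("model", "physician", "panelist"), 2),
    tbsa_percent = c(4, 5, 5, 2, 2.5, 2),
    depth_class = rep("superficial_partial", 6)
  )
}

tiny_study <- function() study_tables(tiny_cases(), tiny_ratings())

# Study with 3 panelists and 2 physicians; panel non-assessability
# configurable per case for analysis-set tests.
panel_study <- function(non_assessable = list()) {
  cases <- tibble::tibble(
    region_case_id = c("C1", "C2", "C3"),
    patient_id = c("PA", "PA", "PB"),
    age_years = c(40, 40, 8),
    sex = c("male", "male", "female"),
    anatomical_region = c("torso", "face_head", "lower_extremity"),
    image_quality = c(9L, 9L, NA)
  )
  grid <- expand.grid(
    region_case_id = cases$region_case_id,
    rater_id = c("model_1", "phys_01", "phys_02", "panel_1", "panel_2", "panel_3"),
    stringsAsFactors = FALSE
  )
  grid$rater_kind <- c("model", "physician", "physician",
                       "panelist", "panelist", "panelist")[
    match(grid$rater_id,
          c("model_1", "phys_01", "phys_02", "panel_1", "panel_2", "panel_3"))]
  grid$tbsa_percent <- 3 + seq_len(nrow(grid)) %% 3
  grid$depth_class <- "superficial_partial"
  for (id in names(non_assessable)) {
    which_panel <- paste0("panel_", seq_len(non_assessable[[id]]))
    sel <- grid$region_case_id == id & grid$rater_id %in% which_panel
    grid$depth_class[sel] <- "non_assessable"
    grid$tbsa_percent[sel] <- NA
  }
  study_tables(cases, tibble::as_tibble(grid))
}

# Deltas table built directly (for primary-analysis unit tests).
make_deltas <- function(delta, patient_id = NULL) {
  n <- length(delta)
  tibble::tibble(
    region_case_id = sprintf("C%02d", seq_len(n)),
    patient_id = patient_id %||% sprintf("P%02d", seq_len(n)),
    model_tbsa = 0, physician_tbsa = 0, panel_tbsa = 0,
    model_abs_error = pmax(delta, 0),
    physician_abs_error = pmax(-delta, 0),
    delta = delta
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

random_confusion3 <- function() {
  m <- matrix(sample(0:9, 9, replace = TRUE), 3, 3)
  if (sum(m) == 0) m[1, 1] <- 1L
  m
}
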