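#' Cohort configuration for the synthetic study generator
#'
#' Defines the marginal structure of a simulated single-centre ED burn
#' cohort: number of patients, the distribution of region-cases per patient
#' (regions of one patient share age and sex, inducing patient-level
#' clustering), the pediatric share, anatomical-site and true-depth
#' prevalences, and the true regional TBSA distribution.
#'
#' Defaults reproduce the marginal structure of a 52-patient cohort with 64
#' region-cases (43/6/3 patients contributing 1/2/3 regions), a region-level
#' pediatric share of 35/64, site mix 7/6/21/30 over face-head / torso /
#' upper / lower extremity, and depth prevalence 47/16/1 over SP/DP/FT.
#' True regional TBSA follows a right-skewed scaled Beta on (0, 15\] pp
#' (small regions dominate); this family is a modelling choice, not an
#' estimate from any dataset.
#'
#' @param n_patients number of patients (default 52).
#' @param regions_per_patient_probs probability vector over 1, 2, 3 regions.
#' @param pediatric_fraction probability a patient is pediatric (< 18 y).
#' @param region_site_probs probability vector over the four anatomical sites.
#' @param depth_probs probability vector over true depth SP, DP, FT.
#' @param tbsa_shape1,tbsa_shape2,tbsa_max true TBSA is
#'   `tbsa_max * Beta(tbsa_shape1, tbsa_shape2)`.
#' @return a list of class `cohort_config`.
#' @export
cohort_config <- function(n_patients = 52,
                          regions_per_patient_probs = c(43, 6, 3) / 52,
                          pediatric_fraction = 35 / 64,
                          region_site_probs = c(7, 6, 21, 30) / 64,
                          depth_probs = c(47, 16, 1) / 64,
                          tbsa_shape1 = 1.5, tbsa_shape2 = 5, tbsa_max = 15) {
  stopifnot(n_patients >= 1)
  check_probs(regions_per_patient_probs, 3, "regions_per_patient_probs")
  check_probs(region_site_probs, 4, "region_site_probs")
  check_probs(depth_probs, 3, "depth_probs")
  stopifnot(pediatric_fraction >= 0, pediatric_fraction <= 1,
            tbsa_shape1 > 0, tbsa_shape2 > 0, tbsa_max > 0)
  structure(
    list(n_patients = as.integer(n_patients),
         regions_per_patient_probs = regions_per_patient_probs,
         pediatric_fraction = pediatric_fraction,
         region_site_probs = setNames(region_site_probs, REGIONS),
         depth_probs = setNames(depth_probs, DEPTH_LEVELS),
         tbsa_shape1 = tbsa_shape1, tbsa_shape2 = tbsa_shape2, tbsa_max = tbsa_max),
    class = "cohort_config"
  )
}

check_probs <- function(p, len, name) {
  if (length(p) != len || any(p < 0) || abs(sum(p) - 1) > 1e-12) {
    abort(sprintf("%s must be %d non-negative probabilities summing to 1", name, len))
  }
  invisible(TRUE)
}

#' Rater error model
#'
#' One rater group's TBSA and depth error process. A rating of a region-case
#' with true TBSA `t` is
#' `tbsa_intercept + tbsa_slope * t + b_rater + eps`, clipped to \[0, 100\],
#' with `b_rater ~ N(0, sigma_rater^2)` a per-rater random effect shared
#' across cases and `eps ~ N(0, sigma_resid^2)` residual noise. A slope
#' below 1 emulates calibration compression (estimates pulled toward the
#' centre). The reported depth class is drawn from the row of
#' `depth_confusion` corresponding to the true class, independently across
#' raters given the true class.
#'
#' @param kind `"model"`, `"physician"` or `"panelist"`.
#' @param n_raters number of raters in the group.
#' @param tbsa_intercept,tbsa_slope calibration line of ratings on truth.
#' @param sigma_rater,sigma_resid standard deviations (pp) of the rater
#'   random effect and the residual.
#' @param depth_confusion 3x3 row-stochastic matrix, true class (rows) to
#'   reported class (columns).
#' @return a list of class `rater_model`.
#' @export
rater_model <- function(kind, n_raters,
                        tbsa_intercept = 0, tbsa_slope = 1,
                        sigma_rater = 0, sigma_resid = 0,
                        depth_confusion = diag(3)) {
  kind <- match.arg(kind, RATER_KINDS)
  stopifnot(n_raters >= 1, sigma_rater >= 0, sigma_resid >= 0)
  depth_confusion <- as.matrix(depth_confusion)
  if (!all(dim(depth_confusion) == c(3, 3)) || any(depth_confusion < 0) ||
      any(abs(rowSums(depth_confusion) - 1) > 1e-12)) {
    abort("depth_confusion must be a 3x3 row-stochastic matrix")
  }
  structure(
    list(kind = kind, n_raters = as.integer(n_raters),
         tbsa_intercept = tbsa_intercept, tbsa_slope = tbsa_slope,
         sigma_rater = sigma_rater, sigma_resid = sigma_resid,
         depth_confusion = depth_confusion),
    class = "rater_model"
  )
}

#' Noise SDs that attain a target intraclass correlation
#'
#' For the generating model `rating = t + b_rater + eps` (slope 1), the
#' theoretical single-rater absolute-agreement ICC is
#' \deqn{ICC = \sigma^2_{case} / (\sigma^2_{case} + \sigma^2_{rater} + \sigma^2_{resid}),}
#' so a target ICC fixes the total noise variance given the case variance.
#' `rater_share` splits that total between the rater random effect and the
#' residual.
#'
#' @param target_icc desired ICC in (0, 1).
#' @param case_var variance of true TBSA across region-cases.
#' @param rater_share fraction of noise variance assigned to the rater
#'   random effect (default 0.23).
#' @return named numeric vector `c(sigma_rater =, sigma_resid =)`.
#' @export
icc_noise_sd <- function(target_icc, case_var, rater_share = 0.23) {
  stopifnot(target_icc > 0, target_icc < 1, case_var > 0,
            rater_share >= 0, rater_share <= 1)
  noise_var <- case_var * (1 - target_icc) / target_icc
  c(sigma_rater = sqrt(rater_share * noise_var),
    sigma_resid = sqrt((1 - rater_share) * noise_var))
}

# Variance of the scaled-Beta true TBSA family.
true_tbsa_var <- function(config) {
  a <- config$tbsa_shape1; b <- config$tbsa_shape2
  config$tbsa_max^2 * a * b / ((a + b)^2 * (a + b + 1))
}

#' Default rater models and cohort for a single-centre ED burn study
#'
#' Returns the configuration used throughout this package's examples and
#' simulation studies: the [cohort_config()] defaults plus three rater
#' groups —
#' * `model`: a single automated rater with calibration compression
#'   (intercept 1.05 pp, slope 0.71), residual SD 2 pp, and a
#'   severity-downgrading depth confusion whose rows are the empirical
#'   misclassification rates of the reconstructed 3x3 depth table
#'   (13/16 of true deep-partial cases reported as superficial partial;
#'   full thickness never reported);
#' * `physician`: 18 raters with noise calibrated so the theoretical
#'   TBSA ICC(2,1) is 0.71, and moderate adjacent-category depth confusion;
#' * `panelist`: 3 raters with noise calibrated to ICC 0.97 and
#'   near-diagonal depth confusion (high pre-consensus agreement).
#'
#' @return list with elements `config` (a `cohort_config`) and `raters`
#'   (named list of `rater_model`s).
#' @export
burn_ed_preset <- function() {
  config <- cohort_config()
  cv <- true_tbsa_var(config)
  phys_sd <- icc_noise_sd(0.71, cv)
  panel_sd <- icc_noise_sd(0.97, cv)
  model_confusion <- rbind(
    c(45, 2, 0) / 47,
    c(13, 3, 0) / 16,
    c(1, 0, 0)
  )
  phys_confusion <- rbind(
    c(0.85, 0.14, 0.01),
    c(0.25, 0.65, 0.10),
    c(0.02, 0.28, 0.70)
  )
  # near-diagonal confusion calibrated analytically so the expected pairwise
  # quadratic-weighted kappa at the default depth prevalence is ~0.86
  panel_confusion <- rbind(
    c(0.972, 0.028, 0.000),
    c(0.035, 0.940, 0.025),
    c(0.000, 0.060, 0.940)
  )
  raters <- list(
    model = rater_model("model", 1,
                        tbsa_intercept = 1.05, tbsa_slope = 0.71,
                        sigma_rater = 0, sigma_resid = 2,
                        depth_confusion = model_confusion),
    physician = rater_model("physician", 18,
                            sigma_rater = phys_sd["sigma_rater"],
                            sigma_resid = phys_sd["sigma_resid"],
                            depth_confusion = phys_confusion),
    panelist = rater_model("panelist", 3,
                           sigma_rater = panel_sd["sigma_rater"],
                           sigma_resid = panel_sd["sigma_resid"],
                           depth_confusion = panel_confusion)
  )
  list(config = config, raters = raters)
}

#' Noise-free rater models (for end-to-end smoke checks)
#'
#' All SDs zero, identity calibration, identity depth confusion: ratings
#' reproduce the truth exactly, so every downstream agreement statistic
#' attains its perfect value.
#'
#' @param n_physicians,n_panelists group sizes (defaults 18 and 3).
#' @return named list of `rater_model`s.
#' @export
noise_free_raters <- function(n_physicians = 18, n_panelists = 3) {
  list(
    model = rater_model("model", 1),
    physician = rater_model("physician", n_physicians),
    panelist = rater_model("panelist", n_panelists)
  )
}

#' Generate a synthetic cohort
#'
#' Draws patients i.i.d. (age group, age, sex), a region count per patient,
#' and per region a site, a true depth class and a true TBSA. All regions of
#' a patient share the patient-level covariates. Fully reproducible from
#' `seed`.
#'
#' @param config a [cohort_config()].
#' @param seed integer seed.
#' @return list with tibbles `cases` (the region-case metadata, including an
#'   `image_quality` score drawn independently of everything else) and
#'   `truth` (`region_case_id`, `true_tbsa`, `true_depth`).
#' @export
generate_cohort <- function(config = cohort_config(), seed = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  seed_locally(seed)
  n <- config$n_patients
  pediatric <- runif(n) < config$pediatric_fraction
  age <- ifelse(pediatric,
                pmin(17.5, 0.5 + rgamma(n, shape = 2, scale = 2.2)),
                pmin(90, 18 + rgamma(n, shape = 3, scale = 6)))
  sex <- ifelse(runif(n) < 0.5, "male", "female")
  n_regions <- sample.int(3, n, replace = TRUE, prob = config$regions_per_patient_probs)

  pid <- sprintf("P%03d", seq_len(n))
  cases <- tibble::tibble(
    patient_id = rep(pid, n_regions),
    age_years = round(rep(age, n_regions), 1),
    sex = rep(sex, n_regions)
  )
  m <- nrow(cases)
  cases$region_case_id <- paste0(
    cases$patient_id, "_R",
    unlist(lapply(n_regions, seq_len), use.names = FALSE))
  cases$anatomical_region <- sample(REGIONS, m, replace = TRUE,
                                    prob = config$region_site_probs)
  # image quality: narrow high range (median 9, IQR 8-9), independent of error
  cases$image_quality <- sample(6:10, m, replace = TRUE,
                                prob = c(0.02, 0.05, 0.25, 0.45, 0.23))
  truth <- tibble::tibble(
    region_case_id = cases$region_case_id,
    true_tbsa = config$tbsa_max * rbeta(m, config$tbsa_shape1, config$tbsa_shape2),
    true_depth = sample.int(3, m, replace = TRUE, prob = config$depth_probs)
  )
  cases <- cases[c("region_case_id", "patient_id", "age_years", "sex",
                   "anatomical_region", "image_quality")]
  list(cases = cases, truth = truth)
}

#' Simulate ratings for a cohort
#'
#' Applies each [rater_model()] to the true values: exactly `n_raters`
#' ratings per region-case per group, TBSA clipped to \[0, 100\], depth
#' drawn from the true-class row of the group's confusion matrix.
#'
#' @param truth tibble with `region_case_id`, `true_tbsa`, `true_depth`.
#' @param raters named list of `rater_model`s.
#' @param seed integer seed.
#' @return ratings tibble in the `study_tables` schema.
#' @export
simulate_ratings <- function(truth, raters, seed = NULL) {
  if (nrow(truth) == 0) abort("empty truth table")
  seed_locally(seed)
  m <- nrow(truth)
  out <- lapply(raters, function(rm) {
    k <- rm$n_raters
    b <- rnorm(k, 0, rm$sigma_rater)
    rid <- if (k == 1) paste0(rm$kind, "_1") else sprintf("%s_%02d", rm$kind, seq_len(k))
    per_rater <- lapply(seq_len(k), function(j) {
      tbsa <- rm$tbsa_intercept + rm$tbsa_slope * truth$true_tbsa +
        b[j] + rnorm(m, 0, rm$sigma_resid)
      tbsa <- pmin(100, pmax(0, tbsa))
      depth <- vapply(truth$true_depth, function(d) {
        sample.int(3, 1, prob = rm$depth_confusion[d, ])
      }, integer(1))
      tibble::tibble(
        region_case_id = truth$region_case_id,
        rater_id = rid[j],
        rater_kind = rm$kind,
        tbsa_percent = round(tbsa, 2),
        depth_class = DEPTH_LEVELS[depth]
      )
    })
    dplyr::bind_rows(per_rater)
  })
  dplyr::bind_rows(out)
}

#' Simulate a complete synthetic study
#'
#' Convenience wrapper: generates a cohort, simulates all rater groups, and
#' returns validated `study_tables` plus the ground truth. Cohort generation
#' and rating simulation use distinct seeds derived from `seed`, so each
#' stage is independently reproducible.
#'
#' @param preset list with `config` and `raters`, e.g. [burn_ed_preset()].
#' @param seed integer seed.
#' @param margin_pp non-inferiority margin (default 3 pp).
#' @return list with `tables` (a `study_tables`) and `truth` (tibble).
#' @export
simulate_study <- function(preset = burn_ed_preset(), seed = NULL, margin_pp = 3) {
  seeds <- derive_seeds(seed, 2)
  cohort <- generate_cohort(preset$config, seed = seeds[[1]])
  ratings <- simulate_ratings(cohort$truth, preset$raters, seed = seeds[[2]])
  list(tables = study_tables(cohort$cases, ratings, margin_pp = margin_pp),
       truth = cohort$truth)
}

# Derive k child seeds from one master seed, keeping them in 32-bit range.
derive_seeds <- function(seed, k) {
  if (is.null(seed)) return(rep(list(NULL), k))
  as.list(withr::with_seed(seed, sample.int(.Machine$integer.max - 1L, k)))
}

#' Write a synthetic study to CSV
#'
#' Writes `cases.csv` and `ratings.csv` in the [read_study()] schema plus
#' `truth.csv` (`region_case_id,true_tbsa,true_depth`) for
#' parameter-recovery checks.
#'
#' @param sim result of [simulate_study()].
#' @param dir output directory.
#' @return invisibly, the three file paths.
#' @export
write_cohort <- function(sim, dir) {
  paths <- write_study(sim$tables, dir)
  tp <- file.path(dir, "truth.csv")
  readr::write_csv(sim$truth, tp)
  invisible(c(paths, truth = tp))
}
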