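SP <- 1L; DP <- 2L; FT <- 3L

test_that("panel consensus applies the median / majority / adjudication rules", {
  r <- panel_consensus(c(4, 5, 6), c(SP, SP, DP))
  expect_equal(r$consensus_tbsa, 5)
  expect_equal(r$consensus_depth, SP)
  expect_equal(r$adjudication_flag, "auto_accepted")

  # three-way depth tie defaults to deep partial
  r2 <- panel_consensus(c(5, 5, 5), c(SP, DP, FT))
  expect_equal(r2$consensus_depth, DP)
  expect_equal(r2$adjudication_flag, "needs_adjudication")

  # TBSA range above 2 pp forces adjudication even with unanimous depth
  r3 <- panel_consensus(c(2, 5, 9), c(DP, DP, DP))
  expect_equal(r3$consensus_tbsa, 5)
  expect_equal(r3$consensus_depth, DP)
  expect_equal(r3$adjudication_flag, "needs_adjudication")
})

test_that("panel consensus is permutation-invariant and interpolation-free for odd panels", {
  set.seed(11)
  for (i in 1:20) {
    tbsa <- round(runif(3, 0, 12), 1)
    depth <- sample(1:3, 3, replace = TRUE)
    base <- panel_consensus(tbsa, depth)
    perm <- sample(3)
    expect_equal(panel_consensus(tbsa[perm], depth[perm]), base)
    expect_true(base$consensus_tbsa %in% tbsa)  # odd panel: median is a panelist value
    expect_true(base$consensus_tbsa >= min(tbsa) && base$consensus_tbsa <= max(tbsa))
  }
})

test_that("unanimous depth is never changed by adjudication flagging", {
  for (d in 1:3) {
    r <- panel_consensus(c(0, 50, 100), rep(d, 3))  # huge range
    expect_equal(r$consensus_depth, d)
    expect_equal(r$adjudication_flag, "needs_adjudication")
  }
})

test_that("raising any single vote of a 3-member panel never lowers the consensus class", {
  # exhaustive over all 27 vote patterns and all single-vote raises
  grid <- expand.grid(v1 = 1:3, v2 = 1:3, v3 = 1:3)
  for (r in seq_len(nrow(grid))) {
    votes <- as.integer(grid[r, ])
    base <- panel_consensus(rep(5, 3), votes)$consensus_depth
    for (j in 1:3) {
      if (votes[j] < 3) {
        votes2 <- votes
        votes2[j] <- votes2[j] + 1L
        raised <- panel_consensus(rep(5, 3), votes2)$consensus_depth
        expect_gte(raised, base)
      }
    }
  }
})

test_that("physician consensus uses midpoint medians and deeper-class tie-breaks", {
  r <- physician_consensus(rep(3, 18), rep(SP, 18))
  expect_equal(r$consensus_tbsa, 3)
  expect_equal(r$consensus_depth, SP)
  expect_false(r$depth_tie)

  expect_equal(physician_consensus(c(1, 2, 3, 10), rep(SP, 4))$consensus_tbsa, 2.5)

  tie <- physician_consensus(rep(2, 18), c(rep(SP, 9), rep(DP, 9)))
  expect_equal(tie$consensus_depth, DP)
  expect_true(tie$depth_tie)
})

test_that("pre-consensus agreement is perfect for identical raters and robust to a constant rater", {
  cases <- tibble::tibble(
    region_case_id = sprintf("C%d", 1:6),
    patient_id = sprintf("P%d", 1:6),
    age_years = 30, sex = "male",
    anatomical_region = "torso", image_quality = 9L
  )
  tbsa <- c(1, 3, 5, 7, 9, 11)
  depth <- c(1, 1, 2, 2, 3, 3)
  ratings <- dplyr::bind_rows(lapply(1:3, function(j) {
    tibble::tibble(
      region_case_id = cases$region_case_id,
      rater_id = paste0("panel_", j), rater_kind = "panelist",
      tbsa_percent = tbsa,
      depth_class = c("superficial_partial", "superficial_partial",
                      "deep_partial", "deep_partial",
                      "full_thickness", "full_thickness")
    )
  }))
  st <- study_tables(cases, ratings)
  agr <- preconsensus_agreement(st)
  expect_equal(agr$tbsa_icc, 1)
  expect_equal(agr$depth_kappa_w, 1)

  # one constant rater: ICC drops below 1 but is computed without error
  ratings2 <- ratings
  ratings2$tbsa_percent[ratings2$rater_id == "panel_3"] <- 6
  agr2 <- preconsensus_agreement(study_tables(cases, ratings2))
  expect_lt(agr2$tbsa_icc, 1)
  expect_true(is.finite(agr2$tbsa_icc))
})

test_that("panel ICC recovery: simulated panels attain the generating-model ICC", {
  # closed-form oracle: ICC = case_var / (case_var + rater_var + resid_var)
  preset <- burn_ed_preset()
  target <- 0.97
  reps <- sapply(1:50, function(s) {
    sim <- simulate_study(preset, seed = 5000 + s)
    preconsensus_agreement(sim$tables, "panelist")$tbsa_icc
  })
  expect_lt(abs(mean(reps) - target), 0.03)
})

test_that("consensus_table aggregates per case and skips fully non-assessable cases", {
  st <- panel_study(non_assessable = list(C1 = 3))
  pc <- consensus_table(st, "panel")
  expect_false("C1" %in% pc$region_case_id)
  expect_setequal(pc$region_case_id, c("C2", "C3"))
  expect_true(all(pc$n_raters_used == 3))
  ph <- consensus_table(st, "physician")
  expect_equal(nrow(ph), 3)
  expect_true(all(is.na(ph$adjudication_flag)))
})
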