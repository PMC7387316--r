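# Step 3 testing: stratified z-scoring, panel composition, longitudinal
# composites, ROC state prediction and Cox trait prediction.

two_stratum_visits <- function() {
  dplyr::bind_rows(
    visits_from_retention(c(50, 60, 70), subject_id = "S1", gender = "M",
                          diagnosis = "BP"),
    visits_from_retention(c(30, 40, 50), subject_id = "S2", gender = "F",
                          diagnosis = "SZ")
  )
}

test_that("stratum z-scoring gives mean 0, SD 1 (population convention)", {
  v <- two_stratum_visits()
  x <- setNames(c(1, 2, 3, 10, 20, 60), v$visit_id)
  z <- zscore_by_stratum(x, v)
  expect_equal(unname(z[1:3]), c(-1.2247449, 0, 1.2247449), tolerance = 1e-6)
  expect_equal(mean(z[1:3]), 0)
  expect_equal(mean(z[4:6]), 0)
  expect_equal(sqrt(mean(z[4:6]^2)), 1)
})

test_that("zero-variance and singleton strata yield zeros with a warning", {
  v <- two_stratum_visits()
  x <- setNames(c(5, 5, 5, 1, 2, 3), v$visit_id)
  expect_warning(z <- zscore_by_stratum(x, v), "zero variance")
  expect_equal(unname(z[1:3]), c(0, 0, 0))
  v1 <- visits_from_retention(50, subject_id = "S3", gender = "F",
                              diagnosis = "BP")
  expect_warning(z1 <- zscore_by_stratum(setNames(3, v1$visit_id), v1),
                 "singleton")
  expect_equal(unname(z1), 0)
})

test_that("z-scoring absorbs affine rescaling of a marker", {
  v <- two_stratum_visits()
  x <- setNames(c(1.2, 3.4, 2.2, 8, 9, 7.5), v$visit_id)
  expect_equal(zscore_by_stratum(x, v), zscore_by_stratum(3.7 * x + 11, v))
})

test_that("panel score sums increased-risk minus decreased-risk members", {
  z <- matrix(c(1.0, 0.4), nrow = 2, dimnames = list(c("A", "B"), "v1"))
  panel <- tibble::tibble(probeset_id = c("A", "B"),
                          direction = c("increased_risk", "decreased_risk"))
  expect_equal(unname(panel_score(z, panel)), 0.6)
  flipped <- panel
  flipped$direction <- rev(panel$direction)
  expect_equal(unname(panel_score(z, flipped)), -0.6)
  expect_equal(unname(panel_score(z * 0, panel)), 0)
  expect_error(panel_score(z, tibble::tibble(probeset_id = "C",
                                             direction = "increased_risk")),
               "C")
})

test_that("longitudinal measures follow the level/slope/extreme definitions", {
  m <- longitudinal_measure(c(8, 8), c(0, 100), "increased")
  expect_equal(m$slope, 0.01)
  m_inc <- longitudinal_measure(c(7, 9, 8), c(0, 10, 20), "increased")
  expect_equal(m_inc$extreme_level, c(9, 9))
  m_dec <- longitudinal_measure(c(7, 9, 8), c(0, 10, 20), "decreased")
  expect_equal(m_dec$extreme_level, c(7, 7))
  expect_equal(m_inc$max_slope, cummax(m_inc$slope))
  expect_error(longitudinal_measure(c(7, 9), c(0, 0), "increased"),
               "strictly increasing")
  expect_warning(longitudinal_measure(c(0, 9), c(0, 10), "increased"),
                 "slope undefined")
})

test_that("single-visit subjects are excluded from longitudinal analyses", {
  v <- dplyr::bind_rows(
    visits_from_retention(c(50, 60), subject_id = "S1"),
    visits_from_retention(70, subject_id = "S2")
  )
  x <- setNames(c(7, 8, 9), v$visit_id)
  comp <- suppressWarnings(longitudinal_composite(x, v))
  expect_equal(names(comp), "S1_V2")
})

test_that("identical trajectories give a composite constant across subjects", {
  v <- dplyr::bind_rows(lapply(1:4, function(i) {
    visits_from_retention(c(50, 60, 70), subject_id = paste0("S", i),
                          days = c(0, 50, 100))
  }))
  x <- setNames(rep(c(7, 8, 7.5), 4), v$visit_id)
  comp <- suppressWarnings(longitudinal_composite(x, v))
  # same composite for every subject at the same visit position
  second <- comp[grep("_V2$", names(comp))]
  third <- comp[grep("_V3$", names(comp))]
  expect_equal(unname(second), rep(second[[1]], 4))
  expect_equal(unname(third), rep(third[[1]], 4))
  # a flat constant series carries no signal at all
  flat <- suppressWarnings(longitudinal_composite(
    setNames(rep(7, nrow(v)), v$visit_id), v))
  expect_true(all(flat == 0))
})

test_that("AUC matches brute force over case-control pairs", {
  scores <- c(0.9, 0.8, 0.3, 0.2)
  labels <- c(TRUE, TRUE, FALSE, FALSE)
  expect_equal(mann_whitney_auc(scores, labels)$auc, 1.0)
  swapped <- c(TRUE, FALSE, TRUE, FALSE)
  expect_equal(mann_whitney_auc(scores, swapped)$auc, 0.75)
  expect_equal(brute_force_auc(scores, swapped), 0.75)
  set.seed(53)
  for (i in 1:10) {
    s <- sample(round(stats::rnorm(30), 1))   # rounding induces ties
    lab <- sample(c(TRUE, FALSE), 30, replace = TRUE, prob = c(0.3, 0.7))
    if (sum(lab) == 0 || sum(!lab) == 0) next
    expect_equal(mann_whitney_auc(s, lab)$auc, brute_force_auc(s, lab))
    # rank-based antisymmetry
    expect_equal(mann_whitney_auc(-s, lab)$auc,
                 1 - mann_whitney_auc(s, lab)$auc)
  }
})

test_that("AUC agrees with pROC on a fixed example", {
  set.seed(59)
  s <- stats::rnorm(60)
  lab <- stats::runif(60) < stats::plogis(s)
  ours <- mann_whitney_auc(s, lab)$auc
  ref <- as.numeric(pROC::auc(pROC::roc(response = lab, predictor = s,
                                        direction = "<", quiet = TRUE)))
  expect_equal(ours, ref, tolerance = 1e-12)
})

test_that("permuted labels give chance AUC and uniform p values", {
  set.seed(61)
  n <- 200
  s <- stats::rnorm(n)
  res <- replicate(500, {
    lab <- sample(rep(c(TRUE, FALSE), c(40, 160)))
    r <- mann_whitney_auc(s, lab)
    c(r$auc, r$p_value)
  })
  expect_lt(abs(mean(res[1, ]) - 0.5), 0.02)
  expect_lt(abs(mean(res[2, ]) - 0.5), 0.05)
  expect_lt(abs(mean(res[2, ] < 0.05) - 0.05), 0.03)
})

test_that("state prediction labels visits at the retention cutoff and reports untestable groups", {
  v <- dplyr::bind_rows(
    visits_from_retention(c(30, 40, 80), subject_id = "S1", gender = "M",
                          diagnosis = "BP"),
    visits_from_retention(c(90, 85, 70), subject_id = "S2", gender = "F",
                          diagnosis = "SZ")
  )
  scores <- setNames(c(2, 1.5, -1, -2, -1.5, -0.5), v$visit_id)
  all_res <- predict_state(scores, v, cutoff = 40, grouping = "ALL")
  expect_equal(all_res$n_low, 2)
  expect_equal(all_res$n_total, 6)
  expect_equal(all_res$auc, 1.0)
  by_gender <- predict_state(scores, v, cutoff = 40, grouping = "gender")
  f <- by_gender[by_gender$group == "F", ]
  expect_false(f$testable)
  expect_true(is.na(f$auc))
  m <- by_gender[by_gender$group == "M", ]
  expect_true(m$testable)
  expect_equal(m$n_low, 2)
})

test_that("Cox sign check: the higher-scoring subject with the event gives HR > 1", {
  v <- dplyr::bind_rows(
    visits_from_retention(50, subject_id = "S1"),
    visits_from_retention(50, subject_id = "S2"),
    visits_from_retention(50, subject_id = "S3")
  )
  v$neuropsych_event <- c(TRUE, FALSE, FALSE)
  v$event_day <- c(100, 1000, 1000)
  scores <- setNames(c(2, -1, -1), v$visit_id)
  res <- suppressWarnings(predict_trait(scores, v, grouping = "ALL"))
  expect_true(res$hazard_ratio > 1)
  # zero events -> untestable, not an error
  v0 <- v
  v0$neuropsych_event <- FALSE
  res0 <- predict_trait(scores, v0, grouping = "ALL")
  expect_false(res0$testable)
  expect_true(is.na(res0$hazard_ratio))
})

test_that("trait prediction recovers the generating log-hazard on synthetic outcomes", {
  est <- sapply(1:5, function(s) {
    co <- simulate_cohort(cohort_config(
      n_subjects = 150, n_probesets = 40, n_planted_increased = 5,
      n_planted_decreased = 5, event_hazard_coefficient = 0.5,
      event_base_rate = 2e-4, seed = 300 + s))
    score <- suppressWarnings(
      planted_panel_score(co$expression, co$truth, co$visits))
    fit <- survival::coxph(
      survival::Surv(co$visits$event_day, co$visits$neuropsych_event) ~
        score[co$visits$visit_id])
    unname(stats::coef(fit))
  })
  se <- stats::sd(est) / sqrt(length(est))
  expect_lt(abs(mean(est) - 0.5), 2 * se + 0.05)
})
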