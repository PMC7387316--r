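# Step 1 discovery: comparison-pair selection, DE and AP scoring,
# raw-score summation, internal points and method combination.

test_that("comparison pairs require a 20% relative change between consecutive visits", {
  expect_equal(nrow(select_comparison_pairs(visits_from_retention(c(50, 50, 50)))), 0)

  p <- select_comparison_pairs(visits_from_retention(c(50, 65)))
  expect_equal(nrow(p), 1)
  expect_equal(p$relative_change, 0.30)
  expect_equal(p$high_visit_id, "S1_V2")
  expect_equal(p$low_visit_id, "S1_V1")

  # consecutive qualifying pairs only; (40, 80) is not consecutive
  p <- select_comparison_pairs(visits_from_retention(c(40, 50, 80)))
  expect_equal(nrow(p), 2)
  expect_equal(p$relative_change, c(0.25, 0.60))
  expect_false(any(p$low_visit_id == "S1_V1" & p$high_visit_id == "S1_V3"))

  # decreasing change: high label goes to the earlier visit
  p <- select_comparison_pairs(visits_from_retention(c(80, 60)))
  expect_equal(p$high_visit_id, "S1_V1")
  expect_equal(p$relative_change, 0.25)
})

test_that("pair selection handles zero and missing retention", {
  expect_warning(p <- select_comparison_pairs(visits_from_retention(c(0, 30))),
                 "retention 0")
  expect_equal(nrow(p), 1)
  expect_warning(p0 <- select_comparison_pairs(visits_from_retention(c(0, 0))),
                 "retention 0")
  expect_equal(nrow(p0), 0)
  expect_warning(pna <- select_comparison_pairs(visits_from_retention(c(50, NA, 80))),
                 "missing retention")
  expect_equal(nrow(pna), 0)
})

test_that("DE scoring follows the 1.1/1.2 fold-change tiers", {
  v <- visits_from_retention(c(40, 80))
  pair <- select_comparison_pairs(v)
  expr <- matrix(0, nrow = 6, ncol = 2,
                 dimnames = list(paste0("p", 1:6), v$visit_id))
  # high-minus-low log2 differences and their expected scores
  expr[, "S1_V2"] <- c(0.32, -0.20, 0, log2(1.2), -log2(1.1), 0.1)
  s <- score_pair_de(expr, pair)
  expect_equal(s$score, c(1, -0.5, 0, 1, -0.5, 0))
})

test_that("AP scoring rewards detection-call flips only", {
  v <- visits_from_retention(c(40, 80))
  pair <- select_comparison_pairs(v)
  calls <- matrix(c("A", "P",   # low A, high P -> +1
                    "P", "A",   # low P, high A -> -1
                    "A", "A",
                    "P", "P"),
                  nrow = 4, byrow = TRUE,
                  dimnames = list(paste0("p", 1:4), v$visit_id))
  s <- score_pair_ap(calls, pair)
  expect_equal(s$score, c(1, -1, 0, 0))
})

test_that("missing visit columns are reported by name", {
  v <- visits_from_retention(c(40, 80))
  pair <- select_comparison_pairs(v)
  expr <- matrix(1, 1, 1, dimnames = list("p1", "S1_V1"))
  expect_error(score_pair_de(expr, pair), "S1_V2")
})

test_that("raw scores sum per-pair scores and cancel opposing evidence", {
  scores <- tibble::tibble(probeset_id = c("p1", "p1", "p1", "p2", "p2"),
                           score = c(1, 1, -0.5, 1, -1))
  raw <- sum_raw_scores(scores)
  expect_equal(raw$raw_score[raw$probeset_id == "p1"], 1.5)
  expect_equal(raw$raw_score[raw$probeset_id == "p2"], 0)
})

test_that("internal points follow the 33.3/50/80 percent-of-max tiers", {
  expect_equal(internal_points(c(80.8, 69.6, 43.8, 33.7, 33.2, 100, 50, 80)),
               c(6L, 4L, 2L, 2L, 0L, 6L, 4L, 6L))
  raw <- tibble::tibble(probeset_id = c("a", "b", "c", "d"),
                        raw_score = c(10, -8, 4, 0))
  ds <- assign_internal_points(raw, "DE")
  expect_equal(ds$percent_of_max, c(100, 80, 40, 0))
  expect_equal(ds$internal_points, c(6L, 6L, 2L, 0L))
  expect_equal(ds$direction, c("increased", "decreased", "increased", "none"))
  expect_true(all(ds$internal_points %in% c(0, 2, 4, 6)))
})

test_that("all-zero raw scores yield zero points with a warning", {
  raw <- tibble::tibble(probeset_id = c("a", "b"), raw_score = c(0, 0))
  expect_warning(ds <- assign_internal_points(raw, "AP"), "all raw scores")
  expect_equal(ds$internal_points, c(0L, 0L))
})

test_that("methods combine by maximum with conflicts flagged", {
  de <- assign_internal_points(
    tibble::tibble(probeset_id = c("a", "b", "c"), raw_score = c(6, 10, 0)), "DE")
  ap <- assign_internal_points(
    tibble::tibble(probeset_id = c("a", "b", "c"), raw_score = c(-4, 4, 0)), "AP")
  comb <- combine_methods(de, ap)
  # a: DE 4 (60%) vs AP 6 (100%, decreased) -> 6 decreased, conflicting
  a <- comb[comb$probeset_id == "a", ]
  expect_equal(a$internal_points, 6L)
  expect_equal(a$direction, "decreased")
  expect_true(a$conflict)
  # b: DE 6 ties AP 6, same direction, no conflict
  b <- comb[comb$probeset_id == "b", ]
  expect_equal(b$internal_points, 6L)
  expect_equal(b$direction, "increased")
  expect_false(b$conflict)
  expect_equal(comb$internal_points[comb$probeset_id == "c"], 0L)
  # DE-only cohorts combine unchanged
  solo <- combine_methods(de, NULL)
  expect_equal(solo$internal_points, de$internal_points)
})

test_that("relabeling high/low in every pair negates every raw score", {
  co <- simulate_cohort(small_config(seed = 31))
  pairs <- select_comparison_pairs(co$visits)
  flipped <- pairs
  flipped$high_visit_id <- pairs$low_visit_id
  flipped$low_visit_id <- pairs$high_visit_id
  raw <- memtrack:::raw_scores_matrix(co$expression, pairs, "DE")
  raw_f <- memtrack:::raw_scores_matrix(co$expression, flipped, "DE")
  expect_equal(raw_f$raw_score, -raw$raw_score)
  rawa <- memtrack:::raw_scores_matrix(co$calls, pairs, "AP")
  rawa_f <- memtrack:::raw_scores_matrix(co$calls, flipped, "AP")
  expect_equal(rawa_f$raw_score, -rawa$raw_score)
})

test_that("|raw score| never exceeds the number of pairs", {
  co <- simulate_cohort(small_config(seed = 37))
  d <- suppressWarnings(run_discovery(co$expression, co$visits, co$calls))
  n_pairs <- nrow(d$pairs)
  expect_true(all(abs(d$per_method$raw_score) <= n_pairs))
  expect_true(all(d$per_method$internal_points %in% c(0, 2, 4, 6)))
})

test_that("vectorized raw scores equal the naive per-pair loop on tiny cohorts", {
  for (s in 1:3) {
    cfg <- cohort_config(n_subjects = 5, visits_per_subject = c(2, 4),
                         n_probesets = 20, n_planted_increased = 3,
                         n_planted_decreased = 3, seed = 200 + s)
    co <- simulate_cohort(cfg)
    pairs <- select_comparison_pairs(co$visits)
    raw_de <- memtrack:::raw_scores_matrix(co$expression, pairs, "DE")
    expect_equal(raw_de$raw_score,
                 unname(naive_raw_de(co$expression, pairs)[raw_de$probeset_id]))
    raw_ap <- memtrack:::raw_scores_matrix(co$calls, pairs, "AP")
    expect_equal(raw_ap$raw_score,
                 unname(naive_raw_ap(co$calls, pairs)[raw_ap$probeset_id]))
  }
})
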