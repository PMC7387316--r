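# Shared fixtures: small cohort configurations and independent oracles
# used across test files.

small_config <- function(seed = 1L, ...) {
  args <- list(n_subjects = 30, n_probesets = 100,
               n_planted_increased = 5, n_planted_decreased = 5, seed = seed)
  over <- list(...)
  args[names(over)] <- over
  do.call(cohort_config, args)
}

# Visit table builder for hand-crafted retention sequences.
visits_from_retention <- function(retention, subject_id = "S1",
                                  gender = "M", diagnosis = "BP",
                                  days = NULL) {
  k <- length(retention)
  if (is.null(days)) days <- seq(0, by = 100, length.out = k)
  tibble::tibble(
    visit_id = sprintf("%s_V%d", subject_id, seq_len(k)),
    subject_id = subject_id,
    gender = gender,
    diagnosis = diagnosis,
    day = days,
    retention = retention,
    neuropsych_event = FALSE,
    event_day = 1000
  )
}

# Independent naive per-pair DE raw-score oracle: plain double loop and
# fold-change arithmetic, no shared code with the package's vectorized path.
naive_raw_de <- function(expr, pairs) {
  raw <- setNames(rep(0, nrow(expr)), rownames(expr))
  for (i in seq_len(nrow(pairs))) {
    hi <- expr[, pairs$high_visit_id[i]]
    lo <- expr[, pairs$low_visit_id[i]]
    for (p in rownames(expr)) {
      fold <- 2^abs(hi[p] - lo[p])
      s <- if (fold >= 1.2) 1 else if (fold >= 1.1) 0.5 else 0
      raw[p] <- raw[p] + if (hi[p] >= lo[p]) s else -s
    }
  }
  raw
}

naive_raw_ap <- function(calls, pairs) {
  raw <- setNames(rep(0, nrow(calls)), rownames(calls))
  for (i in seq_len(nrow(pairs))) {
    hi <- calls[, pairs$high_visit_id[i]]
    lo <- calls[, pairs$low_visit_id[i]]
    for (p in rownames(calls)) {
      s <- 0
      if (hi[p] == "P" && lo[p] == "A") s <- 1
      if (hi[p] == "A" && lo[p] == "P") s <- -1
      raw[p] <- raw[p] + s
    }
  }
  raw
}

# Brute-force AUC over all case-control pairs (ties count 0.5).
brute_force_auc <- function(scores, is_case) {
  cases <- scores[is_case]
  controls <- scores[!is_case]
  tot <- 0
  for (a in cases) for (b in controls) {
    tot <- tot + (a > b) + 0.5 * (a == b)
  }
  tot / (length(cases) * length(controls))
}

# Semi-analytic probability that a two-visit subject shows a >= 20%
# relative retention change, under the generator's model: subject mean
# mu ~ N(m, sb), visit retention clip(mu + e, 0, 100) with e ~ N(0, sw).
# The first visit is Monte-Carlo sampled; the second-visit tail is exact.
analytic_change_prob <- function(m, sb, sw, threshold = 0.2, n_mc = 10000,
                                 seed = 99) {
  set.seed(seed)
  mu <- rnorm(n_mc, m, sb)
  r1 <- pmin(100, pmax(0, mu + rnorm(n_mc, 0, sw)))
  up_cut <- (1 + threshold) * r1
  dn_cut <- (1 - threshold) * r1
  p_up <- ifelse(up_cut <= 100, pnorm(up_cut, mu, sw, lower.tail = FALSE), 0)
  p_dn <- pnorm(dn_cut, mu, sw)
  p <- ifelse(r1 == 0, pnorm(0, mu, sw, lower.tail = FALSE), p_up + p_dn)
  mean(p)
}
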