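# Synthetic longitudinal cohort generator: subjects with repeated visits,
# memory retention trajectories, planted phenotype-tracking probesets, and a
# panel-driven time-to-event outcome. All randomness is governed by
# config$seed; identical (config, seed) regenerates identical outputs.

#' Default gender x diagnosis strata
#'
#' Sampling weights loosely shaped like a male-predominant psychiatric
#' cohort spanning bipolar disorder (BP), depression (MDD), schizophrenia
#' (SZ), schizoaffective disorder (SZA) and PTSD.
#'
#' @return A tibble with columns `gender`, `diagnosis`, `weight`.
#' @export
default_strata <- function() {
  dx <- c(BP = 0.35, MDD = 0.16, SZA = 0.23, SZ = 0.17, PTSD = 0.09)
  g <- c(M = 0.82, F = 0.18)
  tibble::tibble(
    gender = rep(names(g), each = length(dx)),
    diagnosis = rep(names(dx), times = length(g)),
    weight = rep(unname(g), each = length(dx)) * rep(unname(dx), times = length(g))
  )
}

#' Configuration for the synthetic cohort generator
#'
#' @param n_subjects Number of subjects.
#' @param visits_per_subject Integer range `c(min, max)` of visits per
#'   subject; each subject's visit count is drawn uniformly from it.
#'   Must lie within \[2, 6\].
#' @param strata Tibble of `(gender, diagnosis, weight)` sampling weights;
#'   defaults to [default_strata()].
#' @param n_probesets Total probesets on the simulated array.
#' @param n_planted_increased,n_planted_decreased Number of probesets whose
#'   expression increases (resp. decreases) with memory retention.
#' @param effect_size Standardized log2-expression shift per 10 retention
#'   points for planted probesets (dimensionless slope).
#' @param noise_sd Visit-level expression noise SD (log2 units).
#' @param baseline_mean Grand mean log2 expression.
#' @param baseline_mean_sd Between-subject baseline SD (log2 units).
#' @param retention_mean Population mean of the HVLT Retention score (%).
#' @param retention_between_sd Between-subject SD of the subject-level mean
#'   retention (%).
#' @param retention_within_sd Within-subject visit-to-visit retention
#'   fluctuation SD (%).
#' @param visit_interval_days_range Integer range of days between
#'   consecutive visits.
#' @param event_hazard_coefficient Log-hazard increase of the future
#'   neuropsychological event per unit of planted-panel risk score.
#' @param event_base_rate Baseline exponential event rate per day.
#' @param censor_day Administrative censoring horizon (days from each
#'   visit).
#' @param ap_call_threshold Log2 expression below which a probeset is
#'   called Absent.
#' @param seed Integer seed governing all generation.
#'
#' @return An object of class `cohort_config` (a validated list).
#' @export
cohort_config <- function(n_subjects = 150,
                          visits_per_subject = c(2L, 6L),
                          strata = default_strata(),
                          n_probesets = 1000,
                          n_planted_increased = 20,
                          n_planted_decreased = 20,
                          effect_size = 0.5,
                          noise_sd = 0.25,
                          baseline_mean = 7,
                          baseline_mean_sd = 1,
                          retention_mean = 60,
                          retention_between_sd = 15,
                          retention_within_sd = 15,
                          visit_interval_days_range = c(30L, 365L),
                          event_hazard_coefficient = 0.5,
                          event_base_rate = 5e-5,
                          censor_day = 3650,
                          ap_call_threshold = 6,
                          seed = 42L) {
  cfg <- list(
    n_subjects = n_subjects,
    visits_per_subject = as.integer(visits_per_subject),
    strata = strata,
    n_probesets = n_probesets,
    n_planted_increased = n_planted_increased,
    n_planted_decreased = n_planted_decreased,
    effect_size = effect_size,
    noise_sd = noise_sd,
    baseline_mean = baseline_mean,
    baseline_mean_sd = baseline_mean_sd,
    retention_mean = retention_mean,
    retention_between_sd = retention_between_sd,
    retention_within_sd = retention_within_sd,
    visit_interval_days_range = as.integer(visit_interval_days_range),
    event_hazard_coefficient = event_hazard_coefficient,
    event_base_rate = event_base_rate,
    censor_day = censor_day,
    ap_call_threshold = ap_call_threshold,
    seed = as.integer(seed)
  )
  class(cfg) <- "cohort_config"
  validate_cohort_config(cfg)
}

validate_cohort_config <- function(cfg) {
  stopifnot(inherits(cfg, "cohort_config"))
  if (!is.numeric(cfg$n_subjects) || cfg$n_subjects < 1) {
    stop("configuration error: n_subjects must be a positive integer",
         call. = FALSE)
  }
  v <- cfg$visits_per_subject
  if (length(v) != 2 || v[1] < 2 || v[2] > 6 || v[1] > v[2]) {
    stop("configuration error: visits_per_subject must be a range within [2, 6]",
         call. = FALSE)
  }
  st <- cfg$strata
  if (!is.data.frame(st) || nrow(st) == 0 ||
      !all(c("gender", "diagnosis", "weight") %in% names(st)) ||
      any(st$weight < 0) || sum(st$weight) <= 0) {
    stop("configuration error: strata must be a non-empty table of (gender, diagnosis, weight)",
         call. = FALSE)
  }
  if (!all(st$gender %in% c("M", "F")) ||
      !all(st$diagnosis %in% c("BP", "MDD", "SZ", "SZA", "PTSD"))) {
    stop("configuration error: strata levels must be gender in {M,F}, diagnosis in {BP,MDD,SZ,SZA,PTSD}",
         call. = FALSE)
  }
  if (cfg$n_probesets < 1) {
    stop("configuration error: n_probesets must be positive", call. = FALSE)
  }
  if (cfg$n_planted_increased + cfg$n_planted_decreased > cfg$n_probesets) {
    stop("configuration error: planted probesets exceed n_probesets", call. = FALSE)
  }
  if (cfg$effect_size < 0) {
    stop("configuration error: effect_size must be >= 0", call. = FALSE)
  }
  if (cfg$noise_sd <= 0) {
    stop("configuration error: noise_sd must be > 0", call. = FALSE)
  }
  if (cfg$censor_day < 0 || cfg$event_base_rate < 0) {
    stop("configuration error: censor_day and event_base_rate must be >= 0",
         call. = FALSE)
  }
  cfg
}

#' Generate subjects and phenotyping visits
#'
#' Subjects are assigned to gender x diagnosis strata by the configured
#' weights. Each subject receives a uniform number of visits in the
#' configured range, at uniformly drawn day intervals. Retention follows a
#' subject-level Gaussian mean plus i.i.d. Gaussian visit fluctuation,
#' clipped to \[0, 100\].
#'
#' @param config A [cohort_config()].
#' @return A list with tibbles `subjects` (subject_id, gender, diagnosis)
#'   and `visits` (visit_id, subject_id, gender, diagnosis, day, retention,
#'   neuropsych_event, event_day); the outcome columns are `NA` until
#'   [generate_outcomes()] fills them.
#' @export
generate_cohort <- function(config) {
  config <- validate_cohort_config(config)
  set.seed(config$seed)
  n <- as.integer(config$n_subjects)
  st <- config$strata
  stratum_idx <- sample.int(nrow(st), n, replace = TRUE,
                            prob = st$weight / sum(st$weight))
  subjects <- tibble::tibble(
    subject_id = sprintf("S%04d", seq_len(n)),
    gender = st$gender[stratum_idx],
    diagnosis = st$diagnosis[stratum_idx]
  )

  # sample() from a length-1 vector would expand it to 1:x; index instead
  resample <- function(x, size) x[sample.int(length(x), size, replace = TRUE)]
  v <- config$visits_per_subject
  n_visits <- resample(seq(v[1], v[2]), n)
  iv <- config$visit_interval_days_range
  mu_s <- rnorm(n, config$retention_mean, config$retention_between_sd)

  visits <- lapply(seq_len(n), function(i) {
    k <- n_visits[i]
    gaps <- resample(seq(iv[1], iv[2]), k - 1)
    day <- c(0L, cumsum(gaps))
    retention <- pmin(100, pmax(0, mu_s[i] + rnorm(k, 0, config$retention_within_sd)))
    tibble::tibble(
      visit_id = sprintf("%s_V%d", subjects$subject_id[i], seq_len(k)),
      subject_id = subjects$subject_id[i],
      gender = subjects$gender[i],
      diagnosis = subjects$diagnosis[i],
      day = day,
      retention = retention,
      neuropsych_event = NA,
      event_day = NA_real_
    )
  })
  list(subjects = subjects, visits = bind_rows(visits))
}

#' Generate probeset expression and detection calls
#'
#' Log2 expression is `probeset mean + subject offset + slope * (retention -
#' retention_mean) / 10 + noise`, where the slope is `+effect_size` for
#' planted increased probesets, `-effect_size` for planted decreased ones
#' and 0 otherwise. Present/Absent calls threshold the log2 value at
#' `ap_call_threshold`.
#'
#' @param cohort Output of [generate_cohort()].
#' @param config The same [cohort_config()].
#' @return A list with `expression` (numeric matrix, probesets x visits),
#'   `calls` (character matrix of "P"/"A"), and `truth` (tibble probeset_id,
#'   direction, in_outcome_panel).
#' @export
generate_expression <- function(cohort, config) {
  config <- validate_cohort_config(config)
  visits <- cohort$visits
  if (nrow(visits) == 0) stop("cohort is empty", call. = FALSE)
  set.seed(config$seed + 1L)

  p <- config$n_probesets
  probeset_ids <- sprintf("ps_%04d_at", seq_len(p))
  n_inc <- config$n_planted_increased
  n_dec <- config$n_planted_decreased
  direction <- rep("null", p)
  if (n_inc > 0) direction[seq_len(n_inc)] <- "increased_in_high_memory"
  if (n_dec > 0) direction[n_inc + seq_len(n_dec)] <- "decreased_in_high_memory"
  slope <- config$effect_size *
    (direction == "increased_in_high_memory") -
    config$effect_size * (direction == "decreased_in_high_memory")

  subjects <- unique(visits$subject_id)
  probe_mean <- rnorm(p, config$baseline_mean, 1)
  subj_offset <- matrix(rnorm(p * length(subjects), 0, config$baseline_mean_sd),
                        nrow = p, dimnames = list(probeset_ids, subjects))

  centered <- (visits$retention - config$retention_mean) / 10
  expr <- probe_mean +
    subj_offset[, visits$subject_id, drop = FALSE] +
    outer(slope, centered) +
    matrix(rnorm(p * nrow(visits), 0, config$noise_sd), nrow = p)
  expr <- pmax(expr, 0)
  dimnames(expr) <- list(probeset_ids, visits$visit_id)

  calls <- matrix(ifelse(expr >= config$ap_call_threshold, "P", "A"),
                  nrow = p, dimnames = dimnames(expr))
  truth <- tibble::tibble(
    probeset_id = probeset_ids,
    direction = direction,
    in_outcome_panel = direction != "null"
  )
  list(expression = expr, calls = calls, truth = truth)
}

#' Risk-oriented score of the planted outcome panel
#'
#' Z-scores each panel probeset by gender x diagnosis across visits and sums
#' decreased-in-high-memory members minus increased-in-high-memory members,
#' so larger values mean higher risk of the future neuropsychological event.
#'
#' @param expression Probesets x visits matrix.
#' @param truth Planted-truth tibble from [generate_expression()].
#' @param visits Visit tibble with `visit_id`, `gender`, `diagnosis`.
#' @return Named numeric vector of per-visit risk scores.
#' @export
planted_panel_score <- function(expression, truth, visits) {
  members <- truth %>% filter(.data$in_outcome_panel)
  if (nrow(members) == 0) {
    stop("no probesets flagged in_outcome_panel", call. = FALSE)
  }
  panel <- tibble::tibble(
    probeset_id = members$probeset_id,
    direction = ifelse(members$direction == "decreased_in_high_memory",
                       "increased_risk", "decreased_risk")
  )
  z <- zscore_by_stratum(expression[members$probeset_id, , drop = FALSE], visits)
  panel_score(z, panel)
}

#' Generate time-to-event outcomes from the planted panel
#'
#' Event times are exponential with log-hazard linear in the planted-panel
#' risk score: `rate = event_base_rate * exp(event_hazard_coefficient *
#' score)`, censored administratively at `censor_day` days after each visit.
#'
#' @inheritParams generate_expression
#' @param expression Probesets x visits matrix from [generate_expression()].
#' @param truth Planted-truth tibble.
#' @return The visit tibble with `neuropsych_event` and `event_day` filled.
#' @export
generate_outcomes <- function(cohort, expression, truth, config) {
  config <- validate_cohort_config(config)
  visits <- cohort$visits
  set.seed(config$seed + 2L)
  score <- planted_panel_score(expression, truth, visits)
  rate <- config$event_base_rate *
    exp(config$event_hazard_coefficient * score[visits$visit_id])
  t_event <- rexp(nrow(visits), rate = pmax(rate, 1e-12))
  visits$neuropsych_event <- t_event < config$censor_day
  visits$event_day <- pmin(t_event, config$censor_day)
  cohort$visits <- visits
  cohort
}

#' Simulate a complete synthetic cohort
#'
#' Runs [generate_cohort()], [generate_expression()] and
#' [generate_outcomes()] under one configuration.
#'
#' @param config A [cohort_config()].
#' @return An object of class `memory_cohort`: list with `subjects`,
#'   `visits`, `expression`, `calls`, `truth`, `config`.
#' @export
simulate_cohort <- function(config = cohort_config()) {
  cohort <- generate_cohort(config)
  ex <- generate_expression(cohort, config)
  cohort <- generate_outcomes(cohort, ex$expression, ex$truth, config)
  out <- list(
    subjects = cohort$subjects,
    visits = cohort$visits,
    expression = ex$expression,
    calls = ex$calls,
    truth = ex$truth,
    config = config
  )
  class(out) <- "memory_cohort"
  out
}

#' @export
print.memory_cohort <- function(x, ...) {
  cat(sprintf(
    "<memory_cohort> %d subjects, %d visits, %d probesets (%d planted), %d events\n",
    nrow(x$subjects), nrow(x$visits), nrow(x$expression),
    sum(x$truth$direction != "null"), sum(x$visits$neuropsych_event)
  ))
  invisible(x)
}

#' Probeset to gene-symbol annotation for a simulated array
#'
#' One synthetic gene symbol per probeset ("G0001" for "ps_0001_at").
#'
#' @param probeset_ids Character vector of probeset ids.
#' @return Tibble with `probeset_id`, `gene_symbol`.
#' @export
synthetic_annotation <- function(probeset_ids) {
  tibble::tibble(
    probeset_id = probeset_ids,
    gene_symbol = sub("^ps_(\\d+)_at$", "G\\1", probeset_ids)
  )
}

#' Synthetic literature-evidence database planted on true biomarkers
#'
#' Emulates a curated evidence database: genes of planted probesets receive
#' records on several lines of evidence for the target disorder, a random
#' minority of null genes receive one line. Deterministic given `seed`.
#'
#' @param truth Planted-truth tibble.
#' @param annotation Probeset to gene mapping.
#' @param disorder Disorder tag stamped on planted records (default "AD").
#' @param background_rate Fraction of null genes given a single evidence
#'   line.
#' @param seed Integer seed.
#' @return Evidence tibble (gene_symbol, line, direction, source_tag,
#'   disorder_tag).
#' @export
synthetic_evidence <- function(truth, annotation, disorder = "AD",
                               background_rate = 0.05, seed = 1L) {
  set.seed(seed)
  lines <- evidence_lines()
  planted <- annotation$gene_symbol[match(
    truth$probeset_id[truth$direction != "null"], annotation$probeset_id)]
  nulls <- setdiff(annotation$gene_symbol, planted)
  recs <- lapply(planted, function(g) {
    k <- sample(3:6, 1)
    tibble::tibble(
      gene_symbol = g,
      line = sample(lines, k),
      direction = sample(c("up", "down", "unspecified"), k, replace = TRUE),
      source_tag = sprintf("synth_%s_%d", g, seq_len(k)),
      disorder_tag = disorder
    )
  })
  bg <- nulls[runif(length(nulls)) < background_rate]
  recs_bg <- lapply(bg, function(g) {
    tibble::tibble(
      gene_symbol = g,
      line = sample(lines, 1),
      direction = "unspecified",
      source_tag = sprintf("synth_%s_bg", g),
      disorder_tag = disorder
    )
  })
  bind_rows(c(recs, recs_bg))
}
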