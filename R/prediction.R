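# Step 3: testing markers and panels in an independent cohort. Expression
# is Z-scored within gender x diagnosis strata, markers are combined into
# panels (increased-risk minus decreased-risk), state (low memory, HVLT
# Retention <= 40) is predicted by rank-based ROC, and trait (future
# positive neuropsychological testing) by Cox regression on the time in
# days from each lab visit to the positive test.

#' Z-score visit values within gender x diagnosis strata
#'
#' Normalizes each marker within each (gender, diagnosis) stratum to mean
#' 0 and SD 1, using the population SD convention (divisor n). Strata with
#' zero variance, or singleton strata, yield 0 with a warning; this avoids
#' artefacts from different expression ranges across demographic groups
#' and makes markers combinable into panels.
#'
#' @param x Named numeric vector (one marker) or matrix (markers x
#'   visits) with visit ids as (column) names.
#' @param visits Tibble with `visit_id`, `gender`, `diagnosis`.
#' @return Same shape as `x`, z-scored within strata.
#' @export
zscore_by_stratum <- function(x, visits) {
  vec_in <- is.null(dim(x))
  m <- if (vec_in) matrix(x, nrow = 1, dimnames = list("marker", names(x))) else x
  if (is.null(colnames(m))) stop("x must carry visit ids as names", call. = FALSE)
  idx <- match(colnames(m), visits$visit_id)
  if (anyNA(idx)) stop("visit id(s) missing from metadata", call. = FALSE)
  stratum <- paste(visits$gender[idx], visits$diagnosis[idx], sep = ":")
  z <- m
  for (s in unique(stratum)) {
    cols <- which(stratum == s)
    vals <- m[, cols, drop = FALSE]
    mu <- rowMeans(vals)
    sdev <- sqrt(rowMeans((vals - mu)^2))
    if (length(cols) < 2 || any(sdev == 0)) {
      flat <- if (length(cols) < 2) seq_len(nrow(m)) else which(sdev == 0)
      warning(sprintf("stratum %s: %s; affected values set to 0", s,
                      if (length(cols) < 2) "singleton stratum" else "zero variance"))
      sdev[flat] <- Inf
    }
    z[, cols] <- (vals - mu) / sdev
  }
  if (vec_in) setNames(z[1, ], colnames(m)) else z
}

#' Panel score: increased-risk minus decreased-risk members
#'
#' @param z Z-scored markers x visits matrix (see [zscore_by_stratum()]).
#' @param panel Tibble `probeset_id`, `direction` with direction in
#'   \{"increased_risk", "decreased_risk"\}.
#' @return Named numeric vector of per-visit panel scores.
#' @export
panel_score <- function(z, panel) {
  stopifnot(all(c("probeset_id", "direction") %in% names(panel)),
            nrow(panel) > 0, !anyDuplicated(panel$probeset_id))
  missing <- setdiff(panel$probeset_id, rownames(z))
  if (length(missing) > 0) {
    stop("panel member(s) missing from matrix: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  sign <- ifelse(panel$direction == "increased_risk", 1,
                 ifelse(panel$direction == "decreased_risk", -1, NA))
  if (anyNA(sign)) stop("panel direction must be increased_risk or decreased_risk",
                        call. = FALSE)
  colSums(z[panel$probeset_id, , drop = FALSE] * sign)
}

#' Longitudinal measures for one subject's visit sequence
#'
#' For each visit from the second onward, computes the four longitudinal
#' quantities on the (non-Z-scored) level series: current level, slope
#' (ratio of current to previous level divided by days between the
#' visits), running maximum level over current and past visits (running
#' minimum for decreased markers), and running maximum slope.
#'
#' @param levels Numeric vector of marker levels in visit order.
#' @param days Strictly increasing visit days.
#' @param direction "increased" (running max of levels) or "decreased"
#'   (running min).
#' @return Tibble with one row per visit from the second on: `index`,
#'   `level`, `slope`, `extreme_level`, `max_slope`.
#' @export
longitudinal_measure <- function(levels, days, direction = c("increased", "decreased")) {
  direction <- match.arg(direction)
  stopifnot(length(levels) == length(days), length(levels) >= 2)
  dd <- diff(days)
  if (any(dd <= 0)) stop("visit days must be strictly increasing", call. = FALSE)
  prev <- levels[-length(levels)]
  cur <- levels[-1]
  slope <- (cur / prev) / dd
  if (any(prev == 0)) {
    warning("previous level 0: slope undefined for some visit(s), excluded")
    slope[prev == 0] <- NA_real_
  }
  extreme <- if (direction == "increased") cummax(levels) else cummin(levels)
  tibble::tibble(
    index = seq_along(cur) + 1L,
    level = cur,
    slope = slope,
    extreme_level = extreme[-1],
    max_slope = cummax(ifelse(is.na(slope), -Inf, slope))
  ) %>%
    mutate(max_slope = ifelse(is.infinite(.data$max_slope), NA_real_,
                              .data$max_slope))
}

#' Longitudinal composite measure across a cohort
#'
#' Applies [longitudinal_measure()] to every subject with at least two
#' visits, Z-scores each of the four measures by gender x diagnosis across
#' the contributing visits, and sums them into a single per-visit
#' composite. Single-visit subjects contribute nothing.
#'
#' @param values Named numeric vector of per-visit marker levels (raw,
#'   positive scale — ratios are taken on it).
#' @param visits Tibble with `visit_id`, `subject_id`, `day`, `gender`,
#'   `diagnosis`.
#' @param direction Marker direction for the running-extreme choice.
#' @return Named numeric vector of composites for visits with >= 1 prior
#'   visit.
#' @export
longitudinal_composite <- function(values, visits,
                                   direction = c("increased", "decreased")) {
  direction <- match.arg(direction)
  v <- visits %>% arrange(.data$subject_id, .data$day)
  per_subject <- split(v, v$subject_id)
  rows <- lapply(per_subject, function(sv) {
    if (nrow(sv) < 2) return(NULL)
    lm <- longitudinal_measure(values[sv$visit_id], sv$day, direction)
    lm$visit_id <- sv$visit_id[lm$index]
    lm
  })
  meas <- bind_rows(rows)
  if (nrow(meas) == 0) return(setNames(numeric(0), character(0)))
  meas <- meas[complete.cases(meas[, c("level", "slope", "extreme_level", "max_slope")]), ]
  mat <- t(as.matrix(meas[, c("level", "slope", "extreme_level", "max_slope")]))
  colnames(mat) <- meas$visit_id
  z <- zscore_by_stratum(mat, visits)
  setNames(colSums(z), colnames(z))
}

#' Rank-based (Mann-Whitney) AUC and one-sided p value
#'
#' AUC is the probability that a randomly chosen case scores higher than a
#' randomly chosen control, computed from midranks (ties at 0.5). The p
#' value is from the one-sided normal approximation to the Mann-Whitney U
#' statistic with tie correction and no continuity correction, testing
#' AUC > 0.5.
#'
#' @param scores Numeric scores (higher = predicted case).
#' @param is_case Logical labels.
#' @return List with `auc`, `p_value`, `n_case`, `n_control`.
#' @export
mann_whitney_auc <- function(scores, is_case) {
  stopifnot(length(scores) == length(is_case))
  n1 <- sum(is_case)
  n0 <- sum(!is_case)
  if (n1 == 0 || n0 == 0) {
    stop("need at least one case and one control", call. = FALSE)
  }
  r <- rank(scores)
  u <- sum(r[is_case]) - n1 * (n1 + 1) / 2
  auc <- u / (n1 * n0)
  n <- n1 + n0
  ties <- table(scores)
  sigma2 <- (n1 * n0 / 12) * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  p <- if (sigma2 <= 0) 1 else pnorm((u - n1 * n0 / 2) / sqrt(sigma2),
                                     lower.tail = FALSE)
  list(auc = auc, p_value = p, n_case = n1, n_control = n0)
}

# Visit subsets for the ALL / by-gender / by-gender-and-diagnosis analyses.
analysis_groups <- function(visits, grouping = c("ALL", "gender", "gender_dx")) {
  grouping <- match.arg(grouping)
  if (grouping == "ALL") {
    return(list(ALL = visits$visit_id))
  }
  key <- if (grouping == "gender") visits$gender else
    paste(visits$gender, visits$diagnosis, sep = "-")
  split(visits$visit_id, key)
}

#' Predict low-memory state by ROC analysis
#'
#' Visits with Retention at or below `cutoff` form the Low Memory class;
#' the marker's risk-oriented score is tested against that label with a
#' rank-based AUC per group. Groups without both classes are reported as
#' untestable rather than raising an error.
#'
#' @param scores Named per-visit risk scores (higher = more at risk of low
#'   memory).
#' @param visits Tibble with `visit_id`, `retention`, `gender`,
#'   `diagnosis`.
#' @param marker Marker/panel label for the report.
#' @param mode "C" (cross-sectional) or "L" (longitudinal), a report
#'   label.
#' @param cutoff Low-memory Retention cutoff (default 40).
#' @param grouping "ALL", "gender" or "gender_dx".
#' @return Tibble: `group_type`, `group`, `marker`, `mode`, `n_low`,
#'   `n_total`, `auc`, `p_value`, `testable`.
#' @export
predict_state <- function(scores, visits, marker = "marker", mode = "C",
                          cutoff = 40,
                          grouping = c("ALL", "gender", "gender_dx")) {
  grouping <- match.arg(grouping)
  visits <- visits %>% filter(.data$visit_id %in% names(scores))
  groups <- analysis_groups(visits, grouping)
  rows <- lapply(names(groups), function(g) {
    ids <- groups[[g]]
    ret <- visits$retention[match(ids, visits$visit_id)]
    low <- ret <= cutoff
    if (sum(low) == 0 || sum(!low) == 0) {
      return(tibble::tibble(group_type = grouping, group = g, marker = marker,
                            mode = mode, n_low = sum(low), n_total = length(ids),
                            auc = NA_real_, p_value = NA_real_, testable = FALSE))
    }
    res <- mann_whitney_auc(scores[ids], low)
    tibble::tibble(group_type = grouping, group = g, marker = marker,
                   mode = mode, n_low = res$n_case, n_total = length(ids),
                   auc = res$auc, p_value = res$p_value, testable = TRUE)
  })
  bind_rows(rows)
}

#' Predict future positive neuropsychological testing by Cox regression
#'
#' Fits a proportional-hazards model per group with the risk-oriented
#' marker measure as sole covariate, on the time in days from each lab
#' visit to the positive neuropsychological test (censored visits use the
#' follow-up end). With a risk-oriented covariate, a hazard ratio above 1
#' means the marker's stated risk direction carries increased risk.
#'
#' @param scores Named per-visit risk scores.
#' @param visits Tibble with `visit_id`, `subject_id`, `event_day`,
#'   `neuropsych_event`, `gender`, `diagnosis`.
#' @param marker,mode Report labels.
#' @param grouping "ALL", "gender" or "gender_dx".
#' @param robust Cluster-by-subject robust variance (visits of one subject
#'   are repeated observations); off by default.
#' @return Tibble: `group_type`, `group`, `marker`, `mode`, `n_events`,
#'   `n_total`, `hazard_ratio`, `p_value`, `testable`, `converged`.
#' @export
predict_trait <- function(scores, visits, marker = "marker", mode = "C",
                          grouping = c("ALL", "gender", "gender_dx"),
                          robust = FALSE) {
  grouping <- match.arg(grouping)
  visits <- visits %>% filter(.data$visit_id %in% names(scores))
  groups <- analysis_groups(visits, grouping)
  rows <- lapply(names(groups), function(g) {
    ids <- groups[[g]]
    d <- visits[match(ids, visits$visit_id), ]
    base <- tibble::tibble(group_type = grouping, group = g, marker = marker,
                           mode = mode, n_events = sum(d$neuropsych_event),
                           n_total = nrow(d), hazard_ratio = NA_real_,
                           p_value = NA_real_, testable = FALSE,
                           converged = NA)
    if (sum(d$neuropsych_event) == 0) return(base)
    dat <- data.frame(time = d$event_day, event = d$neuropsych_event,
                      score = as.numeric(scores[ids]), subject = d$subject_id)
    warned <- FALSE
    fit <- tryCatch({
      withCallingHandlers({
        if (robust) {
          survival::coxph(survival::Surv(time, event) ~ score +
                            survival::cluster(subject), data = dat)
        } else {
          survival::coxph(survival::Surv(time, event) ~ score, data = dat)
        }
      }, warning = function(w) {
        warned <<- TRUE
        invokeRestart("muffleWarning")
      })
    }, error = function(e) NULL)
    base$testable <- TRUE
    if (is.null(fit)) {
      base$converged <- FALSE
      return(base)
    }
    s <- summary(fit)
    base$hazard_ratio <- unname(exp(stats::coef(fit)["score"]))
    base$p_value <- unname(s$coefficients["score", "Pr(>|z|)"])
    base$converged <- !warned
    base
  })
  bind_rows(rows)
}

#' Cross-sectional and longitudinal scores for a panel
#'
#' Cross-sectional: stratum-Z-scored members combined by
#' [panel_score()]. Longitudinal: per-member longitudinal composites
#' (running extrema chosen by each member's risk direction) combined
#' increased-risk minus decreased-risk.
#'
#' @param expr Probesets x visits log2 expression matrix.
#' @param visits Visit tibble.
#' @param panel Panel definition tibble (`probeset_id`, `direction`).
#' @return List with named vectors `cross_sectional` (all visits) and
#'   `longitudinal` (visits with a prior visit).
#' @export
panel_measures <- function(expr, visits, panel) {
  z <- zscore_by_stratum(expr[panel$probeset_id, , drop = FALSE], visits)
  cs <- panel_score(z, panel)
  comp <- lapply(seq_len(nrow(panel)), function(i) {
    dirn <- if (panel$direction[i] == "increased_risk") "increased" else "decreased"
    longitudinal_composite(expr[panel$probeset_id[i], ], visits, dirn)
  })
  common <- Reduce(intersect, lapply(comp, names))
  sign <- ifelse(panel$direction == "increased_risk", 1, -1)
  long <- Reduce(`+`, lapply(seq_along(comp),
                             function(i) sign[i] * comp[[i]][common]))
  names(long) <- common
  list(cross_sectional = cs, longitudinal = long)
}
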