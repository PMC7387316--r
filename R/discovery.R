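# Step 1: within-subject discovery of probesets tracking memory retention.
# Qualifying consecutive visit pairs (>= 20% relative change in Retention)
# are scored per probeset by fold change (DE) or detection-call flips (AP),
# summed across all pairs and subjects into raw scores, and converted to
# internal points at 33.3/50/80% of the maximum absolute raw score.

#' Select qualifying high/low memory comparison pairs
#'
#' Scans each subject's visits in day order and keeps every consecutive
#' pair whose relative Retention change versus the earlier visit is at
#' least `change_threshold`. The visit with the higher Retention is labeled
#' `high`. An earlier retention of exactly 0 qualifies whenever the later
#' retention is positive (treated as a maximal change).
#'
#' @param visits Tibble with `visit_id`, `subject_id`, `day`, `retention`.
#' @param change_threshold Minimum relative change (default 0.20).
#' @return Tibble of comparison pairs: `subject_id`, `high_visit_id`,
#'   `low_visit_id`, `retention_high`, `retention_low`, `relative_change`.
#' @export
select_comparison_pairs <- function(visits, change_threshold = 0.20) {
  stopifnot(all(c("visit_id", "subject_id", "day", "retention") %in% names(visits)))
  v <- visits %>% arrange(.data$subject_id, .data$day)
  v <- v %>%
    group_by(.data$subject_id) %>%
    mutate(
      prev_visit = lag(.data$visit_id),
      prev_ret = lag(.data$retention)
    ) %>%
    ungroup() %>%
    filter(!is.na(.data$prev_visit))
  if (nrow(v) == 0) return(empty_pairs())

  missing <- is.na(v$retention) | is.na(v$prev_ret)
  if (any(missing)) {
    warning(sprintf("%d consecutive pair(s) skipped: missing retention", sum(missing)))
    v <- v[!missing, , drop = FALSE]
  }
  zero_base <- v$prev_ret == 0
  if (any(zero_base)) {
    warning(sprintf("%d pair(s) with earlier retention 0: qualify iff later retention > 0",
                    sum(zero_base)))
  }
  rel <- ifelse(zero_base,
                ifelse(v$retention > 0, Inf, 0),
                abs(v$retention - v$prev_ret) / v$prev_ret)
  keep <- rel >= change_threshold
  v <- v[keep, , drop = FALSE]
  rel <- rel[keep]
  if (nrow(v) == 0) return(empty_pairs())

  high_is_current <- v$retention >= v$prev_ret
  tibble::tibble(
    subject_id = v$subject_id,
    high_visit_id = ifelse(high_is_current, v$visit_id, v$prev_visit),
    low_visit_id = ifelse(high_is_current, v$prev_visit, v$visit_id),
    retention_high = pmax(v$retention, v$prev_ret),
    retention_low = pmin(v$retention, v$prev_ret),
    relative_change = rel
  )
}

empty_pairs <- function() {
  tibble::tibble(
    subject_id = character(), high_visit_id = character(),
    low_visit_id = character(), retention_high = numeric(),
    retention_low = numeric(), relative_change = numeric()
  )
}

# DE score from a high-minus-low log2 difference: +/-1 at >= 1.2-fold,
# +/-0.5 between 1.1- and 1.2-fold, 0 below 1.1-fold (closed at both cuts).
de_score_from_log2diff <- function(d) {
  a <- abs(d)
  mag <- ifelse(a >= log2(1.2), 1, ifelse(a >= log2(1.1), 0.5, 0))
  sign(d) * mag
}

#' DE-score one comparison pair
#'
#' Fold change between the high- and low-memory visit of a pair, per
#' probeset: at least 1.2-fold up gives +1 (increased in high memory),
#' at least 1.2-fold down gives -1; folds in \[1.1, 1.2) give +/-0.5;
#' below 1.1-fold gives 0.
#'
#' @param expr Probesets x visits log2 expression matrix.
#' @param pair One-row comparison-pair tibble (see
#'   [select_comparison_pairs()]).
#' @return Tibble `probeset_id`, `score`.
#' @export
score_pair_de <- function(expr, pair) {
  check_pair_columns(expr, pair)
  d <- expr[, pair$high_visit_id] - expr[, pair$low_visit_id]
  tibble::tibble(probeset_id = rownames(expr),
                 score = unname(de_score_from_log2diff(d)))
}

#' AP-score one comparison pair
#'
#' Detection-call flips between the high- and low-memory visit: Present in
#' high and Absent in low scores +1 (gene turning on with high memory),
#' Absent in high and Present in low scores -1, anything else 0.
#'
#' @param calls Probesets x visits matrix of "P"/"A" calls.
#' @param pair One-row comparison-pair tibble.
#' @return Tibble `probeset_id`, `score`.
#' @export
score_pair_ap <- function(calls, pair) {
  check_pair_columns(calls, pair)
  hi <- calls[, pair$high_visit_id]
  lo <- calls[, pair$low_visit_id]
  score <- (hi == "P" & lo == "A") - (hi == "A" & lo == "P")
  tibble::tibble(probeset_id = rownames(calls), score = unname(as.numeric(score)))
}

check_pair_columns <- function(mat, pair) {
  missing <- setdiff(c(pair$high_visit_id, pair$low_visit_id), colnames(mat))
  if (length(missing) > 0) {
    stop("visit column(s) missing from matrix: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Sum per-pair comparison scores into raw scores
#'
#' @param scores Long tibble of per-pair scores (`probeset_id`, `score`),
#'   e.g. row-bound outputs of [score_pair_de()] over all pairs.
#' @return Tibble `probeset_id`, `raw_score`.
#' @export
sum_raw_scores <- function(scores) {
  scores %>%
    group_by(.data$probeset_id) %>%
    summarise(raw_score = sum(.data$score), .groups = "drop")
}

# Vectorized raw scores over all pairs at once (same result as summing
# score_pair_* over a per-pair loop; the loop is kept as the test oracle).
raw_scores_matrix <- function(mat, pairs, method = c("DE", "AP")) {
  method <- match.arg(method)
  if (nrow(pairs) == 0) {
    return(tibble::tibble(probeset_id = rownames(mat),
                          raw_score = rep(0, nrow(mat))))
  }
  for (i in seq_len(nrow(pairs))) check_pair_columns(mat, pairs[i, ])
  hi <- mat[, pairs$high_visit_id, drop = FALSE]
  lo <- mat[, pairs$low_visit_id, drop = FALSE]
  s <- if (method == "DE") {
    de_score_from_log2diff(hi - lo)
  } else {
    (hi == "P" & lo == "A") - (hi == "A" & lo == "P")
  }
  tibble::tibble(probeset_id = rownames(mat), raw_score = unname(rowSums(s)))
}

#' Internal discovery points from percent-of-maximum raw score
#'
#' Probesets at or above 33.3% of the maximum absolute raw score receive 2
#' points, at or above 50% receive 4 points, and at or above 80% receive 6
#' points.
#'
#' @param percent_of_max Numeric vector of percentages in \[0, 100\].
#' @return Integer vector of points in \{0, 2, 4, 6\}.
#' @export
internal_points <- function(percent_of_max) {
  ifelse(percent_of_max >= 80, 6L,
         ifelse(percent_of_max >= 50, 4L,
                ifelse(percent_of_max >= 33.3, 2L, 0L)))
}

#' Convert raw scores to internal discovery points
#'
#' `percent_of_max` is 100 * |raw| / max |raw| within the method; internal
#' points follow the 33.3/50/80% tiers of [internal_points()]; direction is
#' the sign of the raw score.
#'
#' @param raw_scores Tibble `probeset_id`, `raw_score`.
#' @param method "DE" or "AP" (recorded in the output).
#' @return Tibble `probeset_id`, `method`, `raw_score`, `percent_of_max`,
#'   `direction`, `internal_points`.
#' @export
assign_internal_points <- function(raw_scores, method = c("DE", "AP")) {
  method <- match.arg(method)
  max_abs <- max(abs(raw_scores$raw_score))
  if (max_abs == 0) {
    warning("all raw scores are zero; all internal points set to 0")
    pct <- rep(0, nrow(raw_scores))
  } else {
    pct <- 100 * abs(raw_scores$raw_score) / max_abs
  }
  tibble::tibble(
    probeset_id = raw_scores$probeset_id,
    method = method,
    raw_score = raw_scores$raw_score,
    percent_of_max = pct,
    direction = ifelse(raw_scores$raw_score > 0, "increased",
                       ifelse(raw_scores$raw_score < 0, "decreased", "none")),
    internal_points = internal_points(pct)
  )
}

#' Combine DE and AP internal points per probeset
#'
#' The combined internal score is the maximum over methods; the direction
#' is that of the max-scoring method (ties broken by higher
#' percent-of-max, then DE). Probesets where the two methods give nonzero
#' points in opposite directions are flagged.
#'
#' @param de,ap Per-method tibbles from [assign_internal_points()]; `ap`
#'   may be `NULL` if no detection calls are available.
#' @return Tibble `probeset_id`, `internal_points`, `direction`,
#'   `max_abs_raw`, `conflict`.
#' @export
combine_methods <- function(de, ap = NULL) {
  if (is.null(ap)) {
    return(tibble::tibble(
      probeset_id = de$probeset_id,
      internal_points = de$internal_points,
      direction = de$direction,
      max_abs_raw = abs(de$raw_score),
      conflict = FALSE
    ))
  }
  m <- left_join(de, ap, by = "probeset_id", suffix = c("_de", "_ap"))
  de_wins <- m$internal_points_de > m$internal_points_ap |
    (m$internal_points_de == m$internal_points_ap &
       m$percent_of_max_de >= m$percent_of_max_ap)
  tibble::tibble(
    probeset_id = m$probeset_id,
    internal_points = pmax(m$internal_points_de, m$internal_points_ap),
    direction = ifelse(de_wins, m$direction_de, m$direction_ap),
    max_abs_raw = pmax(abs(m$raw_score_de), abs(m$raw_score_ap)),
    conflict = m$internal_points_de > 0 & m$internal_points_ap > 0 &
      m$direction_de != m$direction_ap
  )
}

#' Run the full discovery step
#'
#' Pairs visits, scores every probeset by the DE method (and the AP method
#' when calls are given), sums raw scores, assigns internal points and
#' combines the methods.
#'
#' @param expr Probesets x visits log2 expression matrix.
#' @param visits Visit tibble.
#' @param calls Optional "P"/"A" call matrix.
#' @param annotation Optional probeset-to-gene tibble.
#' @param change_threshold Retention change threshold for pairing.
#' @return List of class `discovery_result` with `pairs`, `per_method`
#'   (long tibble over methods) and `combined` (per-probeset tibble with
#'   gene symbols when annotation is given).
#' @export
run_discovery <- function(expr, visits, calls = NULL, annotation = NULL,
                          change_threshold = 0.20) {
  pairs <- select_comparison_pairs(visits, change_threshold)
  de <- assign_internal_points(raw_scores_matrix(expr, pairs, "DE"), "DE")
  ap <- NULL
  if (!is.null(calls)) {
    ap <- assign_internal_points(raw_scores_matrix(calls, pairs, "AP"), "AP")
  }
  combined <- combine_methods(de, ap)
  if (!is.null(annotation)) {
    combined <- left_join(combined, annotation, by = "probeset_id")
  }
  out <- list(pairs = pairs, per_method = bind_rows(de, ap), combined = combined)
  class(out) <- "discovery_result"
  out
}

#' @export
print.discovery_result <- function(x, ...) {
  cat(sprintf(
    "<discovery_result> %d pairs; %d/%d probesets with internal points >= 2\n",
    nrow(x$pairs), sum(x$combined$internal_points >= 2), nrow(x$combined)
  ))
  invisible(x)
}
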