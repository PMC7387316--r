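# Step 2: Convergent Functional Genomics (CFG) prioritization. Candidate
# genes are scored against a curated evidence database; each line of
# evidence is capped so that one positive study already earns the line's
# full weight (avoiding popularity bias), human evidence outweighs
# nonhuman, and brain expression outweighs peripheral or genetic evidence.

#' The six lines of literature evidence
#' @return Character vector of valid `line` values.
#' @export
evidence_lines <- function() {
  c("human_genetic", "human_brain_expression", "human_peripheral_expression",
    "nonhuman_genetic", "nonhuman_brain_expression", "nonhuman_peripheral_expression")
}

#' Capped line-of-evidence weights
#'
#' Default caps: human genetic 2, human brain expression 4, human
#' peripheral expression 2, nonhuman genetic 1, nonhuman brain expression
#' 2, nonhuman peripheral expression 1 — a maximum external score of 12.
#'
#' @return Named numeric vector over [evidence_lines()].
#' @export
line_weights <- function() {
  c(human_genetic = 2, human_brain_expression = 4,
    human_peripheral_expression = 2, nonhuman_genetic = 1,
    nonhuman_brain_expression = 2, nonhuman_peripheral_expression = 1)
}

validate_evidence <- function(records) {
  needed <- c("gene_symbol", "line")
  if (!all(needed %in% names(records))) {
    stop("evidence records need columns gene_symbol and line", call. = FALSE)
  }
  bad <- !records$line %in% evidence_lines()
  if (any(bad)) {
    stop("unknown evidence line category in record(s) for gene(s): ",
         paste(unique(records$gene_symbol[bad]), collapse = ", "),
         call. = FALSE)
  }
  invisible(records)
}

#' External CFG score from evidence records
#'
#' Sums the line caps over the distinct lines on which a gene has at least
#' one record (after filtering to `disorder`); additional studies on an
#' already-counted line add nothing.
#'
#' @param records Evidence tibble (`gene_symbol`, `line`, optional
#'   `disorder_tag`, ...).
#' @param weights Named caps, default [line_weights()].
#' @param disorder Keep only records with this `disorder_tag` (default
#'   "AD"); `NULL` keeps all records.
#' @param genes Optional gene universe; genes without evidence get 0.
#' @return Tibble `gene_symbol`, `external_points`.
#' @export
score_external <- function(records, weights = line_weights(), disorder = "AD",
                           genes = NULL) {
  validate_evidence(records)
  if (!is.null(disorder) && "disorder_tag" %in% names(records)) {
    records <- records %>% filter(.data$disorder_tag %in% disorder)
  }
  scored <- records %>%
    distinct(.data$gene_symbol, .data$line) %>%
    mutate(points = unname(weights[.data$line])) %>%
    group_by(.data$gene_symbol) %>%
    summarise(external_points = sum(.data$points), .groups = "drop")
  if (!is.null(genes)) {
    scored <- tibble::tibble(gene_symbol = unique(genes)) %>%
      left_join(scored, by = "gene_symbol") %>%
      mutate(external_points = ifelse(is.na(.data$external_points), 0,
                                      .data$external_points))
  }
  scored
}

#' Total CFG score
#'
#' Internal discovery points (0/2/4/6) plus external literature points
#' (0-12), for a maximum of 18.
#'
#' @param internal_points Vector of internal points in \{0, 2, 4, 6\}.
#' @param external_points Vector of external points in \[0, 12\].
#' @return Numeric vector of totals.
#' @export
total_cfg <- function(internal_points, external_points) {
  if (!all(internal_points %in% c(0, 2, 4, 6))) {
    stop("internal_points must be in {0, 2, 4, 6}", call. = FALSE)
  }
  if (any(external_points < 0 | external_points > 12)) {
    stop("external_points must be in [0, 12]", call. = FALSE)
  }
  internal_points + external_points
}

#' Prioritize discovery candidates by CFG score
#'
#' Broadcasts gene-level external evidence scores to all probesets of each
#' gene (internal points stay probeset-level), totals them, and flags
#' probesets at or above the selection threshold.
#'
#' @param combined Combined discovery tibble from [run_discovery()]
#'   (`probeset_id`, `internal_points`, `direction`, `max_abs_raw`,
#'   `gene_symbol`).
#' @param evidence Evidence record tibble.
#' @param weights Line caps.
#' @param disorder Disorder filter for [score_external()].
#' @param threshold Selection threshold on the total (default 10).
#' @return Tibble sorted by (total desc, |raw| desc, probeset_id) with
#'   columns `probeset_id`, `gene_symbol`, `direction`, `internal_points`,
#'   `external_points`, `total`, `selected`.
#' @export
cfg_prioritize <- function(combined, evidence, weights = line_weights(),
                           disorder = "AD", threshold = 10) {
  stopifnot("gene_symbol" %in% names(combined))
  ext <- score_external(evidence, weights, disorder,
                        genes = combined$gene_symbol)
  out <- combined %>%
    left_join(ext, by = "gene_symbol") %>%
    mutate(
      external_points = ifelse(is.na(.data$external_points), 0,
                               .data$external_points),
      total = total_cfg(.data$internal_points, .data$external_points),
      selected = .data$total >= threshold
    ) %>%
    arrange(dplyr::desc(.data$total), dplyr::desc(.data$max_abs_raw),
            .data$probeset_id)
  out
}

#' Select candidate probesets at a CFG threshold
#'
#' @param scores Prioritization tibble with `total`, `max_abs_raw`,
#'   `probeset_id`, `gene_symbol`.
#' @param threshold Minimum total CFG score (default 10).
#' @return The selected rows, sorted by (total desc, |raw| desc,
#'   probeset_id); the number of unique genes is attached as attribute
#'   `n_genes`.
#' @export
select_candidates <- function(scores, threshold = 10) {
  sel <- scores %>%
    filter(.data$total >= threshold) %>%
    arrange(dplyr::desc(.data$total), dplyr::desc(.data$max_abs_raw),
            .data$probeset_id)
  attr(sel, "n_genes") <- n_distinct(sel$gene_symbol)
  sel
}
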