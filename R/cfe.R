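# Convergent Functional Evidence (CFE): a 30-point tabulation per
# biomarker — discovery internal points (<= 6), external CFG literature
# points (<= 12), and a 6/4/2/0 tier each for state and trait prediction —
# plus the enrichment arithmetic used to summarize how many probesets
# survive each step and how strongly circadian genes are over-represented.

#' Prediction-tier points for the CFE score
#'
#' 6 points if the marker significantly predicts (p < 0.05) in all
#' subjects, otherwise 4 points if in a gender group, otherwise 2 points
#' if in a gender x diagnosis subgroup, otherwise 0. The best tier
#' achieved is taken, not a sum across tiers. Applied separately to state
#' and trait result sets; cross-sectional and longitudinal results both
#' count.
#'
#' @param results Tibble of [predict_state()]/[predict_trait()] rows for
#'   one marker, with `group_type` and `p_value`.
#' @param alpha Significance level (default 0.05).
#' @return Integer points in \{0, 2, 4, 6\}.
#' @export
prediction_points <- function(results, alpha = 0.05) {
  if (is.null(results) || nrow(results) == 0) return(0L)
  sig <- results %>% filter(!is.na(.data$p_value), .data$p_value < alpha)
  if (any(sig$group_type == "ALL")) return(6L)
  if (any(sig$group_type == "gender")) return(4L)
  if (any(sig$group_type == "gender_dx")) return(2L)
  0L
}

#' Total CFE score
#'
#' Sum of discovery points (0/2/4/6), external CFG points (0-12), and the
#' state and trait prediction tiers (each 0/2/4/6); up to 30 points, 18
#' from the study's own data and 12 from the literature.
#'
#' @param discovery_points,state_points,trait_points Vectors in
#'   \{0, 2, 4, 6\}.
#' @param external_points Vector in \[0, 12\].
#' @return Numeric vector of CFE totals.
#' @export
cfe_total <- function(discovery_points, external_points, state_points,
                      trait_points) {
  tiers <- c(0, 2, 4, 6)
  if (!all(discovery_points %in% tiers)) {
    stop("discovery_points must be in {0, 2, 4, 6}", call. = FALSE)
  }
  if (any(external_points < 0 | external_points > 12)) {
    stop("external_points must be in [0, 12]", call. = FALSE)
  }
  if (!all(state_points %in% tiers) || !all(trait_points %in% tiers)) {
    stop("state and trait points must be in {0, 2, 4, 6}", call. = FALSE)
  }
  discovery_points + external_points + state_points + trait_points
}

#' Tabulate CFE scores for a set of markers
#'
#' @param prioritization Tibble with `probeset_id`, `gene_symbol`,
#'   `internal_points`, `external_points`.
#' @param state_results,trait_results Prediction result tibbles carrying a
#'   `marker` column of probeset ids.
#' @param alpha Significance level for the prediction tiers.
#' @return Tibble with the four components and `cfe_total`, sorted by
#'   total descending (ties by probeset id).
#' @export
cfe_table <- function(prioritization, state_results = NULL,
                      trait_results = NULL, alpha = 0.05) {
  rows <- lapply(seq_len(nrow(prioritization)), function(i) {
    p <- prioritization[i, ]
    st <- if (is.null(state_results)) NULL else
      state_results %>% filter(.data$marker == p$probeset_id)
    tr <- if (is.null(trait_results)) NULL else
      trait_results %>% filter(.data$marker == p$probeset_id)
    tibble::tibble(
      probeset_id = p$probeset_id,
      gene_symbol = p$gene_symbol,
      discovery_points = p$internal_points,
      external_points = p$external_points,
      state_points = prediction_points(st, alpha),
      trait_points = prediction_points(tr, alpha)
    )
  })
  bind_rows(rows) %>%
    mutate(cfe_total = cfe_total(.data$discovery_points, .data$external_points,
                                 .data$state_points, .data$trait_points)) %>%
    arrange(dplyr::desc(.data$cfe_total), .data$probeset_id)
}

#' Fold enrichment of a gene set among selected candidates
#'
#' Compares the fraction of set members among selected candidates with the
#' fraction in a reference universe (e.g. circadian genes in the genome).
#'
#' @param selected_in_set Selected candidates belonging to the set.
#' @param selected_total All selected candidates.
#' @param reference_in_set Set members in the reference universe.
#' @param reference_total Size of the reference universe.
#' @return List: `selected_fraction` and `reference_fraction` (percent),
#'   `fold`, and the input counts.
#' @export
enrichment_fold <- function(selected_in_set, selected_total,
                            reference_in_set, reference_total) {
  stopifnot(selected_total > 0, reference_total > 0,
            selected_in_set <= selected_total,
            reference_in_set <= reference_total)
  sel <- 100 * selected_in_set / selected_total
  ref <- 100 * reference_in_set / reference_total
  if (ref == 0) stop("reference fraction is zero; fold undefined", call. = FALSE)
  list(
    selected_in_set = selected_in_set, selected_total = selected_total,
    reference_in_set = reference_in_set, reference_total = reference_total,
    selected_fraction = sel, reference_fraction = ref, fold = sel / ref
  )
}

#' Probeset survival fold
#'
#' How many times the candidate pool shrank relative to the full array:
#' `n_total / n_survivors`.
#'
#' @param n_survivors Probesets surviving a step (> 0).
#' @param n_total Probesets on the array.
#' @return The fold (numeric).
#' @export
survival_fold <- function(n_survivors, n_total) {
  stopifnot(n_total > 0, n_survivors <= n_total)
  if (n_survivors <= 0) stop("zero survivors; fold undefined", call. = FALSE)
  n_total / n_survivors
}

#' Render a fold at reporting precision
#'
#' Nearest 0.1 below 10, nearest integer from 10 to 100, nearest hundred
#' above 100 — the rendering used in prose such as "5-fold", "2.4-fold",
#' "400-fold".
#'
#' @param fold Numeric fold value(s).
#' @return Numeric rounded fold(s).
#' @export
render_fold <- function(fold) {
  ifelse(fold < 10, round(fold, 1),
         ifelse(fold <= 100, round(fold), round(fold / 100) * 100))
}

#' Circadian clock gene database summary
#'
#' Class sizes of the compiled clock-gene database: core clock genes (the
#' engine of circadian function), immediate genes (direct input/output to
#' the core clock), and distant genes (input/output to the immediate
#' ones), with the genome size used as reference universe.
#'
#' @param core,immediate,distant Class sizes (defaults 18, 331, 1119).
#' @param genome_size Reference gene universe (default 21000).
#' @param genes Optional tibble `gene_symbol`, `class` listing members;
#'   when given, class counts are tallied from it.
#' @return List of class `clock_gene_db` with `counts`, `total`,
#'   `genome_size` and optional `genes`.
#' @export
clock_gene_db <- function(core = 18, immediate = 331, distant = 1119,
                          genome_size = 21000, genes = NULL) {
  if (!is.null(genes)) {
    stopifnot(all(c("gene_symbol", "class") %in% names(genes)))
    if (anyDuplicated(genes$gene_symbol)) {
      stop("each clock gene must have exactly one class", call. = FALSE)
    }
    if (!all(genes$class %in% c("core", "immediate", "distant"))) {
      stop("clock gene class must be core, immediate or distant", call. = FALSE)
    }
    tab <- table(factor(genes$class, levels = c("core", "immediate", "distant")))
    core <- tab[["core"]]; immediate <- tab[["immediate"]]; distant <- tab[["distant"]]
  }
  out <- list(
    counts = c(core = core, immediate = immediate, distant = distant),
    total = core + immediate + distant,
    genome_size = genome_size,
    genes = genes
  )
  class(out) <- "clock_gene_db"
  out
}

#' Circadian enrichment of a candidate gene list
#'
#' @param n_circadian Candidate genes with circadian evidence.
#' @param n_candidates Total candidate genes.
#' @param db A [clock_gene_db()].
#' @return [enrichment_fold()] result with a `fold_rendered` element.
#' @export
clock_enrichment <- function(n_circadian, n_candidates, db = clock_gene_db()) {
  res <- enrichment_fold(n_circadian, n_candidates, db$total, db$genome_size)
  res$fold_rendered <- render_fold(res$fold)
  res
}

#' Cross-disorder evidence annotation
#'
#' For each gene, the set of disorders with at least one evidence record
#' (duplicates count once), plus the percent of the input genes carrying
#' each disorder tag. Pharmacogenomic annotations travel through the same
#' path as "drug:<name>" tags.
#'
#' @param genes Character vector of gene symbols.
#' @param evidence Evidence tibble with `gene_symbol`, `disorder_tag`.
#' @return List with `per_gene` (tibble gene_symbol, disorders) and
#'   `summary` (tibble disorder, n_genes, percent).
#' @export
annotate_cross_disorder <- function(genes, evidence) {
  genes <- unique(genes)
  hits <- evidence %>%
    filter(.data$gene_symbol %in% genes, !is.na(.data$disorder_tag)) %>%
    distinct(.data$gene_symbol, .data$disorder_tag)
  per_gene <- tibble::tibble(gene_symbol = genes) %>%
    left_join(
      hits %>%
        group_by(.data$gene_symbol) %>%
        summarise(disorders = paste(sort(.data$disorder_tag), collapse = ";"),
                  .groups = "drop"),
      by = "gene_symbol"
    ) %>%
    mutate(disorders = ifelse(is.na(.data$disorders), "", .data$disorders))
  summary <- hits %>%
    group_by(disorder = .data$disorder_tag) %>%
    summarise(n_genes = n_distinct(.data$gene_symbol), .groups = "drop") %>%
    mutate(percent = 100 * .data$n_genes / length(genes)) %>%
    arrange(dplyr::desc(.data$percent), .data$disorder)
  list(per_gene = per_gene, summary = summary)
}
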