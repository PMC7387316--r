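# End-to-end pipeline driver: simulate (or load) a cohort, discover,
# prioritize, predict state and trait, tabulate CFE and enrichment, and
# write every stage table plus a run manifest with input digests.

#' Run the full biomarker pipeline on a synthetic cohort
#'
#' Executes simulate -> discover -> prioritize -> predict-state ->
#' predict-trait -> cfe -> enrich, writing one TSV per stage, a JSON
#' summary and a run manifest into `out_dir`. All randomness flows through
#' `config$seed`; two runs with the same configuration produce
#' byte-identical stage outputs.
#'
#' @param config A [cohort_config()]; its `seed` governs the run.
#' @param out_dir Output directory (created if needed).
#' @param cfg_threshold CFG selection threshold (default 10).
#' @param evidence Optional evidence tibble; defaults to a
#'   [synthetic_evidence()] database planted on the simulated truth.
#' @param top_markers How many selected candidates are additionally tested
#'   one by one in the prediction stages (default 10).
#' @return The run manifest (list), invisibly; also written as
#'   `manifest.json`.
#' @export
run_pipeline <- function(config = cohort_config(), out_dir,
                         cfg_threshold = 10, evidence = NULL,
                         top_markers = 10) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  path <- function(f) file.path(out_dir, f)
  stages <- character(0)

  run_stage <- function(name, f) {
    tryCatch(f(), error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }

  # -- simulate ------------------------------------------------------------
  cohort <- run_stage("simulate", function() simulate_cohort(config))
  write_expression(cohort$expression, path("expression.tsv"))
  write_calls(cohort$calls, path("calls.tsv"))
  write_metadata(cohort$visits, path("metadata.tsv"))
  readr::write_tsv(cohort$truth, path("truth.tsv"))
  stages <- c(stages, "simulate")

  annotation <- synthetic_annotation(rownames(cohort$expression))
  if (is.null(evidence)) {
    evidence <- synthetic_evidence(cohort$truth, annotation, seed = config$seed)
  }
  readr::write_tsv(evidence, path("evidence.tsv"))

  # -- discover ------------------------------------------------------------
  disc <- run_stage("discover", function() {
    run_discovery(cohort$expression, cohort$visits, cohort$calls, annotation)
  })
  readr::write_tsv(
    left_join(disc$per_method, annotation, by = "probeset_id"),
    path("discovery.tsv"))
  stages <- c(stages, "discover")

  # -- prioritize ----------------------------------------------------------
  prior <- run_stage("prioritize", function() {
    cfg_prioritize(disc$combined, evidence, threshold = cfg_threshold)
  })
  readr::write_tsv(prior, path("prioritization.tsv"))
  stages <- c(stages, "prioritize")

  candidates <- select_candidates(prior, cfg_threshold)
  # a tracking direction of "increased in high memory" means low values
  # signal low memory: the marker's risk direction is decreased_risk
  keep <- candidates$direction != "none"
  cand_panel <- tibble::tibble(
    probeset_id = candidates$probeset_id[keep],
    direction = ifelse(candidates$direction[keep] == "increased",
                       "decreased_risk", "increased_risk")
  )

  state <- trait <- NULL
  if (nrow(cand_panel) > 0) {
    meas <- suppressWarnings(panel_measures(cohort$expression, cohort$visits, cand_panel))
    marker_scores <- list(
      list(marker = "candidate_panel", mode = "C", scores = meas$cross_sectional),
      list(marker = "candidate_panel", mode = "L", scores = meas$longitudinal)
    )
    for (i in seq_len(min(top_markers, nrow(cand_panel)))) {
      single <- cand_panel[i, ]
      m <- suppressWarnings(panel_measures(cohort$expression, cohort$visits, single))
      marker_scores <- c(marker_scores, list(
        list(marker = single$probeset_id, mode = "C", scores = m$cross_sectional),
        list(marker = single$probeset_id, mode = "L", scores = m$longitudinal)
      ))
    }

    # -- predict-state -----------------------------------------------------
    state <- run_stage("predict-state", function() {
      bind_rows(lapply(marker_scores, function(ms) {
        bind_rows(lapply(c("ALL", "gender", "gender_dx"), function(g) {
          predict_state(ms$scores, cohort$visits, marker = ms$marker,
                        mode = ms$mode, grouping = g)
        }))
      }))
    })
    readr::write_tsv(state, path("state.tsv"))
    stages <- c(stages, "predict-state")

    # -- predict-trait -----------------------------------------------------
    trait <- run_stage("predict-trait", function() {
      bind_rows(lapply(marker_scores, function(ms) {
        bind_rows(lapply(c("ALL", "gender", "gender_dx"), function(g) {
          suppressWarnings(predict_trait(ms$scores, cohort$visits,
                                         marker = ms$marker, mode = ms$mode,
                                         grouping = g))
        }))
      }))
    })
    readr::write_tsv(trait, path("trait.tsv"))
    stages <- c(stages, "predict-trait")
  }

  # -- cfe -----------------------------------------------------------------
  cfe <- run_stage("cfe", function() {
    cfe_table(candidates, state, trait)
  })
  readr::write_tsv(cfe, path("cfe.tsv"))
  stages <- c(stages, "cfe")

  # -- enrich --------------------------------------------------------------
  enrich <- run_stage("enrich", function() {
    n_total <- nrow(cohort$expression)
    n_disc <- sum(disc$combined$internal_points >= 2)
    n_sel <- nrow(candidates)
    planted_genes <- annotation$gene_symbol[match(
      cohort$truth$probeset_id[cohort$truth$direction != "null"],
      annotation$probeset_id)]
    sel_planted <- sum(unique(candidates$gene_symbol) %in% planted_genes)
    list(
      discovery_survival_fold =
        if (n_disc > 0) render_fold(survival_fold(n_disc, n_total)) else NA,
      prioritization_survival_fold =
        if (n_sel > 0) render_fold(survival_fold(n_sel, n_total)) else NA,
      planted_enrichment = if (n_sel > 0) {
        enrichment_fold(sel_planted, n_distinct(candidates$gene_symbol),
                        length(unique(planted_genes)),
                        n_distinct(annotation$gene_symbol))
      } else NULL
    )
  })
  jsonlite::write_json(enrich, path("enrichment.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  stages <- c(stages, "enrich")

  # -- summary + manifest --------------------------------------------------
  summary <- list(
    n_subjects = nrow(cohort$subjects),
    n_visits = nrow(cohort$visits),
    n_probesets = nrow(cohort$expression),
    n_pairs = nrow(disc$pairs),
    n_discovery_2pt = sum(disc$combined$internal_points >= 2),
    n_selected_probesets = nrow(candidates),
    n_selected_genes = attr(candidates, "n_genes"),
    n_events = sum(cohort$visits$neuropsych_event)
  )
  jsonlite::write_json(summary, path("summary.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)

  outputs <- c("expression.tsv", "calls.tsv", "metadata.tsv", "truth.tsv",
               "evidence.tsv", "discovery.tsv", "prioritization.tsv",
               "state.tsv", "trait.tsv", "cfe.tsv", "enrichment.json",
               "summary.json")
  outputs <- outputs[file.exists(vapply(outputs, path, character(1)))]
  manifest <- list(
    tool = "memtrack",
    version = as.character(utils::packageVersion("memtrack")),
    seed = config$seed,
    config = config[setdiff(names(config), "strata")],
    strata = config$strata,
    stages = stages,
    outputs = as.list(setNames(
      unname(tools::md5sum(vapply(outputs, path, character(1)))), outputs)),
    timestamp = format(Sys.time(), tz = "UTC")
  )
  jsonlite::write_json(manifest, path("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, force = TRUE)
  invisible(manifest)
}
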