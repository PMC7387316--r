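# Readers and writers for the pipeline's TSV dialects: expression and call
# matrices (probeset rows, visit-id header), visit metadata, evidence
# databases (TSV or JSON) and panel definitions. All readers validate
# shape and vocabulary and fail with informative errors.

read_tsv_strict <- function(path, ...) {
  df <- suppressWarnings(
    readr::read_tsv(path, show_col_types = FALSE, progress = FALSE, ...))
  probs <- readr::problems(df)
  if (nrow(probs) > 0) {
    stop(sprintf("parse error in %s at line %d: expected %s, got %s", path,
                 probs$row[1] + 1L, probs$expected[1], probs$actual[1]),
         call. = FALSE)
  }
  df
}

#' Read a probeset x visit expression matrix from TSV
#'
#' Expects a header of visit ids, a first column of probeset ids, and
#' finite numeric cells. Duplicate probeset ids, ragged rows and
#' non-numeric cells are rejected with the offending location.
#'
#' @param path TSV path.
#' @return Numeric matrix with probeset rownames and visit colnames.
#' @export
read_expression <- function(path) {
  df <- read_tsv_strict(path, col_types = readr::cols(
    probeset_id = readr::col_character(), .default = readr::col_double()))
  if (names(df)[1] != "probeset_id") {
    stop("expression TSV must start with a probeset_id column", call. = FALSE)
  }
  dup <- df$probeset_id[duplicated(df$probeset_id)]
  if (length(dup) > 0) {
    stop("duplicate probeset id(s): ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$probeset_id
  if (!all(is.finite(m))) {
    bad <- which(!is.finite(m), arr.ind = TRUE)[1, ]
    stop(sprintf("non-finite expression value at probeset %s, visit %s",
                 rownames(m)[bad[1]], colnames(m)[bad[2]]), call. = FALSE)
  }
  m
}

#' Write an expression (or any numeric) matrix as TSV
#' @param mat Matrix with probeset rownames and visit colnames.
#' @param path Output path.
#' @export
write_expression <- function(mat, path) {
  df <- tibble::as_tibble(mat, rownames = "probeset_id")
  readr::write_tsv(df, path)
  invisible(path)
}

#' Read a Present/Absent call matrix from TSV
#' @param path TSV path.
#' @return Character matrix of "P"/"A".
#' @export
read_calls <- function(path) {
  df <- read_tsv_strict(path, col_types = readr::cols(.default = readr::col_character()))
  if (names(df)[1] != "probeset_id") {
    stop("calls TSV must start with a probeset_id column", call. = FALSE)
  }
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$probeset_id
  if (!all(m %in% c("P", "A"))) {
    stop("calls must be 'P' or 'A'", call. = FALSE)
  }
  m
}

#' Write a call matrix as TSV
#' @inheritParams write_expression
#' @export
write_calls <- function(mat, path) {
  df <- tibble::as_tibble(mat, rownames = "probeset_id")
  readr::write_tsv(df, path)
  invisible(path)
}

#' Read visit-level metadata from TSV
#'
#' Columns: visit_id, subject_id, gender, diagnosis, day, retention,
#' neuropsych_event, event_day.
#'
#' @param path TSV path.
#' @return Visit tibble.
#' @export
read_metadata <- function(path) {
  df <- read_tsv_strict(path, col_types = readr::cols(
    visit_id = readr::col_character(), subject_id = readr::col_character(),
    gender = readr::col_character(), diagnosis = readr::col_character(),
    day = readr::col_double(), retention = readr::col_double(),
    neuropsych_event = readr::col_logical(), event_day = readr::col_double()))
  needed <- c("visit_id", "subject_id", "gender", "diagnosis", "day", "retention")
  missing <- setdiff(needed, names(df))
  if (length(missing) > 0) {
    stop("metadata TSV missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(df$visit_id)) stop("duplicate visit ids", call. = FALSE)
  df
}

#' Write visit metadata as TSV
#' @param visits Visit tibble.
#' @param path Output path.
#' @export
write_metadata <- function(visits, path) {
  readr::write_tsv(visits, path)
  invisible(path)
}

#' Read an evidence database from TSV or JSON
#'
#' Fields: gene_symbol, line, direction, source_tag, disorder_tag; the
#' line vocabulary is validated against [evidence_lines()].
#'
#' @param path `.tsv` or `.json` path.
#' @return Evidence tibble.
#' @export
read_evidence <- function(path) {
  df <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    tibble::as_tibble(jsonlite::fromJSON(path))
  } else {
    read_tsv_strict(path, col_types = readr::cols(.default = readr::col_character()))
  }
  validate_evidence(df)
  df
}

#' Read a panel definition from TSV
#'
#' Columns: probeset_id, direction (increased_risk/decreased_risk).
#'
#' @param path TSV path.
#' @return Panel tibble.
#' @export
read_panel <- function(path) {
  df <- read_tsv_strict(path, col_types = readr::cols(.default = readr::col_character()))
  if (!all(c("probeset_id", "direction") %in% names(df))) {
    stop("panel TSV needs probeset_id and direction columns", call. = FALSE)
  }
  if (!all(df$direction %in% c("increased_risk", "decreased_risk"))) {
    stop("panel direction must be increased_risk or decreased_risk", call. = FALSE)
  }
  if (anyDuplicated(df$probeset_id)) stop("duplicate panel members", call. = FALSE)
  df
}
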