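#' Read a feature table
#'
#' Reads a subjects-by-features table of tractometry measures (or any tabular
#' features) from CSV or TSV. The first column must hold unique subject
#' identifiers; every remaining column is a numeric feature (for fiber-cluster
#' tractometry, one column per cluster). Empty cells — empty clusters in a
#' tractography parcellation, where no streamlines were assigned — are
#' zero-filled on load, so the returned table never contains missing values.
#'
#' @param path Path to a delimited text file with a header row. Files ending in
#'   `.tsv` are read as tab-separated, anything else as comma-separated.
#' @param measure_name Optional short name of the measure the table holds
#'   (e.g., `"FA"`, `"MD"`, `"NoS"`). Stored as the `measure_name` attribute.
#' @return A tibble whose first column is `subject_id` (character) and whose
#'   remaining columns are numeric features, with attribute `measure_name`.
#' @examples
#' tf <- tempfile(fileext = ".csv")
#' writeLines(c("subject_id,c1,c2", "s1,0.5,", "s2,0.4,0.7"), tf)
#' read_feature_table(tf, "FA")
#' @export
read_feature_table <- function(path, measure_name = NULL) {
  delim <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  tbl <- readr::read_delim(path, delim = delim, col_types = readr::cols(
    readr::col_character(),
    .default = readr::col_double()
  ), progress = FALSE)
  names(tbl)[1] <- "subject_id"
  as_feature_table(tbl, measure_name = measure_name)
}

#' Coerce a data frame to a validated feature table
#'
#' @param data A data frame with a subject-identifier first column and numeric
#'   feature columns. `NA` entries are zero-filled (empty-cluster convention).
#' @inheritParams read_feature_table
#' @return A tibble as described in [read_feature_table()].
#' @export
as_feature_table <- function(data, measure_name = NULL) {
  if (ncol(data) < 2) {
    abort("a feature table needs a subject-id column and at least one feature column")
  }
  tbl <- tibble::as_tibble(data)
  names(tbl)[1] <- "subject_id"
  tbl$subject_id <- as.character(tbl$subject_id)
  if (anyDuplicated(tbl$subject_id)) {
    abort("duplicate subject ids in feature table")
  }
  not_num <- !vapply(tbl[-1], is.numeric, logical(1))
  if (any(not_num)) {
    abort(paste0(
      "non-numeric feature column(s): ",
      paste(names(tbl)[-1][not_num], collapse = ", ")
    ))
  }
  tbl[-1] <- lapply(tbl[-1], function(x) {
    x[is.na(x)] <- 0
    x
  })
  if (!all(vapply(tbl[-1], function(x) all(is.finite(x)), logical(1)))) {
    abort("non-finite feature values after zero-filling")
  }
  attr(tbl, "measure_name") <- measure_name
  tbl
}

#' Write a feature table to CSV
#'
#' @param table A feature table tibble.
#' @param path Output file path (`.tsv` writes tab-separated).
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(table, path) {
  delim <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  readr::write_delim(table, path, delim = delim)
  invisible(path)
}

#' Read a score (label) table
#'
#' Continuous regression labels, one per subject: a two-column delimited file
#' `subject_id,score`. Component scores in the intended application span
#' roughly \[-3, 3\].
#'
#' @param path Path to a two-column CSV/TSV with a header.
#' @return A tibble with columns `subject_id` (character) and `score` (double).
#' @export
read_scores <- function(path) {
  delim <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  tbl <- readr::read_delim(path, delim = delim, col_types = readr::cols(
    readr::col_character(), readr::col_double()
  ), progress = FALSE)
  names(tbl) <- c("subject_id", "score")
  if (anyDuplicated(tbl$subject_id)) abort("duplicate subject ids in score table")
  if (!all(is.finite(tbl$score))) abort("scores must be finite")
  tibble::as_tibble(tbl)
}

#' Read a feature-to-category map
#'
#' Two-column file `feature_id,category` assigning every fiber cluster to an
#' anatomical tract category (association, projection, commissural, cerebellar,
#' superficial).
#'
#' @param path Path to a two-column CSV/TSV with a header.
#' @return A tibble with columns `feature_id` and `category`.
#' @export
read_category_map <- function(path) {
  delim <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  tbl <- readr::read_delim(path, delim = delim, col_types = readr::cols(
    readr::col_character(), readr::col_character()
  ), progress = FALSE)
  names(tbl) <- c("feature_id", "category")
  tibble::as_tibble(tbl)
}

# Numeric matrix view of a feature table (rows named by subject).
feature_matrix <- function(table) {
  m <- as.matrix(table[-1])
  rownames(m) <- table$subject_id
  m
}

# Align a score tibble to a feature table's subjects; errors on mismatch.
aligned_scores <- function(table, scores) {
  idx <- match(table$subject_id, scores$subject_id)
  if (anyNA(idx)) abort("scores missing for some subjects in the feature table")
  scores$score[idx]
}
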