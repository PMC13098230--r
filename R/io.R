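#' Read and write feature tables
#'
#' Feature tables are serialized as TSV in the conventional features-by-
#' samples orientation: a `feature_id` column followed by one column per
#' sample. In memory the package works samples-by-features (a `sample_id`
#' column followed by feature columns), so these helpers transpose.
#'
#' @param table Samples-by-features tibble with a `sample_id` column.
#' @param path TSV file path.
#' @return `write_feature_table()` returns `path` invisibly;
#'   `read_feature_table()` returns a samples-by-features tibble.
#' @export
write_feature_table <- function(table, path) {
  stopifnot("sample_id" %in% names(table))
  feats <- setdiff(names(table), "sample_id")
  m <- t(as.matrix(table[feats]))
  colnames(m) <- table$sample_id
  out <- dplyr::bind_cols(tibble(feature_id = feats), as_tibble(m))
  readr::write_tsv(out, path)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  raw <- readr::read_tsv(path, show_col_types = FALSE,
    col_types = readr::cols(feature_id = "c", .default = "d"))
  m <- t(as.matrix(raw[setdiff(names(raw), "feature_id")]))
  colnames(m) <- raw$feature_id
  dplyr::bind_cols(tibble(sample_id = rownames(m)), as_tibble(m))
}

#' Read and write sample metadata
#'
#' Metadata CSV columns: `sample_id`, `subject_id`, `role`
#' (donor/patient), `timepoint` (baseline/post, empty for donors),
#' `responder` (R/NR, empty for donors), `donor_id`, `cohort`, and the
#' per-sample clinical markers `crp`, `calprotectin`.
#'
#' @param meta Metadata tibble.
#' @param path CSV file path.
#' @export
write_metadata <- function(meta, path) {
  readr::write_csv(meta, path, na = "")
  invisible(path)
}

#' @rdname write_metadata
#' @export
read_metadata <- function(path) {
  readr::read_csv(path, show_col_types = FALSE, na = c("", "NA"),
    col_types = readr::cols(crp = "d", calprotectin = "d", .default = "c"))
}
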