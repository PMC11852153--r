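# Plain-text IO for expression tables, group assignments, tag tables and
# screened edges. Everything is TSV with a header row.

#' Read / write tidy expression tables as TSV
#'
#' Layout: `feature_id`, `feature_class`, then one numeric column per sample.
#'
#' @param path TSV file.
#' @param kind `"counts"` or `"tpm"`, attached as an attribute.
#' @return A tidy expression tibble.
#' @export
read_expression_tsv <- function(path, kind = "counts") {
  d <- tibble::as_tibble(utils::read.delim(path, sep = "\t", check.names = FALSE))
  stopifnot(all(EXPR_ANNOT_COLS %in% names(d)))
  attr(d, "kind") <- kind
  assert_expr(d)
  d
}

#' @rdname read_expression_tsv
#' @param expr Expression tibble.
#' @export
write_expression_tsv <- function(expr, path) {
  utils::write.table(expr, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a sample-to-group assignment (TSV: sample_id, group)
#' @param path TSV file.
#' @return Tibble `sample_id`, `group`.
#' @export
read_groups_tsv <- function(path) {
  d <- tibble::as_tibble(utils::read.delim(path, sep = "\t",
                                           colClasses = "character"))
  assert_groups(d)
  d
}

#' @rdname read_groups_tsv
#' @param groups Groups tibble.
#' @export
write_groups_tsv <- function(groups, path) {
  utils::write.table(groups, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a generic tidy table as TSV
#' @param x Data frame.
#' @param path Output path.
#' @export
write_tsv_table <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a two-column miRNA-target prediction list (TSV: mirna_id, rna_id)
#'
#' For importing externally produced target predictions so they can enter
#' [intersect_predictions()] alongside the in-package seed-match predictor.
#'
#' @param path TSV file.
#' @return Tibble `mirna_id`, `rna_id`.
#' @export
read_prediction_tsv <- function(path) {
  d <- tibble::as_tibble(utils::read.delim(path, sep = "\t",
                                           colClasses = "character"))
  stopifnot(all(c("mirna_id", "rna_id") %in% names(d)))
  d[, c("mirna_id", "rna_id")]
}
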