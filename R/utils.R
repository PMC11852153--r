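# Shared internal helpers: alphabet handling, reverse complement, sample-column
# discovery on tidy expression tables.

DNA_BASES <- c("A", "C", "G", "T")

#' Reverse complement of a DNA/RNA string
#'
#' U is treated as T; the result is always on the DNA alphabet.
#'
#' @param x A character vector of nucleotide strings.
#' @return A character vector of reverse complements.
#' @examples
#' revcomp("ACGT")
#' @export
revcomp <- function(x) {
  x <- normalize_dna(x)
  vapply(x, function(s) {
    comp <- chartr("ACGTN", "TGCAN", s)
    paste(rev(strsplit(comp, "", fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# Uppercase, U -> T; error on anything outside {A,C,G,T,N}.
normalize_dna <- function(x, allow_n = TRUE) {
  x <- chartr("u", "t", toupper(x))
  x <- chartr("U", "T", x)
  pat <- if (allow_n) "^[ACGTN]*$" else "^[ACGT]*$"
  bad <- !grepl(pat, x)
  if (any(bad)) {
    stop("invalid nucleotide alphabet in: ", paste(head(x[bad], 3), collapse = ", "))
  }
  x
}

complement_base <- function(b) chartr("ACGTU", "TGCAA", toupper(b))

# Sample (numeric measurement) columns of a tidy expression table are every
# column that is not a recognised annotation column.
EXPR_ANNOT_COLS <- c("feature_id", "feature_class")

sample_cols <- function(expr) {
  setdiff(names(expr), EXPR_ANNOT_COLS)
}

expr_values <- function(expr) {
  m <- as.matrix(expr[, sample_cols(expr), drop = FALSE])
  rownames(m) <- expr$feature_id
  storage.mode(m) <- "double"
  m
}

expr_kind <- function(expr) {
  k <- attr(expr, "kind")
  if (is.null(k)) "counts" else k
}

`expr_kind<-` <- function(expr, value) {
  attr(expr, "kind") <- value
  expr
}

assert_expr <- function(expr) {
  stopifnot(is.data.frame(expr), all(EXPR_ANNOT_COLS %in% names(expr)))
  v <- expr_values(expr)
  if (any(v < 0)) stop("expression values must be non-negative")
  invisible(expr)
}

# group tibble: sample_id, group (two levels, reference second so log2fc is
# first-level over second, i.e. HF over LF with the default factor order).
assert_groups <- function(groups, samples = NULL) {
  stopifnot(is.data.frame(groups), all(c("sample_id", "group") %in% names(groups)))
  if (!is.null(samples) && !all(samples %in% groups$sample_id)) {
    stop("groups table is missing sample ids: ",
         paste(setdiff(samples, groups$sample_id), collapse = ", "))
  }
  invisible(groups)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
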