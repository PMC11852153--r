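# Priority-ordered tag annotation. Each clean tag gets exactly one category:
# when several sources match, the highest-priority one wins. The housekeeping
# RNA classes (rRNA, scRNA, snoRNA, snRNA, tRNA) outrank everything and are
# flagged for exclusion from miRNA quantification. "novel_candidate" is an
# abstract lookup category standing in for hairpin-based novel-miRNA
# prediction, which is out of scope here.

ANNOTATION_PRIORITY <- c("rRNA_etc", "exist_miRNA", "exist_miRNA_edit",
                         "known_miRNA", "repeat", "exon", "novel_candidate",
                         "intron")
MIRNA_CATEGORIES <- c("exist_miRNA", "exist_miRNA_edit", "known_miRNA",
                      "novel_candidate")

#' Annotate clean tags against category lookups with a fixed priority
#'
#' `sources` is a named list mapping category names (a subset of
#' `rRNA_etc`, `exist_miRNA`, `known_miRNA`, `repeat`, `exon`,
#' `novel_candidate`, `intron`) to character vectors of reference sequences.
#' Matching is exact, except `exist_miRNA_edit`, which is derived from the
#' `exist_miRNA` source: same length with exactly one substitution outside
#' seed positions 2-7. Tags matching nothing are `unann`; `rRNA_etc` tags are
#' flagged `excluded` (removed from quantification).
#'
#' @param tags Tag tibble from [collapse_tags()].
#' @param sources Named list of reference sequence vectors.
#' @return The tag tibble with `category` filled and a logical `excluded`
#'   column.
#' @examples
#' tg <- tibble::tibble(sequence = "ACGTACGTACGTACGTACGTA", S1 = 3,
#'                      total = 3, category = NA_character_)
#' annotate_tags(tg, list(known_miRNA = "ACGTACGTACGTACGTACGTA"))$category
#' @export
annotate_tags <- function(tags, sources) {
  stopifnot(is.list(sources))
  allowed <- setdiff(ANNOTATION_PRIORITY, "exist_miRNA_edit")
  bad <- setdiff(names(sources), allowed)
  if (length(bad)) stop("unknown annotation categories: ", paste(bad, collapse = ", "))
  sources <- lapply(sources, normalize_dna)

  seqs <- normalize_dna(tags$sequence)
  cat_out <- rep("unann", length(seqs))
  # walk priority from lowest to highest so higher priorities overwrite
  for (cat in rev(ANNOTATION_PRIORITY)) {
    hit <- if (cat == "exist_miRNA_edit") {
      if (is.null(sources$exist_miRNA)) rep(FALSE, length(seqs))
      else matches_one_edit(seqs, sources$exist_miRNA)
    } else if (!is.null(sources[[cat]])) {
      seqs %in% sources[[cat]]
    } else {
      rep(FALSE, length(seqs))
    }
    cat_out[hit] <- cat
  }
  tags$category <- cat_out
  tags$excluded <- cat_out == "rRNA_etc"
  tags
}

# One substitution relative to some reference of equal length, with the
# mismatch outside seed positions 2-7 (an "edited" existing miRNA).
matches_one_edit <- function(seqs, refs) {
  ref_by_len <- split(refs, nchar(refs))
  vapply(seqs, function(s) {
    cand <- ref_by_len[[as.character(nchar(s))]]
    if (is.null(cand)) return(FALSE)
    sv <- strsplit(s, "", fixed = TRUE)[[1]]
    for (r in cand) {
      rv <- strsplit(r, "", fixed = TRUE)[[1]]
      d <- which(sv != rv)
      if (length(d) == 1 && (d < 2 || d > 7)) return(TRUE)
    }
    FALSE
  }, logical(1), USE.NAMES = FALSE)
}

#' Build a miRNA count matrix from annotated tags
#'
#' Keeps tags in the miRNA categories (existing, edited, known, novel
#' candidate), drops excluded housekeeping-RNA tags, and returns a tidy
#' expression table with the tag sequence as the feature id.
#'
#' @param tags Annotated tag tibble from [annotate_tags()].
#' @return Expression tibble (`feature_id`, `feature_class` = "miRNA", one
#'   column per sample), kind "counts".
#' @export
quantify_mirna_tags <- function(tags) {
  stopifnot("category" %in% names(tags))
  excluded <- if ("excluded" %in% names(tags)) tags$excluded else FALSE
  keep <- tags$category %in% MIRNA_CATEGORIES & !excluded
  samples <- setdiff(names(tags), c("sequence", "total", "category", "excluded"))
  out <- tibble::tibble(
    feature_id = tags$sequence[keep],
    feature_class = "miRNA"
  )
  for (s in samples) out[[s]] <- as.numeric(tags[[s]][keep])
  attr(out, "kind") <- "counts"
  out
}
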