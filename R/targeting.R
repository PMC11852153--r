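# Canonical seed-match target prediction and the anti-correlation screen.
#
# Site definitions follow the canonical classification. With the transcript
# written 5'->3', a site is anchored on a 6mer core: the reverse complement
# of miRNA positions 2-7. The base 5' of the core on the transcript pairs
# with miRNA position 8 (the "m8" match) and the base 3' of the core is an
# adenosine opposite miRNA position 1 (the "A1"):
#   8mer     = m8 match + core + A1
#   7mer-m8  = m8 match + core
#   7mer-A1  = core + A1
#   6mer     = core only

SITE_TYPES <- c("8mer", "7mer-m8", "7mer-A1", "6mer")

#' Find canonical seed-match sites of a miRNA on a transcript
#'
#' @param mirna_seq miRNA sequence (5'->3', RNA or DNA alphabet), length >= 8.
#' @param transcript_seq Transcript sequence (5'->3').
#' @return Tibble `site_type`, `position` (1-based start of the 6mer core on
#'   the transcript), one row per core occurrence, ordered by position.
#'   Every site can be re-verified by direct string comparison.
#' @examples
#' find_seed_sites("UAGCAGCACGUAAAUAUUGGCG", "CCTGCTGCTAGG")
#' @export
find_seed_sites <- function(mirna_seq, transcript_seq) {
  m <- normalize_dna(mirna_seq, allow_n = FALSE)
  tx <- normalize_dna(transcript_seq, allow_n = FALSE)
  if (nchar(m) < 8) stop("miRNA must be at least 8 nt")
  core <- revcomp(substr(m, 2, 7))
  m8_base <- complement_base(substr(m, 8, 8))
  nt <- nchar(tx)
  if (nt < 6) {
    return(tibble::tibble(site_type = character(0), position = integer(0)))
  }
  starts <- seq_len(nt - 5L)
  hits <- starts[substring(tx, starts, starts + 5L) == core]
  if (length(hits) == 0) {
    return(tibble::tibble(site_type = character(0), position = integer(0)))
  }
  m8 <- hits > 1 & substring(tx, hits - 1L, hits - 1L) == m8_base
  a1 <- hits + 6L <= nt & substring(tx, hits + 6L, hits + 6L) == "A"
  type <- dplyr::case_when(
    m8 & a1 ~ "8mer",
    m8 ~ "7mer-m8",
    a1 ~ "7mer-A1",
    .default = "6mer"
  )
  tibble::tibble(site_type = type, position = as.integer(hits))
}

#' Predict miRNA-target pairs across sequence tables
#'
#' Runs [find_seed_sites()] for every miRNA x transcript combination and
#' keeps pairs with at least one qualifying site. Multiple sites collapse to
#' one pair carrying the strongest site type
#' (8mer > 7mer-m8 > 7mer-A1 > 6mer). 6mer-only pairs are excluded by
#' default, which keeps this single predictor conservative - comparable to
#' intersecting several permissive predictors.
#'
#' @param mirnas Tibble `mirna_id`, `sequence`.
#' @param transcripts Tibble `rna_id`, `sequence` (optionally `rna_class`).
#' @param include_6mer Keep pairs whose best site is a 6mer.
#' @return Tibble `mirna_id`, `rna_id` (, `rna_class`), `best_site`,
#'   `n_sites`.
#' @export
predict_targets <- function(mirnas, transcripts, include_6mer = FALSE) {
  stopifnot(all(c("mirna_id", "sequence") %in% names(mirnas)),
            all(c("rna_id", "sequence") %in% names(transcripts)))
  tx_norm <- normalize_dna(transcripts$sequence, allow_n = FALSE)
  res <- purrr::map_dfr(seq_len(nrow(mirnas)), function(i) {
    m <- normalize_dna(mirnas$sequence[i], allow_n = FALSE)
    core <- revcomp(substr(m, 2, 7))
    cand <- which(grepl(core, tx_norm, fixed = TRUE))  # cheap prefilter
    purrr::map_dfr(cand, function(j) {
      sites <- find_seed_sites(mirnas$sequence[i], transcripts$sequence[j])
      if (nrow(sites) == 0) return(NULL)
      best <- SITE_TYPES[min(match(sites$site_type, SITE_TYPES))]
      tibble::tibble(
        mirna_id = mirnas$mirna_id[i],
        rna_id = transcripts$rna_id[j],
        rna_class = if ("rna_class" %in% names(transcripts))
          transcripts$rna_class[j] else NA_character_,
        best_site = best,
        n_sites = nrow(sites)
      )
    })
  })
  if (nrow(res) == 0) {
    res <- tibble::tibble(mirna_id = character(0), rna_id = character(0),
                          rna_class = character(0), best_site = character(0),
                          n_sites = integer(0))
  }
  if (!include_6mer) res <- dplyr::filter(res, .data$best_site != "6mer")
  res
}

#' Intersect target predictions from multiple sources
#'
#' Mirrors the practice of keeping only miRNA-target pairs called by every
#' predictor.
#'
#' @param sets A list of data frames, each with `mirna_id` and `rna_id`
#'   columns (extra columns are dropped).
#' @return Tibble of the pairs present in every set.
#' @export
intersect_predictions <- function(sets) {
  if (length(sets) == 0) stop("need at least one prediction set")
  keys <- lapply(sets, function(s) {
    stopifnot(all(c("mirna_id", "rna_id") %in% names(s)))
    dplyr::distinct(tibble::as_tibble(s)[, c("mirna_id", "rna_id")])
  })
  purrr::reduce(keys, dplyr::inner_join, by = c("mirna_id", "rna_id"))
}

# Pairwise correlation of rows of an expression table; constant vectors give
# NA with a warning collected by the caller.
row_cor <- function(x, y, method) {
  if (var(x) == 0 || var(y) == 0) return(NA_real_)
  cor(x, y, method = method)
}

#' Screen candidate miRNA-target pairs for strong anti-correlation
#'
#' Computes the Spearman rank correlation (average ranks for ties) between
#' each miRNA and its candidate target across all samples (both groups
#' pooled) and keeps pairs with `rho <= threshold` (inclusive, as the
#' screening rule is stated).
#'
#' @param pairs Tibble `mirna_id`, `rna_id` of candidate pairs.
#' @param expr Expression tibble containing both the miRNAs and the targets
#'   (typically TPM).
#' @param threshold Inclusive upper bound on Spearman's rho. The comparison
#'   carries a 1e-12 guard: rank correlations are rational numbers and a
#'   value mathematically equal to the threshold must pass despite
#'   floating-point round-off.
#' @return Tibble `mirna_id`, `rna_id`, `rna_class`, `spearman_rho` for
#'   surviving pairs. Pairs with a constant expression vector are skipped
#'   with a warning.
#' @export
spearman_screen <- function(pairs, expr, threshold = -0.6) {
  stopifnot(all(c("mirna_id", "rna_id") %in% names(pairs)))
  assert_expr(expr)
  v <- expr_values(expr)
  cls <- setNames(expr$feature_class, expr$feature_id)
  missing <- setdiff(unique(c(pairs$mirna_id, pairs$rna_id)), rownames(v))
  if (length(missing)) {
    stop("features absent from the expression table: ",
         paste(head(missing, 3), collapse = ", "))
  }
  if (ncol(v) < 3) stop("need at least 3 samples for a correlation screen")

  rho <- vapply(seq_len(nrow(pairs)), function(i) {
    row_cor(v[pairs$mirna_id[i], ], v[pairs$rna_id[i], ], "spearman")
  }, numeric(1))
  n_skip <- sum(is.na(rho))
  if (n_skip > 0) {
    warning(n_skip, " pair(s) skipped: constant expression vector")
  }
  keep <- !is.na(rho) & rho <= threshold + 1e-12
  tibble::tibble(
    mirna_id = pairs$mirna_id[keep],
    rna_id = pairs$rna_id[keep],
    rna_class = unname(cls[pairs$rna_id[keep]]),
    spearman_rho = rho[keep]
  )
}
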