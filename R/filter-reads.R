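# Staged small-RNA read filter with per-category accounting. Stages run in a
# fixed order and every discarded read is charged to the FIRST stage it fails:
#   1. quality           -> low_quality
#   2. 3' adapter absent -> adapter3_null   (else the insert is the sequence
#                                            strictly before the first match)
#   3. 5' adapter in the trimmed insert -> adapter5_hit
#   4. insert length outside [18, 30]   -> insert_too_short / insert_too_long
#   5. polyA insert      -> polyA
# Surviving inserts are collapsed to tags; tags with total read frequency < 2
# are charged to low_frequency, the rest are clean_tags.

FILTER_CATEGORIES <- c("low_quality", "adapter3_null", "adapter5_hit",
                       "insert_too_short", "insert_too_long", "polyA",
                       "low_frequency", "clean_tags")

#' Quality and polyA policies for read filtering
#'
#' The source protocol only names the filters ("low-quality", "containing
#' polyA") without defining them; these policies make the rules explicit and
#' configurable. A read is low-quality when more than `max_frac_below` of its
#' bases are below `phred_min`, or when it contains an N (unless `allow_n`).
#' An insert is polyA when at least `frac_a` of its bases are A, or it
#' contains a run of at least `run_a` consecutive A's.
#'
#' @param max_frac_below,phred_min,allow_n Quality rule parameters.
#' @param frac_a,run_a PolyA rule parameters.
#' @return A named list of policy parameters.
#' @export
quality_policy <- function(max_frac_below = 0.2, phred_min = 20, allow_n = FALSE) {
  list(max_frac_below = max_frac_below, phred_min = phred_min, allow_n = allow_n)
}

#' @rdname quality_policy
#' @export
polya_policy <- function(frac_a = 0.8, run_a = 10) {
  list(frac_a = frac_a, run_a = run_a)
}

is_polya <- function(insert, policy = polya_policy()) {
  n_a <- nchar(insert) - nchar(gsub("A", "", insert, fixed = TRUE))
  frac <- ifelse(nchar(insert) > 0, n_a / nchar(insert), 0)
  frac >= policy$frac_a | grepl(strrep("A", policy$run_a), insert, fixed = TRUE)
}

is_low_quality <- function(sequence, quality, policy = quality_policy()) {
  stopifnot(length(sequence) == length(quality))
  mism <- nchar(sequence) != nchar(quality)
  if (any(mism)) stop("quality string length mismatch for ", sum(mism), " read(s)")
  frac_bad <- vapply(quality, function(q) {
    ph <- utf8ToInt(q) - 33L
    mean(ph < policy$phred_min)
  }, numeric(1), USE.NAMES = FALSE)
  bad <- frac_bad > policy$max_frac_below
  if (!policy$allow_n) bad <- bad | grepl("N", sequence, fixed = TRUE)
  bad
}

new_filter_report <- function(counts, total) {
  counts <- counts[FILTER_CATEGORIES]
  counts[is.na(counts)] <- 0
  rep_tbl <- tibble::tibble(
    category = FILTER_CATEGORIES,
    reads = as.numeric(counts),
    percent = if (total > 0) 100 * as.numeric(counts) / total else 0
  )
  attr(rep_tbl, "total") <- total
  class(rep_tbl) <- c("filter_report", class(rep_tbl))
  rep_tbl
}

#' Filter raw small-RNA reads and trim to insert sequences
#'
#' Applies the staged filter described above. The 3' and 5' adapters are
#' matched by the exact first `adapter_match_len` bases (no mismatches); the
#' insert is everything strictly before the first 3' match.
#'
#' @param reads Tibble with `sample_id` (optional; defaults to one sample),
#'   `id`, `sequence`, `quality`.
#' @param adapter_3p,adapter_5p Non-empty adapter sequences.
#' @param qc A [quality_policy()].
#' @param polya A [polya_policy()].
#' @param insert_range Allowed insert length range (defaults to the 18-30 nt
#'   gel selection window).
#' @param adapter_match_len Number of leading adapter bases used for exact
#'   matching.
#' @return A list with `inserts` (tibble `sample_id`, `sequence`, one row per
#'   surviving read) and `report` (a `filter_report` tibble: category, reads,
#'   percent; `low_frequency` is 0 until [collapse_tags()]).
#' @examples
#' r <- tibble::tibble(id = "r1", sequence = paste0(strrep("ACGT", 6), "TGGAATTC"),
#'                     quality = strrep("I", 32))
#' filter_reads(r, "TGGAATTC", "GTTCAGAG")$report
#' @export
filter_reads <- function(reads, adapter_3p, adapter_5p,
                         qc = quality_policy(), polya = polya_policy(),
                         insert_range = c(18, 30), adapter_match_len = 8) {
  stopifnot(all(c("id", "sequence", "quality") %in% names(reads)))
  if (!nzchar(adapter_3p) || !nzchar(adapter_5p)) stop("adapters must be non-empty")
  if (!"sample_id" %in% names(reads)) reads$sample_id <- "S1"

  seqs <- normalize_dna(reads$sequence)
  seed3 <- substr(normalize_dna(adapter_3p, allow_n = FALSE), 1, adapter_match_len)
  seed5 <- substr(normalize_dna(adapter_5p, allow_n = FALSE), 1, adapter_match_len)

  n <- length(seqs)
  fate <- rep(NA_character_, n)

  lowq <- is_low_quality(seqs, reads$quality, qc)
  fate[lowq] <- "low_quality"

  todo <- is.na(fate)
  pos3 <- rep(-1L, n)
  pos3[todo] <- regexpr(seed3, seqs[todo], fixed = TRUE)
  fate[todo & pos3 < 0] <- "adapter3_null"

  todo <- is.na(fate)
  insert <- rep(NA_character_, n)
  insert[todo] <- substr(seqs[todo], 1, pos3[todo] - 1L)

  hit5 <- todo & grepl(seed5, ifelse(is.na(insert), "", insert), fixed = TRUE)
  fate[hit5] <- "adapter5_hit"

  todo <- is.na(fate)
  len <- nchar(insert)
  fate[todo & len < insert_range[1]] <- "insert_too_short"
  todo <- is.na(fate)
  fate[todo & len > insert_range[2]] <- "insert_too_long"

  todo <- is.na(fate)
  pa <- todo & is_polya(ifelse(is.na(insert), "", insert), polya)
  fate[pa] <- "polyA"

  keep <- is.na(fate)
  counts <- table(factor(fate[!keep], levels = FILTER_CATEGORIES))
  counts <- setNames(as.numeric(counts), names(counts))
  counts["clean_tags"] <- sum(keep)

  list(
    inserts = tibble::tibble(sample_id = reads$sample_id[keep],
                             sequence = insert[keep]),
    report = new_filter_report(counts, n)
  )
}

#' Collapse inserts to clean tags and apply the frequency cutoff
#'
#' Identical insert sequences across all samples collapse into one tag with
#' per-sample read counts. Tags whose summed count is below `min_frequency`
#' are removed and their reads charged to the `low_frequency` category of the
#' report. Tags are ordered by total count descending, ties broken by
#' sequence.
#'
#' @param inserts Tibble `sample_id`, `sequence` from [filter_reads()].
#' @param report Optional `filter_report` to update (reads move from
#'   `clean_tags` to `low_frequency`).
#' @param min_frequency Minimum summed read count for a tag to be kept.
#' @return A list with `tags` (tibble: `sequence`, one count column per
#'   sample, `total`, `category` = NA) and `report`.
#' @export
collapse_tags <- function(inserts, report = NULL, min_frequency = 2) {
  stopifnot(all(c("sample_id", "sequence") %in% names(inserts)))
  samples <- sort(unique(inserts$sample_id))
  tags <- inserts |>
    dplyr::count(.data$sequence, .data$sample_id) |>
    tidyr::pivot_wider(names_from = "sample_id", values_from = "n",
                       values_fill = 0)
  missing_samp <- setdiff(samples, names(tags))
  for (s in missing_samp) tags[[s]] <- 0
  if (nrow(tags) == 0) {
    tags <- tibble::tibble(sequence = character(0))
    for (s in samples) tags[[s]] <- numeric(0)
  }
  tags$total <- rowSums(tags[, samples, drop = FALSE])
  dropped_reads <- sum(tags$total[tags$total < min_frequency])
  tags <- tags |>
    dplyr::filter(.data$total >= min_frequency) |>
    dplyr::arrange(dplyr::desc(.data$total), .data$sequence) |>
    dplyr::mutate(category = NA_character_) |>
    dplyr::select("sequence", dplyr::all_of(samples), "total", "category")

  if (!is.null(report)) {
    i_lf <- report$category == "low_frequency"
    i_ct <- report$category == "clean_tags"
    report$reads[i_lf] <- report$reads[i_lf] + dropped_reads
    report$reads[i_ct] <- report$reads[i_ct] - dropped_reads
    total <- attr(report, "total")
    report$percent <- if (total > 0) 100 * report$reads / total else 0
  }
  list(tags = tags, report = report)
}

#' Length distribution of clean tags
#'
#' Histogram of insert lengths over the retained window, weighted by total
#' read counts. Mature miRNA-dominated libraries concentrate at 21-23 nt.
#'
#' @param tags Tag tibble from [collapse_tags()] (annotated or not).
#' @param range Length window to tabulate.
#' @return Tibble `length`, `count`; counts sum to the total retained reads.
#' @export
length_distribution <- function(tags, range = c(18, 30)) {
  lens <- seq(range[1], range[2])
  out <- tibble::tibble(length = lens, count = 0)
  if (nrow(tags) > 0) {
    h <- tags |>
      dplyr::mutate(length = nchar(.data$sequence)) |>
      dplyr::group_by(.data$length) |>
      dplyr::summarise(count = sum(.data$total), .groups = "drop")
    idx <- match(h$length, out$length)
    ok <- !is.na(idx)
    out$count[idx[ok]] <- h$count[ok]
  }
  class(out) <- c("tag_length_dist", class(out))
  out
}
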