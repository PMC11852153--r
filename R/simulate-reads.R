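# Raw small-RNA read fixtures of known composition. Every read is built to
# trip exactly one filter stage (or to survive all of them), so the filter's
# per-category accounting can be checked against the generator's truth.

# default adapters: Illumina TruSeq small-RNA 3' and 5' sequences
ADAPTER_3P_DEFAULT <- "TGGAATTCTCGGGTGCCAAGG"
ADAPTER_5P_DEFAULT <- "GTTCAGAGTTCTACAGTCCGACGATC"

READ_CATEGORIES <- c("low_quality", "no_3prime_adapter", "has_5prime_adapter",
                     "short_insert", "polyA", "singleton", "clean")

#' Simulate raw small-RNA reads with a known filter-fate composition
#'
#' Constructs FASTQ-writable reads where each requested category is built to
#' fail exactly one stage of [filter_reads()] (quality, 3' adapter, 5'
#' adapter, insert length, polyA) or to survive everything: `clean` reads
#' collapse to tags with total frequency >= 2, `singleton` reads are valid
#' inserts seen exactly once (removed later by the frequency cutoff).
#' Constructed inserts are guaranteed not to contain the adapter match seeds,
#' so the intended fate is the realised fate.
#'
#' @param config A [sim_config()]; only its seed and sample count are used.
#' @param composition Named integer vector over (a subset of)
#'   `low_quality`, `no_3prime_adapter`, `has_5prime_adapter`, `short_insert`,
#'   `polyA`, `singleton`, `clean`.
#' @param adapter_3p,adapter_5p Adapter sequences ligated 3' and 5' of the
#'   insert.
#' @param insert_length_range Length range of clean/singleton inserts;
#'   the default 21-23 nt mimics mature miRNA lengths.
#' @param n_samples Number of samples the reads are spread over (round-robin).
#' @return A list (`read_set`) with `reads` (tibble `sample_id`, `id`,
#'   `sequence`, `quality`), `adapter_3p`, `adapter_5p`, and `truth`
#'   (a `sim_truth` whose `read_composition` equals `composition`).
#' @examples
#' rs <- simulate_reads(sim_config(seed = 3), c(clean = 10, polyA = 2))
#' nrow(rs$reads)
#' @export
simulate_reads <- function(config,
                           composition = c(low_quality = 50, no_3prime_adapter = 100,
                                           has_5prime_adapter = 20, short_insert = 150,
                                           polyA = 5, singleton = 100, clean = 600),
                           adapter_3p = ADAPTER_3P_DEFAULT,
                           adapter_5p = ADAPTER_5P_DEFAULT,
                           insert_length_range = c(21, 23),
                           n_samples = 2) {
  config <- validate_sim_config(config)
  composition <- composition[composition > 0]
  if (length(composition) == 0) stop("composition is empty")
  if (any(composition < 0)) stop("composition counts must be non-negative")
  bad <- setdiff(names(composition), READ_CATEGORIES)
  if (length(bad)) stop("unknown read categories: ", paste(bad, collapse = ", "))
  composition <- vapply(composition, function(x) as.integer(round(x)), integer(1))
  withr::with_seed(config$seed,
    simulate_reads_impl(composition, adapter_3p, adapter_5p,
                        insert_length_range, n_samples))
}

simulate_reads_impl <- function(composition, adapter_3p, adapter_5p,
                                len_range, n_samples) {
  adapter_3p <- normalize_dna(adapter_3p, allow_n = FALSE)
  adapter_5p <- normalize_dna(adapter_5p, allow_n = FALSE)
  seed3 <- substr(adapter_3p, 1, 8)   # what the trimmer actually matches
  seed5 <- substr(adapter_5p, 1, 8)
  forbid <- c(seed3, seed5)

  if (!is.na(composition["clean"]) && composition[["clean"]] == 1L) {
    stop("a single clean read cannot form a tag with frequency >= 2; ",
         "request clean >= 2 (or use 'singleton')")
  }
  ids_used <- new.env(parent = emptyenv())

  draw_insert <- function(len) {
    repeat {
      s <- paste(sample(DNA_BASES, len, replace = TRUE), collapse = "")
      if (any(vapply(forbid, function(f) grepl(f, s, fixed = TRUE), logical(1)))) next
      if (is_polya(s)) next
      if (!is.null(ids_used[[s]])) next
      ids_used[[s]] <- TRUE
      return(s)
    }
  }
  draw_len <- function() sample(seq(len_range[1], len_range[2]), 1)

  good_qual <- function(len) strrep("I", len)              # Phred 40
  bad_qual <- function(len) {
    # 25% of positions at Phred 2: fails the ">20% below Phred 20" policy
    q <- rep("I", len)
    n_bad <- ceiling(0.25 * len)
    q[sample(len, n_bad)] <- "#"
    paste(q, collapse = "")
  }

  seqs <- character(0); quals <- character(0); fates <- character(0)
  add_read <- function(sequence, quality, fate) {
    seqs[[length(seqs) + 1L]] <<- sequence
    quals[[length(quals) + 1L]] <<- quality
    fates[[length(fates) + 1L]] <<- fate
  }
  with_adapter <- function(insert) paste0(insert, adapter_3p)

  for (cat in names(composition)) {
    n <- composition[[cat]]
    if (cat == "clean") {
      # distinct tags, each duplicated so total frequency >= 2
      left <- n
      while (left > 0) {
        freq <- if (left == 3) 3L else 2L
        ins <- draw_insert(draw_len())
        read <- with_adapter(ins)
        for (j in seq_len(min(freq, left))) add_read(read, good_qual(nchar(read)), "clean")
        left <- left - freq
      }
    } else if (cat == "singleton") {
      for (i in seq_len(n)) {
        read <- with_adapter(draw_insert(draw_len()))
        add_read(read, good_qual(nchar(read)), "singleton")
      }
    } else if (cat == "low_quality") {
      for (i in seq_len(n)) {
        read <- with_adapter(draw_insert(draw_len()))
        add_read(read, bad_qual(nchar(read)), "low_quality")
      }
    } else if (cat == "no_3prime_adapter") {
      for (i in seq_len(n)) {
        # read-length sequence with no adapter match seed anywhere
        len <- draw_len() + nchar(adapter_3p)
        repeat {
          s <- paste(sample(DNA_BASES, len, replace = TRUE), collapse = "")
          if (!grepl(seed3, s, fixed = TRUE)) break
        }
        add_read(s, good_qual(len), "no_3prime_adapter")
      }
    } else if (cat == "has_5prime_adapter") {
      for (i in seq_len(n)) {
        ins <- paste0(seed5, draw_insert(draw_len()))
        read <- with_adapter(ins)
        add_read(read, good_qual(nchar(read)), "has_5prime_adapter")
      }
    } else if (cat == "short_insert") {
      for (i in seq_len(n)) {
        read <- with_adapter(draw_insert(sample(15:17, 1)))
        add_read(read, good_qual(nchar(read)), "short_insert")
      }
    } else if (cat == "polyA") {
      for (i in seq_len(n)) {
        # 20 nt insert, >= 80% A with a few non-A bases to vary the sequence
        ins <- rep("A", 20)
        ins[sample(20, 2)] <- sample(c("C", "G", "T"), 2, replace = TRUE)
        read <- with_adapter(paste(ins, collapse = ""))
        add_read(read, good_qual(nchar(read)), "polyA")
      }
    }
  }

  n_reads <- length(seqs)
  ord <- sample.int(n_reads)  # shuffle so category order carries no signal
  samples <- paste0("S", seq_len(n_samples))
  reads <- tibble::tibble(
    sample_id = rep_len(samples, n_reads),
    id = sprintf("read_%06d", seq_len(n_reads)),
    sequence = seqs[ord],
    quality = quals[ord],
    intended_fate = fates[ord]
  )

  truth <- structure(
    list(de_mirnas = tibble::tibble(feature_id = character(), direction = character()),
         triplets = tibble::tibble(),
         read_composition = composition),
    class = "sim_truth"
  )
  structure(
    list(reads = reads, adapter_3p = adapter_3p, adapter_5p = adapter_5p,
         truth = truth),
    class = "read_set"
  )
}

#' Write / read small-RNA reads as FASTQ (Sanger Phred+33)
#'
#' Thin wrappers around Biostrings' quality-scaled string sets. `write_fastq()`
#' writes one file per sample when the table has more than one `sample_id`.
#'
#' @param reads Tibble with `id`, `sequence`, `quality` (and optionally
#'   `sample_id`).
#' @param path Output file (single sample) or directory (multiple samples).
#' @return `write_fastq()` returns the written paths invisibly; `read_fastq()`
#'   returns a reads tibble.
#' @export
write_fastq <- function(reads, path) {
  stopifnot(all(c("id", "sequence", "quality") %in% names(reads)))
  by_sample <- if ("sample_id" %in% names(reads) &&
                   length(unique(reads$sample_id)) > 1) {
    split(reads, reads$sample_id)
  } else {
    setNames(list(reads), basename(path))
  }
  multi <- length(by_sample) > 1
  if (multi && !dir.exists(path)) dir.create(path, recursive = TRUE)
  paths <- character(0)
  for (nm in names(by_sample)) {
    r <- by_sample[[nm]]
    out <- if (multi) file.path(path, paste0(nm, ".fastq")) else path
    x <- Biostrings::QualityScaledDNAStringSet(
      Biostrings::DNAStringSet(setNames(r$sequence, r$id)),
      Biostrings::PhredQuality(r$quality)
    )
    Biostrings::writeQualityScaledXStringSet(x, out)
    paths <- c(paths, out)
  }
  invisible(paths)
}

#' @rdname write_fastq
#' @param sample_id Sample label attached to all reads in the file.
#' @export
read_fastq <- function(path, sample_id = "S1") {
  # Biostrings keeps the FASTQ per-record metadata as mcols and warns when
  # dropping them while pairing sequences with qualities; irrelevant here
  x <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(path))
  tibble::tibble(
    sample_id = sample_id,
    id = names(x) %||% sprintf("read_%06d", seq_along(x)),
    sequence = unname(as.character(x)),
    quality = unname(as.character(Biostrings::quality(x)))
  )
}
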