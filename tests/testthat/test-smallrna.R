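# Read filtering, tag collapsing and annotation.

mk_read <- function(sequence, quality = strrep("I", nchar(sequence)),
                    id = "r1", sample_id = "S1") {
  tibble::tibble(sample_id = sample_id, id = id,
                 sequence = sequence, quality = quality)
}
A3 <- "TGGAATTCTCGGGTGCCAAGG"
A5 <- "GTTCAGAGTTCTACAGTCCGACGATC"
INS21 <- "ACGTGACTGATCGTACGGTCA"  # 21 nt, free of both adapter seeds

test_that("each filter stage charges the first failing category", {
  reads <- dplyr::bind_rows(
    mk_read(paste0(INS21, A3), quality = paste0(strrep("#", 10), strrep("I", 32)), id = "lowq"),
    mk_read(strrep("C", 40), id = "noad"),
    mk_read(paste0(substr(A5, 1, 8), INS21, A3), id = "ad5"),
    mk_read(paste0(substr(INS21, 1, 17), A3), id = "short"),
    mk_read(paste0(strrep("ACGT", 9), INS21, A3), id = "long"),
    mk_read(paste0(strrep("A", 20), A3), id = "polya"),
    mk_read(paste0(INS21, A3), id = "ok")
  )
  f <- filter_reads(reads, A3, A5)
  got <- setNames(f$report$reads, f$report$category)
  expect_equal(got[["low_quality"]], 1)
  expect_equal(got[["adapter3_null"]], 1)
  expect_equal(got[["adapter5_hit"]], 1)
  expect_equal(got[["insert_too_short"]], 1)
  expect_equal(got[["insert_too_long"]], 1)
  expect_equal(got[["polyA"]], 1)
  expect_equal(got[["clean_tags"]], 1)
  expect_equal(f$inserts$sequence, INS21)
  # accounting conservation and percentages
  expect_equal(sum(f$report$reads), nrow(reads))
  expect_equal(sum(f$report$percent), 100, tolerance = 0.01)
})

test_that("insert is the sequence strictly before the first 3' adapter match", {
  r <- mk_read(paste0(INS21, A3, "GGGG", A3))
  f <- filter_reads(r, A3, A5)
  expect_equal(f$inserts$sequence, INS21)
})

test_that("a read containing N fails quality under the default policy", {
  r <- mk_read(paste0(substr(INS21, 1, 20), "N", A3))
  f <- filter_reads(r, A3, A5)
  expect_equal(f$report$reads[f$report$category == "low_quality"], 1)
})

test_that("report counts are invariant to read order", {
  rs <- simulate_reads(sim_config(seed = 13),
                       c(low_quality = 5, no_3prime_adapter = 8, short_insert = 6,
                         polyA = 3, singleton = 7, clean = 20))
  f1 <- filter_reads(rs$reads, rs$adapter_3p, rs$adapter_5p)
  shuffled <- rs$reads[rev(seq_len(nrow(rs$reads))), ]
  f2 <- filter_reads(shuffled, rs$adapter_3p, rs$adapter_5p)
  expect_equal(f1$report$reads, f2$report$reads)
})

test_that("quality/sequence length mismatch and empty adapters error", {
  r <- mk_read("ACGT", quality = "II")
  expect_error(filter_reads(r, A3, A5), "mismatch")
  expect_error(filter_reads(mk_read(INS21), "", A5), "non-empty")
})

test_that("frequency cutoff is on the total across samples", {
  ins <- tibble::tibble(
    sample_id = c("S1", "S2", "S1", "S1", "S2"),
    sequence = c(INS21, INS21,                      # once in each of 2 samples
                 "TTTGACCGTACGATCAGTCAC", "TTTGACCGTACGATCAGTCAC",  # twice in S1
                 "GACTGACTGACTGACTGACTG")           # singleton
  )
  cl <- collapse_tags(ins)
  expect_equal(nrow(cl$tags), 2)
  expect_true(INS21 %in% cl$tags$sequence)              # 1 + 1 = 2, retained
  expect_false("GACTGACTGACTGACTGACTG" %in% cl$tags$sequence)
  expect_equal(sort(cl$tags$total), c(2, 2))
})

test_that("tags sort by total descending with lexicographic tie-break", {
  ins <- tibble::tibble(
    sample_id = "S1",
    sequence = c(rep("TTTTGACCGTACGATCAGTCA", 5), rep("AAACGTGACTGATCGTACGGT", 5),
                 rep("CCCGTGACTGATCGTACGGTC", 2))
  )
  cl <- collapse_tags(ins)
  expect_equal(cl$tags$total, c(5, 5, 2))
  expect_equal(cl$tags$sequence[1:2],
               sort(c("TTTTGACCGTACGATCAGTCA", "AAACGTGACTGATCGTACGGT")))
})

test_that("collapse updates the report's low-frequency accounting", {
  rs <- simulate_reads(sim_config(seed = 17), c(singleton = 9, clean = 12))
  f <- filter_reads(rs$reads, rs$adapter_3p, rs$adapter_5p)
  cl <- collapse_tags(f$inserts, f$report)
  got <- setNames(cl$report$reads, cl$report$category)
  expect_equal(got[["low_frequency"]], 9)
  expect_equal(got[["clean_tags"]], 12)
  expect_equal(sum(cl$report$reads), nrow(rs$reads))
})

test_that("annotation respects the priority order for every category pair", {
  priority <- c("rRNA_etc", "exist_miRNA", "known_miRNA", "repeat",
                "exon", "novel_candidate", "intron")
  s <- INS21
  for (i in seq_along(priority)) {
    for (j in seq_along(priority)) {
      if (i == j) next
      sources <- setNames(list(s, s), c(priority[i], priority[j]))
      tg <- tibble::tibble(sequence = s, S1 = 5, total = 5,
                           category = NA_character_)
      res <- annotate_tags(tg, sources)
      expect_equal(res$category, priority[min(i, j)],
                   info = paste(priority[i], "vs", priority[j]))
    }
  }
})

test_that("edited miRNA matches one substitution outside the seed only", {
  ref <- INS21
  mutate_at <- function(s, i) {
    old <- substr(s, i, i)
    paste0(substr(s, 1, i - 1), setdiff(c("A", "C", "G", "T"), old)[1],
           substr(s, i + 1, nchar(s)))
  }
  tg <- function(s) tibble::tibble(sequence = s, S1 = 2, total = 2,
                                   category = NA_character_)
  src <- list(exist_miRNA = ref)
  expect_equal(annotate_tags(tg(mutate_at(ref, 10)), src)$category, "exist_miRNA_edit")
  expect_equal(annotate_tags(tg(mutate_at(ref, 1)), src)$category, "exist_miRNA_edit")
  expect_equal(annotate_tags(tg(mutate_at(ref, 5)), src)$category, "unann")  # in seed
  two <- mutate_at(mutate_at(ref, 10), 12)
  expect_equal(annotate_tags(tg(two), src)$category, "unann")
  expect_equal(annotate_tags(tg(ref), src)$category, "exist_miRNA")
})

test_that("unmatched tags are unann and rRNA-class tags are excluded", {
  tg <- tibble::tibble(sequence = c(INS21, "TTTGACCGTACGATCAGTCAC"),
                       S1 = c(3, 4), total = c(3, 4),
                       category = NA_character_)
  res <- annotate_tags(tg, list(rRNA_etc = INS21))
  expect_equal(res$category, c("rRNA_etc", "unann"))
  expect_equal(res$excluded, c(TRUE, FALSE))
  expect_error(annotate_tags(tg, list(bogus = INS21)), "unknown annotation")
  # idempotent and deterministic
  res2 <- annotate_tags(res[, names(tg)], list(rRNA_etc = INS21))
  expect_equal(res2$category, res$category)
})

test_that("length distribution is count-weighted and conserves totals", {
  tg <- tibble::tibble(sequence = c(strrep("A", 22), strrep("C", 19)),
                       S1 = c(10, 2), total = c(10, 2),
                       category = "known_miRNA")
  h <- length_distribution(tg)
  expect_equal(h$count[h$length == 22], 10)
  expect_equal(h$count[h$length == 19], 2)
  expect_equal(sum(h$count), sum(tg$total))
  empty <- length_distribution(tg[0, ])
  expect_true(all(empty$count == 0))
})

test_that("a 21-23 nt clean fixture concentrates its mass at 21-23", {
  rs <- simulate_reads(sim_config(seed = 19), c(clean = 200),
                       insert_length_range = c(21, 23))
  f <- filter_reads(rs$reads, rs$adapter_3p, rs$adapter_5p)
  cl <- collapse_tags(f$inserts, f$report)
  h <- length_distribution(cl$tags)
  expect_gte(sum(h$count[h$length %in% 21:23]) / sum(h$count), 0.99)
})

test_that("miRNA tag quantification keeps only miRNA-category tags", {
  tg <- tibble::tibble(
    sequence = c(INS21, "TTTGACCGTACGATCAGTCAC", "GACTGACTGACTGACTGACTG"),
    S1 = c(5, 3, 2), S2 = c(1, 0, 2), total = c(6, 3, 4),
    category = c("known_miRNA", "rRNA_etc", "unann"),
    excluded = c(FALSE, TRUE, FALSE)
  )
  q <- quantify_mirna_tags(tg)
  expect_equal(q$feature_id, INS21)
  expect_equal(q$S1, 5)
  expect_equal(q$feature_class, "miRNA")
})
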