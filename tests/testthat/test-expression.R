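# TPM and the negative-binomial differential screen.

mk_expr <- function(mat, classes = "mRNA") {
  d <- tibble::tibble(
    feature_id = sprintf("f%02d", seq_len(nrow(mat))),
    feature_class = rep_len(classes, nrow(mat))
  )
  for (j in seq_len(ncol(mat))) d[[paste0("S", j)]] <- mat[, j]
  d
}
mk_groups <- function(n1 = 2, n2 = 2) {
  tibble::tibble(sample_id = paste0("S", seq_len(n1 + n2)),
                 group = rep(c("HF", "LF"), c(n1, n2)))
}

test_that("TPM normalisation is a fixed point, proportional, and sums to 1e6", {
  fixed <- mk_expr(matrix(c(250000, 750000), ncol = 1))
  expect_equal(tpm_normalize(fixed)$S1, c(250000, 750000))
  prop <- mk_expr(matrix(c(1, 3), ncol = 1))
  expect_equal(tpm_normalize(prop)$S1, c(250000, 750000))
  set.seed(5)
  r <- mk_expr(matrix(runif(40, 0, 50), ncol = 4))
  tp <- tpm_normalize(r)
  for (s in paste0("S", 1:4)) {
    expect_equal(sum(tp[[s]]), 1e6, tolerance = 1e-6)
  }
  zero <- mk_expr(matrix(c(0, 0), ncol = 1))
  expect_error(tpm_normalize(zero), "all-zero")
})

test_that("identical group counts give log2fc 0 and p 1", {
  m <- matrix(c(50, 60, 50, 60), nrow = 1)
  filler <- matrix(rep(1000, 4), nrow = 1)
  de <- differential_test(mk_expr(rbind(m, filler)), mk_groups())
  expect_equal(de$log2fc[1], 0)
  expect_equal(de$p_value[1], 1)
})

test_that("log2 fold change follows the pseudo-count TPM formula", {
  # engineer TPM means: per-sample totals 1e6 so counts are TPM directly
  f1 <- c(63, 63, 15, 15)
  filler <- 1e6 - f1
  de <- differential_test(mk_expr(rbind(f1, filler)), mk_groups())
  expect_equal(de$log2fc[1], log2(64 / 16))
})

test_that("the test is invariant to sample order and anti-symmetric in groups", {
  set.seed(8)
  expr <- random_expr(40, 8, seed = 8)
  groups <- tibble::tibble(sample_id = paste0("S", 1:8),
                           group = rep(c("HF", "LF"), each = 4))
  de1 <- differential_test(expr, groups)
  perm <- c("feature_id", "feature_class", "S3", "S1", "S4", "S2",
            "S7", "S5", "S8", "S6")
  de2 <- differential_test(expr[, perm], groups)
  expect_equal(de1$p_value, de2$p_value, tolerance = 1e-10)
  expect_equal(de1$log2fc, de2$log2fc)
  flipped <- groups
  flipped$group <- ifelse(groups$group == "HF", "LF", "HF")
  de3 <- differential_test(expr, flipped)
  expect_equal(de3$log2fc, -de1$log2fc, tolerance = 1e-12)
  expect_equal(de3$p_value, de1$p_value, tolerance = 1e-8)
})

test_that("exact NB p-values track an established exact-test implementation", {
  skip_if_not_installed("edgeR")
  sim <- simulate_expression(sim_config(n_mirna = 0, n_mrna = 200, n_lncrna = 0,
                                        n_circrna = 0, n_planted_de_mirna = 0,
                                        n_planted_triplets = 0,
                                        with_sequences = FALSE, seed = 31))
  de <- differential_test(sim$counts, sim$groups)
  cnt <- as.matrix(sim$counts[, -(1:2)])
  grp <- factor(sim$groups$group, levels = c("LF", "HF"))
  y <- edgeR::DGEList(counts = cnt, group = grp)
  y <- edgeR::estimateCommonDisp(y)
  et <- edgeR::exactTest(y)
  expect_gt(cor(de$p_value, et$table$PValue, method = "spearman"), 0.95)
})

test_that("screen boundaries are inclusive exactly as stated", {
  rec <- tibble::tibble(
    feature_id = c("a", "b", "c", "d"),
    feature_class = "miRNA",
    log2fc = c(1.0, 0.99, -1.0, 2),
    p_value = c(0.05, 0.001, 0.05, 0.051)
  )
  out <- screen_de(rec)
  expect_equal(out$significant, c(TRUE, FALSE, TRUE, FALSE))
  expect_equal(out$direction, c("up", "ns", "down", "ns"))
})

test_that("recovery of planted DE miRNAs is non-decreasing in effect size", {
  rec_at <- function(lfc) {
    sim <- simulate_expression(sim_config(n_planted_triplets = 0,
                                          de_log2fc = lfc, nb_dispersion = 0.05,
                                          with_sequences = FALSE, seed = 23))
    de <- screen_de(differential_test(sim$counts, sim$groups))
    sum(de$significant[match(sim$truth$de_mirnas$feature_id, de$feature_id)])
  }
  r <- vapply(c(0.5, 1.5, 3), rec_at, numeric(1))
  expect_true(all(diff(r) >= 0))
  expect_equal(r[3], 10)
})

test_that("the rank-based alternative agrees directionally with the exact test", {
  sim <- simulate_expression(sim_config(n_planted_triplets = 0, de_log2fc = 4,
                                        nb_dispersion = 0.02,
                                        with_sequences = FALSE, seed = 29))
  w <- screen_de(differential_test(sim$counts, sim$groups, method = "wilcoxon"),
                 p_threshold = 0.05)
  de_ids <- sim$truth$de_mirnas$feature_id
  # exact Wilcoxon at 4v4 bottoms out at p = 0.029: planted features reach it
  expect_true(all(w$p_value[match(de_ids, w$feature_id)] <= 0.05))
})

test_that("degenerate inputs error clearly", {
  expr <- random_expr(5, 4, seed = 2)
  expect_error(differential_test(expr, mk_groups(1, 3)), "two samples")
  g <- mk_groups()
  g$group <- "HF"
  expect_error(differential_test(expr, g), "two groups")
})
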