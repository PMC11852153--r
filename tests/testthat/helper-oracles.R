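# Independent brute-force oracles used across test files. These deliberately
# avoid the code paths they check.

# Spearman by definition: average ranks, then the raw Pearson sum formula.
oracle_spearman <- function(x, y) {
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  oracle_pearson(rx, ry)
}

oracle_pearson <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n; my <- sum(y) / n
  num <- sum((x - mx) * (y - my))
  den <- sqrt(sum((x - mx)^2)) * sqrt(sum((y - my)^2))
  num / den
}

# Exhaustive window scan for seed sites, built directly from the site
# definitions by string comparison.
oracle_seed_sites <- function(mirna, tx) {
  to_dna <- function(s) chartr("Uu", "Tt", toupper(s))
  rc <- function(s) {
    paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
  }
  m <- to_dna(mirna); tx <- to_dna(tx)
  core <- rc(substr(m, 2, 7))
  m8 <- chartr("ACGT", "TGCA", substr(m, 8, 8))
  out <- NULL
  for (p in seq_len(max(0, nchar(tx) - 5))) {
    if (substr(tx, p, p + 5) != core) next
    has_m8 <- p > 1 && substr(tx, p - 1, p - 1) == m8
    has_a1 <- p + 6 <= nchar(tx) && substr(tx, p + 6, p + 6) == "A"
    type <- if (has_m8 && has_a1) "8mer" else if (has_m8) "7mer-m8"
            else if (has_a1) "7mer-A1" else "6mer"
    out <- rbind(out, data.frame(site_type = type, position = p))
  }
  if (is.null(out)) data.frame(site_type = character(0), position = integer(0))
  else out
}

# Brute-force triple enumeration for ceRNA pairing.
oracle_triplets <- function(edges, expr_mat, threshold = 0.7,
                            ce_classes = c("lncRNA", "circRNA")) {
  out <- NULL
  for (m in unique(edges$mirna_id)) {
    e <- edges[edges$mirna_id == m, ]
    for (a in e$rna_id[e$rna_class %in% ce_classes]) {
      for (b in e$rna_id[e$rna_class == "mRNA"]) {
        r <- suppressWarnings(cor(expr_mat[a, ], expr_mat[b, ]))
        if (!is.na(r) && r > threshold) {
          out <- rbind(out, data.frame(rna_a = a, mirna_id = m, rna_b = b))
        }
      }
    }
  }
  if (is.null(out)) data.frame(rna_a = character(0), mirna_id = character(0),
                               rna_b = character(0))
  else out
}

# Hypergeometric upper tail by exhaustive enumeration of all size-n draws.
oracle_hyper_upper <- function(N, K, n, k) {
  draws <- utils::combn(N, n)
  in_set <- draws <= K  # first K elements of 1..N form the gene set
  mean(colSums(in_set) >= k)
}

# Small random expression table of the tidy layout.
random_expr <- function(n_feat = 10, n_samp = 8, classes = "mRNA", seed = 1) {
  set.seed(seed)
  d <- tibble::tibble(
    feature_id = sprintf("f%03d", seq_len(n_feat)),
    feature_class = rep_len(classes, n_feat)
  )
  for (s in paste0("S", seq_len(n_samp))) {
    d[[s]] <- rnbinom(n_feat, mu = 100, size = 10)
  }
  d
}

quiet_pipeline <- function(...) {
  suppressWarnings(run_pipeline(pipeline_config(...)))
}
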