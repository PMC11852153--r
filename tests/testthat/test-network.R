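# ceRNA pairing, network assembly/export, recovery scoring.

mk_edge <- function(m, r, cls, rho = -0.9) {
  tibble::tibble(mirna_id = m, rna_id = r, rna_class = cls, spearman_rho = rho)
}

test_that("a shared miRNA with perfectly co-expressed targets yields one triplet", {
  expr <- tibble::tibble(feature_id = c("m", "g1", "l1"),
                         feature_class = c("miRNA", "mRNA", "lncRNA"))
  for (j in 1:8) expr[[paste0("S", j)]] <- c(9 - j, j, 2 * j)  # g1, l1 colinear
  edges <- dplyr::bind_rows(mk_edge("m", "g1", "mRNA"), mk_edge("m", "l1", "lncRNA"))
  tr <- pair_cernas(edges, expr)
  expect_equal(nrow(tr), 1)
  expect_equal(tr$rna_a, "l1")
  expect_equal(tr$rna_b, "g1")
  expect_equal(tr$pearson_r, 1, tolerance = 1e-12)
})

test_that("the Pearson threshold is strict: r equal to it is dropped", {
  set.seed(41)
  expr <- random_expr(3, 8, classes = c("miRNA", "mRNA", "lncRNA"), seed = 41)
  edges <- dplyr::bind_rows(mk_edge("f001", "f002", "mRNA"),
                            mk_edge("f001", "f003", "lncRNA"))
  v <- as.matrix(expr[, -(1:2)])
  r_obs <- cor(v[3, ], v[2, ])
  expect_equal(nrow(pair_cernas(edges, expr, threshold = r_obs)), 0)
  expect_equal(nrow(pair_cernas(edges, expr, threshold = r_obs - 1e-9)), 1)
})

test_that("pairing equals brute-force triple enumeration on random instances", {
  set.seed(55)
  for (rep in 1:50) {
    n_mir <- sample(2:10, 1)
    n_rna <- sample(4:20, 1)
    classes <- sample(c("mRNA", "lncRNA", "circRNA"), n_rna, replace = TRUE)
    expr <- random_expr(n_mir + n_rna, 8,
                        classes = c(rep("miRNA", n_mir), classes),
                        seed = 1000 + rep)
    ids <- expr$feature_id
    mir_ids <- ids[seq_len(n_mir)]
    rna_ids <- ids[-seq_len(n_mir)]
    # random subset of miRNA-target edges with dummy screened rho
    grid <- expand.grid(mirna_id = mir_ids, rna_id = rna_ids,
                        stringsAsFactors = FALSE)
    grid <- grid[sample(nrow(grid), min(nrow(grid), 25)), ]
    edges <- tibble::tibble(
      mirna_id = grid$mirna_id, rna_id = grid$rna_id,
      rna_class = expr$feature_class[match(grid$rna_id, ids)],
      spearman_rho = -runif(nrow(grid), 0.6, 1)
    )
    v <- as.matrix(expr[, -(1:2)]); rownames(v) <- ids
    got <- suppressWarnings(pair_cernas(edges, expr, threshold = 0.3))
    want <- oracle_triplets(edges, v, threshold = 0.3)
    expect_equal(sort(paste(got$rna_a, got$mirna_id, got$rna_b)),
                 sort(paste(want$rna_a, want$mirna_id, want$rna_b)))
  }
})

test_that("restricting the partner class restricts the pair universe", {
  expr <- tibble::tibble(feature_id = c("m", "g", "l", "c"),
                         feature_class = c("miRNA", "mRNA", "lncRNA", "circRNA"))
  for (j in 1:8) expr[[paste0("S", j)]] <- c(9 - j, j, j * 2, j + 3)
  edges <- dplyr::bind_rows(mk_edge("m", "g", "mRNA"), mk_edge("m", "l", "lncRNA"),
                            mk_edge("m", "c", "circRNA"))
  expect_equal(nrow(pair_cernas(edges, expr, mode = "both")), 2)
  expect_equal(pair_cernas(edges, expr, mode = "lncRNA")$rna_a, "l")
  expect_equal(pair_cernas(edges, expr, mode = "circRNA")$rna_a, "c")
})

mk_triplet <- function(a = "l1", m = "m1", b = "g1", rho = -0.8, r = 0.9,
                       a_class = "lncRNA") {
  tibble::tibble(rna_a = a, rna_a_class = a_class, mirna_id = m,
                 rna_b = b, rna_b_class = "mRNA",
                 rho_a = rho, rho_b = rho, pearson_r = r)
}

test_that("network assembly deduplicates and keeps class/witness invariants", {
  tr <- dplyr::bind_rows(mk_triplet(), mk_triplet(a = "l2"),
                         mk_triplet(a = "l1", m = "m2"))
  net <- assemble_network(tr)
  expect_equal(sum(net$nodes$id == "l1"), 1)
  g <- glance(net)
  expect_equal(g$n_mirna, 2)
  expect_equal(g$n_mrna, 1)
  expect_equal(g$n_lncrna, 2)
  expect_equal(g$n_interactions, 3)
  mt <- net$edges[net$edges$type == "mirna_target", ]
  expect_true(all(mt$from %in% c("m1", "m2")))
  expect_false(any(mt$to %in% c("m1", "m2")))
})

test_that("empty input gives an empty network and invalid triplets are rejected", {
  net <- assemble_network(mk_triplet()[0, ])
  expect_equal(unlist(glance(net)[1, 1:7]), setNames(rep(0, 7),
    c("n_nodes", "n_mirna", "n_mrna", "n_lncrna", "n_circrna",
      "n_edges", "n_interactions")))
  expect_error(assemble_network(mk_triplet(rho = -0.5)), "invariant")
  expect_error(assemble_network(mk_triplet(r = 0.7)), "invariant")
  expect_error(assemble_network(mk_triplet(a = "g1", b = "g1")), "invariant")
})

test_that("one triplet exports as 3 SIF interaction lines and round-trips", {
  net <- assemble_network(mk_triplet())
  dir <- tempfile()
  paths <- export_network(net, dir)
  sif <- readLines(paths[["sif"]])
  expect_length(sif, 3)
  expect_length(grep("mirna_target", sif), 2)
  expect_length(grep("cerna_pair", sif), 1)
  back <- import_network(paths[["sif"]], paths[["attrs"]])
  g1 <- igraph::graph_from_data_frame(net$edges[, c("from", "to")], directed = FALSE)
  g2 <- igraph::graph_from_data_frame(back$edges[, c("from", "to")], directed = FALSE)
  expect_true(igraph::isomorphic(g1, g2))
  expect_equal(sort(back$nodes$id), sort(net$nodes$id))
  # node classes partition the node set
  expect_equal(sum(table(back$nodes$class)), nrow(back$nodes))
  expect_true(file.exists(paths[["graphml"]]))
})

test_that("recovery scoring handles perfect, partial and degenerate cases", {
  truth <- structure(list(
    de_mirnas = tibble::tibble(feature_id = "m1", direction = "up"),
    triplets = tibble::tibble(rna_a = c("l1", "l2"), rna_a_class = "lncRNA",
                              mirna_id = c("m1", "m2"), rna_b = c("g1", "g2"),
                              rna_b_class = "mRNA"),
    read_composition = NULL), class = "sim_truth")
  perfect <- dplyr::bind_rows(mk_triplet(), mk_triplet(a = "l2", m = "m2", b = "g2"))
  sc <- score_recovery(perfect, truth)
  expect_equal(sc$precision, c(1, 1))
  expect_equal(sc$recall, c(1, 1))
  partial <- dplyr::bind_rows(mk_triplet(), mk_triplet(a = "l9", m = "m1", b = "g1"))
  sp <- score_recovery(partial, truth)
  expect_equal(sp$recall[sp$level == "triplet"], 0.5)
  expect_equal(sp$precision[sp$level == "triplet"], 0.5)
  expect_warning(s0 <- score_recovery(mk_triplet()[0, ], truth), "precision undefined")
  expect_equal(s0$recall[1], 0)
  expect_true(is.nan(s0$precision[1]))
})

test_that("with no planted structure discoveries stay within the null envelope", {
  null_cfg <- function(seed) {
    sim_config(n_samples_per_group = 4, n_mirna = 5, n_mrna = 30, n_lncrna = 10,
               n_circrna = 5, n_planted_de_mirna = 0, n_planted_triplets = 0,
               with_sequences = FALSE, seed = seed)
  }
  n_trip <- vapply(1:12, function(s) {
    run <- quiet_pipeline(seed = s, sim = null_cfg(s), with_reads = FALSE,
                          de_filter = FALSE, out_dir = tempfile())
    nrow(run$triplets)
  }, numeric(1))
  env <- quantile(n_trip, c(0.025, 0.975))
  probe <- quiet_pipeline(seed = 99, sim = null_cfg(99), with_reads = FALSE,
                          de_filter = FALSE, out_dir = tempfile())
  expect_gte(nrow(probe$triplets), floor(env[1]))
  expect_lte(nrow(probe$triplets), ceiling(env[2]) + 2)
})
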