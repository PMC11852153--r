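# ceRNA triplet assembly and network export. Two RNAs sharing a repressing
# miRNA and strongly positively co-expressed form a sponge (ceRNA) pair; the
# triplet (ceRNA, miRNA, mRNA) is the atom of the exported network.

#' Pair screened miRNA targets into ceRNA triplets
#'
#' For each miRNA, forms all (mRNA, lncRNA) and/or (mRNA, circRNA) pairs
#' among its anti-correlated targets and keeps pairs whose Pearson
#' correlation is strictly greater than `threshold` ("more than 0.7").
#' `rna_a` is the non-coding partner (lncRNA/circRNA), `rna_b` the mRNA.
#'
#' @param edges Tibble of screened edges from [spearman_screen()]
#'   (`mirna_id`, `rna_id`, `rna_class`, `spearman_rho`).
#' @param expr Expression tibble used for the co-expression correlation
#'   (the same vectors as the Spearman screen).
#' @param threshold Strict lower bound on Pearson's r (a value
#'   mathematically equal to the threshold is dropped; the comparison
#'   carries a 1e-12 guard against floating-point round-off).
#' @param mode `"both"`, `"lncRNA"` or `"circRNA"`: which non-coding partner
#'   classes to pair with mRNAs.
#' @return Tibble `rna_a`, `rna_a_class`, `mirna_id`, `rna_b`, `rna_b_class`,
#'   `rho_a`, `rho_b`, `pearson_r`.
#' @export
pair_cernas <- function(edges, expr, threshold = 0.7,
                        mode = c("both", "lncRNA", "circRNA")) {
  mode <- match.arg(mode)
  needed <- c("mirna_id", "rna_id", "rna_class", "spearman_rho")
  stopifnot(all(needed %in% names(edges)))
  assert_expr(expr)
  v <- expr_values(expr)
  missing <- setdiff(unique(edges$rna_id), rownames(v))
  if (length(missing)) {
    stop("edge features absent from expression table: ",
         paste(head(missing, 3), collapse = ", "))
  }
  ce_classes <- switch(mode, both = c("lncRNA", "circRNA"),
                       lncRNA = "lncRNA", circRNA = "circRNA")

  empty <- tibble::tibble(
    rna_a = character(0), rna_a_class = character(0),
    mirna_id = character(0), rna_b = character(0), rna_b_class = character(0),
    rho_a = numeric(0), rho_b = numeric(0), pearson_r = numeric(0)
  )
  if (nrow(edges) == 0) return(empty)

  n_skip <- 0L
  out <- purrr::map_dfr(split(edges, edges$mirna_id), function(e) {
    mr <- e[e$rna_class == "mRNA", ]
    ce <- e[e$rna_class %in% ce_classes, ]
    if (nrow(mr) == 0 || nrow(ce) == 0) return(NULL)
    grid <- tidyr::expand_grid(a = seq_len(nrow(ce)), b = seq_len(nrow(mr)))
    r <- vapply(seq_len(nrow(grid)), function(k) {
      row_cor(v[ce$rna_id[grid$a[k]], ], v[mr$rna_id[grid$b[k]], ], "pearson")
    }, numeric(1))
    n_skip <<- n_skip + sum(is.na(r))
    keep <- !is.na(r) & r > threshold + 1e-12  # strict, guarded against round-off
    if (!any(keep)) return(NULL)
    tibble::tibble(
      rna_a = ce$rna_id[grid$a[keep]],
      rna_a_class = ce$rna_class[grid$a[keep]],
      mirna_id = e$mirna_id[1],
      rna_b = mr$rna_id[grid$b[keep]],
      rna_b_class = "mRNA",
      rho_a = ce$spearman_rho[grid$a[keep]],
      rho_b = mr$spearman_rho[grid$b[keep]],
      pearson_r = r[keep]
    )
  })
  if (n_skip > 0) warning(n_skip, " pair(s) skipped: constant expression vector")
  if (nrow(out) == 0) return(empty)
  dplyr::arrange(out, .data$mirna_id, .data$rna_a, .data$rna_b)
}

#' Assemble a ceRNA network from validated triplets
#'
#' Deduplicates nodes and edges. Edges are typed: `mirna_target` (miRNA to
#' RNA, carrying the Spearman rho) and `cerna_pair` (the two partner RNAs,
#' carrying the Pearson r); every cerna_pair edge is witnessed by at least
#' one shared miRNA in the network. Triplets violating the screen invariants
#' (arm rho above the Spearman threshold, pair r at or below the Pearson
#' threshold, or a self-pair) are rejected.
#'
#' @param triplets Tibble from [pair_cernas()].
#' @param de Optional screened `sponge_de` table; node attribute `direction`
#'   is joined from it.
#' @param spearman_threshold,pearson_threshold Invariant bounds used for
#'   validation.
#' @return A `cerna_network`: list with `nodes`, `edges`, `triplets`.
#' @export
assemble_network <- function(triplets, de = NULL,
                             spearman_threshold = -0.6,
                             pearson_threshold = 0.7) {
  cols <- c("rna_a", "rna_a_class", "mirna_id", "rna_b", "rna_b_class",
            "rho_a", "rho_b", "pearson_r")
  stopifnot(all(cols %in% names(triplets)))
  if (nrow(triplets) > 0) {
    bad <- triplets$rho_a > spearman_threshold |
      triplets$rho_b > spearman_threshold |
      triplets$pearson_r <= pearson_threshold |
      triplets$rna_a == triplets$rna_b
    if (any(bad)) {
      stop(sum(bad), " triplet(s) violate the screen invariants ",
           "(arm rho, pair r, or a self-pair)")
    }
  }

  nodes <- dplyr::bind_rows(
    tibble::tibble(id = triplets$mirna_id, class = "miRNA"),
    tibble::tibble(id = triplets$rna_a, class = triplets$rna_a_class),
    tibble::tibble(id = triplets$rna_b, class = triplets$rna_b_class)
  ) |> dplyr::distinct()
  if (!is.null(de)) {
    dirn <- tibble::as_tibble(de)[, c("feature_id", "direction")]
    nodes <- dplyr::left_join(nodes, dirn, by = c(id = "feature_id"))
  } else {
    nodes$direction <- NA_character_
  }

  arm_edges <- dplyr::bind_rows(
    tibble::tibble(from = triplets$mirna_id, to = triplets$rna_a,
                   type = "mirna_target", weight = triplets$rho_a,
                   provenance = paste0("arm:", triplets$mirna_id, "->", triplets$rna_a)),
    tibble::tibble(from = triplets$mirna_id, to = triplets$rna_b,
                   type = "mirna_target", weight = triplets$rho_b,
                   provenance = paste0("arm:", triplets$mirna_id, "->", triplets$rna_b))
  )
  pair_edges <- tibble::tibble(
    from = triplets$rna_a, to = triplets$rna_b,
    type = "cerna_pair", weight = triplets$pearson_r,
    provenance = paste0("via:", triplets$mirna_id)
  )
  edges <- dplyr::bind_rows(arm_edges, pair_edges) |>
    dplyr::group_by(.data$from, .data$to, .data$type) |>
    dplyr::summarise(weight = .data$weight[1],
                     provenance = paste(unique(.data$provenance), collapse = ";"),
                     .groups = "drop")

  net <- structure(
    list(nodes = nodes, edges = edges, triplets = tibble::as_tibble(triplets)),
    class = "cerna_network"
  )
  validate_network(net)
  net
}

validate_network <- function(net) {
  mirna_ids <- net$nodes$id[net$nodes$class == "miRNA"]
  mt <- net$edges[net$edges$type == "mirna_target", ]
  if (nrow(mt) > 0) {
    stopifnot(all(mt$from %in% mirna_ids), !any(mt$to %in% mirna_ids))
  }
  cp <- net$edges[net$edges$type == "cerna_pair", ]
  if (nrow(cp) > 0) {
    witnesses <- grep("^via:", unlist(strsplit(cp$provenance, ";")), value = TRUE)
    stopifnot(length(witnesses) >= nrow(cp),
              all(sub("^via:", "", witnesses) %in% mirna_ids))
  }
  invisible(net)
}

#' @export
print.cerna_network <- function(x, ...) {
  g <- glance(x)
  cat("<cerna_network> ", g$n_nodes, " nodes (", g$n_mirna, " miRNA, ",
      g$n_mrna, " mRNA, ", g$n_lncrna, " lncRNA, ", g$n_circrna,
      " circRNA), ", g$n_interactions, " interactions\n", sep = "")
  invisible(x)
}

#' @method glance cerna_network
#' @export
glance.cerna_network <- function(x, ...) {
  tibble::tibble(
    n_nodes = nrow(x$nodes),
    n_mirna = sum(x$nodes$class == "miRNA"),
    n_mrna = sum(x$nodes$class == "mRNA"),
    n_lncrna = sum(x$nodes$class == "lncRNA"),
    n_circrna = sum(x$nodes$class == "circRNA"),
    n_edges = nrow(x$edges),
    n_interactions = nrow(x$triplets)
  )
}

#' @method tidy cerna_network
#' @export
tidy.cerna_network <- function(x, ...) x$edges

as_igraph <- function(net) {
  igraph::graph_from_data_frame(net$edges, directed = FALSE,
                                vertices = net$nodes)
}

#' Export / import a ceRNA network in Cytoscape-friendly formats
#'
#' Writes a SIF file (`node TAB relation TAB node`), a node-attribute TSV
#' (`id`, `class`, `direction`) and GraphML. Re-importing the SIF plus
#' attributes reconstructs an isomorphic network.
#'
#' @param net A `cerna_network`.
#' @param dir Output directory (created if needed).
#' @param basename File stem for the three outputs.
#' @param formats Subset of `c("sif", "attrs", "graphml")`.
#' @return Named character vector of written paths, invisibly.
#' @export
export_network <- function(net, dir, basename = "cerna_network",
                           formats = c("sif", "attrs", "graphml")) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  if ("sif" %in% formats) {
    p <- file.path(dir, paste0(basename, ".sif"))
    lines <- sprintf("%s\t%s\t%s", net$edges$from, net$edges$type, net$edges$to)
    writeLines(lines, p)
    paths["sif"] <- p
  }
  if ("attrs" %in% formats) {
    p <- file.path(dir, paste0(basename, ".node_attrs.tsv"))
    utils::write.table(net$nodes, p, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths["attrs"] <- p
  }
  if ("graphml" %in% formats) {
    p <- file.path(dir, paste0(basename, ".graphml"))
    igraph::write_graph(as_igraph(net), p, format = "graphml")
    paths["graphml"] <- p
  }
  invisible(paths)
}

#' @rdname export_network
#' @param sif_path,attrs_path Paths written by [export_network()].
#' @export
import_network <- function(sif_path, attrs_path) {
  lines <- readLines(sif_path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  edges <- tibble::tibble(
    from = vapply(parts, `[`, character(1), 1),
    type = vapply(parts, `[`, character(1), 2),
    to = vapply(parts, `[`, character(1), 3)
  )
  nodes <- tibble::as_tibble(utils::read.delim(attrs_path, sep = "\t",
                                               colClasses = "character"))
  structure(list(nodes = nodes, edges = edges, triplets = tibble::tibble()),
            class = "cerna_network")
}

#' Score recovery of planted triplets
#'
#' Compares discovered triplets against the generator's truth at two levels:
#' whole triplets (ceRNA, miRNA, mRNA) and individual miRNA-target arms.
#' Precision with no discoveries is undefined and reported as NaN with a
#' warning.
#'
#' @param x A `cerna_network` or a triplet tibble.
#' @param truth A `sim_truth` from the same simulation.
#' @return Tibble `level` ("triplet", "arm"), `tp`, `n_found`, `n_planted`,
#'   `precision`, `recall`.
#' @export
score_recovery <- function(x, truth) {
  triplets <- if (inherits(x, "cerna_network")) x$triplets else tibble::as_tibble(x)
  stopifnot(inherits(truth, "sim_truth"))
  tkey <- function(d) paste(d$rna_a, d$mirna_id, d$rna_b, sep = "|")
  found_t <- if (nrow(triplets)) unique(tkey(triplets)) else character(0)
  plant_t <- if (nrow(truth$triplets)) unique(tkey(truth$triplets)) else character(0)

  akey <- function(d) unique(c(paste(d$mirna_id, d$rna_a, sep = "|"),
                               paste(d$mirna_id, d$rna_b, sep = "|")))
  found_a <- if (nrow(triplets)) akey(triplets) else character(0)
  plant_a <- if (nrow(truth$triplets)) akey(truth$triplets) else character(0)

  level_row <- function(level, found, planted) {
    tp <- length(intersect(found, planted))
    prec <- if (length(found) == 0) NaN else tp / length(found)
    rec <- if (length(planted) == 0) NaN else tp / length(planted)
    tibble::tibble(level = level, tp = tp, n_found = length(found),
                   n_planted = length(planted), precision = prec, recall = rec)
  }
  out <- dplyr::bind_rows(level_row("triplet", found_t, plant_t),
                          level_row("arm", found_a, plant_a))
  if (any(is.nan(out$precision))) {
    warning("no discoveries at some level: precision undefined (NaN)")
  }
  out
}
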