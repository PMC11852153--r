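# Over-representation analysis of a gene list against user-supplied gene-set
# collections (GMT), by the hypergeometric upper tail with Benjamini-Hochberg
# adjustment across all tested terms.

#' Read / write gene-set collections in GMT format
#'
#' One set per line: term id, description, then member genes,
#' tab-separated.
#'
#' @param path GMT file path.
#' @return Tibble `term_id`, `term_name`, `genes` (list column).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  tibble::tibble(
    term_id = vapply(parts, `[`, character(1), 1),
    term_name = vapply(parts, `[`, character(1), 2),
    genes = lapply(parts, function(p) unique(p[-(1:2)]))
  )
}

#' @rdname read_gmt
#' @param collections Tibble as returned by [read_gmt()].
#' @export
write_gmt <- function(collections, path) {
  lines <- vapply(seq_len(nrow(collections)), function(i) {
    paste(c(collections$term_id[i], collections$term_name[i],
            collections$genes[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Hypergeometric over-representation analysis
#'
#' For each term with `K` universe members, a query of size `n` drawn from a
#' universe of size `N` and `k` observed hits, the p-value is the upper tail
#' `P[X >= k]` for `X ~ Hypergeometric(N, K, n)`. Gene sets are intersected
#' with the universe before testing; q-values are Benjamini-Hochberg across
#' all tested terms; results are sorted by p.
#'
#' @param query Character vector of query genes (must lie in the universe).
#' @param collections GMT tibble from [read_gmt()], or a named list of
#'   character vectors.
#' @param universe Character vector of background genes.
#' @param min_set_size Terms with fewer than this many universe members are
#'   skipped.
#' @return Tibble `term_id`, `term_name`, `k`, `K`, `n`, `N`, `p_value`,
#'   `q_value`.
#' @examples
#' ora(c("g1", "g2"), list(set_a = c("g1", "g2", "g3")),
#'     universe = paste0("g", 1:10))
#' @export
ora <- function(query, collections, universe, min_set_size = 1) {
  if (length(universe) == 0) stop("empty universe")
  query <- unique(query)
  universe <- unique(universe)
  if (length(query) == 0) stop("empty query")
  outside <- setdiff(query, universe)
  if (length(outside)) {
    stop("query genes outside the universe: ",
         paste(head(outside, 3), collapse = ", "))
  }
  if (is.list(collections) && !is.data.frame(collections)) {
    collections <- tibble::tibble(
      term_id = names(collections),
      term_name = names(collections),
      genes = unname(collections)
    )
  }
  N <- length(universe)
  n <- length(query)
  res <- purrr::map_dfr(seq_len(nrow(collections)), function(i) {
    set <- intersect(collections$genes[[i]], universe)
    K <- length(set)
    if (K < min_set_size) return(NULL)
    k <- length(intersect(query, set))
    tibble::tibble(
      term_id = collections$term_id[i],
      term_name = collections$term_name[i],
      k = k, K = K, n = n, N = N,
      p_value = phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    )
  })
  if (nrow(res) == 0) {
    return(tibble::tibble(term_id = character(0), term_name = character(0),
                          k = integer(0), K = integer(0), n = integer(0),
                          N = integer(0), p_value = numeric(0),
                          q_value = numeric(0)))
  }
  res$q_value <- p.adjust(res$p_value, method = "BH")
  dplyr::arrange(res, .data$p_value, .data$term_id)
}
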