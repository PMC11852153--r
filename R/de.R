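# TPM normalisation and the two-group differential screen.
#
# The differential test is an exact conditional negative-binomial test: counts
# are first scaled to a common library size, a single common dispersion is
# estimated across all features by method of moments, and for each feature the
# group totals are compared through the conditional distribution of the
# first-group total given the overall total (summing the probabilities of all
# outcomes at most as likely as the observed one, two-sided). This is the
# classical small-n exact test family for RNA-seq counts, kept deliberately
# simple: no shrinkage toward tagwise dispersions, no TMM factors.

#' Transcripts-per-million normalisation
#'
#' Scales each sample column to sum to one million. Small-RNA tags get no
#' length correction, so TPM is proportional to counts within a sample.
#'
#' @param expr Expression tibble (`feature_id`, `feature_class`, sample
#'   columns) of raw counts.
#' @return The same tibble with each sample column summing to 1e6 (kind
#'   "tpm").
#' @examples
#' m <- tibble::tibble(feature_id = c("a", "b"), feature_class = "miRNA",
#'                     S1 = c(1, 3))
#' tpm_normalize(m)$S1
#' @export
tpm_normalize <- function(expr) {
  assert_expr(expr)
  sc <- sample_cols(expr)
  for (s in sc) {
    tot <- sum(expr[[s]])
    if (tot <= 0) stop("sample ", s, " has an all-zero count column")
    expr[[s]] <- expr[[s]] / tot * 1e6
  }
  attr(expr, "kind") <- "tpm"
  expr
}

# Common dispersion by pooled method of moments on library-size-adjusted
# counts: E[within-group variance] = mean + phi * mean^2, solved as a ratio
# of sums across features for stability. A small number of features with
# genuinely high biological variability would otherwise dominate the pooled
# ratio, so features whose individual estimate exceeds 10x the pooled value
# are rejected as gross outliers and the pool re-estimated; under a clean
# common-dispersion null this cut is essentially never triggered.
estimate_common_dispersion <- function(y, group) {
  lv <- unique(group)
  m <- lapply(lv, function(g) rowMeans(y[, group == g, drop = FALSE]))
  v <- lapply(lv, function(g) apply(y[, group == g, drop = FALSE], 1, var))
  num <- Reduce(`+`, Map(function(vi, mi) vi - mi, v, m)) / length(lv)
  den <- Reduce(`+`, lapply(m, function(mi) mi^2)) / length(lv)
  ok <- den > 0 & is.finite(num)
  ratio <- num / den
  # start from the (robust) median ratio so heavy contamination cannot
  # drag the cut threshold up with it; the reported value is the pooled
  # ratio of sums over the kept features
  phi <- median(ratio[ok])
  for (it in 1:4) {
    keep <- ok & ratio <= 10 * max(phi, 0.01)
    if (!any(keep)) break
    phi_new <- sum(num[keep]) / sum(den[keep])
    if (!is.finite(phi_new) || abs(phi_new - phi) < 1e-10) { phi <- phi_new; break }
    phi <- phi_new
  }
  max(phi, 1e-6)
}

# Two-sided exact conditional NB test for one feature: group totals s1, s2
# with n1, n2 samples and common dispersion phi. Work on the conditional
# distribution of the group-1 total given t = s1 + s2, restricted to a window
# that carries all but ~1e-12 of the mass.
nb_exact_test <- function(s1, s2, n1, n2, phi) {
  t <- s1 + s2
  if (t == 0) return(1)
  mu0 <- t / (n1 + n2)
  mu1 <- n1 * mu0; mu2 <- n2 * mu0
  size1 <- n1 / phi; size2 <- n2 / phi
  lo <- max(0, min(s1, qnbinom(1e-13, mu = mu1, size = size1)))
  hi <- min(t, max(s1, qnbinom(1e-13, mu = mu1, size = size1, lower.tail = FALSE)))
  x <- lo:hi
  f <- dnbinom(x, mu = mu1, size = size1) * dnbinom(t - x, mu = mu2, size = size2)
  f_obs <- f[x == s1]
  tot <- sum(f)
  if (tot <= 0) return(1)
  min(1, sum(f[f <= f_obs * (1 + 1e-10)]) / tot)
}

#' Two-group differential expression by an exact negative-binomial test
#'
#' @param expr Expression tibble of raw counts.
#' @param groups Tibble `sample_id`, `group` with exactly two group levels and
#'   at least two samples each. Fold change is reported as the first level
#'   over the second in `group_order` (default "HF" over "LF" when present).
#' @param method `"exact"` for the NB exact conditional test, `"wilcoxon"`
#'   for a rank-based alternative (exact Wilcoxon rank-sum on TPM).
#' @param pseudo_tpm Pseudo-count (TPM units) added to both group means in the
#'   fold-change ratio.
#' @param group_order Optional length-2 character giving numerator and
#'   denominator groups.
#' @return A `sponge_de` tibble: `feature_id`, `feature_class`, `mean_tpm_1`,
#'   `mean_tpm_2` (numerator / denominator group means), `log2fc`, `p_value`.
#' @examples
#' sim <- simulate_expression(sim_config(n_mrna = 10, n_lncrna = 0,
#'                                       n_circrna = 0, n_planted_triplets = 0))
#' de <- differential_test(sim$counts, sim$groups)
#' head(de)
#' @export
differential_test <- function(expr, groups, method = c("exact", "wilcoxon"),
                              pseudo_tpm = 1, group_order = NULL) {
  method <- match.arg(method)
  assert_expr(expr)
  sc <- sample_cols(expr)
  assert_groups(groups, sc)
  grp <- groups$group[match(sc, groups$sample_id)]
  lv <- group_order %||% (if (all(c("HF", "LF") %in% grp)) c("HF", "LF")
                          else sort(unique(grp)))
  if (length(unique(grp)) != 2) stop("exactly two groups are required")
  if (any(table(grp) < 2)) stop("need at least two samples per group")

  counts <- expr_values(expr)
  lib <- colSums(counts)
  if (any(lib == 0)) stop("a sample has zero total counts")
  g1 <- grp == lv[1]; g2 <- grp == lv[2]
  if (sum(counts[, g1]) == 0 || sum(counts[, g2]) == 0) {
    stop("a group has zero total counts")
  }

  tpm <- t(t(counts) / lib * 1e6)
  mean1 <- unname(rowMeans(tpm[, g1, drop = FALSE]))
  mean2 <- unname(rowMeans(tpm[, g2, drop = FALSE]))
  log2fc <- log2((mean1 + pseudo_tpm) / (mean2 + pseudo_tpm))

  if (method == "exact") {
    # equalise library sizes: scale to the geometric mean library, then round
    gm <- exp(mean(log(lib)))
    y <- round(t(t(counts) / lib * gm))
    phi <- estimate_common_dispersion(y, grp)
    s1 <- rowSums(y[, g1, drop = FALSE])
    s2 <- rowSums(y[, g2, drop = FALSE])
    n1 <- sum(g1); n2 <- sum(g2)
    p <- vapply(seq_len(nrow(y)),
                function(i) nb_exact_test(s1[i], s2[i], n1, n2, phi),
                numeric(1))
  } else {
    p <- vapply(seq_len(nrow(tpm)), function(i) {
      x <- tpm[i, g1]; yv <- tpm[i, g2]
      if (all(x == x[1]) && all(yv == yv[1]) && x[1] == yv[1]) return(1)
      suppressWarnings(wilcox.test(x, yv, exact = TRUE)$p.value)
    }, numeric(1))
  }

  out <- tibble::tibble(
    feature_id = expr$feature_id,
    feature_class = expr$feature_class,
    mean_tpm_1 = mean1, mean_tpm_2 = mean2,
    log2fc = log2fc, p_value = p
  )
  attr(out, "groups") <- lv
  attr(out, "method") <- method
  class(out) <- c("sponge_de", class(out))
  out
}

#' Apply the significance screen to differential results
#'
#' A feature is significant when `|log2fc| >= lfc_threshold` and
#' `p_value <= p_threshold` (both boundaries inclusive). Direction is `up`
#' (positive fold change), `down`, or `ns`.
#'
#' @param records A `sponge_de` tibble from [differential_test()].
#' @param lfc_threshold,p_threshold Screen thresholds.
#' @return The records with `significant` and `direction` columns.
#' @export
screen_de <- function(records, lfc_threshold = 1, p_threshold = 0.05) {
  stopifnot(all(c("log2fc", "p_value") %in% names(records)))
  records$significant <- abs(records$log2fc) >= lfc_threshold &
    records$p_value <= p_threshold
  records$direction <- dplyr::case_when(
    records$significant & records$log2fc > 0 ~ "up",
    records$significant & records$log2fc < 0 ~ "down",
    .default = "ns"
  )
  if (!inherits(records, "sponge_de")) {
    class(records) <- c("sponge_de", class(records))
  }
  records
}

#' @method glance sponge_de
#' @export
glance.sponge_de <- function(x, ...) {
  sig <- x$significant %||% rep(NA, nrow(x))
  dirn <- x$direction %||% rep(NA_character_, nrow(x))
  tibble::tibble(
    n_features = nrow(x),
    n_significant = sum(sig, na.rm = TRUE),
    n_up = sum(dirn == "up", na.rm = TRUE),
    n_down = sum(dirn == "down", na.rm = TRUE),
    method = attr(x, "method") %||% NA_character_
  )
}

#' @method tidy sponge_de
#' @export
tidy.sponge_de <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "sponge_de")
  tibble::as_tibble(out)
}
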