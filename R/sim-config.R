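#' Configuration for the synthetic expression / read generator
#'
#' Bundles every knob of the planted-truth simulator. The defaults emulate a
#' 4-vs-4 two-group small-RNA study (high- vs low-trait groups, labelled
#' HF/LF) with a modest feature universe, ten planted differential miRNAs and
#' ten planted sponge triplets whose arm correlations are strong but noisy.
#'
#' @param n_samples_per_group Samples in each of the two groups.
#' @param n_mirna,n_mrna,n_lncrna,n_circrna Number of features per RNA class.
#' @param n_planted_de_mirna Number of miRNAs given a between-group fold
#'   change; directions alternate up/down.
#' @param de_log2fc Log2 fold change (HF over LF) applied to planted
#'   differential miRNAs on the mean scale.
#' @param n_planted_triplets Number of planted sponge triplets
#'   (ceRNA, miRNA, mRNA). Triplet miRNAs are taken from the planted
#'   differential miRNAs first, so they survive a differential-expression gate.
#' @param regulation_slope Log2-scale decrease of each regulated target per
#'   unit increase of its miRNA's log2 expression.
#' @param noise_sd Log2-scale Gaussian noise added independently to each
#'   regulated arm, per sample. 0 gives the deterministic regulation limit.
#' @param nb_dispersion Negative-binomial dispersion of counts
#'   (variance = mu + dispersion * mu^2). 0 means the deterministic count
#'   limit: counts equal their means exactly (continuous values, no sampling).
#' @param mean_log_expression_range Range (log2 scale) of baseline feature
#'   mean expression, drawn uniformly per feature.
#' @param mirna_signal_sd Log2-scale per-sample biological variability given
#'   to sponged (triplet) miRNAs; this is the cross-sample signal regulated
#'   targets track, so it controls how detectable planted arms are.
#' @param size_factors Optional per-sample library size factors
#'   (length `2 * n_samples_per_group`); defaults to 1 for every sample.
#' @param with_sequences Also generate miRNA and transcript sequences in
#'   which each planted target carries one 8mer site for its miRNA and no
#'   non-planted pair carries any site stronger than a 6mer, so seed-match
#'   target prediction recovers exactly the planted arms.
#' @param mirna_length,transcript_length Sequence lengths (nt) used when
#'   `with_sequences` is TRUE.
#' @param seed Integer seed; identical configurations reproduce identical data.
#'
#' @return A `sim_config` list.
#' @examples
#' cfg <- sim_config(n_mrna = 20, seed = 1)
#' @export
sim_config <- function(n_samples_per_group = 4,
                       n_mirna = 20, n_mrna = 200, n_lncrna = 50, n_circrna = 30,
                       n_planted_de_mirna = 10, de_log2fc = 3,
                       n_planted_triplets = 10,
                       regulation_slope = 1.5, noise_sd = 0.2,
                       nb_dispersion = 0.05,
                       mean_log_expression_range = c(5, 10),
                       mirna_signal_sd = 1,
                       size_factors = NULL,
                       with_sequences = TRUE,
                       mirna_length = 22, transcript_length = 120,
                       seed = 1) {
  cfg <- list(
    n_samples_per_group = as.integer(n_samples_per_group),
    n_mirna = as.integer(n_mirna), n_mrna = as.integer(n_mrna),
    n_lncrna = as.integer(n_lncrna), n_circrna = as.integer(n_circrna),
    n_planted_de_mirna = as.integer(n_planted_de_mirna),
    de_log2fc = as.numeric(de_log2fc),
    n_planted_triplets = as.integer(n_planted_triplets),
    regulation_slope = as.numeric(regulation_slope),
    noise_sd = as.numeric(noise_sd),
    nb_dispersion = as.numeric(nb_dispersion),
    mean_log_expression_range = as.numeric(mean_log_expression_range),
    mirna_signal_sd = as.numeric(mirna_signal_sd),
    size_factors = size_factors,
    with_sequences = isTRUE(with_sequences),
    mirna_length = as.integer(mirna_length),
    transcript_length = as.integer(transcript_length),
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  counts <- c(cfg$n_samples_per_group, cfg$n_mirna, cfg$n_mrna,
              cfg$n_lncrna, cfg$n_circrna, cfg$n_planted_de_mirna,
              cfg$n_planted_triplets)
  if (any(is.na(counts)) || any(counts < 0)) stop("all counts must be >= 0")
  if (cfg$n_samples_per_group < 1) stop("need at least one sample per group")
  if (cfg$n_planted_triplets > cfg$n_mirna) {
    stop("n_planted_triplets must be <= n_mirna")
  }
  if (cfg$n_planted_de_mirna > cfg$n_mirna) {
    stop("n_planted_de_mirna must be <= n_mirna")
  }
  if (cfg$n_planted_triplets > cfg$n_mrna) {
    stop("need one mRNA per planted triplet")
  }
  if (cfg$n_planted_triplets > 0 && cfg$n_lncrna + cfg$n_circrna < cfg$n_planted_triplets) {
    stop("need one lncRNA or circRNA per planted triplet")
  }
  if (cfg$noise_sd < 0) stop("noise_sd must be >= 0")
  if (cfg$nb_dispersion < 0) stop("nb_dispersion must be >= 0")
  if (length(cfg$mean_log_expression_range) != 2 ||
      diff(cfg$mean_log_expression_range) < 0) {
    stop("mean_log_expression_range must be an increasing pair")
  }
  n_samp <- 2L * cfg$n_samples_per_group
  if (!is.null(cfg$size_factors) && length(cfg$size_factors) != n_samp) {
    stop("size_factors must have one entry per sample (", n_samp, ")")
  }
  if (cfg$with_sequences %||% FALSE) {
    if (cfg$mirna_length < 8) stop("mirna_length must be >= 8")
    if (cfg$transcript_length < 24) stop("transcript_length must be >= 24")
  }
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat("  design: ", x$n_samples_per_group, " vs ", x$n_samples_per_group,
      " (HF/LF)\n", sep = "")
  cat("  features: ", x$n_mirna, " miRNA, ", x$n_mrna, " mRNA, ",
      x$n_lncrna, " lncRNA, ", x$n_circrna, " circRNA\n", sep = "")
  cat("  planted: ", x$n_planted_de_mirna, " DE miRNA (log2FC ",
      x$de_log2fc, "), ", x$n_planted_triplets, " triplets\n", sep = "")
  cat("  slope ", x$regulation_slope, ", noise_sd ", x$noise_sd,
      ", dispersion ", x$nb_dispersion, ", seed ", x$seed, "\n", sep = "")
  invisible(x)
}
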