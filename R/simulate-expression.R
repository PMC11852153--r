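#' Simulate multi-class count matrices with planted sponge structure
#'
#' Draws negative-binomial counts for miRNA, mRNA, lncRNA and circRNA features
#' over a two-group (HF/LF) design, planting (i) differential miRNAs whose
#' group means differ by `de_log2fc` and (ii) sponge triplets in which a
#' ceRNA (lncRNA or circRNA) and an mRNA are both repressed by the same
#' miRNA: each regulated arm's log2 mean is
#' `baseline - regulation_slope * (miRNA log2 signal, centred) + N(0, noise_sd)`,
#' independently per arm, so the two arms are anti-correlated with the miRNA
#' and positively co-expressed with each other. Sponged miRNAs carry
#' per-sample log2 variability (`mirna_signal_sd`) on top of any group effect;
#' all other features have constant means within (or across) groups.
#'
#' With `nb_dispersion = 0` counts equal their means exactly (continuous,
#' unrounded), which is the deterministic limit used for exact-recovery
#' checks; combined with `noise_sd = 0` every planted arm is a strictly
#' monotone decreasing map of the miRNA, so Spearman is exactly -1.
#'
#' @param config A [sim_config()].
#' @return A list with
#'   * `counts`: tibble `feature_id`, `feature_class`, one column per sample;
#'   * `groups`: tibble `sample_id`, `group`;
#'   * `truth`: a `sim_truth` list with `de_mirnas` (tibble `feature_id`,
#'     `direction`), `triplets` (tibble `rna_a`, `rna_a_class`, `mirna_id`,
#'     `rna_b`, `rna_b_class`) and `read_composition` (NULL here; filled by
#'     [simulate_reads()]);
#'   * `sequences` (when `with_sequences`): `mirnas` (tibble `mirna_id`,
#'     `sequence`) and `transcripts` (tibble `rna_id`, `rna_class`,
#'     `sequence`), built so seed-match prediction recovers exactly the
#'     planted arms.
#' @examples
#' sim <- simulate_expression(sim_config(n_mrna = 30, n_planted_triplets = 3))
#' dplyr::count(sim$counts, feature_class)
#' @export
simulate_expression <- function(config) {
  config <- validate_sim_config(config)
  withr::with_seed(config$seed, simulate_expression_impl(config))
}

simulate_expression_impl <- function(cfg) {
  n_per <- cfg$n_samples_per_group
  samples <- c(paste0("HF-", seq_len(n_per)), paste0("LF-", seq_len(n_per)))
  groups <- tibble::tibble(
    sample_id = samples,
    group = rep(c("HF", "LF"), each = n_per)
  )
  n_samp <- length(samples)
  size_factors <- cfg$size_factors %||% rep(1, n_samp)

  ids <- list(
    miRNA  = sprintf("mir-%03d",  seq_len(cfg$n_mirna)),
    mRNA   = sprintf("gene-%03d", seq_len(cfg$n_mrna)),
    lncRNA = sprintf("lnc-%03d",  seq_len(cfg$n_lncrna)),
    circRNA = sprintf("circ-%03d", seq_len(cfg$n_circrna))
  )
  feature_id <- unlist(ids, use.names = FALSE)
  feature_class <- rep(names(ids), lengths(ids))
  n_feat <- length(feature_id)

  # baseline log2 means, one per feature
  rng <- cfg$mean_log_expression_range
  baseline <- runif(n_feat, rng[1], rng[2])
  L <- matrix(baseline, nrow = n_feat, ncol = n_samp)
  rownames(L) <- feature_id

  # planted DE miRNAs: group effect on the mean scale, alternating direction
  de_mirnas <- tibble::tibble(feature_id = character(), direction = character())
  if (cfg$n_planted_de_mirna > 0) {
    de_ids <- ids$miRNA[seq_len(cfg$n_planted_de_mirna)]
    direction <- rep(c("up", "down"), length.out = length(de_ids))
    hf <- groups$group == "HF"
    for (i in seq_along(de_ids)) {
      shift <- if (direction[i] == "up") cfg$de_log2fc else -cfg$de_log2fc
      L[de_ids[i], hf] <- L[de_ids[i], hf] + shift
    }
    de_mirnas <- tibble::tibble(feature_id = de_ids, direction = direction)
  }

  # planted triplets: miRNAs drawn DE-first so they pass a DE gate downstream
  triplets <- tibble::tibble(
    rna_a = character(), rna_a_class = character(),
    mirna_id = character(), rna_b = character(), rna_b_class = character()
  )
  if (cfg$n_planted_triplets > 0) {
    trip_mirnas <- ids$miRNA[seq_len(cfg$n_planted_triplets)]
    # sponged miRNAs get per-sample biological variability: the signal that
    # regulated targets track across samples
    for (m in trip_mirnas) {
      L[m, ] <- L[m, ] + rnorm(n_samp, 0, cfg$mirna_signal_sd)
    }
    # ceRNA partners alternate lncRNA / circRNA while supplies last
    ce_pool <- character(0)
    lnc_i <- 0L; circ_i <- 0L
    for (t in seq_len(cfg$n_planted_triplets)) {
      take_lnc <- (t %% 2L == 1L && lnc_i < cfg$n_lncrna) || circ_i >= cfg$n_circrna
      if (take_lnc) {
        lnc_i <- lnc_i + 1L
        ce_pool[t] <- ids$lncRNA[lnc_i]
      } else {
        circ_i <- circ_i + 1L
        ce_pool[t] <- ids$circRNA[circ_i]
      }
    }
    trip_mrnas <- ids$mRNA[seq_len(cfg$n_planted_triplets)]
    for (t in seq_len(cfg$n_planted_triplets)) {
      m <- trip_mirnas[t]
      u <- L[m, ] - mean(L[m, ])  # centred miRNA log2 signal
      for (f in c(ce_pool[t], trip_mrnas[t])) {
        eps <- if (cfg$noise_sd > 0) rnorm(n_samp, 0, cfg$noise_sd) else 0
        L[f, ] <- baseline[match(f, feature_id)] - cfg$regulation_slope * u + eps
      }
    }
    triplets <- tibble::tibble(
      rna_a = ce_pool,
      rna_a_class = ifelse(grepl("^lnc", ce_pool), "lncRNA", "circRNA"),
      mirna_id = trip_mirnas,
      rna_b = trip_mrnas,
      rna_b_class = "mRNA"
    )
  }

  mu <- 2^L * rep(size_factors, each = n_feat)
  clamp_lo <- 2^-4
  clamp_hi <- 2^24
  if (any(mu < clamp_lo) || any(mu > clamp_hi)) {
    warning("some simulated means fell outside [2^-4, 2^24] and were clamped")
    mu <- pmin(pmax(mu, clamp_lo), clamp_hi)
  }

  if (cfg$nb_dispersion == 0) {
    counts_mat <- mu  # deterministic count limit: means themselves
  } else {
    counts_mat <- matrix(
      rnbinom(length(mu), mu = mu, size = 1 / cfg$nb_dispersion),
      nrow = n_feat
    )
  }
  counts <- tibble::as_tibble(as.data.frame(counts_mat))
  names(counts) <- samples
  counts <- dplyr::bind_cols(
    tibble::tibble(feature_id = feature_id, feature_class = feature_class),
    counts
  )
  attr(counts, "kind") <- "counts"

  truth <- structure(
    list(de_mirnas = de_mirnas, triplets = triplets, read_composition = NULL),
    class = "sim_truth"
  )
  sequences <- if (cfg$with_sequences %||% FALSE) {
    simulate_sequences(cfg, ids, triplets)
  } else NULL
  list(counts = counts, groups = groups, truth = truth, sequences = sequences)
}

# miRNA and transcript sequences realising the planted targeting structure:
# each planted target transcript carries exactly one 8mer site for its
# miRNA; every non-planted (miRNA, transcript) pair is scrubbed of 7mer/8mer
# sites so a seed-match predictor recovers exactly the planted arms.
simulate_sequences <- function(cfg, ids, triplets) {
  rand_seq <- function(len) paste(sample(DNA_BASES, len, replace = TRUE),
                                  collapse = "")
  # miRNAs with pairwise-distinct seed regions (positions 2-7)
  mir_seq <- character(cfg$n_mirna)
  seeds_seen <- character(0)
  for (i in seq_len(cfg$n_mirna)) {
    repeat {
      s <- rand_seq(cfg$mirna_length)
      sd6 <- substr(s, 2, 7)
      if (!sd6 %in% seeds_seen) { seeds_seen <- c(seeds_seen, sd6); break }
    }
    mir_seq[i] <- s
  }
  mirnas <- tibble::tibble(mirna_id = ids$miRNA, sequence = mir_seq)

  tx_ids <- c(ids$mRNA, ids$lncRNA, ids$circRNA)
  tx_class <- rep(c("mRNA", "lncRNA", "circRNA"),
                  c(cfg$n_mrna, cfg$n_lncrna, cfg$n_circrna))
  L <- cfg$transcript_length
  tx_seq <- vapply(tx_ids, function(i) rand_seq(L), character(1))

  # plant one 8mer site per regulated arm: [comp(m8)] [revcomp(seed 2-7)] [A]
  site_of <- function(m) {
    paste0(complement_base(substr(m, 8, 8)), revcomp(substr(m, 2, 7)), "A")
  }
  protected <- setNames(rep(list(integer(0)), length(tx_ids)), tx_ids)
  if (nrow(triplets) > 0) {
    for (t in seq_len(nrow(triplets))) {
      m <- mir_seq[match(triplets$mirna_id[t], ids$miRNA)]
      site <- site_of(m)
      for (f in c(triplets$rna_a[t], triplets$rna_b[t])) {
        pos <- sample(seq(10L, L - 17L), 1)
        s <- tx_seq[[f]]
        tx_seq[[f]] <- paste0(substr(s, 1, pos - 1), site,
                              substr(s, pos + 8, L))
        protected[[f]] <- pos:(pos + 7L)
      }
    }
  }

  # scrub accidental >= 7mer sites on non-planted pairs by point mutation:
  # a site is stronger than a 6mer exactly when the transcript contains
  # "m8 + core" (7mer-m8) or "core + A" (7mer-A1); 8mers contain both.
  planted_key <- if (nrow(triplets) > 0) {
    c(paste(triplets$mirna_id, triplets$rna_a), paste(triplets$mirna_id, triplets$rna_b))
  } else character(0)
  bad_words <- lapply(seq_len(cfg$n_mirna), function(i) {
    m <- mir_seq[i]
    core <- revcomp(substr(m, 2, 7))
    c(paste0(complement_base(substr(m, 8, 8)), core), paste0(core, "A"))
  })
  for (pass in 1:25) {
    dirty <- FALSE
    for (i in seq_len(cfg$n_mirna)) {
      for (w in seq_along(bad_words[[i]])) {
        word <- bad_words[[i]][w]
        core_off <- if (w == 1) 1L else 0L  # core start offset inside the word
        hit_tx <- which(vapply(tx_seq, grepl, logical(1),
                               pattern = word, fixed = TRUE))
        for (j in hit_tx) {
          is_planted <- paste(ids$miRNA[i], tx_ids[j]) %in% planted_key
          prot <- protected[[tx_ids[j]]]
          starts <- gregexpr(word, tx_seq[[j]], fixed = TRUE)[[1]]
          for (st in starts) {
            p <- st + core_off  # core start
            if (is_planted && (p %in% prot)) next  # the intended site
            span <- setdiff(p:(p + 5L), prot)
            if (length(span) == 0) next  # buried in a protected site
            pos <- span[ceiling(length(span) / 2)]
            old <- substr(tx_seq[[j]], pos, pos)
            substr(tx_seq[[j]], pos, pos) <- sample(setdiff(DNA_BASES, old), 1)
            dirty <- TRUE
          }
        }
      }
    }
    if (!dirty) break
  }

  list(
    mirnas = mirnas,
    transcripts = tibble::tibble(rna_id = tx_ids, rna_class = tx_class,
                                 sequence = unname(tx_seq))
  )
}

#' @export
print.sim_truth <- function(x, ...) {
  cat("<sim_truth> ", nrow(x$de_mirnas), " DE miRNAs, ",
      nrow(x$triplets), " planted triplets", sep = "")
  if (!is.null(x$read_composition)) {
    cat(", ", sum(x$read_composition), " reads in ",
        length(x$read_composition), " filter categories", sep = "")
  }
  cat("\n")
  invisible(x)
}
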