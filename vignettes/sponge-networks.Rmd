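---
title: "Inferring miRNA sponge networks: models, thresholds and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring miRNA sponge networks: models, thresholds and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spongenet)
```

## The model

The ceRNA (competing endogenous RNA) hypothesis predicts a specific
correlational signature in expression data: an RNA that sponges a miRNA is
negatively correlated with it across samples, and two RNAs sponging the
*same* miRNA are positively correlated with each other. `spongenet` encodes
the standard operational version of that prediction as a screened triplet

> (RNA_a, miRNA, RNA_b) with Spearman ρ(miRNA, RNA_a) ≤ −0.6,
> Spearman ρ(miRNA, RNA_b) ≤ −0.6 and Pearson r(RNA_a, RNA_b) > 0.7,

where RNA_a is a lncRNA or circRNA, RNA_b an mRNA, both are significant in
the two-group differential screen, and both are predicted targets of the
miRNA. Everything upstream exists to produce trustworthy inputs to this
screen; everything downstream packages its output.

The key assumptions, stated plainly:

* correlations over the pooled samples of both groups (n = 8 in the default
  4-vs-4 design) carry the sponge signal — at this n, a single threshold on
  a rank correlation is a coarse instrument, which is exactly why the
  package ships a generator with planted truth to quantify what the screen
  can and cannot see;
* a negative-binomial count model with a dispersion shared across most
  features is adequate for the differential screen at 4 vs 4;
* canonical seed matching (positions 2–8) is an acceptable stand-in for an
  intersection of heavier target predictors; externally produced prediction
  lists can be supplied instead and are intersected.

## Stages and their parameters

### Read filtering

Filters run in a fixed order and each discarded read is charged to the
*first* stage it fails, so the report categories partition the input
exactly: quality → 3′ adapter → 5′ adapter → insert length → polyA, then a
tag-frequency cutoff after collapsing. Protocol descriptions of this
filtering style typically name the filters without defining them, so the
rules here are explicit and configurable:

* **quality** (`quality_policy()`): a read fails if more than 20% of bases
  are below Phred 20, or it contains an `N`. Quality is judged on the raw
  read, before trimming.
* **3′ adapter** (`adapter_match_len = 8`): exact match of the first 8
  adapter bases; the insert is the sequence strictly before the first
  match. Production trimmers allow mismatches; exact matching keeps the
  accounting decidable and is documented as such.
* **5′ adapter**: a read whose *trimmed insert* contains the 5′ adapter
  prefix is a ligation artefact and is discarded.
* **insert length**: the retained window is 18–30 nt, mirroring the gel
  size selection of small-RNA libraries. The lower bound is the stated
  filter; the upper bound is enforced computationally and reported under
  its own category (`insert_too_long`) so the two causes stay separable.
* **polyA** (`polya_policy()`): an insert is polyA if ≥ 80% of its bases
  are A or it contains a run of ≥ 10 A's.
* **frequency**: tags with total read count < 2 are removed. The total is
  summed *across samples* (a tag seen once in each of two samples is kept);
  this interpretation is a package decision and is exercised by a boundary
  test.

### Annotation

Each clean tag receives exactly one category via a fixed priority:
housekeeping RNAs (rRNA/scRNA/snoRNA/snRNA/tRNA, excluded from
quantification) > existing miRNA > edited miRNA > known miRNA > repeat >
exon > novel candidate > intron > unannotated. Lookups are abstract
sequence sets supplied by the user — there is deliberately no genome
alignment and no hairpin-based novel-miRNA prediction here; `novel_candidate`
is a plain lookup category. The "edited miRNA" rule is exact length match
with one substitution outside seed positions 2–7.

### Quantification and the differential screen

TPM is plain count-proportional scaling to 10⁶ per sample (small-RNA tags
need no length correction). The differential test is an exact conditional
negative-binomial test: counts are scaled to the geometric-mean library
size, a single common dispersion φ is estimated by method of moments
(within-group variance = μ + φμ² solved as a ratio of sums across
features), and each feature's group totals are compared through the
conditional distribution of the group-1 total given the overall total,
summing the probabilities of all outcomes at most as likely as the observed
one (two-sided). This deliberately replaces the shrinkage machinery of
production DE packages with the simplest member of the same family; a
rank-based alternative (`method = "wilcoxon"`) is provided as a
cross-check, and the package's tests compare the exact test's p-values
against an independent established implementation.

Two numerical details matter:

* **dispersion robustness**: a few features with genuine per-sample
  biological variability (exactly what planted sponge miRNAs have) would
  inflate a naively pooled dispersion and mute every test. The estimator
  therefore starts from the median per-feature ratio and rejects gross
  outliers (individual estimate > 10× the pooled value) before re-pooling.
  Under a clean common-dispersion null the cut is essentially never
  triggered, which is what keeps the null fraction of p ≤ 0.05 at its
  nominal level (the acceptance script measures this on 10,000 null
  features).
* **fold change**: log₂FC = log₂((mean TPM₁ + 1)/(mean TPM₂ + 1)), with a
  1-TPM pseudo-count; the significance rule |log₂FC| ≥ 1 and p ≤ 0.05 is
  inclusive on both boundaries.

### Targeting and the correlation screens

Seed sites are classified canonically on the transcript written 5′→3′: a
6mer core (reverse complement of miRNA positions 2–7), optionally extended
by the m8 match (base 5′ of the core pairing miRNA position 8) and/or an
adenosine 3′ of the core (A1). 6mer-only pairs are excluded from the
default candidate set: one permissive predictor minus its weakest site
class approximates the stringency of intersecting several predictors.
Sequences are normalised to the DNA alphabet (U→T) on input.

Correlations are computed on TPM over all samples of both groups pooled.
Which normalisation enters the correlation is genuinely underdetermined in
protocol descriptions; it is configurable here by passing any expression
table to the screens. Threshold semantics are implemented exactly as
conventionally printed: ρ ≤ −0.6 **inclusive**, r > 0.7 **strict**. Both
comparisons carry a 1e-12 guard because rank correlations of small samples
are rational numbers that floating point reproduces only to round-off; a
value mathematically equal to the threshold must land on the correct side.
Constant expression vectors make a correlation undefined; such pairs are
skipped with a warning, never an error.

### Network assembly

For each miRNA all (mRNA, lncRNA) and (mRNA, circRNA) pairs among its
screened targets are formed — mRNA–mRNA sponge pairs are excluded by
default (configurable via `cerna_mode`), and the lncRNA- and circRNA-
centred networks are unioned rather than recomputed jointly. Only
features significant in the differential screen enter (toggleable with
`de_filter = FALSE` for power studies). Duplicate arms collapse to single
typed edges; every ceRNA-pair edge records its witnessing miRNA(s) as
provenance. Export is SIF + node-attribute TSV + GraphML; re-importing the
SIF reconstructs an isomorphic graph.

## What the generator emulates — and what it does not

`sim_config()` defaults define the study conditions: a 4-vs-4 two-group
design; 20 miRNAs, 200 mRNAs, 50 lncRNAs, 30 circRNAs; negative-binomial
counts (dispersion 0.05) around log-normal feature means (log₂ means
uniform on [5, 10]); 10 planted differential miRNAs (log₂FC 3, directions
alternating); 10 planted triplets. Regulation acts on the log scale:
each regulated arm's log₂ mean is
baseline − slope × (centred miRNA log₂ signal) + N(0, noise_sd),
independently per arm, so `noise_sd` is the interpretable knob for arm
strength. Sponged miRNAs carry per-sample log₂ variability
(`mirna_signal_sd = 1`) — the cross-sample signal that regulated targets
track; all other features have constant within-group means, which keeps the
null calibration clean. With the default `regulation_slope = 1.5` and
`noise_sd = 0.2` the planted arm correlations sit near −0.9, the regime the
screen is expected to detect. `de_log2fc = 3` makes the planted miRNAs
detectable at 4 vs 4 *despite* their biological variability — a weaker group
effect would make the differential gate, not the correlation screen, the
binding constraint on recovery.

The generator also emits miRNA and transcript sequences in which every
planted arm carries exactly one 8mer site and every non-planted pair is
scrubbed of 7mer/8mer sites by point mutation, so seed-match prediction
recovers exactly the planted arms. The read generator constructs each read
to trip exactly one filter stage (or none), with adapter-seed substrings
excluded from inserts so intended fate equals realised fate; clean inserts
default to 21–23 nt, the mature-miRNA length mode.

Deliberate omissions, hence what passing tests do *not* show about real
data: no real genome or homology to any organism's miRNAs; no sequencing
error, GC or ligation bias; no batch effects or library-size imbalance
(size factors default to 1; the generator exposes them); no indirect
regulation, transcription-factor confounding or shared-pathway
co-expression, which in real data produce correlated features that are not
sponge pairs — precision measured here is an upper bound under the model's
own assumptions; and no hairpin structure for novel-miRNA calling.

## Deterministic limits and degenerate inputs

`nb_dispersion = 0` switches counts to their means exactly (continuous,
unrounded); with `noise_sd = 0` every planted arm is a strictly monotone
decreasing map of its miRNA across samples, so Spearman is exactly −1 and
the two arms of a triplet are exactly proportional (Pearson +1) on the
generated counts. These exact statements hold on the count scale: per-sample
TPM division rescales each sample by a different total and can perturb ranks
by round-off-scale amounts, which is also why the threshold comparisons are
guarded. Degenerate inputs follow one rule: impossible requests error
(all-zero sample column, empty adapter, a group without samples), while
data-dependent gaps degrade softly (constant vectors skipped with a
warning; precision with zero discoveries reported as NaN).

## Problem sizes used by the tests

The suite checks enumeration equivalences on instances small enough to
brute-force (≤ 10 miRNAs, ≤ 20 RNAs, 50 instances; hypergeometric
enumeration at N ≤ 20), calibration on 10,000 null features, and recovery
on the default conditions over 20 seeded replicates — sizes chosen so the
whole suite runs in about a minute while each property retains resolution.
The acceptance script (`scripts/acceptance.R`) recomputes the same
quantities from scratch with seed-derived randomness.

## Known limitations

* The exact NB test with one pooled dispersion is anti-conservative for
  features whose true variability exceeds the pool and conservative in the
  opposite case; it is the stated simplification, not a replacement for
  shrinkage-based DE machinery on real data.
* A Spearman threshold at n = 8 has limited resolution; the null
  distribution of ρ is coarse and discoveries at |ρ| just past 0.6 are weak
  evidence individually. Recovery claims here are about the pipeline, not
  about any single edge.
* Seed matching ignores thermodynamics, conservation and 3′-supplementary
  pairing; the 6mer exclusion is a blunt stringency control.
* Enrichment is a plain hypergeometric over user-supplied sets: no GO DAG
  propagation, no topology-aware pathway statistics.
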