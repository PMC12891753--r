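---
title: "Detecting Y-chromosome loss and extreme downregulation of Y-linked expression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting Y-chromosome loss and extreme downregulation of Y-linked expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(edyloy)
```

# Background

Somatic loss of the Y chromosome (LOY) is one of the most common
chromosomal alterations in aging men, and its transcriptional shadow —
extreme downregulation of Y-chromosome gene expression (EDY) — is
detectable in bulk and single-cell RNA-seq long before a karyotype
would be. In oral potentially malignant disorders (OPMD, e.g.
leukoplakia), LOY/EDY status is a candidate marker for the risk of
progression to squamous cell carcinoma. `edyloy` implements the full
detection stack for this question: per-sample Y-panel enrichment
scoring, reference-calibrated EDY thresholds, a zero-UMI single-cell
EDY classifier, a cellularity/ploidy-adjusted Y copy-number signal,
and the exact and resampling inference used to associate calls with
progression outcomes.

# The Y-panel enrichment score

The bulk EDY detector is a from-scratch implementation of
single-sample gene-set variation scoring. For a genes × samples
matrix $x$ it proceeds in three steps:

1. **Kernel-smoothed expression CDF.** For gene $i$ and sample $j$,
   $z_{ij} = \frac1n \sum_k \Phi\left(\frac{x_{ij} - x_{ik}}{h_i}\right)$
   with per-gene bandwidth $h_i = \max(\mathrm{sd}_i/4, 10^{-8})$
   (Gaussian kernel, for log-scale data), or the analogous Poisson-CDF
   smoother $\frac1n\sum_k F_{\mathrm{Pois}}(x_{ij};\, x_{ik}+0.5)$
   for raw counts. The bandwidth floor makes zero-variance genes
   well-defined rather than a crash. `kernel = "none"` passes values
   through for rank-only scoring.
2. **Symmetric rank statistic.** Per sample, genes are ranked by
   $z$ in decreasing order (average ranks on ties) and mapped to
   $r_{ij} = |p/2 - \rho_{ij}|$, so both expression extremes carry
   large weight.
3. **Weighted Kolmogorov–Smirnov random walk.** Walking genes in
   decreasing-$z$ order (ties broken deterministically by input gene
   order, which makes regression tests reproducible), in-panel genes
   step up by $r^\tau / \sum_{\mathrm{panel}} r^\tau$ and out-of-panel
   genes step down by $1/(p - |\mathrm{panel}|)$. The default score is
   `max_diff`: the sum of the walk's positive and negative extremes;
   `max_abs` is available. Scores live in $[-1, 1]$.

Defaults are $\tau = 1$, `max_diff`, Gaussian kernel for
log-normalized layers and Poisson for raw counts. These are the
documented defaults of the standard GSVA method; the tests pin the
implementation against naive direct-formula oracles (every panel
placement at $p \le 8$ agrees to $10^{-10}$).

## Y gene panels

Three panel modes cover the use cases: `fixed_human_12` (DDX3Y, KDM5D,
ZFY, UTY, USP9Y, EIF1AY, RPS4Y1, PRKY, NLGN4Y, TMSB4Y, SRY, TBL1Y) for
human bulk data; `mouse_all_protein_coding`, which takes every
annotated protein-coding chromosome-Y gene from a user-supplied
annotation (annotation releases differ in how they enumerate mouse Y
genes, so the annotation is deliberately an input rather than a
built-in); and `dataset_specific` for explicit lists such as the
4-gene single-cell panel (RPS4Y1, TTTY15, DDX3Y, EIF1AY) used where
droplet-level detection sensitivity limits the usable genes. Panel
genes are matched to matrices by symbol, case-sensitively; unmatched
genes are dropped with a warning. Chromosome names are normalized by
stripping the `chr` prefix internally because public matrices mix
dialects.

# EDY thresholds for bulk cohorts

A sample is EDY iff its score is **strictly below** the threshold
(ties are non-EDY; "below" is read literally). Three calibration rules
reflect how reference information differs between cohorts:

- `min_of_controls` — the minimum score among control-treated
  samples (used when a same-experiment control arm exists);
- `max_of_reference` — the maximum score among female reference
  samples, optionally after removing an **explicit** exclusion list.
  Which reference samples are outliers is an analyst decision:
  `flag_reference_outliers()` lists candidates above Q3 + 1.5 IQR but
  is never applied automatically, because an ad-hoc exclusion baked
  into the algorithm would be impossible to audit;
- `fixed` — a literal threshold (e.g. 0.3 or 0) for reproducing a
  published cut.

# Single-cell EDY

QC keeps cells expressing > 200 and < 8000 genes with < 10% of UMIs on
mitochondrial genes (symbol prefix `MT-`/`mt-`, overridable by
annotation), then keeps genes detected in > 0.1% of surviving cells;
all comparisons are strict. Normalization is the standard
`log(1 + 10^4 x / total)` recipe. Y genes enter the single-cell panel
when mean normalized expression exceeds 0.05 **or** the gene is
detected in more than 5% of cells; the "and/or" wording of this filter
in the field is ambiguous, so OR is the default (a gene passing either
evidence channel is usable for a zero-based classifier) and AND is
available. The filter is evaluated on male cells — the analysis
population — since female cells are Y-negative by construction.
A cell is EDY iff **every** panel gene has exactly zero raw UMIs;
normalized values are never consulted, which makes the call invariant
to normalization by construction.

Module scores for gene signatures (the 14-gene epithelial-malignancy
and 24-gene progression sets ship in `inst/extdata/`) use
binned-control scoring: genes are placed in 24 equal-frequency bins of
average expression, each set gene draws 100 control genes with
replacement from its bin using a seeded RNG, and the score is mean(set)
− mean(controls) per cell. Set genes are excluded from their own
control pools (falling back to the full bin if a bin holds nothing
else); this keeps the score an unbiased contrast and makes it exactly
translation-equivariant when the set's bin assignments are unchanged.

# The copy-number Y signal

Segment values are absolute copy-number estimates (autosomal diploid
= 2, normal male Y = 1); depth-ratio inputs can be converted via
`ratio_to_cn()` using the mixture's average genome copy number
$\rho\psi + 2(1-\rho)$. The raw Y signal is the length-weighted mean
over Y segments after dropping missing values. The adjustment inverts
the normal/tumor mixture: with cellularity $\rho$ and one Y copy per
normal male cell,

$$\mathrm{raw} = (1-\rho)\cdot 1 + \rho\, c_t
  \quad\Rightarrow\quad
  c_t = \frac{\mathrm{raw} - (1-\rho)}{\rho},
  \qquad \mathrm{adjusted} = c_t \cdot \frac{2}{\psi}.$$

The $2/\psi$ factor expresses Y dosage relative to tumor ploidy so
that a genome-doubled tumor retaining two Y copies scores 1 (i.e. no
relative loss). Estimates marginally below zero (noise under the
admixture floor) are clipped to 0; a warning fires only for material
negativity. LOY is called at adjusted < 0.5 by default — loss in the
majority of tumor cells — and the threshold is exposed because
published analyses often pick extreme samples rather than a stated
cutoff. Below $\rho \approx 0.5$ a noisy complete loss can cross the
default threshold, which is the expected sensitivity limit of any
admixture-corrected caller.

# Inference layer

- **Fisher's exact test** reports the upper-tail one-sided p and a
  two-sided p under the minimum-likelihood convention (sum of all
  table probabilities ≤ observed, relative tolerance $1+10^{-7}$).
  This convention is stated explicitly because the doubling convention
  disagrees on the same tables.
- **Odds ratios, two flavors.** The cross-product `ad/bc` (with
  `Inf` for empty off-diagonals) plus the Woolf log-normal CI
  (Haldane–Anscombe +0.5 on zero cells, with a warning), and the
  conditional-exact CI obtained by inverting Fisher's noncentral
  hypergeometric tails (root-finding on $\log\psi$, tolerance
  $10^{-6}$; bounds 0/∞ at the support edges). Both are always
  computed side by side because cohort reports use both styles.
- **Jonckheere–Terpstra** for ordered-group trends: pairwise
  Mann–Whitney counts (ties count ½), tie-corrected normal
  approximation, and an exhaustive exact permutation null when total
  $n \le 12$. The default alternative is "increasing", matching the
  normal < premalignant < cancer design; with two groups the exact
  test coincides with the one-sided Mann–Whitney test (verified in
  tests).
- **Permutation association** (default 10 000 label shuffles, seeded):
  the statistic is the difference in means, the reported p is the
  add-one empirical two-sided p (so $p \ge 1/(B+1)$), and $Z$
  standardizes the observed statistic against the permutation null —
  the style in which such results are usually quoted.
- Wilcoxon and Student's t delegate to the standard R implementations
  (exact Wilcoxon for combined $n \le 20$ without ties); Cohen's $d$
  uses the pooled SD.

# Pathway activity

`mlm_activity()` fits, per sample, ordinary least squares of the
expression vector on an intercept plus the pathway weight matrix over
shared genes, and reports the t-statistic of each pathway coefficient
(positive = activation). t-values rather than raw coefficients make
activities comparable across pathways with different weight scales —
rescaling a weight column leaves its t-value unchanged. Published
footprint weight matrices are external model data; the shipped
`toy_pathway_weights_synthetic.tsv` is a synthetic 150-gene ×
3-pathway fixture for testing and examples only, and
`read_pathway_weights()` accepts any long-format gene/pathway/weight
TSV (optionally truncated to the top-|weight| genes per pathway).

# Synthetic data: what it emulates and what it does not

The generators produce data with the statistical structure the
detectors assume, plus planted truth labels:

- `gen_bulk()` — lognormal expression (σ = 0.25 by default), a
  12-gene Y panel at level 100 in non-EDY males, multiplied by
  `depletion` (default 0, complete silencing) in a planted EDY
  fraction and by 0.01 in females. Default 20 males + 10 females.
- `gen_sc()` — negative-binomial UMIs (size 2), an ordered
  normal < leukoplakia < cancer design with per-group EDY cell
  fractions defaulting to 3.5% / 14.9% / 19.8% (a realistic severity
  gradient for oral lesions), EDY cells planted as exact panel zeros
  and non-EDY cells rejection-sampled to a nonzero panel sum — so the
  zero-UMI rule recovers truth without error, by construction.
- `gen_cna()` — Y-bin values around the mixture mean
  $(1-\rho) + \rho c_t$ with Gaussian bin noise.
- `gen_outcomes()` — binary progression with baseline rate 0.381
  (a typical non-EDY progression rate in OPMD follow-up cohorts) and a
  configurable EDY odds ratio.

All generators are seed-deterministic and restore the caller's RNG
state. They do **not** emulate batch structure, realistic library-size
variation, gene–gene correlation, ambient RNA, or doublets; passing
tests on this synthetic data therefore demonstrates algorithmic
correctness (recovery of planted structure, calibration of the
inference), not robustness to every artifact of real droplet data.
Distributional choices (lognormal bulk, NB UMIs) are standard
emulation conventions, not claims about any particular dataset.

# Numerical choices and degenerate inputs

- Ranking ties: average ranks for the statistic, deterministic
  gene-order tie-break for the walk.
- Zero-variance genes: bandwidth floored at $10^{-8}$.
- Fisher two-sided tolerance $1+10^{-7}$; CI root-finding tolerance
  $10^{-6}$ on $\log\psi$ with an expanding bracket.
- Permutation null with zero variance: $p = 1$, $Z$ defined as 0, with
  a warning.
- Empty panels, all-zero tables, degenerate margins, zero-total cells
  and rank-deficient designs raise errors naming the offender.

# Problem sizes in the test and acceptance runs

The shipped checks use sizes chosen to exercise every property while
remaining quick on a laptop: exhaustive enrichment-score enumeration
at $p = 8$, $n = 4$; bulk recovery over 100 seeds at 20 + 20 samples ×
200 genes; single-cell power over 100 seeds at 3 groups × 10 samples ×
300 cells; Fisher enumeration over all 135 750 tables with total ≤ 40;
permutation calibration over 1000 null runs of $n = 12$ with 999
resamples each.

# Known limitations

- The conditional-exact CI and minimum-likelihood two-sided p are one
  convention pair among several in the literature; published numbers
  computed under other conventions will differ.
- The LOY adjustment assumes exactly one Y copy per contaminating
  normal cell and a single tumor clone; subclonal loss yields
  intermediate adjusted values that the single threshold dichotomizes.
- Module scores depend on the binning of average expression; sets
  whose genes sit at bin edges can shift bins under small
  perturbations (the score remains deterministic under a fixed seed).
- No survival modeling: progression is a binary endpoint.
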