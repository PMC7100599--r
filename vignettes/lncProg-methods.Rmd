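---
title: "Inferring lncRNA expression from coding-gene regulons and screening it for prognostic value"
author: "lncProg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{lncProg methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lncProg)
```

## The problem

Long non-coding RNAs (lncRNAs) are rarely measured on the microarray
platforms that dominate legacy clinical cohorts, yet those cohorts carry the
long survival follow-up that RNA-seq collections mostly lack. lncProg
bridges the two: it learns, from an RNA-seq cohort in which lncRNAs *are*
measured, which protein-coding genes move with each lncRNA (its *regulon*),
and then reads the lncRNA's activity off the coding genes alone in any other
expression dataset. The inferred expression (iExpr) can then be screened for
survival association dataset by dataset, combined across datasets of the
same cancer type by weighted meta-analysis, and interrogated downstream
(copy-number concordance, essentiality overlap, expression-based
subtyping).

Every stage is exercised end to end on a synthetic-data generator that
plants the structure the analysis assumes, so each method has a
parameter-recovery test against known ground truth.

## Regulon inference

For every candidate regulator the package estimates mutual information (MI)
against every other gene. Both estimators operate on within-sample ranks and
are therefore exactly invariant under monotone transforms:

* **Adaptive partitioning** (default): the rank plane is split recursively
  into quadrants while a chi-square test (3 d.f., $\alpha = 0.05$, minimum 8
  points per cell) rejects uniformity; leaf cells contribute
  $p \log\,[p/(p_x p_y)]$. This is the estimator character of the standard
  network-inference tools in this domain.
* **Equal-frequency binning**: the plug-in estimator on a $B \times B$
  equifrequent binning. Its closed form on discrete joint tables makes it
  the oracle-testable alternative ($\mathrm{MI}(X,X) = \log B$ exactly for
  an equifrequent $B$-level variable).

Edges must *strictly exceed* an MI threshold, the empirical $1-p$ quantile
(default $p = 0.01$) of MI between independently permuted vectors of the
same sample size. Strict exceedance matters: the adaptive estimator returns
exactly 0 for most null pairs (the root split is itself a test), so the
quantile can sit at 0 and a non-strict rule would pass everything.

The **data processing inequality** (DPI) prunes indirect edges: in every
fully connected triple the weakest edge is removed when its MI falls below
$(1-\mathrm{tol})$ times the smaller of the other two. Decisions are made
against the input network and applied simultaneously, so the result is
independent of triangle enumeration order (tolerance defaults to 0).

**Bootstrap consensus** (default 100 iterations; the recovery studies below
use 20): samples are resampled with replacement, the thresholded and
DPI-pruned network is recorded, and an edge is kept when its support count
is significant under a Poisson null whose mean is the total number of edge
occurrences divided by the number of *candidate regulator pairs*,
Bonferroni-corrected across the observed distinct edges (default 0.05). The
candidate-pair denominator is the chance expectation of the counting
process; dividing by observed distinct edges instead (a tempting shortcut)
makes the test reject everything precisely when inference is *good* — in
the noiseless limit every planted edge appears in every bootstrap, the mean
equals the bootstrap count and nothing is "surprising". A plain
support-fraction cutoff is available as `consensusMode = "fraction"`. A
single-bootstrap run skips consensus entirely and returns its network.

Each regulon's MI scores are divided by the regulon maximum (largest weight
exactly 1) and signed by the Pearson correlation between regulator and
target expression. Targets with correlation exactly zero fit neither
profile and are dropped (a measure-zero event in continuous data).

**Weight profiles.** Positive-sign weights form the *up* profile, the
magnitudes of negative-sign weights the *down* profile. A profile with
fewer than `minGenes = 20` members is flagged invalid and contributes
nothing downstream. The 20-gene rule is applied *per profile*, not per
lncRNA: a lncRNA with a valid up profile and a 3-gene down profile is still
inferable through its up profile alone. The alternative reading —
disqualifying the whole lncRNA when either profile is small — would discard
most regulators, since negative edges are the minority in practice.

## Inferred expression (iExpr)

For one sample, genes are sorted by expression from highest to lowest (ties
broken by lexicographic gene ID — determinism is worth more at this scale
than tie-randomisation). Walking down the ranking, a foreground function
accumulates the profile's weighted mass and a background function the
zero-weight genes:

$$F(k) = \frac{\sum_{i \le k} w_i\,v_i}{\sum_{i} w_i\,v_i},
\qquad B(k) = \frac{\#\{i \le k : w_i = 0\}}{\#\{i : w_i = 0\}},$$

and the statistic is $F(k^*) - B(k^*)$ at the first $k^*$ maximising
$|F - B|$ (always in $[-1, 1]$; positive when the profile concentrates at
the top). The raw score of a lncRNA in a sample is

$$\text{pre-iExpr} = d_{\text{up}} - d_{\text{down}} \in [-2, 2],$$

with an invalid profile contributing 0.

**What the values $v_i$ are.** The pipeline evaluates the statistic on the
within-sample *rank scores* ($v_i = N, N-1, \dots, 1$ down the sorted
profile), not the raw expression values. This makes iExpr an exact function
of each sample's ranking: any rank-preserving per-sample transform (the
affine platform jitter of microarray data, for instance) leaves the output
bit-identical, which is also asserted as a test. The raw-value weighting
$v_i = |e_i|$ remains available (`useRankScores = FALSE`) but is *not*
invariant under shifts and so cannot support cross-platform use.

**Permutation null and normalisation.** The gene-to-expression assignment
is permuted uniformly (default 1000 times; seeded, reproducible) and
pre-iExpr recomputed. Note the null is *not* symmetric about zero in
general: support genes that land near the top of the ranking carry more
foreground mass than bottom-landers, so a lone up profile has a positively
biased null (about $+0.33$ on a 50-gene fixture). For this reason the
default normalisation is *sign-conditional*: a non-negative score is
divided by the mean of the positive null values, a negative score by the
magnitude of the mean of the negative null values. This preserves the sign
and is numerically stable. Dividing by the plain null mean
(`mode = "literal_mean"`) is retained as an option but that denominator is
near zero and sign-mixed for balanced profiles. A zero or empty denominator
yields iExpr 0 with a flag.

Profile genes absent from the target array are dropped *without*
renormalising the remaining weights (the max-weight anchor is retained),
and a lncRNA with less than half its support present is flagged
low-coverage.

## Survival screening and meta-analysis

Each lncRNA row is fit with a univariate Cox proportional-hazards model
(Efron tie handling, Newton iteration capped at 50 with $10^{-9}$
tolerance); the Wald score $z = \beta/\mathrm{se}$ is positive for
hazardous lncRNAs (higher expression, higher mortality) and negative for
protective ones. The covariate-adjusted variant accepts clinical covariates
(complete-case; rank-deficient designs are an error naming the columns).

Per-dataset z-scores of one cancer-type family are combined by weighted
Stouffer meta-analysis,

$$z_{\text{meta}} = \frac{\sum_i w_i z_i}{\sqrt{\sum_i w_i^2}},$$

with dataset sample sizes as weights (the conventional
$w_i = \sqrt{n_i}$ is available as `weightMode = "sqrt_n"`). The *robust*
meta z leaves out the dataset with the largest $|z|$ (ties: first dataset
in lexicographic ID order) and recombines — a single-dataset artifact
cannot then carry a signal. Meta p-values come from the standard normal and
are adjusted within the family by Benjamini–Hochberg and Bonferroni.
Kaplan–Meier comparisons dichotomise at iExpr 0, with exact zeros assigned
to the low group (the high/low definitions ">0" and "<0" leave zero
unassigned; low is the conservative home for a no-signal score).

One sign-convention footnote: hazardous means $z > 0$ throughout; a
meta-z threshold of 1 sometimes seen in prose is read as the
threshold 0 of this convention.

## Downstream analyses

* **One-sided Fisher enrichment**: the odds ratio is the sample
  $ad/bc$ (flagged degenerate on zero cells) and the p-value the upper
  hypergeometric tail of the top-left cell — verified against full
  enumeration for every table with margins up to 30.
* **Classification schemes** mirror the threshold sets used at each stage
  of the real analysis (`precog_essentiality`: $p \le 0.1$;
  `metabric_cna`: FDR $\le 0.01$; `cross_dataset`: FDR $< 0.05$ prognostic
  vs FDR $> 0.1$ non-prognostic with the in-between excluded;
  `tcga_cna_p`: $p < 0.05$; `tcga_cna_fdr`: FDR $\le 0.1$), plus custom
  triples.
* **Cross-dataset validation** reports the Pearson correlation of two
  z-score vectors over the shared universe and direction-separated Fisher
  enrichments of prognostic-in-both.
* **Per-patient CNA enrichment** counts lncRNAs (a lncRNA is amplified in
  a patient when *any* overlapping segment carries call +1): rows
  hazardous/protective, columns altered/not. The test runs only when all
  four cells have at least 5 counts; BH adjustment spans the tested
  patients of one direction. Gene-level CNA signal is the unweighted mean
  over overlapping segments (length-weighting deliberately not the
  default, matching the plain "average signal of overlapping segments"
  definition).
* **Subtyping**: the top 500 rows by variance (ties by gene ID), row
  z-transformation, Euclidean complete-linkage clustering (zero-variance
  rows excluded with a warning). `stats::hclust` provides the
  agglomeration; fixtures in the test suite are tie-free so the merge
  sequence is checked against a brute-force $O(n^3)$ oracle.

## The synthetic-data generator

The generator is the package's study design, not a test fixture. A latent
activity matrix $A$ (lncRNA $\times$ sample, standard normal) drives
everything:

* **RNA-seq-like cohort**: lncRNA rows are $A$ plus $N(0,\sigma^2)$ noise;
  each planted target is $s\,w\,\gamma\,A_l$ plus an independent
  unit-normal component plus noise, with sign $s$ negative with
  probability 0.3, weight $w \sim U(0.5, 1)$ (moderate-to-strong
  associations), signal strength $\gamma = 1$ and noise
  $\sigma = 0.5$. Regulon sizes are Poisson with mean 30. Defaults: 50
  lncRNAs, 5000 coding genes, 200 samples.
* **Microarray-like compendium**: fresh patients per dataset (default 3
  datasets of 150), coding genes only (optionally a few retained lncRNA
  "probes"). Survival is exponential with hazard
  $\lambda_0 \exp(\sum_l \beta_l A_{l,i})$ ($\lambda_0 = 0.1$; planted
  effects $\beta = \pm 0.8$), censored by an independent exponential clock
  (rate 0.05; a rate parameterisation rather than uniform censoring, so
  that rate 0 cleanly disables it). A per-dataset affine transform (scale
  $U(0.8, 1.2)$, offset $N(0, 0.5)$) emulates platform differences — it is
  rank-preserving per sample, so iExpr must not change, and a test holds
  the pipeline to that.
* **CNA profiles**: a synthetic genome of 5 chromosomes, genes placed
  round-robin at 15 kb pitch, tiled by 10 kb segments. Each segment carries
  a background event ($\pm 1$, rate 0.25 — a realistic altered-genome
  fraction which also keeps all four cells of the per-patient tables
  populated; at small background rates virtually no patient survives the
  5-count rule, which would make the per-patient test vacuous). On top,
  with probability `cnaBias` (0.9), hazardous loci are amplified in
  patients with positive activity and protective loci deleted in patients
  with negative activity. Segments are deliberately short relative to gene
  pitch: long segments bleed planted events across neighbouring same-class
  loci and erase the discordant cells.
* **Essentiality screen**: essential lncRNAs (the planted hazardous set)
  get mean phenotype score $-0.5$, others 0, across 8 replicates with
  Gaussian noise; the p-value is a one-sample t-test (degenerating to 0/1
  at zero noise).

What the generator does **not** emulate: probe-level effects, batch
structure beyond the affine jitter, realistic copy-number breakpoint
processes, correlated lncRNA activities, or non-proportional hazards.
Passing recovery tests therefore demonstrates that the implementation
faithfully executes the method under the assumed generative structure —
not that the method is robust to real-data violations of it.

## Problem sizes and numerical choices

The recovery studies run at: standard cohort 50 lncRNAs $\times$ 5000
coding genes $\times$ 200 samples with 20 bootstraps and 200 permutations
per iExpr cell; null calibration at 1000 lncRNAs $\times$ 3 datasets;
sign-consistency at 100 replicates of 3 datasets $\times$ 100 samples with
ground-truth profiles (minimum profile size 10 there, since Poisson regulon
sizes occasionally drop an up profile below 20 and the study measures sign
propagation, not profile availability); CNA/essentiality at 40 + 40 planted
loci over 200 patients. These sizes are the package's documented study
conditions and give stable results across seeds.

Numerical details: TSV floats are serialised with 17 significant digits so
round-trips are exact; the running-sum normaliser is accumulated in rank
order so the final foreground point is exactly 1 (guarding deviation ties
at rational values); permutation-sampled support positions are shuffled
before the up/down split (the distinct-sampling algorithm emits a biased
order); all RNG is seeded and every randomised stage reproduces
bit-identically under a fixed seed. Degenerate inputs have defined
behaviour: constant vectors carry zero MI, empty profiles return deviation
0 with a flag, a profile covering the whole universe (no background) is an
error, and zero null denominators yield iExpr 0 with a flag.

## Limitations

The MI estimator and consensus test are characterisations of the
standard bootstrap network-inference procedure, not a re-implementation of
any particular tool's code; the
running-sum foreground/background forms are the standard weighted
enrichment pair satisfying every stated property of the original, behind a
single swappable operation. Survival screening assumes proportional
hazards and offers no diagnostics; endpoint harmonisation across datasets
of a family is the user's responsibility. The per-patient CNA test counts
lncRNAs, not segments; with few prognostic lncRNAs the 5-count rule
excludes everyone, by design.
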