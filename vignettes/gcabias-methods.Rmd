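---
title: "Methods: combining ability and parental bias analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: combining ability and parental bias analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gcabias)
```

This vignette documents the statistical models behind `gcabias`, the
defaults and why they were chosen, what the synthetic-data generator does
and does not emulate, and the numerical conventions that matter when
reproducing results.

## The diallel model

A half-diallel crosses `p` inbred parents in all `p(p-1)/2` pairwise
combinations without reciprocals. Under Griffing's fixed-effect
(Model I) analysis, the mean of cross `i x j` decomposes as

$$x_{ij} = \mu + g_i + g_j + s_{ij},$$

with parental selfs $x_{ii} = \mu + 2 g_i + s_{ii}$. The $g_i$ are the
general combining ability (GCA) effects — in trait units, summing to
zero — and $s_{ij}$ the specific combining ability (SCA) deviations of
individual crosses. `gca_method2()` analyses parents plus one set of
crosses; `gca_method4()` analyses crosses only.

Because parents are routinely phenotyped alongside their hybrids in this
kind of field design, **Method 2 is the package default**; Method 4 is a
flag away for crosses-only data. Both use the closed-form estimators
(e.g. Method 2: $\hat g_i = [x_{i.} + x_{ii} - 2x_{..}/p]/(p+2)$), and
both are verified against `gca_least_squares()`, which solves the full
design-matrix system under the zero-sum constraints numerically and
shares no algebra with the closed forms. The two agree to machine
precision on random tables (the test suite checks 100 tables with
$p \in \{3,\dots,8\}$ at tolerance $10^{-8}$).

Aggregation to cell means (`cross_means()`) is deliberately simple:
plot records are averaged within environment, then environment means are
averaged unweighted. No genotype-by-environment term is modelled, because
the analysis targets a single GCA score per parent; users with seriously
unbalanced multi-environment data should model GxE upstream.

For parent–F1 phenotype correlations, `focal_parent_correlation()` pairs
each cross's F1 value with the *co-parent's own* phenotype. The default
scheme pools traits after z-standardising within trait (for a 5-parent
diallel with 3 traits this gives n = 4 x 3 = 12 pairs per focal parent),
which matches the scale of significance one obtains from a handful of
crosses; a per-trait scheme is available. Which pairing a given study
used is rarely stated, so the scheme is an explicit argument, not a
hidden convention.

## Expression quantification

RPKM is used throughout: $\mathrm{RPKM} = 10^9 C/(N L)$ with count $C$,
library size $N$ (total mapped reads), and feature length $L$ in bp.
Two conventions matter:

* **Gene-body length**, `end - start`, is used for both RNA and ChIP
  signal — not exon-union length. Nuclear RNA libraries and gene-body
  histone marks both cover introns, so a single length definition keeps
  the two assays comparable.
* Coordinates are 0-based half-open internally (BED convention); GFF3 is
  converted on read/write by `rtracklayer`.

The expressed-gene rule defaults to RPKM strictly greater than 0 — any
assigned read counts as evidence of expression. There is no universal
criterion here; the threshold is an argument everywhere it is used, and
every reported fraction carries its denominator.

## The two-library count test

With one pooled library per genotype there are no replicates, so
differential expression uses the Audic–Claverie exact test: conditional
on observing $x$ reads for a gene in library 1, the probability of $y$
reads in library 2 is

$$p(y \mid x) = \left(\frac{N_2}{N_1}\right)^{y}
  \frac{(x+y)!}{x!\,y!\,(1+N_2/N_1)^{x+y+1}},$$

a negative-binomial law with size $x+1$ and success probability
$N_1/(N_1+N_2)$. The implementation evaluates terms with `lgamma` and
accumulates tails by log-sum-exp; the test suite checks it against the
negative-binomial identity and against brute-force summation.

Numerical and statistical conventions:

* **Two-sidedness** is twice the smaller tail, capped at 1. The original
  formulation gives one-sided tails; doubling is the convention chosen
  here and applied uniformly.
* The doubled-tail p is **orientation-dependent**: conditioning on
  library 1 and asking about library 2 is not the same test as the
  reverse, and the two can disagree noticeably deep in the tails (the
  point probability, by contrast, obeys
  $p(y|x; N_1, N_2) = (N_1/N_2)\, p(x|y; N_2, N_1)$ exactly). The
  package always conditions on the first sample argument; pick an
  orientation and keep it.
* **Zero handling**: genes with zero counts in both libraries are not
  testable and are excluded. A gene with one zero and one positive count
  has infinite normalized fold change and therefore passes the
  fold-change criterion; no pseudocount is added, because a pseudocount
  would silently reclassify exactly the low-expression contrasts the
  fold rule is meant to police.
* The DEG rule is *fold change strictly greater than 2* and *BH q below
  0.05*; the FDR family is all tested genes of the sample pair. A flag
  switches the significance criterion to raw p for comparison with
  analyses that reported "P < 0.05".
* For histone modification the same test is applied to gene-body counts
  with the stricter threshold FDR 0.001, and "similar" means q at or
  above that threshold.

## Trio classification

For each gene of a parent/parent/F1 trio, the F1 is compared with both
parents. A gene enters the differential trichotomy when it is a DEG
(full rule) against at least one parent. Within the trichotomy, the
difference is *localised* by statistical significance alone
(q < threshold per comparison):

* significant against exactly one parent: **equal** to the other parent;
* significant against both: **over parents** if the F1's RPKM lies
  strictly outside `[min(P1,P2), max(P1,P2)]` (boundary-equal values
  count as inside), otherwise **between parents**.

The reason the entry rule and the localisation rule differ is
arithmetic, not taste: an F1 at the arithmetic mid-parent value is never
more than 2-fold below the higher parent ($2f/(1+f) < 2$ for any
parental fold $f$), so a fold-gated flag can never register mid-parent
genes as differing from the high parent, while such genes can easily be
*significantly* different from both parents. Gating entry by the DEG
rule keeps the DEG fraction consistent with the headline DEG counts;
localising by significance lets mid-parent expression be recognised as
such.

`closer_parent()` reports which parent the F1's level is nearer to in
log2 ratio. Exact zeros are replaced, inside ratios only, by half the
smallest nonzero value in the data, so observed zeros (which do occur in
real RPKM tables) do not produce infinities; ties are reported as `tie`
and excluded from two-way bias splits.

## Clustering

`cluster_samples()` uses 1 minus Pearson correlation of
`log2(RPKM + 1)` profiles with average linkage. Correlation distance is
standard for expression profiles because it ignores library-level scale;
note the flip side, also relevant to simulation design (below): it is
equally blind to any *constant* log-shift between two samples. Samples
are sorted lexicographically before clustering, so leaf order and
tie-breaks are deterministic. Trees serialise to Newick via `ape`.

## ChIP gene-body analysis

Gene-body read counts per mark and sample are normalised with the shared
RPKM operation. A gene is called "modified" when its gene-body RPKM
exceeds a threshold (default: strictly above 0) *and* its raw count
reaches a floor (default 10 reads) — without a peak-calling step, one or
two stray reads should not make a modified gene. Modification similarity
between hybrid and parent is the fraction of the *union* of the two
samples' modified sets with q at or above 0.001. Mark overlap is
reported as Jaccard plus both directional fractions, since "overlap"
denominators are often left unstated in the literature.

## The synthetic-data generator

The generator produces every input type with known ground truth, at the
scales used by the test suite and the acceptance script:

* **Diallel phenotypes**: 5 parents, 3 traits, 3 environments x 3
  replicate plots — the layout of a realistic field evaluation. SCA
  effects are drawn once per cross (`sca_sd`, default exercised at 0.3
  trait units in tests) and plot error per record (`error_sd`, tests use
  0.5). Field plot variance is study-specific; these are free
  parameters, not calibrated values.
* **Trio counts**: 2000 genes; baseline RPKM log-normal
  (meanlog log 8, sdlog 1, i.e. a median of 8 RPKM with a long right
  tail); library size 10⁷ per sample; gene lengths uniform on
  500–5000 bp. Category fractions default to 17% of genes equal to the
  designated (positive-GCA) parent, 7% equal to the other parent, 4%
  outside the parental range and 2% at mid-parent, the remaining 70%
  equal across all three samples — i.e. roughly 30% of genes
  differential, ~80% of those tracking one parent and ~70% of *those*
  tracking the designated parent, the structure reported for rice
  hybrid trios.
* At differential genes the parents differ by a per-gene fold drawn
  log-normally around 4 (sdlog 0.25, putting virtually all folds above
  the 2-fold rule), with **random direction**: the designated parent is
  the higher-expressed one at about half of these genes. Both choices
  are essential for realism. A constant fold would make the parents'
  log-profiles differ by a constant — invisible to correlation distance;
  a fixed direction would make the designated parent globally
  up-regulated, which is not what combining ability means. GCA is a
  phenotype property; an F1 biased towards a parent tracks that parent's
  level gene by gene, up or down.
* "Over parents" genes sit at twice the nearer boundary (above the
  maximum or below the minimum, at random), guaranteeing detectability
  under the 2-fold rule.
* **Counts are Poisson by default** (`dispersion = 0`): with one pooled
  library per genotype, the sampling noise of sequencing is Poisson, and
  the Audic–Claverie test is exactly calibrated for it. A
  negative-binomial dispersion parameter is available to study
  robustness, but note that the test, like any unreplicated count test,
  becomes anti-conservative under extra-Poisson noise — that is a
  property of the design being emulated, not of the implementation.
* **ChIP counts**: 30% of genes carry the mark (log-normal signal,
  median 5 RPKM); parents differ 4-fold at modified genes; the F1 tracks
  the designated parent at a tunable fraction (0.9 in the recovery
  checks) and the other parent otherwise; unmodified genes get 0.05 RPKM
  background, which the 10-read count floor removes from modified sets.

What the generator does **not** emulate: mappability and GC biases,
transcript-level structure (isoforms, UTR differences), allele-specific
signal within the F1, structured ChIP background, and biological
replicate variance. Passing recovery tests therefore show
that the estimators invert the generator's model at realistic scales —
they cannot show robustness to artefacts the model omits.

## Determinism and seeds

Every generator takes an explicit `seed` and restores the caller's RNG
state; no function depends on global random state. The pipeline
(`run_pipeline()`) is deterministic given inputs and configuration, and
its JSON report contains every fraction with numerator, denominator and
thresholds, so each number can be recomputed from the emitted per-gene
tables.

## Known limitations

* Griffing Model I only: GCA/SCA are fixed effects; no variance
  components, no reciprocal effects (Methods 1/3), no GxE modelling.
* The count test assumes unreplicated Poisson libraries; with replicates
  a dispersion-modelling framework (e.g. negative-binomial GLMs) is the
  right tool and deliberately out of scope.
* Similarity and bias fractions depend visibly on their denominators
  (expressed set, DEG set, modified-gene union); the package always
  reports the denominator next to the fraction, and comparisons across
  studies should check denominators first.
* The packaged pathway RPKM table is a 12-gene fixture for direction
  checks, not a benchmark dataset.
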