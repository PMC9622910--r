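---
title: "Methods: TAD-constrained expression-methylation analysis"
author: "methylTAD"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: TAD-constrained expression-methylation analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical models, the synthetic-data
generator, and the numerical and design choices behind methylTAD, in the
spirit of a methods supplement.  Nothing here states an empirical result
that the test suite or `scripts/acceptance.R` does not itself compute.

# The analysis model

## Why TADs

Cytosine methylation correlates poorly with the expression of the nearest
gene, especially outside CpG islands.  Topologically associating domains
(TADs) are megabase-scale regions of elevated 3D contact frequency; a CpG
and a gene in the same TAD can interact physically even at hundreds of
kilobases.  The pipeline therefore tests every (gene, CpG) pair that
shares a TAD, and only those.

The TAD partition is built from called domains: overlapping **and
book-ended** domains are merged into one consecutive TAD, and the
complement of the merged domains against each chromosome is added as
additional TADs, so the partition is disjoint and exhaustive
(`buildTadPartition()`).  A feature overlapping a TAD by a single base is
assigned to it; boundary-spanning features belong to all TADs they touch.

## Coordinates

Internally every interval is a `GRanges` (1-based, closed), the
Bioconductor convention; BED and bedGraph input/output are 0-based
half-open and converted at the boundary, GTF is 1-based inclusive.  The
gene–site distance is edge-coordinate arithmetic on the 0-based half-open
view: a site 2,000 bp upstream of the body start is at distance 2,000, a
site at coordinate 520,000 downstream of a body ending (exclusively) at
20,000 is at distance 500,000, and any site inside the body is at 0.
Distance bins are closed exactly at their stated edges: proximal
(within the body or ≤ 2 kb), intermediate (≤ 500 kb), long (beyond).

## Correlation discovery

For each within-TAD pair, the Spearman coefficient is computed across the
shared samples with average ranks for ties, vectorised as a rank-space
cross-product over all pairs at once (`cor.test` serves as the per-pair
oracle in the test suite).  P-values use the t approximation for more
than nine samples and the exact distribution otherwise.
Benjamini–Hochberg correction is applied **genome-wide across all tested
pairs**: per-TAD correction was rejected as anticonservative for small
TADs.  A pair eligible through two TADs (a boundary-spanning gene) is
tested once — the analysis tests pairs, not (pair, TAD) tuples.  A pair
is significant when |ρ| > 0.5 *and* FDR < 5%; both thresholds are
arguments.  Zero-variance expression or methylation vectors make ρ
undefined; such pairs are skipped and counted (`nSkipped` attribute).

Filtering precedes discovery and follows the assay type: site-level
(bisulfite-sequencing-like) data drop any site with coverage below 10 in
*any* sample; probe-level (array-like) data keep probes with a value
above 0.3 in more than 3% of samples; expression keeps the top half of
protein-coding genes by mean expression.  The differential-methylation
stage later uses coverage **strictly above** 10 — the two rules are kept
distinct deliberately, matching their separate definitions.

Strand is ignored for all overlap and distance computations; it matters
only to the B-box scan, which searches both orientations explicitly.

## Architecture statistics

Per-gene metrics are computed on the union of merged exons and the gaps
between them (introns): lengths, GC content (weighted mean of a binned
GC track), conservation (weighted median of a binned phyloP-like track,
over covered bases only; genes with under 50% coverage are flagged), and
per-family repeat densities (overlapped bases / region length, on
reduced elements so overlapping annotations never double-count).
Intronless genes carry `NA` intronic fields and drop out of intron-based
tests.

Gene-set shifts are summarised as an **ECDF-shift curve**: on the
combined grid of observed values, background ECDF minus set ECDF, so
positive values mean the set is shifted toward higher values.  The
one-sample KS statistic is defined as the maximum absolute curve value —
the identity between the curve and D is enforced by construction and
cross-checked against `stats::ks.test` on tie-free data — with an
asymptotic Kolmogorov p-value at the set size.  Two-sample KS tests
(`stats::ks.test`) are used only where two empirical samples genuinely
meet: TAD-boundary distances and the MIR-zero matched comparison.

The MIR-zero comparison matches the top decile of intronic-MIR-density
genes to genes with no MIR at all, on CpG density (sites per kb of gene
body), nearest-neighbour within a caliper of 0.2 SD and without
replacement; below 20 matched pairs the test refuses to run.  The
caliper and matching scheme are this package's choices — no published
algorithm exists for this step.

The B-box scan counts `GTTCNANNC` matches on the forward strand plus
matches of its reverse complement `GNNTNGAAC` in the same segment,
overlapping matches included.  Any non-ACGT character fails the motif,
including at N positions: N is permissive across the four bases, not
across ambiguity codes.

## Monte-Carlo DBP enrichment

Peaks are shuffled with lengths preserved, each placed uniformly among
all start positions where it fits entirely inside one segment of the
space (longer segments get proportionally more mass; shuffled peaks may
overlap one another — forbidding overlap would bias the null for dense
peak sets).  The observed statistic is the number of features overlapped
by at least one peak; 1,000 iterations build the null, and the Z-score
of the observed count is reported, with |Z| > 10 as the significance
convention.  A null SD of zero is flagged as degenerate rather than
reported as an infinite Z.

The intronic-MIR variant asks a sharper question: do a DBP's peaks
concentrate on the query gene set's intronic MIRs beyond uniform
placement over the intronic MIR footprint of the background genes?
Peaks outside the MIR space carry no information about within-MIR
preference and are dropped before shuffling.  (Defining the space as the
query set's own MIRs would make the statistic insensitive by
construction; the background-MIR space is the definition under which a
MIR-indifferent DBP scores |Z| ≈ 0 and a set-specific binder scores
Z ≫ 0.)

## PPI bridging

For each ordered interacting pair (A, B): over the population of
significant mCpG–gene pairs, draws are pairs with A bound at the site,
population successes pairs with B bound at the gene (gene body, or
intronic-MIR footprint in `mir` mode), observed both; one-sided
hypergeometric p, BH-corrected across all interactions.  The two
orientations of an interaction are distinct tests, a protein bound at
both ends may contribute to either, and self-interactions are excluded.
The hypergeometric framing reflects the background being all possible
interactions over the correlated pairs themselves.

## SAM

The two-class SAM statistic is Tusher's relative difference
$d_i = (\bar x_{i2} - \bar x_{i1})/(s_i + s_0)$ with the class-size
coefficient pooled scatter.  $s_0$ minimises the coefficient of
variation of the d-spread (MAD) across $s$-percentile windows, over
candidates at every 5th percentile of $s$.  The null comes from class
label permutations — all distinct assignments when fewer than the
requested number exist, otherwise sampled — and the expected order
statistics $\bar d_{(i)}$ from their sorted d-vectors.  For a threshold
$\delta$, the cutoffs are the first order statistics deviating from
expectation by $\delta$ on each side; the estimated FDR is the median
permutation count beyond the cutoffs divided by the observed call count;
$\delta$ is the smallest value (on a capped grid of observed deviations)
with estimated FDR at or below the target.  No $\pi_0$ correction is
applied, keeping the estimate slightly conservative.  Constant features
are retained ($s_0$ prevents division by zero).

The same machinery drives: differentially methylated cytosines per
retrotransposon family (sites on the family with coverage > 10 and
non-zero methylation in at least two samples per class — the
"more than one" rule read as ≥ 2), differential expression after
log2(x+1) (with the pseudo-replicate rule: a class of exactly two
replicates gets their per-gene mean appended as a third column), and
the distance-SAM, in which reference samples are the features and query
samples the observations of the median-centred Manhattan distance
matrix.

## Projection

Expression profiles are rank-normalised per sample (highest expression
= highest rank, average ranks on ties), making every downstream result
invariant to strictly monotone per-sample transforms.  PCA is fit on
reference samples only — centering by reference gene means, SVD — and
query samples are projected with the fitted loadings; by default enough
components to explain 80% of reference variance are retained, but
distances are always computed in full rank space, not PC space.
Manhattan distances between each query and each reference are centred to
per-query median zero before the distance-SAM.  Cell-type enrichment of
the significant reference samples uses one-sided hypergeometric tests
against all reference samples and all cell types, BH-corrected, within
each direction (closer to / further from the second query group).

# The synthetic-data generator

The generator defines the conditions under which the pipeline is
validated; its defaults are fixed study conditions, not tuning knobs.

**Genome** (`generateGenome()`): two 10-Mb chromosomes; called domains
drawn from a gamma distribution with mean 1.4 Mb (shape 4, clipped to
0.2–3 Mb), separated by sub-5-kb gaps, 10% of tiles dropped so
complement-origin TADs exist.  200 genes (85% protein-coding), placed
non-overlapping strictly inside called TADs, 3–8 exons of 100–300 bp
with 2–12 kb introns.  Half the genes form the **regulatable** class —
intronic MIR density 0.10, GC-rich (0.55) and conservation-neutral
(phyloP-like mean 0) introns; the **independent** class has densities
0.02/GC 0.45/conservation 0.8, and 30% of it carries no MIR at all (the
MIR-zero pool for the matched comparison).  Repeats are placed
non-overlapping by an equal-slot scheme (MIR 130–260 bp, Alu ≈ 300 bp,
L1 0.5–6 kb), with subfamily labels and divergence scores (sum of
substitution/insertion/deletion percentages) drawn per family — MIRs
oldest, Alus youngest.  ~2,000 CpG sites: island clusters, 20% on MIRs,
15% on enhancers, 10% directly on enhancer∩MIR intersections (the
driver-eligible pool), the rest uniform.  250 enhancers, 30% centred on
MIRs.  GC and conservation tracks are 200-bp bins classified
exon/intron-by-class/intergenic.  Sequence exists only under repeat
footprints; 30% of MIRs carry an intact B-box in a random orientation.

**Planted binding**: in a random half of the TADs, protein `DBP_A`
covers 80% of driver-eligible CpGs and `DBP_B` one intronic MIR of 80%
of regulatable genes; elsewhere both drop to 10% — coverage is applied
per gene, not per element, since per-element background coverage would
saturate MIR-rich genes and erase the planted contrast.  The PPI list
contains the (`DBP_A`, `DBP_B`) edge plus random edges among the null
DBPs.

**Cohort** (`generateCohort()`): 16 DNMT3A / 9 IDH / 11 double-mutant
samples (WT added only for the cohort-comparison analysis).  One
regulatory module is planted per TAD: a per-sample latent methylation
level drawn from the genotype-group distributions — DNMT3A-low
Beta(2,8), IDH-high Beta(8,2), double-mutant Beta(5,5), WT Beta(5,5)
with doubled dispersion (Beta(2.25, 2.25)).  Driver sites are the latent
plus N(0, 0.05) jitter; regulated genes follow
log2-expr = α + β·(u − ū) + ε with |β| = 3, the sign negative with
probability 98.5%, and ε calibrated per module so the planted pair
Spearman magnitude is ≈ 0.8.  Centering the methylation term keeps a
gene's mean expression — and hence its survival of the top-expression
filter — independent of the effect sign.  Selecting √f of the genes and
of the sites per TAD yields a planted fraction f of within-TAD pairs
(default 10%); the per-pair recipe in which every pair has its own
independent driver cannot reach that fraction, because one gene cannot
track many independent sites.  All other sites get independent
site-specific Beta noise; all other genes independent Gaussian
log-expression.  Coverage is 10 + Poisson(40), with 3% of sites given
one low-coverage sample to exercise the filter.  In WT samples the
expression link defaults to β = 0: the observation that
coefficients are lower in unmutated samples is a statement about the
absence of mutation-driven methylation variation driving expression,
and wider WT methylation dispersion alone would *raise*, not lower, the
coefficients.

**Differentiation series** (`generateDifferentiationSeries()`): 211
samples over 15 hematopoietic cell types (HSC root plus progenitor,
myeloid, erythroid and lymphoid types), 14–15 samples per type.  Each
non-root type shifts 10% of genes by ±2 log2 units around a common base
profile, with upregulated genes drawn from the regulatable class at an
odds ratio of 4 and downregulated genes with the inverse bias; per-type
DE sets are recorded as ground truth.  Cell types are independent given
the base profile — real hematopoiesis has nested lineage structure
(sister cell types share signatures), which this generator does not
model; passing the recovery tests therefore shows correct nearest-type
assignment under type-specific signatures, not robustness to lineage
correlation.

**What passing tests do and do not show.**  The generator plants clean,
module-structured effects with Beta/Gaussian noise, a single driver
latent per TAD, and no batch effects, copy-number structure, cell-type
admixture or methylation–coverage dependence.  Green tests demonstrate
that the statistics are implemented correctly, calibrated under their
own null, and powered against their intended alternatives at the study
scale — not that real AML cohorts satisfy those assumptions.

# Numerical choices and degenerate inputs

* Spearman ties: average ranks; ±1 values clipped after floating-point
  cross-products.
* BH correction is `stats::p.adjust(method = "BH")` behind `bhFdr()`,
  with input validation; the test suite checks it against a literal
  step-up implementation.
* The SAM delta grid is capped at ~400 candidate values (quantiles of
  the observed deviations) so threshold selection stays O(hundreds) of
  FDR evaluations; permutation statistics are computed by matrix
  products over all permutations at once.
* `compareCohortCoefficients()` with an alternate cohort identical to
  discovery yields all-zero paired differences, where the signed-rank
  test is undefined; it returns p = 0.5 (no shift) for that case, and
  excludes (and counts) pairs whose alternate vectors have zero
  variance.
* Degenerate Monte-Carlo nulls (SD 0) are flagged, never an infinite Z;
  an interval longer than every space segment is a placement error
  naming the width.
* Chi-squared annotation tests fall back to a Monte-Carlo p-value
  (flagged) when any expected category count drops below 5.
* Weighted medians over binned tracks use the midpoint rule at exact
  50% splits; conservation medians ignore uncovered bases.
* W-set ties break lexicographically by gene id, making the set
  deterministic.

# Problem sizes

The shipped validation uses two scales, chosen so the full suite runs in
a few minutes on one CPU: a reduced fixture (two 6-Mb chromosomes, 80
genes, 800 sites) for unit tests of mechanics, and the study-scale
design (two 10-Mb chromosomes, 200 genes, ~2,000 sites, 36 samples, 20
replicate cohorts) for operating characteristics: false-discovery
control of the discovery stage, planted-pair recovery, Monte-Carlo
calibration (100 null runs of 1,000 iterations), bridge recovery across
20 cohorts, and nearest-cell-type projection recovery on the 211-sample
series.  SAM property tests run at 500–1,000 features with exhaustive
(252-permutation) nulls.  Default SAM permutations are 5,000 in line
with common practice; validation calls pass smaller values explicitly.

# Known limitations

* TAD calls are consumed as input (or simulated); no contact-matrix
  processing is included, and partitions from different assemblies are
  not lifted over.
* The one-sample KS p-value is asymptotic; at set sizes below ~10 it is
  approximate and flagged.
* The hypergeometric bridging test conditions on the observed binding
  maps; a pair-permutation null is a possible sensitivity analysis and
  is not implemented.
* Full-cohort headline counts from the motivating study design
  (tens of thousands of significant pairs across a full genome) are not
  reproducible at desk scale; the acceptance script instead verifies
  the operating characteristics — FDR control and threshold fidelity —
  on the synthetic study design.
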