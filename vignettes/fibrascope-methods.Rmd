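---
title: "Methods: crossover metagenomic profiling and statistics in fibrascope"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: crossover metagenomic profiling and statistics in fibrascope}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fibrascope)
```

This vignette is the package's own account of the models and procedures it
implements, the parameters that matter, the numerical choices made where a
definition leaves room, and what the synthetic-data tests do and do not
demonstrate.

## The quantification model

### From alignments to gene counts

The input is per-read candidate lists: a read either maps uniquely to one
catalog gene or maps with tied best score to several ("shared" reads, a
consequence of catalog redundancy between close genomes and paralogs).
`attribute_reads()` performs the classic two-pass attribution: unique reads
are counted first, then each shared read contributes a total of exactly 1,
split across its candidates proportionally to their unique-read counts. The
rationale is that unique reads estimate the relative copy support of each
candidate, and shared mass should follow it.

*Degenerate case.* A shared read whose candidates all have zero unique
counts carries no evidence either way; it is split uniformly. This keeps
read totals conserved (an invariant tested to 1e-9, the tolerance only
absorbing floating-point summation error of fractional shares) and is
unbiased among the candidates.

### Downsizing

Sequencing depth and mapping rate differ across samples, and detection-based
statistics (richness, the 10% marker rule) are depth-sensitive. Samples are
therefore rarefied to a common mapped-read target by a single draw without
replacement (multivariate hypergeometric) from each count vector —
a single draw, not an average over repeated rarefactions, so downstream
zeros behave like real sampling zeros. Two choices deserve note:

* **Fractional counts.** Shared-read attribution leaves fractional counts,
  but sampling without replacement needs integers. Counts are rounded
  stochastically — floor plus a Bernoulli draw on the fractional part — so
  the expected rounded count equals the fractional count. Deterministic
  rounding would bias low-abundance genes systematically.
* **Shallow samples.** Samples whose total falls below the target cannot be
  downsized without replacement and are excluded and reported, rather than
  silently kept at a lower depth that would inflate their apparent absences.

The default target in the command-line configuration is 14 million reads,
matching deep shotgun practice; tests and the generator use targets of a few
thousand, which exercise identical code paths.

### Frequencies

Downsized counts are divided by gene length in kilobases and by mapped reads
in millions (FPKM convention). Only ratios matter downstream (MSP abundances
are means of frequencies; all tests are rank-based), so the constant is a
convention; `normalize_frequencies(rescale_to =)` offers constant column
sums instead when comparability of column totals is wanted.

### MSP abundances and the 10% rule

An MSP's abundance is the arithmetic mean of its 100 marker-gene
frequencies, **including zeros** — the mean is over the marker panel, not
over detected markers, so an MSP with half its markers missing is (correctly)
half as abundant. If fewer than 10 of the 100 markers are detected the
abundance is set to exactly 0: with so few markers seen, the signal is more
plausibly cross-mapping noise than true presence. The boundary is strict:
exactly 10 detected markers keeps the mean. Marker selection itself (the 100
most co-varying genes of a cluster) is a property of the catalog build and is
consumed here as input flags.

### Functional carriage

The module-carriage computation deliberately asks a *genomic* question per
sample — does this MSP, as present in this sample, encode this function? —
rather than summing annotated gene abundances:

1. restrict each detected MSP's gene content to its genes detected in the
   sample, plus the MSP's core genes (core genes are assumed present in
   every strain, so their absence from a shallow sample is not evidence of
   absence);
2. compute the fraction of the module's items covered by the restricted
   set's annotations;
3. call the MSP a carrier when that fraction exceeds 90% (strictly);
4. sum the abundances of carriers.

Modules are flat KO sets. KEGG's alternative-path boolean logic is not
modelled: gut metabolic modules are themselves KO-set-like, and the strict
coverage threshold makes path logic second-order for the carriage call. A
CAZy family is a one-item module, for which the >90% rule degenerates to
"at least one annotated gene" — the two formulations are asserted equivalent
in the tests.

## The statistical layer

### Interaction screen

In a complete two-period crossover every subject is observed in all four
cells (bread × pre/post), and an intervention-specific effect appears as a
bread-by-visit interaction. The screen uses a rank-based ANOVA-type
construction: all 4n observations are mid-ranked jointly; each subject
contributes the interaction contrast of its cell ranks
\((R_{MF,post}-R_{MF,pre})-(R_{CTL,post}-R_{CTL,pre})\); the statistic is
\(F = n\,\bar d^2 / \widehat{\mathrm{var}}(d)\). For a rank-one contrast the
box-type numerator degrees of freedom are exactly 1, and the denominator
reference is taken as \(F(1, n-1)\) — the natural within-subject
small-sample reference, since the contrast variance is estimated from the
n subject contrasts. Two empirical checks back this choice: null rejection
rates at \(\alpha = 0.05\) sit inside the 99% binomial band (200 null
replicates at n = 40), and on n = 8 datasets the p-value agrees with the
exact within-subject permutation distribution (all \(2^8\) bread-label
flips) to within 0.05.

The test is invariant under strictly monotone transforms (it sees only
ranks). All-tied features have no defined p-value and raise a degeneracy
error; `differential_screen()` excludes such features *before* the BH
correction so that unanalyzable features do not shrink the BH family, and
reports them separately.

### Per-arm follow-up

For each feature passing or failing the screen, per-arm Wilcoxon signed-rank
tests (post vs pre within each bread) localise which arm moved. The
signed-rank p-value is exact — the full sign-assignment distribution of the
rank sum, computed by convolution, identical to enumerating all \(2^n\)
patterns — up to 25 nonzero pairs, with mid-ranks under ties; beyond that a
normal approximation with continuity correction takes over (the two agree to
<0.01 at the boundary). Zero differences are dropped before ranking (the
classic convention; `zero_method = "pratt"` is available). Two-sided
p-values are twice the smaller tail, capped at 1.

Cliff's delta is computed between the post and pre *distributions* of the
same arm — the unpaired form over all n×n cross pairs, matching the
convention of the standard effect-size implementations; magnitudes are
graded negligible/small/medium/large at 0.147/0.33/0.474 (strict
less-than at each boundary).

### Correlations

Associations between feature changes and clinical changes use per-subject
post−pre deltas within the intervention arm and Spearman correlation
(`exact = FALSE` throughout, since ties are ubiquitous in zero-inflated
abundances). BH correction runs across all computed pairs; pairs with fewer
than 3 complete subjects are skipped and reported. Two annotations are kept,
q ≤ 0.1 and raw p ≤ 0.05, because heatmap-style reporting conventionally
shows both.

### Estimated group difference

For clinical endpoints the package reports the estimated group difference:
per subject, the change under each bread; EGD is the mean of the paired
difference of changes, with a t-interval on those per-subject differences.
This is a deliberate simplification of the repeated-measures mixed models
(Toeplitz/autoregressive covariance, period and sequence fixed effects)
used in trial reports: the paired contrast estimates the same quantity
without covariance modelling, at some efficiency loss and without
period-effect adjustment, so exact replication of mixed-model estimates is
not claimed. EGD is antisymmetric under swapping arm labels (tested).

## The synthetic-data generator

The generator exists so that every stage is testable end-to-end at desk
scale with no downloads. It emulates:

* a catalog with MSP structure (≥100 genes per MSP, exactly 100 markers,
  markers ⊆ core), log-normal gene lengths (median 1 kb), and configurable
  KO/CAZy annotation densities (defaults 0.6 / 0.15);
* a balanced two-sequence crossover (default n = 39 subjects, 4 visits);
* latent compositions: per-MSP log-normal abundances with MSP-level spread
  `sd_msp = 2` (heavy-tailed species abundances), subject effect
  `sd_subject = 1`, visit noise `sd_visit = 0.5` (natural-log scale),
  renormalised to the simplex. These variance components are free
  parameters chosen to look like adult gut metagenomes (a few dominant
  species, strong inter-individual signature, smaller within-subject
  drift); they are not estimates from any particular cohort;
* planted effects: a multiplicative shift on a target MSP at the post visit
  of one arm. The multiplier is calibrated numerically — on an independent
  400-pseudo-subject calibration draw with common random numbers, solved by
  `uniroot` on the log-multiplier — so that the *renormalised* abundance
  contrast reaches the requested Cliff's delta in expectation;
  renormalisation otherwise attenuates the realised effect when the target
  is abundant;
* alignment records with a Bernoulli shared-read fraction, shared candidates
  drawn within the same MSP (paralog-like redundancy; sequence content is
  never simulated);
* clinical tables with baselines near values typical of adults at
  cardiometabolic risk (fasting glucose 5.3 mM, insulin 12 mIU/L, TC 5.1 mM,
  HDL-C 1.2 mM, TG 1.3 mM), Gaussian measurement noise truncated at zero,
  gamma-shaped postprandial curves on the fixed grid 0–240 min
  (0, 15, 30, 45, 60, 90, 120, 180, 210, 240) anchored exactly at the
  fasting value at t = 0, and optional linear couplings between a subject's
  planted-feature delta and either a fasting variable or a postprandial
  excursion amplitude.

All generators are bit-reproducible for a fixed seed and restore the
session RNG state.

**What passing tests show — and do not.** The simulation validates the
*computations*: conservation laws, oracle equivalence, null calibration,
FDR control and power under the generator's assumptions. Real gut
metagenomes violate several of those assumptions: compositions are more
structured than independent log-normals (ecological covariance networks),
marker genes can cross-map between close species, depth varies with DNA
quality rather than at random, and clinical couplings are not linear.
Passing tests therefore certify the pipeline's arithmetic and its
statistical calibration under a plausible null, not biological findings.

## Problem sizes and runtimes

The test suite runs the screen's calibration checks at the study's scale —
40 subjects, 200 features, 100 null replicates for FDR control and 50
replicates for power — with latent compositions feeding the screen directly;
the read-level stages are exercised on catalogs of a few hundred to ten
thousand genes and depths of a few thousand reads, which cover the identical
code paths at a minute of total runtime. Exact oracles (signed-rank
enumeration, BH step-up, brute-force carriage) run at the sizes where
enumeration is feasible (n ≤ 10 sign patterns, ≤5 MSPs / ≤4 modules /
≤3 samples).

## Known limitations

* No read-level sequence simulation (no FASTQ, no mapper in the loop); the
  shared-read mechanism is a statistical emulation of catalog redundancy.
* Flat KO-set module completeness; no KEGG boolean path logic.
* The EGD contrast does not adjust for period or sequence effects.
* Spearman p-values use the asymptotic approximation; no confidence
  intervals for rho are reported.
* MSP abundances default to raw marker means (not renormalised to the
  simplex); `renormalize = TRUE` exposes the alternative, but the two
  differ under depth-dependent detection.
* The interaction test requires complete 4-visit subjects and drops the
  rest; no imputation is attempted.
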