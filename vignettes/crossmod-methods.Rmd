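---
title: "Methods: mouse-to-human co-expression module concordance"
author: "crossmod"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mouse-to-human co-expression module concordance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`crossmod` relates brain transcriptomes of mouse strains carrying
perturbations of Alzheimer's-disease risk genes to human AD co-expression
signatures. This vignette is the package's account of the statistical
model at each stage, the tunable parameters and their defaults, what the
synthetic-data generator does and does not emulate, and the numerical and
design choices that were genuinely open.

## Study design assumed by the defaults

The reference design is 48 bulk RNA-seq samples: five late-onset-model
strains (`APOE4`, `Apoe`, `Clu`, `Bin1`, `Cd2ap`, six replicates each) and
six B6 controls in batch 1; one `APP_PS1` replicate with seven additional
B6 controls in batch 2; four `APP_PS1` replicates in batch 3 — thirteen
controls in all. Every stage accepts arbitrary strain/batch layouts through
the sample metadata; the defaults merely mirror this design.

## Preprocessing

*Filtering.* A gene is removed iff its TPM is below `minTPM` (default 10)
in **strictly more than** `maxFracBelow` (default 0.9) of samples. The
strict inequality is kept deliberately: a gene at exactly the boundary
fraction is retained. The filter is idempotent and applied to the merged
(all-batch) matrix.

*Transform.* `log2(TPM + 1)`; all downstream log-scale work uses this
scale (so regression coefficients are log2 fold changes).

*Batch correction* (`correctBatch`) is a per-gene location/scale model.
Batch means and variances are estimated on data standardized against a
batch-size-weighted grand mean, with strain indicators in the
standardization design so that biological contrasts are not absorbed into
batch parameters; with `eb = TRUE` (default) the per-gene batch locations
get a normal prior and the scales an inverse-gamma prior, hyperparameters
by method of moments, iterated to a 1e-6 relative tolerance. `eb = FALSE`
gives the plain location/scale adjustment (exact removal of a constant
per-gene batch offset, to 1e-10 in the tests). A single batch is the
identity. `covariates = FALSE` reproduces the covariate-free reading; it is
not the default because strain–batch imbalance is severe in the reference
design (all late-onset strains sit in one batch), and a covariate-free
standardization visibly shrinks strain contrasts there. The empirical-Bayes
path is cross-checked against `sva::ComBat` in the test suite.

*PCA* treats samples as observations and genes as variables, gene-centered
and unscaled by default (a `scale.` flag exists). Component signs are fixed
by making the largest-magnitude gene loading positive, so results are
reproducible across BLAS implementations.

## Differential expression

A deliberately simplified negative-binomial Wald test, documented as such:
median-of-ratios size factors (rescaled to geometric mean one), per-gene
method-of-moments dispersion pooled over strain-by-batch cells with at
least two samples (floored at 1e-8), an NB log-linear fit with intercept,
strain indicator, batch indicators and log size factors as offset, and a
Wald test of the strain coefficient. Two small-sample choices matter:

- the Wald statistic is referenced to a *t* distribution with the residual
  degrees of freedom rather than the normal — with six samples per group
  and plug-in dispersions the normal reference is visibly anticonservative
  (type-I error near 0.08 at nominal 0.05 in null simulations; the *t*
  reference restores 0.04–0.065);
- genes with all-zero counts are reported as `untestable` rather than
  p = 1, and non-converging NB fits fall back to Poisson with a flag.

There is no dispersion shrinkage across genes, no fold-change shrinkage
and no independent filtering; the package's contribution is downstream of
this stage, and the stage is required to be *calibrated*, not to reproduce
any particular shrinkage estimator. Each strain is tested against all
controls in a pairwise subset by default (`allStrains = TRUE` fits the
joint model).

## Module discovery

Unsigned adjacency `a_ij = |cor|^power` (power 8 by default; `"auto"`
selects the smallest power whose scale-free fit reaches signed R² ≥ 0.85,
computed on ten equal-occupancy connectivity bins with the bin *frequency
density* regressed on mean connectivity, both log10). The topological
overlap matrix uses the standard unsigned form with unit diagonal, and
`1 − TOM` feeds average-linkage clustering.

*Tree cut.* Branches are obtained by a static cut at 0.995 of the maximum
merge height. A pure static cut, however, admits aggregates of mutually
unconnected high-connectivity genes: for null genes the expected TOM
neighbour sum scales with the product of connectivities, so "hub-like"
noise genes cluster below any near-root cut height. Candidate branches are
therefore additionally required to pass a **separability gate**: the mean
within-branch adjacency must exceed `minDensityContrast` (default 50)
times the mean branch-to-outside adjacency. In simulations with planted
modules (within-module |r| = 0.7, power 8) genuine modules show contrasts
of 107–3100 while noise aggregates stay at 11–18, in both noise-dominated
and module-dominated networks, so the default sits in the middle of a wide
gap. Setting `minDensityContrast = 0` recovers the plain static cut. This
gate — rather than the full PAM-like hybrid tree-cut algorithm — is the
package's answer to the open choice of tree-cut variant: it is fully
specifiable, testable, and sufficient for the module-recovery targets.
A known limitation: weakly co-expressed modules (within-module |r| well
below 0.5 at power 8) may fail the gate.

Branches of at least `minSize` (default 30) genes become modules, labeled
by the conventional WGCNA colour sequence in decreasing size order (the
labels are a naming convention; no correspondence of colours to any
particular dataset's modules is implied). Eigengenes are the first
principal component of the standardized member genes, scaled to unit
variance and sign-oriented towards positive mean member correlation.
Modules whose eigengenes have dissimilarity `1 − cor` below `mergeHeight`
(default 0.25) are merged iteratively, largest-correlation pair first,
recomputing eigengenes after every merge; the merged module keeps the
larger module's label.

## Strain association

Per module eigengene: one-way ANOVA over strains, BH across modules, then
Tukey HSD for significant modules. Both the ANOVA convention (zero
between-group variance gives F = 0, p = 1 rather than NaN, so degenerate
synthetic edge cases cannot crash a scan) and the Tukey family (the
studentized-range distribution always uses the total number of groups,
even when only control contrasts are reported) are fixed and tested. BH is
applied across modules to the ANOVA p-values; Tukey p-values are reported
as family-wise values unmodified — applying BH again to Tukey values is a
defensible alternative reading, so both p-values appear in the output and
the caller can re-adjust. A strain *drives* a module when the module's
BH-adjusted ANOVA p and the strain-vs-control Tukey p are both below
alpha (default 0.05). Strains with a single sample are excluded from the
Tukey step with a warning.

The shift scale matters for power here: an eigengene has unit variance
over samples, so a planted shift of δ = 1 on the *module signal* is a
one-standard-deviation effect at the module level and is only weakly
detectable with six replicates against the sample-to-sample signal — this
is a property of the design, not of the test. The association stage's own
calibration therefore uses eigengene-level simulation (`simEigengenes`),
where δ is expressed relative to the residual noise (default 0.3): at
δ = 1, σ = 0.3 the planted driver is a 3.3 σ contrast and detection is
essentially exact, while label permutation abolishes all calls.

## Enrichment

Hypergeometric upper-tail over-representation of a query gene list in each
catalog set, both intersected with a user-supplied universe, BH across
sets. The recommended universe is the analyzed transcriptome (genes
surviving the low-expression filter), not the genome: the filtered
transcriptome is what the modules were drawn from, and a genome universe
would inflate every enrichment. Transcription-factor target analysis is
the same operation run against a regulon GMT.

## Cross-species comparison

*Mapping.* Gene identifiers are opaque, case-sensitive strings; identity
across species is established solely by the user-supplied ortholog map.
Two policies: `all_pairs` (every mapped pair; used for set overlap, where
one-to-many orthology legitimately widens the image of a module) and
`one_to_one` (genes with a unique partner in both directions, computed on
the whole map; used for correlation, where one-to-many pairs would create
duplicated observations).

*Overlap.* Jaccard index between the human image of a mouse module and a
human module, with an empirical null: draws of `|module|` genes without
replacement from the union of all mouse module genes, each mapped and
scored identically, default 10,000 draws. The empirical p uses the
add-one estimator `(1 + #{J_null ≥ J_obs}) / (nPerm + 1)` — never zero,
and a valid p-value. The null universe is the union of module genes (not
all expressed genes) because modules are drawn from that set; a different
universe can be supplied for sensitivity analysis. Null draws are mapped
*after* sampling, so observed and null scores go through the identical
path. BH is applied across all (mouse module, human module) pairs. Test
suite and acceptance script verify that null p-values are uniform
(Kolmogorov–Smirnov against the uniform on 200 null pairs at 1000
permutations).

*Concordance.* Per gene, ordinary least squares of log2 expression on an
intercept plus one indicator per non-control strain; with this one-hot
design each β is exactly the strain mean minus the control mean, in log2
units. Batch indicators are excluded by default — the regression is run on
batch-corrected expression, and the printed model is the plain
multi-strain contrast — with `withBatch = TRUE` available. Per (strain,
human module, region): Pearson correlation with its t-test between human
log2FC and β over one-to-one orthologs carrying both values; fewer than
three usable genes or zero variance yields an `untestable` row rather
than an error. BH is applied across all (strain × module × region) tests,
and results above the threshold are marked non-significant.

An important behaviour, visible in the demo and intrinsic to co-expression
data: because all member genes of a module share the per-sample module
signal, *every* strain's estimated effect vector on that module is
proportional to the member loading pattern, scaled by that strain's
(planted shift + sampling) contrast of the shared signal. Off-target
strains can therefore show significant positive or negative concordance
with a matched human module, and a weak on-target contrast can even flip
sign (probability ≈ 2% per pair at six replicates). The acceptance script
reports the median over planted pairs for this reason.

## The synthetic-data generator

`simulateStudy` emulates: the strain/batch layout above; log2-scale latent
expression `baseline + loading × (module signal + strain shift) + batch
offset + noise`; TPM as `2^latent − 1` clipped at zero and rescaled to a
constant column sum of 1e6; negative-binomial counts with mean
proportional to TPM times a uniform library size; an ortholog map covering
90% of genes one-to-one plus 5% one-to-many rows; human modules built from
module orthologs plus 20% random contamination; and human log2FC equal to
the driver strain's planted effects plus noise scaled to a target
correlation (0.5 by default for matched pairs).

Defaults chosen once, with their rationale: noise σ = 0.3 log2 units
(typical residual spread of brain bulk RNA-seq on this scale); module
signal standard normal per sample; within-module correlation 0.7 (solid
but not degenerate co-expression at power 8); strain shift δ = 1.0, in the
middle of a plausible 0.3–1.5 log2-unit band for single-gene
perturbations; loadings with random sign and magnitudes in [0.5, 1.5] —
anti-correlated members are common in real modules, and the sign spread
gives planted per-gene effects genuine within-module variance, without
which module-level concordance would be undefined; batch offsets
N(0, 0.5²) per gene for non-reference batches; NB dispersion 0.05.

What the generator does **not** emulate — and hence what passing tests do
not show about real data: gene-length and GC effects (TPM is taken as
given), correlated background structure outside planted modules (real
transcriptomes have pervasive weak correlation; the background here is
independent noise, which is the *harder* case for the separability gate
but the easier one for ARI), cell-type composition shifts, outlier
samples, and any relationship between module membership and expression
level. The planted truth also makes module boundaries crisp; real modules
overlap.

Determinism: every generator stage consumes its own seed derived from the
global one, so regenerating one stage leaves the others unchanged, and
identical seeds give bit-identical outputs on one platform.

## Numerical conventions and degenerate inputs

- BH adjustment is the standard step-up rule (`p.adjust`); inputs outside
  [0, 1] are errors. Re-adjusting already-adjusted values is *not* the
  identity (step-up multiplies by m/i again); the tests assert the true
  properties (monotone, never smaller).
- Pearson r = ±1 reports p = 0; zero variance is a flagged degenerate
  error (or an `untestable` row where a scan must survive it).
- Tukey p-values are clamped to [0, 1]; q = 0 with zero pooled variance
  reports p = 1.
- The hypergeometric tail is `phyper(k − 1, …, lower.tail = FALSE)`,
  exact in log space internally.
- Jaccard of two empty sets is 0 by convention.
- The TOM of an adjacency with unit diagonal is symmetrized against
  floating-point drift and has unit diagonal.
- Eigengene orientation: sign flipped so the mean correlation with member
  expression is non-negative; ties (mean exactly 0) keep the SVD sign.

## Problem sizes used by the tests

The suite exercises the stages at sizes chosen to finish in minutes on one
core while keeping every statistical check well-powered: oracle checks on
100–1000 random small instances; null-calibration at 200 pairs × 1000
permutations; module recovery at the generator default (1500 genes, five
50-gene modules, 48 samples, ten seeds); DE calibration at 2000 null
genes; the demonstration pipeline at the full default design with 1000
permutations. Production runs with 10,000 permutations and transcriptome-
scale matrices are configuration changes only.

## Known limitations

- The static-cut-plus-gate module detection is not the hybrid dynamic
  tree-cut algorithm; very weak or nested modules will differ.
- The DE stage's moment dispersions are noisy at very low counts; genes
  with fewer than ~5 mean counts rely on the Poisson fallback more often.
- Concordance attenuates towards zero with estimation noise in β (errors
  in variables); reported r values are conservative for weak effects.
- One brain region per LFC column is treated independently; no
  meta-analysis across regions is attempted.
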