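---
title: "Methods: Firth logistic differential expression and cross-disease rank aggregation"
author: "firthseq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Firth logistic differential expression and cross-disease rank aggregation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(firthseq)
```

# Scope and data model

`firthseq` analyses a gene × sample count matrix from a case/case/control
bulk mRNA-Seq design: two disease groups (labelled `HD` and `PD`
throughout) and one control group (`C`), with the pooled disease group
(`ND` = HD ∪ PD) as a third contrast. The central container is a
`FirthDataSet`, a `SummarizedExperiment` whose `colData` carries the
condition, batch and covariate columns and whose `rowData` carries gene
symbol, biotype and — for simulated cohorts — the planted ground truth.
The pipeline starts at the count matrix; read processing, alignment and
counting are upstream of this package.

# Preprocessing

**Biotype filter.** Poly-A-selected libraries only capture
polyadenylated transcripts, so genes are restricted to a 13-biotype
whitelist (protein coding, lincRNA, processed transcript, sense
intronic/overlapping, and the IG/TR receptor segment classes;
`polyABiotypes()`). Both the Ensembl spelling `sense_overlapping` and the
variant `sense_overlaping` found in some annotation exports are accepted,
so either dialect of annotation table works unchanged.

**Zero filter.** A gene is removed when *strictly more than half* of the
case samples, or strictly more than half of the control samples, have
zero counts. The case group defaults to the pooled diseases so that all
three contrasts share one gene universe; this keeps per-contrast results,
GSEA rankings and RRA inputs directly comparable. A gene with zeros in
exactly half of a group is retained (the inequality is strict).

**Normalization.** Median-of-ratios: per-sample factors are the median
over reference genes of the ratio between the sample's count and the
gene's geometric mean across samples. Geometric means are computed in log
space and genes with any zero count are excluded from the reference set,
the standard convention for this estimator; a dedicated test checks exact
agreement with `DESeq2::estimateSizeFactorsForMatrix`. If no gene is
all-positive the estimator is undefined and the package stops with advice
to prefilter.

**Outlier trimming.** The winsorization used here is this package's own
deterministic stand-in for count-outlier handling, chosen because it is
scale-robust and preserves the sample count: per gene and per condition
group, values with robust z-score |x − median| / (1.4826 · MAD) above
`zMax` (default 3) are clamped to the boundary median ± zMax · 1.4826 ·
MAD. Degenerate inputs are handled conservatively: a group with MAD 0 is
left untouched, and groups with fewer than three samples are skipped with
a warning. The procedure never moves a group median and never widens a
group range. It can be disabled (`trim = FALSE`) when upstream data are
already cleaned.

# Firth logistic differential expression

For each gene, the trimmed normalized abundance is standardized to mean 0
and sample SD 1 (denominator n − 1), and disease status is regressed on
it: logit P(case) = β₀ + β₁ x (+ covariates). The reported statistic is
the standardized log odds ratio β₁ — log-odds change per SD of
expression, comparable across genes — with the sign convention that
positive LOR means greater abundance in cases.

**Estimation.** The log-likelihood is penalized with Jeffreys' prior,
ℓ*(β) = ℓ(β) + ½ log det I(β), and maximized by Newton–Raphson on the
Firth-modified score U*(β) = Xᵀ(y − μ + h(½ − μ)), where h is the
diagonal of the weighted hat matrix. Numerical safeguards:

- a line search along the Newton direction accepts the first halved step
  that strictly improves ℓ*; if the surface is locally flat — plain
  Newton can 2-cycle around the optimum under quasi-separation — the best
  tried step is taken instead;
- convergence is declared when the score sup-norm falls below `tol`
  (default 1e−6), after which a few damped half-steps polish the
  estimate well past that tolerance (the add-½ oracle tests require
  ~1e−12 agreement);
- fitted probabilities are clamped away from 0/1 before logs;
- at most 50 iterations, after which the fit is flagged non-converged.

For a saturated 2×2 design (binary predictor) the penalized optimum has a
closed form: the log odds ratio of the table with ½ added to every cell.
This exact oracle, including fully separated tables (e.g. 4/0 vs 0/4 →
LOR = log 81), anchors the estimator's property tests.

**Testing.** The count coefficient is tested by the penalized
likelihood-ratio test: the profile fit re-maximizes the nuisance
coefficients with β₁ fixed at 0 *under the full model's penalty*, and
2(ℓ*_full − ℓ*_profile) is referred to χ²₁. The profile-penalty detail
matters: penalizing the reduced model with its own (smaller) Jeffreys
penalty produces a mis-scaled statistic and badly inflated type-I error,
which is why the Wald test is not the default either — the penalized LRT
is the standard recommendation for Firth models and calibrates well at
these sample sizes (the all-null cohort test holds the empirical
P(p < 0.05) inside the 99% binomial band around 0.05).

**Multiplicity.** q-values are Benjamini–Hochberg within each contrast;
genes whose fit fails (constant within the contrast's samples, or
non-convergence) get `NA` p and are excluded from the number of tests so
they do not deflate other genes' q-values. The DE call threshold is
q < 0.01.

**Covariates.** The default model is status ~ count only: which clinical
covariates (RIN, PMI, age) belong in the model is design-specific, so
they are opt-in (`covariates =`). Numeric covariates are standardized
like counts; categoricals are dummy-coded against the first level. The
simulator generates age/PMI/RIN with realistic group means but no effect
on counts, so covariate-adjusted designs are exercised without touching
the planted truth.

**Batch diagnostic.** Rather than modelling batch, the package provides
the concordance diagnostic used to justify omitting it: Spearman ρ
between per-gene LORs from models with and without a categorical batch
term. On simulated cohorts without a planted batch effect ρ is ≈ 1; a
batch perfectly confounded with status is detected and refused.

# Preranked GSEA

The complete per-contrast gene list — all genes irrespective of
significance — is ranked by descending LOR (ties broken by gene id, so
rankings are deterministic). For a set S, the running sum rises by
|score|^p / Σ_S |score|^p at members and falls by 1/(N − |S|) at
non-members; the enrichment score ES is the maximum deviation from zero,
signed, with an exact positive/negative tie resolved to the positive
extreme. The weight is p = 1 (classic weighted GSEA; p = 0 available).
ES is evaluated from hit positions in O(|S|) — between hits the running
sum falls linearly, so extrema occur only adjacent to hits — and is
tested to 1e−12 against a brute-force per-prefix evaluation and against
`fgsea::calcGseaStat`.

Because the ranking is a fixed preranked list, the null is
**gene-sampling**: random same-size member sets drawn from the universe
(one shared null ensemble per distinct set size). NES = ES /
mean(|null ES| of the same sign); the nominal p is the fraction of
same-sign null scores at least as extreme, with a +1 continuity
correction keeping p in (0, 1]. Significance is called at BH q < 0.05
across the collection — a deliberate divergence from the original GSEA
FDR procedure, kept consistent with the BH-everywhere convention of the
rest of the pipeline; q-values from other GSEA implementations will
differ in the decimals. Note the permutation floor: with `nPerm` draws
the smallest attainable p is ≈ 2/`nPerm`, so small collections tested at
stringent thresholds need `nPerm` ≥ 1000 (the default).

Sets are intersected with the ranked universe first; sets shrinking below
`minSize` (default 5) are skipped with a log message.

# Robust rank aggregation

Each contrast contributes a complete ordering of the shared gene
universe. Genes enter ascending by raw p with ties broken by descending
|LOR| and then gene id — per-gene significance ranks, matching how the
aggregated gene tables are usually presented; raw p is used because BH
adjustment coarsens ties. For a gene with normalized ranks r₁…rₙ
(position/N) across n lists, sorted ascending, the binomial tail
β_k = P(Bin(n, r₍k₎) ≥ k) asks how surprising its k-th best rank is under
independent uniform orderings; the score is ρ = min_k β_k with a
Bonferroni correction over k: corrected = min(1, n·ρ). Tails are exact
(`pbinom` survival), no normal approximation — n is 3 here. Genes are
reported ascending by corrected score with a significance flag at
score < 0.01. The corrected score is conservative (stochastically ≥
uniform under the null), which the null-calibration test verifies; the
exact-null refinement of the original RRA algorithm is intentionally not
reproduced.

# Disease comparison

DE genes from the two single-disease contrasts are partitioned into
HD-only, PD-only and common sets (exact set algebra; disjoint and
covering by construction). Each partition is tested against each gene-set
collection by the upper-tail hypergeometric test within the universe of
genes that passed preprocessing — the tested universe, not the genome —
with BH within each partition × collection block.

Enriched sets are grouped when they share more than 20% of their DE
genes. The sharing denominator is the overlap coefficient
|A ∩ B| / min(|A|, |B|) (configurable to Jaccard): the min-set
denominator lets a small pathway nested inside a larger one group with
it, which matches the intent of grouping redundant annotations. Groups
are connected components of the resulting graph; the rule is strict (>)
and component ids are numbered by first appearance so output is
order-stable.

Finally, the direction-concordance table records, for every set
significant in at least two contrasts, whether the NES signs agree, plus
the per-contrast unique/shared counts. On synthetic cohorts with planted
shared effects, concordance is 100% — the behaviour expected when two
diseases perturb the same pathways in the same direction.

# The synthetic-data generator

`simulateCohort()` emulates the statistical structure the analysis
assumes, not any particular tissue's expression landscape:

- counts are negative-binomial with variance μ + αμ², α = 0.1 by
  default — a typical bulk RNA-seq dispersion;
- per-gene base means are log-uniform on [10, 1000] (well-measured genes;
  the zero-filter path is still exercised at the low end), per-sample
  size factors uniform on [0.5, 2];
- group sizes default to 29/29/49, the two-disease brain cohort design
  the package targets;
- planted effects act multiplicatively on the mean: 2^effect for disease
  samples, with fixed magnitude |log2FC| = 1 and random sign; 10% of
  genes share one effect across both diseases, 5% are unique to each;
  labels and signed effects are recorded as ground truth;
- covariates are Gaussian per group with realistic means/SDs but no
  effect on counts; batches shift even-numbered batches by `batchLfc`
  (0 by default);
- all randomness derives from one seed via deterministic per-component
  sub-seeds, so identical parameters reproduce identical cohorts and
  partial regeneration (e.g. gene sets only) is stable.

`simulateGeneSets()` plants enriched sets by drawing a `purity` fraction
(default 0.9) of members from genes with one truth label and one effect
sign; at purity 1 a set shrinks rather than dilutes when the pool is
small. Background sets are uniform draws.

What passing tests on these cohorts shows — and does not. The simulator
matches the analysis assumptions exactly: NB marginals, clean group
labels, effects on independent genes, covariates without signal. Real
brain cohorts violate several (gene–gene correlation, cell-type
composition shifts, covariate–status correlation, dispersion trends), so
recovery rates measured here are upper bounds on real-data performance;
the tests validate correctness of the computations and calibration of
the statistics, not biological effect sizes.

# Numerical choices and problem sizes

Tolerances: Firth score sup-norm 1e−6 (estimates polished to ~1e−12);
ES oracle agreement 1e−12; exact hypergeometric and binomial tails via
`phyper`/`pbinom`. Ties: gene-id tie-breaks in rankings, positive-extreme
tie rule in ES, first-appearance numbering of set groups — all outputs
are deterministic given a seed, and two pipeline runs with the same
configuration are byte-identical.

The shipped validation suite uses cohorts of 120–1000 genes and the
29/29/49 design (down to 10/10/14 for pipeline plumbing tests), 100–1000
permutations for GSEA and 2000 genes for the RRA null calibration —
sizes chosen so the full suite exercises every code path at
Monte-Carlo-stable scale while remaining quick to run; all thresholds and
seeds are fixed in the tests.

# Known limitations

- The winsorization rule is a documented stand-in; it is not a
  reimplementation of any published count-trimming procedure.
- GSEA q-values are BH over permutation p-values, not the original GSEA
  FDR; they have a resolution floor set by `nPerm`.
- The RRA corrected score uses the Bonferroni bound only; it is
  conservative relative to the exact-null corrected score.
- One gene per model: multi-gene designs, negative-binomial DE models and
  surrogate-variable batch correction are out of scope; batch handling is
  diagnostic only.
- The pipeline starts at the count matrix; no FASTQ/BAM handling and no
  annotation or gene-set retrieval clients.
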