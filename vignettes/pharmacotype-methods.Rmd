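---
title: "Pharmacogenomic subtyping: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pharmacogenomic subtyping: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pharmacotype)
```

`pharmacotype` implements a pharmacogenomics-first route to tumor molecular
subtypes: instead of clustering a cohort on globally variable genes, it
first asks which genes track drug response in cell-line panels, then uses
those genes to partition patients, and finally characterizes the resulting
subtypes (projection to other cohorts, immune and genomic landscape,
predicted drug response, prognostic-model benchmarking). This vignette
documents the statistical machinery, the tunable parameters and their
defaults, the synthetic-data model used for validation, and the design
decisions taken where the underlying methods left genuine freedom.

## 1. Drug-response trichotomization and featured genes

For every drug and sensitivity metric (IC50 in micromolar, log10 IC50,
EC50, log10 EC50), cell lines are split at the per-drug mean plus/minus
half a standard deviation (n − 1 denominator): strictly below mean −
0.5 SD is *sensitive*, strictly above mean + 0.5 SD is *resistant*,
everything else — including values exactly on a threshold — is *partial
response*. With all values equal the SD is zero and every line is partial.
When several metrics are available, the final class comes from a designated
primary metric (log10 IC50, then log10 EC50, then the linear forms);
intersecting all four metrics can empty the extreme groups in small panels,
so the other metrics are kept as diagnostics with a per-line concordance
flag instead.

Differential expression between resistant and sensitive lines (partial
excluded) uses a two-sided Welch t-test per gene; the log2 fold change is
the difference of group means on the log2 scale. Genes constant and equal
in both groups are defined to have p = 1, which makes noiseless fixtures
well-behaved. Featured genes must pass p < 0.05 and |log2FC| > 0.5 in
*both* pharmacogenomic databases with the same sign, for at least one
drug; p-values are deliberately unadjusted at this stage (two independent
databases already act as a replication filter — under the null the expected
pass rate per direction is on the order of alpha squared). Genes supported
with opposite directions by different drugs are dropped at deduplication.

## 2. Consensus NMF subtyping

Expression restricted to the featured genes is made nonnegative by
subtracting each gene's minimum. Factorization uses Kullback–Leibler
multiplicative updates; a run stops when the sample connectivity (argmax
over the H columns, ties to the lowest index) has been unchanged for 40
consecutive checks at 10-iteration intervals, or at 2000 iterations. The
KL divergence is recorded at each checkpoint and is non-increasing — the
suite asserts this to 1e-8. The inner loop is compiled (Armadillo) because
a rank sweep multiplies it by thousands of restarts.

For each rank k in 2..7 the pipeline runs 100 random restarts by default
(the tests and acceptance use 30, which the seed sweeps show is already
stable); the consensus matrix is the mean co-clustering indicator. The
cophenetic coefficient correlates 1 − consensus with the cophenetic
distances of its average-linkage tree; the selected rank maximizes it.
Exact ties at the maximum go to the *largest* tied rank, and this matters:
with three clean groups, rank 2 merges the same two subtypes in varying
combinations whose consensus is still exactly ultrametric, so its
cophenetic coefficient equals 1 just like rank 3's — the coefficient
measures tree-representability, not only restart stability. Splitting a
true group (rank 4 and above) is unstable and breaks ultrametricity, so
over-clustering still loses. Preferring the smaller rank on ties instead
mis-selects k = 2 in roughly one seed in seven on clean simulated cohorts.
Final labels cut the consensus tree at k.
Samples with negative silhouette width (computed on 1 − consensus) are
flagged not retained; pruning that empties a cluster is an error rather
than a silent degradation.

## 3. Modules, signatures and projection

Co-expression modules come from an unsigned weighted network: adjacency
|cor|^beta, with the soft power chosen as the smallest value on a 1..10
grid whose scale-free fit reaches R² ≥ 0.85 with negative slope, else the
best-fitting power. We deliberately search 1..10 rather than up to 20: on
block-structured data the fit R² rises monotonically with the power and
crosses the target only at extreme powers that collapse the topological
overlap matrix to zero, destroying real modules; within 1..10 the planted-
module and null behaviors are both correct. Genes are clustered by average
linkage on 1 − TOM with a static cut at 0.99 of the maximum merge height
(a deterministic stand-in for the dynamic hybrid cut); clusters under 30
genes stay unassigned and modules whose eigengenes (first principal
component of the gene-standardized submatrix, sign-oriented) correlate
above 0.8 are merged. A module serves a subtype when its eigengene's
Pearson correlation with the subtype's one-hot indicator strictly exceeds
0.5 (signed, not absolute — a module anti-correlated with a subtype is not
its marker).

A subtype's signature is the intersection of its selected modules' genes
with its one-vs-rest up-regulated genes (log2FC > 0.5, Benjamini–Hochberg
FDR < 0.05). Genes claimed by two subtypes are removed from all signatures
so nearest-template templates are well-posed and pairwise disjoint.

Nearest-template prediction standardizes genes across the validation
cohort, builds 0/1 templates over the union of signature genes, and assigns
each sample to the template with the smallest cosine distance. The
per-sample permutation null draws random marker sets of the same sizes and
— importantly — takes the *minimum* distance over the random templates,
mirroring the argmin in the observed statistic; without this the null is
anti-conservative and the permutation p is no longer uniform for
unstructured data (the suite checks uniformity by a KS test).

The submap-style correspondence test compares subtype i of a trained cohort
with subtype j of a second cohort: the forward leg scores the weighted KS
enrichment (weight exponent 1) of i's signature in cohort B's genes ranked
by the one-vs-rest t statistic for j; the reciprocal leg enriches B's
top-genes markers for j (as many as A's signature) in A's fixed ranking for
i. Both legs are calibrated against permutations of cohort-B labels — the
labels actually under test. Permuting cohort-A labels instead makes the
reciprocal leg meaningless: any random marker set enriches in a strongly
structured true ranking relative to permuted rankings, and even a cohort of
pure noise lights up. The two dependent per-leg p-values (pooled ranking)
are combined by Fisher's statistic whose significance is itself taken from
the permutation distribution, then Bonferroni-corrected over all subtype
pairs; the smallest attainable corrected p is n_pairs/(n_perm + 1), so
calling pairs at 0.05 over a 3 × 3 grid needs at least 200 permutations.
One known degeneracy: with *zero* expression noise all genes of a marker
block are exactly collinear, any chance grouping ranks an entire block at
the top, and no permutation test can separate a true correspondence —
correspondence testing therefore only makes sense on noisy data.

## 4. Landscape scoring and genomic indices

Single-sample enrichment follows the rank-statistic form: per sample, genes
are ranked (ties to average rank), in-set genes accumulate rank^0.25
weights against the uniform ECDF of out-of-set genes, and the summed
difference is normalized by the global score range. Scores are invariant
to strictly monotone per-sample transforms, asserted exactly in the suite.
Simple signature indicators (T-cell-inflammation-like scores, antigen
presentation, checkpoint genes) use the mean of gene-wise z-scores instead,
with constant genes dropped.

Tumor mutation burden divides nonsilent variant counts (missense, nonsense,
frameshift, in-frame, splice-site, translation-start, nonstop) by a
configurable 38 Mb exome. Copy-number fractions use a symmetric log2-ratio
threshold of 0.2 — fraction of genome gained, lost, and their sum, over the
profiled length — so FGA = FGG + FGL holds as an identity. Arm-level events
need altered segments covering at least half an arm (assigning each segment
to its maximal-overlap arm); remaining altered segments count as focal
events, per direction. Mutational-signature exposures solve a nonnegative
least-squares problem per sample over a user-supplied 96-context reference
matrix (trinucleotide contexts taken from the MAF's `ref_context` column,
collapsed to the pyrimidine strand), normalized to proportions. The suite
uses synthetic reference signatures built in code and labelled as such.

## 5. Drug-response prediction and survival benchmarking

Ridge regression on cell lines uses the top 1000 most-variable genes,
z-standardized with training statistics, a 13-point log-spaced penalty grid
from 1e-2 to 1e4, and 10-fold cross-validation with seeded folds; the
closed-form solution makes the OLS limit at vanishing penalty an exact
oracle. Cohort predictions apply the training standardization and impute
missing features at the training mean provided at least 80% of features are
measured. Subtype differences in predicted response use Kruskal–Wallis with
pairwise Wilcoxon (BH) post-hocs; gene–response correlations are Pearson,
ranked, with the top of the list nominating resistance candidates.

Kaplan–Meier estimation, the k-sample log-rank test and Cox regression
(Efron ties, Newton–Raphson at 1e-9) are delegated to the `survival`
package; Harrell's C is implemented by its pair-counting definition
(earlier-time member must have an event, tied times unusable, tied risks
score 0.5) and cross-checked against `survival::concordance` in the tests.
Prognostic-model benchmarking scores each catalog model's linear risk
(coefficients times gene z-scores, at least 60% gene coverage per cohort)
within each subtype of each cohort and averages C over cohorts; catalogs
are user-supplied tables, with synthetic catalogs in the tests.

## 6. The synthetic-data model

The generators produce the statistical structure the analysis assumes, with
closed-form expectations where possible:

* **Cell panels.** IC50 lognormal per drug (default meanlog 0, sdlog 1 in
  micromolar — a typical micromolar-range panel); EC50 = IC50 times
  Uniform(0.5, 1); expression = per-gene N(6, 1) baseline + effect ×
  standardized log10 IC50 for planted effect genes (default 40 genes at
  1 log2 unit, directions alternating) + N(0, 0.5) noise. The default
  seven-drug panel mirrors first-line pancreatic-cancer chemotherapeutics.
* **Patient cohorts.** Three equal subtypes; three 40-gene marker blocks
  with a subtype mean shift of 1.5 log2 units; within-block co-expression
  targets a pairwise correlation of 0.6 *in total*: the subtype shift
  already contributes shift² × p(1 − p) of shared variance, and a latent
  factor supplies only the remainder (floored at zero). At shift 0 the
  factor carries the whole 0.6 and the labels are unrecoverable, as a
  sanity check requires; treating the factor as additional shared variance
  on top of the shift would instead put an information-theoretic ceiling of
  about 0.7 on label recovery, contradicting what a 1.5-unit shift should
  support. Survival is exponential with per-subtype hazards log(2)/240,
  /480, /960 per day (8/16/32-month medians — a poor/intermediate/favorable
  ordering typical of pancreatic cohorts); censoring is an independent
  Bernoulli(0.2) at a Uniform(0, T) time. A noiseless mode (noise and
  censoring zero) supports exact-recovery tests.
* **MAF/SEG.** Mutation counts Poisson per subtype (defaults 60/35/25);
  contexts drawn from a user mixture over the 96 channels, half the rows
  emitted on the purine strand to exercise collapsing; an exact mode uses
  largest-remainder rounding for deterministic spectra. Copy-number
  profiles tile a documented 8-arm toy genome, altering whole arms at the
  subtype's burden probability with log2 ratios of ±0.3, so the expected
  altered fraction equals the burden.

What passing tests on these data do **not** show: robustness to platform
effects and probe-level noise, to non-exponential hazards or informative
censoring, to copy-number-driven expression, or to the mixed cell
populations of real tumors. The generators are calibrated for structural
correctness of the algorithms, not biological realism.

## 7. Problem sizes and numerical conventions

The validation suite uses cohorts of 60–90 samples with 120–300 genes,
panels of 25–40 cell lines, 30 NMF restarts per rank, and 100–200
permutations for NTP and submap — sizes at which every recovery property
is stable across seed sweeps while a full run stays comfortably
interactive. Tie-breaks are deterministic throughout (argmax/argmin to the
lowest index, rank ties to averages or documented methods); degenerate
inputs (constant genes, empty groups, zero-variance drugs, samples without
mutations) either follow a documented convention (p = 1, exposure row of
zeros) or raise an informative error rather than propagating NaN. All
randomness flows from explicit integer seeds; repeated calls with the same
seed are bit-identical.
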