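---
title: "Methods and design choices in phenodx"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design choices in phenodx}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenodx)
```

`phenodx` models the analysis layer of a national ultrarare-disease exome
program: phenotype encoding and semantic similarity, phenotype-space
embedding, diagnostic-yield prediction, multimodal gene prioritization,
candidate-gene evidence grading, and cohort-level genetic-architecture
statistics. This vignette explains each model, its assumptions, the
parameters that matter, and the decisions taken where the design was
genuinely open.

## Ontology and semantic similarity

The ontology layer consumes OBO files with `id`, `name`, `is_a`, `alt_id`
and `is_obsolete` tags. Obsolete terms are excluded; alternative ids
resolve to primary ids; the term graph must be a single-rooted DAG (cycles
and dangling `is_a` references are structural errors). Information content
is corpus-based: entities (diseases, genes or patients) propagate their
annotations to all ancestors and `IC(t) = -ln(n_t / N)` in nats, so the
root always has `IC = 0` and IC is monotone non-decreasing from parent to
child. The corpus is a modelling choice: any list of term sets can be
supplied, and the recommended corpus is the union of a disease annotation
catalog and the cohort itself. A term annotating zero corpus entities has
undefined IC; it is clamped to the maximum observed IC (keeping
similarities finite) and recorded in an attribute for inspection.

Pairwise term similarity is Resnik's most-informative-common-ancestor
(MICA) score, and set similarity is the symmetric best-match-average
(BMA): average, in both directions, each term's best match in the other
set, then average the two directions. This family is the common default of
ontology-similarity software and is deterministic, which makes it
testable against exhaustive oracles. One caution discovered during
testing and asserted in the suite: symmetric BMA is *not* self-maximal in
general — `S(A, B)` can exceed `S(A, A)` when `A` mixes low- and high-IC
terms and `B` contains only the high-IC ones. The true bound, which the
package's property tests assert, is `S(A, B) <= (S(A, A) + S(B, B)) / 2`.

Group assignment follows the at-least-one-term rule: a patient belongs to
a phenotype subcategory if at least one of their terms maps to it, and to
a higher-order group if any of its subcategories fire. Terms absent from
the curated mapping table are assigned via their nearest mapped ancestor
(the mapped ancestor with the largest ancestor closure) so that newer,
more specific terms do not silently drop patients; `use_closure = FALSE`
restores exact matching. Multiple groups per patient are expected, not an
error.

## Phenotype-space embedding

The entity-by-entity BMA similarity matrix (patients plus, optionally, a
disease catalog treated as pseudo-patients) is converted to a
dissimilarity with `D = max(S) - S` (an inverse transform `1/(1+S)` is
available) and embedded by classical multidimensional scaling
(principal-coordinates analysis) on the precomputed distance matrix,
defaulting to four dimensions with the first two intended for plotting.
PCoA was chosen as the embedding method because it operates directly and
exactly on a precomputed dissimilarity, requires no stochastic
optimization, and is fully deterministic — repeated runs are
byte-identical, which the tests rely on. The cost relative to neighbor
graph embeddings is that PCoA preserves global rather than local
structure, so tight nonlinear clusters may appear less separated; the
planted-cluster property tests show that disjoint term pools still
separate cleanly in the first two coordinates. Column signs are fixed by
convention (largest-magnitude loading positive) to remove the eigenvector
sign ambiguity. Degenerate geometries (all entities identical) yield
zero-padded coordinates rather than warnings.

## Diagnostic-yield model

The design matrix has a penalized block — the 49 subcategory indicators —
and an unpenalized confounder block: age class (adult), sex (male), site
one-hots with the first level as reference, and the imaging-consent flag.
The model is L1-penalized logistic regression minimizing
`-(1/n) loglik + lambda * sum_j w_j |beta_j|` with `w_j = 1` on the
penalized block and `w_j = 0` on confounders and intercept, fitted along a
descending 100-point lambda grid (`lambda_min = 1e-3 * lambda_max`) with
warm starts via `glmnet`. Indicator columns are left unstandardized so
coefficients keep their per-subcategory log-odds interpretation. The
solver rescales penalty factors internally to sum to the number of
columns; the model object stores the effective per-column multiplier so
that the stationarity (KKT) diagnostics in `kkt_check()` test exactly the
objective that was optimized: at every grid point, inactive penalized
coordinates satisfy `|gradient| <= lambda * w` and active ones sit on the
subgradient equation to within 1e-6.

The penalty is tuned by stratified k-fold cross-validation (default
`k = 10`, folds balanced within outcome classes, seeded). Two selection
rules are exposed. The default, minimum mean out-of-fold deviance, is
prediction-optimal but — as is well known for the LASSO — over-selects:
on pure-noise outcomes it retains spurious subcategories in a substantial
share of replicates, and on planted 8-of-49 signals its support F1 suffers
from false positives. The one-standard-error rule (`rule = "1se"`) is the
standard parsimony choice and is what the package's support-recovery and
null-sparsity tests use; prediction metrics (AUC) are reported under the
default min rule. Predictions apply the inverse logit at the selected
lambda; confounders not supplied at prediction time (including unseen site
levels) are imputed with training-cohort means, so a phenotype-only query
is always answerable. AUC is the tie-corrected Mann-Whitney statistic with
a case-level percentile bootstrap CI (default B = 2000); a single binary
marker's AUC reduces to `(sensitivity + specificity) / 2`, which is how
per-term discriminatory AUCs are computed. Coefficient paths are exported
only for features active at the selected lambda with training prevalence
of at least 5%.

## Gene prioritization

Each facial image is represented by 12 descriptors of 512 dimensions with
unit norm; the distance between two images is the mean of the 12
index-matched cosine distances (`[0, 2]`). Index-matched pairing (12
distances, not 144) reflects that the descriptors come from distinct
ensemble members or augmentations that are only comparable like-for-like.
Because rows are unit vectors, the mean cosine similarity equals the
flattened inner product divided by 12, so a gallery is scored by one
matrix product. A gene's gestalt score is the similarity of its most
similar gallery patient (max aggregation; a mean-of-top-m variant would be
a one-line change and was not needed). Genes without gallery
representation are missing, not zero, at this stage.

The molecular channel drops variants with population allele frequency
above 0.01 (configurable) and takes the per-gene maximum deleteriousness
score among survivors. The feature channel scores each gene by the BMA
similarity between the patient's terms and the gene's phenotype
annotations; externally computed scores can be substituted anywhere a
named numeric vector is accepted.

Fusion min-max normalizes each channel to `[0, 1]` across the patient's
gene list, maps missing values to 0 *after* normalization (absent evidence
is a neutral floor — it must not rank a gene below one with no evidence at
all), treats constant channels as all-zero, and sums the channels with
weights (equal by default; the weighted-sum combiner is a plug point for a
trained fusion model). Min-max normalization makes the fusion invariant to
affine rescaling of any channel. Ranking is by descending fused score with
worst-rank ties, so a tied causal gene is never flattered. Top-k accuracy
is the fraction of benchmark cases whose causal gene ranks within k, with
case-level percentile bootstrap CIs (B = 1000, seeded); causal genes
outside the vocabulary count as never hit and are flagged.

## Candidate-gene evidence score

Scoring applies only behind a mandatory gate of four criteria (no prior
robust gene-phenotype association; no alternative causative explanation;
allele frequency below the cutoff or absent in controls; inheritance
consistent with the family). The score is a weighted sum over nine
criterion indicators, maximum 8 for autosomal dominant candidates; three
criteria — de novo status and the two gnomAD constraint metrics — apply
to AD only and contribute nothing under recessive or X-linked inheritance
(X-linked uses the recessive mask, a package convention where the grading
scheme is silent). Classification is high at a score of 4+ for AD and 3+
for recessive; an AD score of 0 falls below the defined medium band and is
classified medium with a warning rather than inventing a third class.

The weights are configuration data (a TSV shipped in `inst/extdata/`),
validated so the AD maximum is exactly 8, and replaceable without code
change by any curated scoring table. Nine strictly positive integers
cannot sum to 8, so the default table carries one supportive-only
criterion (tissue expression / pathway plausibility) at weight 0 — it is
recorded per candidate for transparency but adds no points, mirroring how
expression evidence is treated as weak-supportive in gene-curation
frameworks.

## Cohort statistics

Yield tables report per-group solved fractions with all pairwise two-sided
Fisher exact tests, Bonferroni-corrected over the number of pairwise
comparisons. The autozygosity split is strict: high means autozygosity
> 0.02, so a case at exactly 2% is low. The de-novo-normalized recessive
burden exploits the fact that the de novo mutation rate depends on
parental age but not on parental relatedness: with AR = homozygous +
compound-heterozygous fractions,
`R = (AR/denovo)_high / (AR/denovo)_low` estimates the multiplicative
excess of recessive disease in the consanguineous stratum and recovers a
planted hazard multiplier in simulation.

Carrier-screening amenability asks whether a recessive diagnosis would
have been reportable in a healthy carrier: a homozygous variant qualifies
if it was pathogenic/likely pathogenic at the reference date or is
predicted loss-of-function without predicted escape from
nonsense-mediated decay; for compound heterozygotes the strict reading —
both variants individually P/LP — is the default, with a flag for the
relaxed reading in which the LoF route also qualifies (the grading
language is ambiguous on this point). Reference-date classifications are
input data, never live lookups. Reported percentages follow the field's
style per rate: whole-cohort shares as integer percent, fine-grained rates
(mosaicism among de novo diagnoses, amenability among recessive
diagnoses) with one decimal.

ClinVar-style quartiles rank genes by descending submission counts after
removing an exclusion list (e.g. secondary-findings genes, whose counts
are inflated by policy rather than prevalence), with deterministic
alphabetical tie-breaks. Each gene occupies an interval of the cumulative
submission fraction and is assigned to the quartile containing its
interval midpoint; a gene spanning several bins therefore lands in the bin
holding most of its mass (a gene holding 100% of submissions lands in Q2
and is a flagged boundary case). The midpoint rule keeps each quartile's
submission mass within one maximal single-gene fraction of 25%, which the
tests assert as a mass-balance property. Year-of-first-association
distributions are compared with the two-sample two-sided
Kolmogorov-Smirnov test plus a fixed-width (5-year) histogram.

## The synthetic cohort generator

The generator's defaults are the study conditions the analyses assume,
not tuning knobs: 1,577 patients with 268 adults across five sites and six
disease categories; a mean of five phenotype terms per patient (1 plus a
Poisson draw, sampled mainly from the patient's disease-category term
pools with a 20% background admixture); an overall diagnostic yield of
32%, obtained by calibrating the logistic intercept on the realized design
(when `intercept = NULL`, a root-finder matches the mean predicted
probability to the target — so a zero-coefficient model reproduces the
intercept-only rate exactly); a planted coefficient vector with 8 nonzero
subcategories of magnitude 1; consanguinity in 144/1,577 of cases with
autozygosity above 2% (exponential tail, mean about 6%); mode of
inheritance drawn from per-stratum hazards in which the de novo hazard is
identical across strata and the recessive hazard is multiplied by the
planted burden multiplier (default 7) under consanguinity, with the
homozygous share within recessive diagnoses rising from 15% to 90%; dual
diagnoses at 2% of solved cases; parental mosaicism at 1.3% of de novo
diagnoses; an 816-gene vocabulary.

For prioritization benchmarks, each gene has a unit-norm 512-dimensional
disorder center; gallery and test descriptors are Gaussian perturbations
of the causal center, renormalized (a simpler stand-in for a von
Mises-Fisher draw that is adequate for ranking behavior). The molecular
channel comes from a per-case variant table in which roughly 30% of
variants are common (exercising the frequency filter), and the feature
channel is uniform noise plus an additive causal boost. Setting any
channel's boost to 0 switches it off *and* stops forcing the causal
gene's evidence coverage, keeping the causal gene exchangeable with
background genes — this is what makes the no-information benchmark sit at
the 10/816 top-10 chance level instead of inheriting a structural
advantage from guaranteed gallery membership. Submission-count tables are
rank-based power laws (Zipf exponent 1.5) with mild lognormal jitter and
recency-skewed years.

What the generator does not emulate: term co-occurrence structure beyond
category pools, laboratory batch effects, variant-level linkage or
genotype data, realistic facial images, and any correlation between the
three prioritization channels beyond the shared causal gene. Passing
tests on these simulations therefore demonstrate correctness of the
statistical machinery under the planted model, not real-data performance
levels; the headline real-cohort metrics of the motivating study design
(held-out AUCs near 0.7, top-10 accuracies above 80%) depend on external
trained models and unshared data and are deliberately out of scope.

## Numerical choices and problem sizes

Convergence of the penalized fits uses a tight solver threshold (1e-10)
so the KKT checks hold to 1e-6 along the whole path. The lambda = 0
endpoint is validated against an independent IRLS fit on a well-conditioned
n = 200 design (large ill-conditioned designs at lambda = 0 are a known
failure mode of *any* logistic solver under separation and are stopped
early by the path solver). Bootstrap CIs are percentile-based with seeds
recorded in every result object. The test suite runs its simulations at
reduced but statistically meaningful sizes — cohorts of 120-5,000,
10-seed replications for stochastic properties, binomial 99% bands for
null accuracy checks — chosen so the full suite completes in a couple of
minutes while keeping each band's false-alarm probability small.

## Known limitations

* The OBO reader covers the tag subset needed here, not full release
  fidelity (no logical definitions, xrefs or relationship types).
* Similarity is Resnik/BMA only; Lin or Jiang-Conrath variants would be
  small additions but are not implemented.
* The PCoA embedding preserves global geometry; fine local cluster
  structure may be less pronounced than with neighbor-graph methods.
* The fusion combiner is an equal-weight sum; a trained combiner can be
  plugged in but none is shipped.
* The evidence-score weight table is a package default; studies with their
  own curated scheme should supply it as data.
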