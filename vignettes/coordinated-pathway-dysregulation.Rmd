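---
title: "Methods: co-enrichment, inter-pathway networks and coordination dysregulation"
author: "inparkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: co-enrichment, inter-pathway networks and coordination dysregulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The scientific problem

Complex immune diseases leave traces at two levels of biological
organisation: stimulated immune cells change their transcriptional
programs (a *cellular* signal, measured by expression microarrays of
cultured cells), and the population carries common variants associated
with the clinical phenotype (a *systemic* signal, measured by GWAS).
Either signal alone is noisy and hard to interpret mechanistically.
This package implements an integrative strategy: find the pathway
jointly implicated by both data types, delineate the molecular network
that couples it to a pathway already known to drive the disease, show
that the *coordination* of that network (not only mean expression) is
disrupted in patients under stimulation, and quantify how well the
network's expression predicts markers of the downstream differentiation
process.

The motivating design is a 2 x 2 culture experiment — patient and
control mononuclear cells cultured with an allergen or with diluent,
with CD4+ T cells profiled afterwards — combined with a skin-prick-test
GWAS. The package operates purely on standard file formats (expression
TSV + annotations, GWAS summary TSV, GMT gene sets, BED coordinates,
interaction edge lists), so any study with this shape can be analysed.

# Models and statistics

## Expression-side enrichment

Per-gene differential expression uses the log2 ratio of arm means.  On
log2-scale matrices (the microarray convention, and the generator's
output) this is the mean difference with the classic Welch t test; on
linear-scale input the ratio of means is used with a delta-method SE,
because the pooled quantity of interest is the *log ratio of means*,
not the mean of log ratios.  A label-permutation p-value (shuffling arm
labels, recomputing t) is available; Benjamini–Hochberg q-values are
computed over genes via `stats::p.adjust`.

Gene sets are then tested two ways and combined by consensus:

* **Hypergeometric over-representation** of the significant genes
  (defaults: q < 0.05 and |log2 ratio| > 1, both exposed) within the
  measured universe; the odds ratio uses the Haldane–Anscombe 0.5
  correction when any 2 x 2 cell is zero.
* **GSEA** on the t-statistic ranking: set members advance the running
  sum by |score|^w (w = 1 by default, 0 supported) normalised over
  in-set scores, non-members retreat by 1/(N − K); the enrichment score
  is the signed maximum deviation.  Significance comes from gene-label
  permutations, one-sided in the direction of the observed score
  *against the same-sign side of the null* — the convention of the
  original GSEA method.  The direction-conditional form matters: a
  one-sided count against the full signed null would concentrate on
  (0, 0.5) and could never be calibrated; the conditional form is
  uniform under the null, which the test suite verifies.

A set is *consensus-enriched* when both BH q-values pass the FDR level
(inclusive comparisons at all significance boundaries).  Cross-study
reproducibility uses fixed-effect inverse-variance pooling of log2
ratios (a gene is reproducible when the pooled p is strictly smaller
than both the discovery p and alpha/n_tests), and Mantel–Haenszel
pooling of enrichment odds ratios with Woolf's heterogeneity test
(tables flagged at p <= 0.2).

## GWAS-side enrichment

Each gene's GWAS evidence is the smallest SNP p-value within 50 kb
upstream or downstream of the gene span (BED input is 0-based
half-open; internally bounds are 1-based inclusive, so a SNP exactly at
`end + window` counts).  Pathway enrichment counts member genes above
the 95th percentile of −log10(best p) and compares with random draws of
equally many *scored* genes — genes without any window SNP are excluded
from both sides of the comparison.  Full MAGENTA additionally regresses
out gene size, SNP density and LD confounders; with the synthetic
generator's uniform gene sizes and i.i.d. SNP placement those
confounders are constant by construction, so the correction is omitted
and flagged as a limitation for real data (where long genes score
better by chance).  The cutoff quantile is exposed; calibration tests
use 0.75, which gives the discrete count statistic a finer null.

## Co-enrichment and Pareto selection

For pathway k the expression coordinate is
p_expr = max(p_gsea, p_hyper) — the conservative "worse of the two
routes" — and the GWAS coordinate is the MAGENTA permutation p.  The
global co-enrichment p-value treats the joint claim as a conjunction:
all component nulls must be false.  Under independence
p_g = 1 − prod(1 − p_k); without independence the Šidák-corrected
maximum p_g = 1 − (1 − max p_k)^K is used (the default, and the
conservative choice for two different data sets on the same samples'
population).  Raw p-values, not q-values, form the objective space;
q-values govern only the consensus filter.

A pathway is **Pareto-efficient** when no other pathway is at least as
small in both coordinates and strictly smaller in one (duplicates do
not dominate each other), and, when a significance bound is given, both
coordinates also lie at or below it.  The implementation is a
sort-and-sweep; tests compare it against an O(n^2) brute-force oracle
on random instances including ties.  Efficient pathways are ranked by
p_global with the expression odds ratio breaking ties; rank 1 is the
selection.

## The inter-pathway network and its connectivity

Given pathway gene sets A and B, the inter-pathway network keeps every
*direct* interaction with one endpoint in each set, plus the incident
genes.  Indirect edges never qualify; within-pathway edges among
members are reported separately (they do not define membership); a gene
belonging to both sets is kept once with a dual label.

Connectivity is tested with a permutation null that controls for
degree: background nodes are binned by log2-spaced degree (bins merged
upward until they hold at least 5 candidates) and random member sets
are drawn bin-matched.  The direct statistic is the edge count among
members; the indirect statistic counts member pairs sharing at least
one non-member neighbour; per-node statistics are within-member
degrees.  All p-values use the add-one correction (b + 1)/(n + 1).
Degree-binned node resampling replaces within-degree edge rewiring: the
contract (a degree-controlled null) is the same and the estimator is
simpler at this scale.

## Coordination and its dysregulation

Correlation enrichment asks whether a gene set is more co-expressed
than the background: in-group |Spearman rho| over within-set pairs (or
set genes against a response vector) versus the set-to-remainder pairs
(or remainder-to-response).  "Remainder" means all measured genes
outside the set.  Reported are the two means, a Welch t p-value, a
membership-permutation p (one-sided for enrichment), and the ROC AUC in
rank-sum form — the probability that a random in-group |rho| exceeds a
random background |rho| — with the Wilcoxon p and a Hanley–McNeil
normal-approximation 95% CI.

Dysregulated coordination compares arms: for each gene pair, Spearman
correlations are computed per arm and their difference tested with
Fisher's z, z = (atanh r1 − atanh r2) / sqrt(1/(n1−3) + 1/(n2−3)),
two-sided; correlations at exactly |rho| = 1 are clipped to 1 − 1e-10.
The summary statistic is the count of pairs with p < alpha against the
expectation N·alpha, assessed by the **exact two-sided binomial test in
the minimum-likelihood form** (R's `binom.test`).  Two-sidedness here
is an inference from internal consistency: it is the only variant that
reproduces all of the published count-table p-values (5.1e-3 for
25/276, 4.9e-1 for 16/276, 4.5e-1 for 72/1326) at the printed
precision, which the acceptance tests verify.  Expected counts are
rounded half-up for reporting only; the test always uses raw counts.
Pair strata matter: the pipeline reports both the all-pairs analysis of
the network and the cross-pathway pair stratum, because a disruption of
*inter*-pathway coordination concentrates in the latter and is diluted
in the former.

The superiority comparison across gene sets (e.g. "the network's
correlation enrichment beats both parent pathways in all 6
comparisons") is a one-sided sign test, P(X >= s) at success
probability 0.5, with ties dropped.

## Predictive regression

For a single response, ordinary least squares with k-fold
cross-validation gives Q² = 1 − PRESS/TSS, with PRESS pooled over
held-out folds and TSS taken about the *training-fold* means.
Predictors are standardized inside each training fold only (no
leakage).  The in-sample R² and overall-F p come from the full fit; a
response-permutation p is attached to Q².  If a training fold has
predictors >= samples, a ridge fallback with a fixed small penalty
(1e-3 on the standardized scale) is used and logged.

For a response panel, Wilks Λ = det(E)/det(E + H) from the multivariate
linear model, reported as 1 − Λ (the multivariate R² analogue), with
Rao's F approximation for the model p — verified in tests to agree to
machine precision with `stats::manova` — and an out-of-sample 1 − Λ
built from cross-validated residual and total SSCP matrices.  Response
permutations cross-check both the in-sample p and the out-of-sample
statistic.  The methods text of the motivating study states seven-fold
cross-validation while a figure caption says leave-one-out; the package
defaults to 7 folds with a deterministic interleaved assignment and
supports `k_folds = "loo"`.  Standardized coefficients are clustered by
rows (responses) and columns (predictors) with correlation distance
(1 − r, so anti-correlated profiles sit at distance ~2) and average
linkage; cluster support is the fraction of sample-bootstrap refits in
which the same member set reappears as a clade, with support >= 0.95
flagged.

# The synthetic-data generator

`synth_config()` defines the study the pipeline is exercised on; its
defaults are the package's standing emulation of the target design and
are not adjusted per analysis:

* **250 genes, 10 disjoint pathways of 20, 20 samples per arm** in the
  four arms case/control x allergen/diluent, with pairing ids emitted
  but arms analysed as unpaired — matching how the motivating study
  handled its paired cultures.  Twenty samples per arm is the scale of
  that study's arms (13–21).
* **Gaussian noise, sd 0.5, on the log2 scale** (baseline mean 8) —
  the conventional microarray noise model; the effect-size range
  |log2 ratio| in [0.3, 2.7] spans the magnitudes reported for the
  implicated pathway's genes, and the planted pathway (`P01`) is
  coherently **down-regulated**, as that pathway's reproducible genes
  were (all but one).  Coherent direction also makes the planted set
  detectable by a running-sum statistic, which mixed-sign effects
  structurally evade — a known blind spot of GSEA, noted as such.
* **GWAS**: 4 000 SNPs uniform on one 26-Mb chromosome (multi-
  chromosome supported), genes evenly spaced with ±50 kb windows (~16
  SNPs per window); the alternative plants a Beta(0.1, 1) p-value on
  one window SNP for **75%** of `P01`'s genes.  The fraction follows
  the motivating result that a majority of the implicated pathway's
  genes carried associated SNPs, and a power calculation: with the
  95th-percentile threshold, a Beta(0.1, 1) draw clears a typical
  best-SNP threshold with probability ~0.5–0.6, so 15 planted genes
  give the permutation test comfortable power where 10 leave it at the
  edge.
* **Interaction graph**: Erdős–Rényi background at density 0.01 over
  all gene pairs *except* the A x B crossing cell, plus 12 planted
  crossing edges between `P01` and `P02` — so the planted edges are
  exactly the ground-truth inter-pathway network (24 genes, 276 pairs,
  the same pair count as the published network's stratum).  All edges
  are direct; background edges never contaminate the crossing cell by
  construction.
* **Coordination disruption**: the 12 crossing gene pairs gain
  correlation 0.9 in the case-allergen arm only (0 elsewhere), i.e.
  |Delta rho| = 0.9 between cases and controls under allergen and no
  difference under diluent.  Arm-specific target correlation matrices
  are repaired to the nearest correlation matrix by eigenvalue
  clipping (`Matrix::nearPD`) if planted deltas break positive
  semi-definiteness; irreparable targets raise an error naming the
  offending pairs.
* **Protein response and panel**: the response is a linear combination
  of 5 network genes (coefficients 1.2, −1.0, 0.8, −0.8, 0.6) plus
  Gaussian noise with sd = 0.5 x signal sd; the multivariate panel
  scales the same signal by weights (1, 0.8, 0.6, −0.7, −0.9) with
  independent noise per response, emulating a differentiation panel
  with mixed up-/down-regulated members.

What the generator deliberately does **not** emulate: linkage
disequilibrium and realistic minor-allele structure (summary statistics
are simulated directly), probe-level artefacts, batch effects,
non-Gaussian expression noise, gene-size and SNP-density confounding,
and overlapping pathway annotations.  Passing recovery tests therefore
demonstrate that the estimators are correct and calibrated under the
stated statistical structure, not that the pipeline is robust to every
failure mode of real microarray or GWAS data.

# Numerical choices

* Add-one correction (b + 1)/(n_perm + 1) for every permutation p, so
  p in [1/(n+1), 1] and never exactly 0.
* Half-up rounding for reported expected counts (base `round()` is
  banker's rounding and would print 2898 where convention prints 2899);
  tests and p-values always use raw counts.
* atanh clipping at |rho| = 1 − 1e-10 with a warning; degenerate pairs
  (constant genes) are skipped and logged, not silently zeroed.
* Inclusive (<=) comparisons at all significance boundaries; strict
  inequalities only in the reproducibility rule, which is defined that
  way.
* Ties in Pareto space: duplicated points are both efficient; the
  sweep handles tie blocks explicitly and is oracle-checked on rounded
  (tie-rich) instances.
* Deterministic interleaved fold assignment for cross-validation, so
  identical inputs give identical Q² regardless of RNG state.
* Degree bins with minimum occupancy 5 are merged into their
  neighbours; the merge is recorded in the result object.
* All generators derive their streams from the single config seed
  (offsets +0/+1/+2 for expression/GWAS/graph), so a config is one
  reproducible study.

# Problem sizes used by the test and acceptance suites

The suites are sized to demonstrate the properties at desk scale:
calibration runs use 20 simulated null studies (150 genes, 15 samples
per arm) and check all six permutation-test p-value families against
Uniform(0,1) by Kolmogorov–Smirnov at alpha = 0.01; recovery runs use
50 simulated studies at the default configuration and require the
planted pathway to top expression enrichment and be Pareto-selected in
>= 90% of studies, the planted GWAS pathway to be flagged in >= 90%,
crossing edges to be recovered exactly in all studies, and the planted
coordination disruption and protein response to be detected in >= 80%.
Permutation counts are 99–1000 per test.  These sizes were chosen so
each property is measured with meaningful Monte-Carlo resolution while
the whole suite stays comfortably runnable on a laptop.

# Known limitations

* The MAGENTA confounder regression is omitted (see above); on real
  data, gene-length bias must be kept in mind.
* GSEA with gene-label permutation ignores inter-gene correlation;
  strongly co-expressed null sets can reach extreme enrichment scores
  (the generator's co-expression block shows this on occasion).
  Phenotype permutation would address it at the cost of requiring the
  sample-level data at enrichment time.
* The Fisher-z variance 1/(n−3) is the Pearson form; for Spearman
  correlations it is mildly conservative (the Fieller correction would
  use ~1.06/(n−3)).  The null-calibration suite shows the resulting
  per-pair rate is slightly below nominal, which makes the binomial
  excess test conservative, not liberal.
* The binomial excess test treats pair-level tests as independent;
  overlapping pairs share genes, so the effective dispersion is larger
  than binomial.  The published analysis makes the same assumption;
  conclusions rest on effect sizes well beyond this correction.
* Wilks Λ requires more samples than responses and a non-singular
  residual SSCP; the out-of-sample Λ additionally needs every test fold
  to leave a well-conditioned total SSCP.  Errors advise reducing the
  response panel.
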