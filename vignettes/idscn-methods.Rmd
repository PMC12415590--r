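---
title: "Individualized differential structural covariance networks: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Individualized differential structural covariance networks: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(idscn)
```

## The model

A structural covariance network (SCN) describes coordinated anatomy: its
edges are correlations of a regional morphometric measure — here mean
gray-matter density per atlas region — computed *across subjects*. Because a
single subject has no correlation of their own, individualized inference
works by perturbation: given $n$ control subjects, the reference network
$rSCN$ is the matrix of pairwise partial correlations of the $n \times p$
region table, adjusting each region for sex, age, education and total
intracranial volume (TIV). Appending one patient's row and recomputing the
same network gives that patient's perturbed network $pSCN$. The patient's
individualized differential SCN is the edge-wise Z-score of the
perturbation,

$$Z_{ij} \;=\; \frac{pSCN_{ij} - rSCN_{ij}}{\left(1 - rSCN_{ij}^2\right)/(n-1)},$$

where the denominator is the sampling variance of a correlation around
$r_{ij}$ at sample size $n$ (the control count, not $n+1$). Two-tailed
p-values are taken from the standard normal, and each patient's
significantly altered edges are selected by Benjamini–Hochberg FDR at
$q = 0.05$ over the full universe of $p(p-1)/2$ edges (6670 for the
packaged 116-region atlas), each patient corrected separately.

Two points in this construction were genuinely open and are worth stating
as design choices:

* **The denominator.** We follow the source methodology for
  perturbation-based single-subject networks and use the *variance*
  $(1-r^2)/(n-1)$ without a square root. The square-root variant is
  selectable (`compute_idscn(..., denominator = "sd")`) for sensitivity
  analysis; it only rescales Z monotonically per edge, so edge rankings
  within an edge are unchanged but p-values are not.
* **Partial correlation** means pairwise Pearson correlation of the
  covariate-residualized region columns — adjusting the four covariates
  only, not the remaining regions. The patient's own covariates enter the
  $(n+1)$-subject residualization; excluding them would leave the
  patient's residual undefined.

## Downstream pipeline

**Edge ranking and features.** Cohort-level features are the top-$K$
(default 80) edges ranked by the number of patients in which the edge is
FDR-significant, with ties broken by mean $|Z|$ across patients and then
by canonical edge order, making the ranking total and reproducible. The
feature value is the *signed* Z (not $|Z|$, not a binary indicator):
differential edges come in two directional classes, and magnitude-only
features would collapse them. Both alternatives remain available
(`build_feature_matrix(..., value =)`).

**Subtyping.** k-means on the patients-by-$K$ feature matrix, restarted
100 times per candidate $k$ with the best-inertia solution kept, $k$
chosen from 2–20 by mean silhouette width (Euclidean, on the same feature
space; no standardization — Z-scores already share a scale). Labels are
relabeled canonically (cluster 1 = largest) so reports and agreement
indices are stable. Reproducibility across the feature-set size is
quantified by the adjusted Rand index (ARI) between solutions at
$K \in \{60, 70, 80, 90\}$.

**Inter-subtype comparison.** "Two-sample t-tests controlling for
covariates" is operationalized as the t-statistic of the group coefficient
in `edge_Z ~ intercept + subtype + sex + age + education + tiv`; with no
covariates this reduces exactly to the classical pooled two-sample t. BH
correction runs across the $K$ tested edges. The permutation validation
permutes subtype labels only (covariates fixed; full-model residual
permutation schemes are out of scope), recomputes the covariate-adjusted
$|t|$ each iteration, and uses the add-one estimator
$p = (1 + \#\{|t^\ast| \ge |t|\})/(B+1)$ so p-values are never zero.

**Demographics and subgroups.** Continuous variables dispatch on
Shapiro–Wilk normality in each group (both normal: pooled t; otherwise
Mann–Whitney U). Categorical variables use the Pearson chi-square without
continuity correction, switching to Fisher's exact test when any expected
cell count is below 5. The no-Yates default is confirmed by reproducing a
published sex-by-group table's p-value to the printed precision.
Continuous subgroup splits use `< median` versus `>= median`.

**Imaging–clinical associations.** Continuous outcomes use multivariate
linear regression, binary outcomes multivariate logistic regression, the
imaging feature(s) entering alongside the four covariates. Predictors with
VIF > 5 are excluded iteratively (largest first; ties drop the
later-listed predictor). Linear models with Shapiro–Wilk residual
non-normality at $\alpha = 0.05$ are discarded; logistic models are
discarded on non-convergence or separation. A model is retained for
interpretation only if an imaging feature reaches $p < 0.05$. Significant
differential edges enter one joint logistic/linear model (the subtype
indicator is always modelled separately); no multiplicity correction is
applied across the battery, matching the screening character of the
analysis.

## The synthetic cohort generator

The generator emulates the data structure this pipeline consumes, with
known ground truth:

* **Controls** (default 65) are multivariate normal: per-region mean
  structure, additive linear covariate effects, and correlated noise with
  a base correlation matrix. The base matrix comes from a stated recipe —
  eigenvectors from the QR decomposition of a Gaussian matrix, eigenvalues
  i.i.d. Exponential(1), rescaled to unit diagonal — yielding weak-to-
  moderate correlations. Default covariate loadings (age
  $\sim N(-0.0015, 5\times10^{-4})$ per year, sex $\sim N(0.01, 0.01)$,
  education $\sim N(8\times10^{-4}, 4\times10^{-4})$ per year, TIV
  $\sim N(6\times10^{-5}, 3\times10^{-5})$ per ml, against a regional
  noise SD of 0.05) give each covariate roughly 5–10% of regional
  variance — a realistic share for demographic drivers of gray-matter
  density, and enough that covariate-adjusted partial correlation
  demonstrably recovers the base structure better than raw Pearson
  correlation.
* **Patients** (default 55) are drawn from the covariance of their planted
  subtype: the base correlation with a signed perturbation $\delta$ added
  to a specified edge set, repaired to positive semi-definiteness by
  clipping negative eigenvalues at a small floor and rescaling to unit
  diagonal. The repair slightly shrinks the planted $\delta$; the realised
  per-edge change is recorded. The default plants two subtypes of 19 and
  36 patients perturbing a *shared* 40-edge set in *opposite* directions
  ($\pm 0.3$), mirroring the two directional classes of differential edges
  this kind of analysis reports and maximising the between-subtype
  contrast for a given $|\delta|$.
* **Clinical variables** are tied to the subtype by a shifted-mean model
  (headache frequency: $-1.5$ days/month for subtype 2, noise SD 2) and a
  shifted-log-odds model (headache occurrence: $+1.2$ log-odds for
  subtype 2), so the association stage has a recoverable signal with a
  known target. Untruncated Gaussian noise is an idealization: a small
  fraction of simulated frequencies can be negative, which we accept to
  keep coefficient recovery unbiased.

What the generator does **not** emulate: voxel-level images, scanner and
site effects, non-Gaussian morphometric distributions, mean shifts
(atrophy) in patients, and spatial autocorrelation between neighbouring
regions. Passing tests therefore validate the statistical machinery, not
the biological fidelity of any particular dataset.

## What a single subject can and cannot reveal: a power analysis

Two properties of the Z construction shape every downstream result, and
both are consequences of the published method itself, reproduced — not
introduced — by this package.

**The null Z is a product-normal, not a Gaussian.** For a patient
exchangeable with controls, the influence of one added row on a
correlation is $\Delta r \approx \mathrm{IF}/(n+1)$ with
$\mathrm{IF} = \tilde{x}_i\tilde{x}_j - r(\tilde{x}_i^2+\tilde{x}_j^2)/2$,
so $Z \approx \mathrm{IF}/(1-r^2)$ — unit variance, but with the heavier
tails of a product of normals. The normal conversion of Z to p is
therefore mildly anticonservative: the empirical rejection rate at nominal
0.05 is about 0.06–0.08, the Kolmogorov–Smirnov distance from the
standard normal is about 0.11 (our null-calibration check uses 0.15 as its
documented loose threshold, with 500 Monte-Carlo patients at 200
controls), and per-patient BH selects tens of edges even for null
patients, with strongly overdispersed counts across patients — a few
subjects with extreme regional values account for most selections. The
workflow's synthetic cohort reports roughly 120–140 ± 100–120
significantly altered edges per patient from this mechanism alone, so
large, heterogeneous per-patient edge counts should not by themselves be
read as evidence of individual pathology.

**A covariance perturbation of $\delta$ yields per-edge
$Z \sim N(\delta/(1-r^2),\, \approx 1)$.** Because one row moves the
cohort correlation by $O(\delta/n)$ and the Z denominator is
$O(1/n)$, the $n$'s cancel: the planted signal arrives at magnitude
$\approx \delta$, regardless of the control count. At $\delta = 0.3$ this
is far below the $|Z| \approx 4.5$ needed for per-patient FDR
significance among 6670 edges, so significance-frequency ranking cannot
locate the planted edges (recall@80 $\approx$ 5% in our simulations), the
top-80 features carry almost no subtype signal, and clustering agreement
with the planted labels is near zero — even though the planted-edge Z is
cleanly monotone in $\delta$ and planted edges are reliably *enriched*
among selected ones. Recovering subtypes from this construction requires
either much larger perturbations or patient-level mean shifts, which real
pathology may well provide but a pure covariance perturbation does not.
We report this limitation rather than inflating the generator's effect
size.

## Numerical choices

* Edge order is fixed row-major upper-triangle everywhere; flat vectors
  and matrices are interconvertible losslessly, and repeated runs are
  byte-identical given the seed.
* All randomness flows from one seed through named per-stage substreams
  (`stage_seed()`), so stages are individually reproducible.
* k-means uses 100 seeded restarts per $k$ (best inertia kept); the
  silhouette grid is truncated with a warning when it exceeds
  $n_\mathrm{patients}-1$; identical feature rows are a hard error.
* Edges with $|r| = 1$ carry no perturbation information; their Z is set
  to 0 with a warning.
* Permutation exceedance counts treat ties at floating-point resolution
  ($10^{-8}$ relative) as exceedances, so a zero observed statistic gets
  p = 1 rather than an arbitrary tie split.
* Cohort CSVs are written with 17 significant digits so read-back
  round-trips exactly.
* Problem sizes in the test suite and acceptance script (10 cohorts at
  the default 65/55/116 design; 500 null patients at 200 controls; 100
  oracle cohorts at 5 regions; permutation validation at B = 1000) were
  chosen to estimate each rate or agreement index with a standard error
  well below its acceptance margin.

## A worked example

```{r example, eval = FALSE}
library(idscn)
cohort <- simulate_cohort(sim_config(seed = 1))
built  <- build_cohort_idscns(cohort, q = 0.05)
summary_ <- cohort_heterogeneity_summary(built$idscns)
ranking  <- rank_edges(built$idscns)
features <- build_feature_matrix(built$idscns, ranking, K = 80)
subtypes <- cluster_patients(features, k_grid = 2:20, n_repeats = 100, seed = 1)
table(subtypes$labels)
```

The numbered scripts under `analysis/` run the same pipeline end to end
with a narrative of what each stage found, writing their tables under
`results/`.

## Known limitations

* The seven-area grouping shipped with the 116-region atlas is a
  documented convention; published area assignments vary, and users with a
  specific parcellation should supply their own atlas file.
* The association battery's logistic Wald intervals are first-order; at
  55 patients with an unbalanced binary outcome their coverage is
  approximate.
* The pipeline assumes complete data; rows with missing density or
  covariates must be handled upstream.
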