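---
title: "Methods: global-to-local multivariate facial-shape GWAS"
author: "facegwas"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: global-to-local multivariate facial-shape GWAS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(facegwas)
```

This vignette is the package's own account of its models, the choices
behind its defaults, and what its tests do and do not demonstrate.

## The phenotyping model

A subject's face is a configuration of L corresponding quasi-landmarks in
mm. Generalized Procrustes analysis removes nuisance variation:
configurations are centered, scaled to unit centroid size (the centroid
sizes are kept and later used as the "facial size" covariate), and
rotated — reflections disallowed — onto an iteratively refined consensus
until the consensus changes by less than `tol = 1e-8` RMS (cap 100
iterations). After convergence every shape is re-aligned once onto the
final consensus, so each aligned shape is in ordinary-Procrustes-optimal
position relative to the returned consensus; this exactness is what makes
the cross-cohort projection (below) reproduce in-sample scores to
machine precision. Scaling is applied once per configuration rather than
re-estimated every iteration; with shapes this concentrated the
difference is far below `tol` and the fixed-point property is cleaner.

Only the symmetric component of shape is analyzed: each configuration is
averaged with its relabeled mirror image. This assumes the aligned frame
shares the template's midline plane, which holds for data digitized
against a bilateral template (and for the generator by construction).

Outlier QC computes Mahalanobis distances in the PCA subspace holding
98% of aligned-shape variance — the covariance of a dense landmark set is
rank-deficient, so a full-space Mahalanobis distance does not exist; the
98% figure is our choice of metric subspace — and flags z > 2 for
inspection. The pipeline flags rather than auto-drops, since in practice
flagged scans are visually reviewed.

Covariate adjustment regresses every coordinate on an intercept, sex,
age, age², height, weight, centroid size, and (in the full pipeline) four
ancestry PCs; arbitrary extra covariates (e.g. an eye-state indicator)
enter through the same interface. Residuals are exactly orthogonal to the
design, and a rank-deficient design is an error that names the collinear
columns rather than a silent drop.

## Segmentation

Landmark co-variation is summarized by the RV coefficient between the
n×3 residual displacement blocks of each landmark pair — a rotation-
invariant 0–1 similarity. Each node of the hierarchy is split in two by
spectral bipartition: the sign pattern of the Fiedler vector of the
normalized graph Laplacian of the node's RV subgraph. Determinism is
enforced by fixing the eigenvector sign (largest-magnitude entry
positive) and assigning exact-zero entries to the smaller side. Five
rounds below the root give 2⁶ − 1 = 63 nested segments, numbered
breadth-first with the whole face as segment 1 at level 0. The method's
"data-derived" clustering is not uniquely pinned down in the literature
it descends from; RV + normalized-Laplacian bipartition is this package's
canonical choice, stated as such.

Each segment is then re-superimposed on its own landmarks and reduced by
PCA. The number of retained PCs comes from Horn's parallel analysis:
retain leading components whose eigenvalues exceed the 95th percentile of
eigenvalues from 100 column-permuted copies of the aligned data
(seeded; minimum one PC). Two caveats are worth knowing. First,
Procrustes alignment removes 7 of the 3|S| nominal dimensions, which
inflates real eigenvalues by ≈ 3|S|/(3|S|−7) relative to the permutation
null; for segments of ≳ 10 landmarks this sits inside the null
eigenvalue bulk, but on very small segments parallel analysis
over-retains on pure noise. Second, two-landmark segments have no shape
degrees of freedom at all after alignment and are rejected; templates
should be large enough that level-5 segments keep ≥ 3 landmarks (the
default 256-landmark template yields 4–16).

## Association, thresholds, loci

With a univariate predictor, canonical correlation reduces to the
multivariate regression of dosage on the k segment PCs: r² is the
regression R², the loading is the unit-norm coefficient vector (sign
fixed on its largest entry), and Rao's F approximation
F = (r²/k)/((1−r²)/(n−k−1)) on (k, n−k−1) df is exact, right tail. The
suite verifies this equivalence against `lm()`'s overall F test to
1e-10 on a thousand random instances. Covariates are removed from the
phenotypes beforehand (CCA cannot carry covariates); df₂ deliberately
does not subtract the covariate count, a conventional approximation that
is conservative in n. Subjects missing a dosage are dropped for that SNP
only; a zero-variance dosage yields a flagged record with p = 1 rather
than an error.

The genome-wide threshold defaults to 2.5×10⁻⁸ (appropriate for
African-ancestry LD); the study-wide threshold divides it by the Li–Ji
effective number of phenotypes, computed on the correlation matrix of
each segment's first PC score. Which per-segment summary enters Li–Ji is
genuinely open; the first PC is used because it is always defined and
dominates each segment's variance, and Meff is kept at its real value
rather than rounded. Loci are greedy p-ordered clumps with ±500 kb
windows; ties break by position then id.

## Replication T1–T5

T1 transports a source phenotype to a target cohort: the target's
covariate-adjusted segment landmarks are Procrustes-fitted
(translation, unit-size scaling, rotation — matching the source segment
superimposition; the Procrustes conventions of such projections are not
standardized, so consistency with the source GPA is the design rule)
onto the source segment consensus, expressed in source PCs, and
contracted with the source CCA loading. Projecting a cohort onto its own
model reproduces the in-sample canonical variate exactly; the
self-projection T1 p-value equals the discovery p for k = 1 and is
otherwise anti-conservative in-sample (it reuses the optimized loading
without paying its k degrees of freedom), which is why T1 is only
meaningful out-of-cohort. T2–T5 are look-ups with Bonferroni schemes
0.05/n_signals (/40 segments for the "best segment" tests; / local
Li–Ji SNP count for the locus tests, floored at 5×10⁻⁸). `n_signals` is
always an explicit argument — different analyses legitimately test
different signal counts (e.g. 20, 203 or 112). "Qualitatively similar"
segment matching is operationalized as maximum Dice overlap at equal
tree level, ties to the smaller id. The whole battery is one code path
run in either direction.

## Enrichment

20 kb half-open windows tile each chromosome (truncated terminal
window); read counts are per-window overlap counts (a boundary-spanning
read counts in every window it touches), scaled to RPM, and
quantile-normalized across samples (`limma::normalizeQuantiles`, ties
averaged — verified against a hand-worked example and idempotent). The
test windows are those containing lead SNPs (1-based positions converted
explicitly to the 0-based tiling); a ±20 kb neighbourhood variant can be
had by passing the flanking windows. The group comparison is a one-sided
Wilcoxon rank-sum on per-sample mean log10(x+1) signal: the original
analysis names neither test nor transform, and a rank test keeps the
p-value invariant to monotone joint rescalings.

## The synthetic generator: what it emulates and what it does not

Each subject's shape is template + covariate effects + hierarchical
latent variation + planted SNP displacements + isotropic Gaussian noise,
times a size factor. Key defaults, chosen once as plausible study
conditions:

* **Template**: 256 landmarks (a desk-scale stand-in for dense masks of
  thousands), mirror-symmetric half-ellipsoid with face-like axes, 32
  bilateral 8-landmark regions.
* **Latent hierarchy**: a balanced binary tree over regions; each node
  contributes a mirror-symmetric unit displacement field scaled by
  `level_sd = c(1.0, 1.0, 1.1, 1.2, 1.3, 1.4)` mm (global → local).
  Segmentation recovers structure through RV contrasts that scale as the
  *fourth* power of these amplitudes, so a strongly global-dominated
  profile hides the fine levels at moderate n; the default gives every
  level comparable amplitude with slightly stronger local integration
  (regionalized facial units), keeping all five levels identifiable at
  n ≈ 200.
* **Covariates**: ages 3–21 with height/weight tracking age; effects of
  0.15 mm/yr (age), −0.003 mm/yr² (age²), 1.2 mm (sex), 0.02 mm/unit
  (height, weight) along fixed global fields; 3% size spread.
* **Noise**: 0.3 mm isotropic per coordinate. Residual quasi-landmark
  noise after dense surface registration is not well characterized in
  the literature; this is a calibration choice, not an estimate.
* **Genotypes**: Balding–Nichols Beta divergence (closed-form variance
  fst·p(1−p), Monte-Carlo-checked); LD via a latent Gaussian AR(1)
  copula per haplotype. A literal allele-copying chain would distort
  marginal frequencies when adjacent SNPs differ in frequency; the
  copula preserves the Balding–Nichols marginals exactly, at the cost
  that the realized adjacent-genotype correlation is a dichotomization-
  attenuated transform of `ld_rho` rather than `ld_rho` itself. One
  chromosome, 5 kb spacing, so a ±500 kb locus holds ~200 SNPs.
* **Effect calibration**: `calibrate_beta()` solves for the displacement
  (mm/allele) at which a SNP explains a target fraction of its landmark
  set's total variance, from the generator's closed-form variance
  components (halving the noise term when the pipeline symmetrizes).
  "Fraction of segment variance" is the trace measure; because a planted
  effect is concentrated along one direction, the corresponding
  canonical R² is substantially larger, which is what powers the
  genome-wide detection checks. Planting effects along an existing
  latent field (`node_direction()`) guarantees the effect lies in the
  subspace parallel analysis retains.

What passing tests therefore show: the pipeline's operations are
internally correct (oracle equivalences), calibrated under a Gaussian,
linear, homoscedastic null, and powered against localized additive
effects embedded in a recoverable covariance hierarchy. What they do not
show: robustness to registration error, non-Gaussian shape variation,
missing landmarks, relatedness/cryptic structure beyond two diverged
populations, or genotype imputation artifacts — none of which the
generator attempts to mimic.

## Problem sizes and numerical choices

The test suite runs at deliberately modest sizes chosen to make each
statistical claim decidable: 64-landmark/120-subject fixtures for unit
behavior; n = 500 with 2,000 SNPs for null calibration of the scan
(α = 0.01, the binomial band [0.008, 0.012] is tight at this size —
roughly a ±2σ interval); 20 seeded replicates at n = 1,000 (2% segment
variance) for detection power and n = 800 pairs (3%) for T1
replication; 1,000/100 seeds for enrichment null/power. Parallel
analysis uses 100 permutations (30 or fewer in bulk fixtures where only
score geometry matters). Degenerate inputs are errors with specific
messages (all-coincident configurations, single-landmark segments,
rank-deficient designs, zero read counts), except where the field's
convention is a flagged result (zero-variance dosage → p = 1).

Known limitations, restated: symmetrization presumes template-frame
orientation; parallel analysis over-retains on tiny segments (Procrustes
rank deficiency); df₂ ignores the adjusted covariate count; the
segmentation and Li–Ji summary choices are canonical package decisions
where the literature leaves the construction open.
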