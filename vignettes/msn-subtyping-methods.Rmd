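---
title: "Methods: MSN subtyping and imaging transcriptomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: MSN subtyping and imaging transcriptomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msnsubtype)
```

# The pipeline

`msnsubtype` implements a complete analysis chain for case-control structural
neuroimaging cohorts:

1. **Morphometric similarity networks (MSN).** Each subject contributes a
   region x feature table (surface area, cortical thickness, gray matter
   volume, Gaussian curvature, mean curvature). Features are z-normalized
   across regions (sample SD, ddof = 1 -- the divisor is a package choice,
   as either convention cancels in the correlation), and the MSN edge
   between two regions is the Pearson correlation of their 5-feature
   profiles. No thresholding is applied anywhere. A region's *strength* is
   its mean edge weight; the global strength is the mean over regions.
2. **HYDRA subtyping.** Patients are clustered by *how they differ from
   controls*: K linear max-margin classifiers (the faces of a convex
   polytope) jointly separate controls from patients, each patient is
   assigned to the face giving it the largest margin, and face membership
   defines the subtype. Model order is selected by cross-validated
   stability: the K maximizing the mean pairwise adjusted Rand index of
   assignments across leave-one-fold-out refits.
3. **Case-control statistics.** Per region, OLS of strength on
   [intercept, group, age, sex, TIV]; two-sided t on the group coefficient,
   Bonferroni across regions. The same model serves global strength and
   network-aggregated (Yeo-7 / von Economo) strengths.
4. **Imaging transcriptomics.** AHBA-style preprocessing produces a
   left-hemisphere region x gene matrix (probe filtering, homogeneity-based
   collapse, 2 mm sample assignment, scaled-robust-sigmoid normalization).
   PLS1 links expression to the case-control t-map; inference uses spatial
   (spin) permutations and bootstrap gene Z scores; downstream screens
   relate the resulting gene lists to disease gene sets, cross-disorder
   differential expression, and cell-type marker sets (ssGSEA).

# HYDRA: objective and numerical choices

The objective minimized is

$$\sum_{j=1}^{K}\Big[\tfrac12\lVert w_j\rVert^2
 + C\sum_{i\in\text{controls}}\tfrac1K\,\max(0,\,1 + w_j^\top x_i + b_j)
 + C\sum_{i\in\text{patients}} s_{ij}\,\max(0,\,1 - w_j^\top x_i - b_j)\Big]$$

with hard assignments $s_{ij}\in\{0,1\}$, $\sum_j s_{ij}=1$, by
block-coordinate descent: (a) each face is refit as a weighted soft-margin
linear classifier given the assignments; (b) each patient is reassigned.
Defaults follow the reference analysis: `C = 0.25`, 50 alternations,
consensus over 20 seeded initializations, tenfold cross-validation for the
stability scan over K = 2..10.

Choices a maintainer should know about:

* **Assignment tie-break.** Any face whose raw margin for a patient exceeds
  1 contributes zero hinge loss, so step (b) determines the assignment only
  up to ties. Resolving ties by the raw margin $w_j^\top x + b_j$
  systematically favours the face with the largest $\lVert w\rVert$ and
  empirically collapses all patients onto one face. We therefore pick among
  the hinge-minimizing faces the one with the largest *geometric* signed
  distance $(w_j^\top x + b_j)/\lVert w_j\rVert$ -- the same rule as the
  original formulation of the method. Descent remains exact, so the
  objective trace is non-increasing.
* **Face solver.** Each face's weighted soft-margin problem is solved
  exactly by dual coordinate descent in compiled code (liblinear-style),
  with the intercept handled through an augmented constant feature of value
  10 (a penalized intercept, as in `LinearSVC`; the induced penalty
  $(b/10)^2/2$ is reported as part of the objective so the trace is
  monotone by construction). Convergence tolerance is 1e-4 on the maximal
  projected gradient, capped at 300 passes. A pure-R Huber-smoothed primal
  solver is kept in the package purely as an independent reference for the
  test suite.
* **Initialization.** k-means++ seeds are drawn in the space of patients'
  *deviation directions*: each patient row minus the control mean, whitened
  by the shrunk control covariance (shrinkage 0.2 of the mean diagonal),
  and length-normalized. Whitening downweights variance the controls share
  (e.g. a global strength factor); normalization leaves only the direction
  of departure from the control cloud, which is what the polytope faces
  discriminate. Seeding on raw high-dimensional rows makes initializations
  noise-driven and the alternation stalls in mixed fixed points; the
  optimization itself is unchanged by this choice.
* **Empty faces** are repaired by reseeding with the patient whose best
  margin is worst. A repair forcibly moves a patient, so descent is not
  guaranteed across a repair step; repairs are logged per alternation, and
  an objective-plateau rule (3 stalled alternations) stops repair-induced
  cycling. The 50-alternation limit remains the hard cap.
* **Input features.** Regional strengths are residualized on age, sex, and
  TIV, with coefficients estimated in controls only (consistent with the
  later case-control model), then column-z-scored inside `hydra_fit`
  (`standardize = TRUE`, exposed as a flag since the reference analysis
  does not state it).
* **Stability pairing.** The single stability value per K is the mean ARI
  over all 45 fold-pair comparisons, computed on the patients common to
  both training sets (fold-vs-fold; the alternative fold-vs-full pairing is
  not used).

# The synthetic world

The generator emulates the statistical structure the analyses assume, not
raw MRI. Everything is a pure function of (configuration, seed) and the
planted truth is returned alongside the data.

* **Baseline profiles.** In z-space each region's 5-feature profile is
  `alignment(region) * u + struct_noise * noise`, with `u` a fixed unit
  vector and `struct_noise = 0.35`. The alignment field is a *skewed*
  smooth function of the anterior-posterior coordinate
  (`zscore(-exp(1.3 z))`). The skew matters: per-subject z-normalization
  removes the mean profile, and with a symmetric alignment distribution the
  mean unit-profile direction is null, leaving regional strength almost
  unresponsive to planted perturbations. The skew (many mildly aligned
  regions, few strongly anti-aligned) keeps that direction nonzero, so
  strength responds monotonically to a region's alignment -- the mechanism
  the subtype effects exploit.
* **Covariates.** Age, sex, and TIV shift profiles along `u` with distinct
  smooth regional susceptibility patterns (effect sizes 0.3 / 0.2 / 0.3
  baseline SD). A spatially uniform covariate shift would be absorbed by
  z-normalization, which is why the generator gives each covariate a
  regional pattern. Sex is coded M = 0 / F = 1 (column `sex01`).
* **Subtype effects** (`paper_default_config`): 106 controls, 100 patients
  split 53/47 into two subtypes. Each subtype shifts one 48-region set down
  and a disjoint 48-region set up by 2.5 baseline SD; subtype 2 carries the
  mirrored signs. The two sets interleave the mid-range ranks of the
  alignment field, where strength responds most steeply; rank-interleaving
  matches their baseline distributions so the between-subtype contrast is
  decorrelated from the cohort's global strength factor. The mirrored
  design reproduces the reference phenomenon of the two subtypes' t-maps
  being approximately inverse. Because strength is a bounded correlation
  summary, arbitrarily large feature effects do *not* yield arbitrarily
  clean separation -- magnitudes were chosen once (with subject noise
  `noise_sd = 0.35`) so that recovery is strong but not degenerate, and are
  part of the stated configuration, not tunable by the analysis code.
* **Expression.** Planted genes follow `beta * standardized(target map)`
  plus a spatially correlated field with exponential angular covariance
  (`exp(-angle / 0.3)`), the simplest stationary model that makes spin
  tests meaningful; null genes are pure field. Cell-type sets draw planted
  genes at configurable odds (odds 1 reduces to hypergeometric overlap);
  DGE tables set `log2FC = a * loading + noise`.
* **What a green test does not establish.** The generator has no
  scanner/site effects, no motion artefacts, no real cortical geometry
  (each hemisphere is a Fibonacci lattice on its own sphere, the natural
  coordinate system for spin tests), no donor structure in expression, and
  subject noise is i.i.d. across regions and features. Recovery results
  calibrate the pipeline's internal consistency, not its performance on
  real cohorts.

# Inference details

* **Spin test.** Uniformly random 3D rotations of the (single-hemisphere)
  centroid sphere; each region is relabelled by its nearest rotated
  centroid, and the nearest-neighbour map is repaired to a bijection by
  greedy global matching whenever rotations create duplicates, so every
  null map is a true permutation of the observed values. Two-sided p on
  |Spearman rho| with the add-one estimator `(1 + #{|null| >= |obs|}) /
  (n_rot + 1)`.
* **PLS1** is fitted in closed form: for a univariate response the first
  PLS weight vector is the normalized covariance vector `X'y` (genes
  z-scored first -- required for cross-gene weight comparability), scores
  are `Xw`, explained variance is the squared score-response correlation,
  and the sign convention makes that correlation non-negative. The
  permutation null for the association defaults to spin (shuffle retained
  for calibration tests); bootstrap gene Z scores resample regions with
  replacement, re-standardize, sign-align each replicate to the original
  weights, and report `Z = w / SE` with strict |Z| > 5 list thresholds.
* **ssGSEA.** Rank-weighted running sum with exponent `alpha = 0.25`; raw
  regional scores are reported (a z-normalization flag exists, default
  off). The reference text mentions a "Gaussian" kernel, which belongs to
  the GSVA scoring method rather than ssGSEA; the standard ssGSEA form is
  implemented.
* **Degenerate inputs** raise errors naming the offending unit:
  zero-variance features, constant region profiles, zero IQR in SRS,
  constant maps in spin tests, gene sets covering the whole matrix. DGE
  overlaps below 5 genes are flagged rather than tested, mirroring the
  reference handling of sparse overlaps.

# Known limitations

* HYDRA's alternation is a local method; with weak planted structure
  different seeds can disagree (the consensus step and the stability scan
  are the guardrails, as in the reference analysis).
* The spin-test bijection repair is greedy, not optimal matching; for
  quasi-uniform lattices the difference is negligible.
* Expression preprocessing pools samples per region (single-donor
  reading); multi-donor normalize-then-average workflows are out of scope.
* The quadrant decomposition and trajectory fits are descriptive tools; no
  inference is attached to them beyond what the tests assert.
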