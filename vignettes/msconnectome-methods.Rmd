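---
title: "Network analysis of structural disconnection and morphometric similarity from conventional MRI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Network analysis of structural disconnection and morphometric similarity from conventional MRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msconnectome)
```

## Scope

`msconnectome` implements a complete conventional-MRI network pipeline for
multiple sclerosis (MS) cohorts: atlas-based structural disconnectomes
computed from binary lesion masks, cortical morphometric similarity networks
built from vertex-level surface features, network-based statistics (NBS)
with permutation family-wise error (FWE) control — cross-sectionally with
general linear models and longitudinally with linear mixed models —
connectome-based prediction of long-term confirmed disability progression
(CDP), and multi-scale coupling between the two network domains.  Because
real MRI cohorts of this kind cannot be redistributed, the package ships a
synthetic cohort generator that emulates every input (parcellation,
normative streamline atlas, lesion masks, vertex features, clinical
records) with plantable subnetwork effects, so the full pipeline is testable
end-to-end from code alone.

## Structural disconnectomes

A subject's structural disconnectome is defined on a fixed gray-matter
parcellation (by default 100 cortical + 14 subcortical regions, giving
114 × 114 matrices) and a normative streamline atlas in the same voxel
space.  For each structurally connected region pair, the disconnection value
is the proportion of that pair's streamlines that intersect the subject's
lesion mask.  Implementation choices:

* **Exact voxel traversal.** Streamline–lesion intersection uses
  Amanatides–Woo segment traversal of each polyline, not point sampling, so
  the traversed voxel set is exact and resolution-independent.  Polyline
  points live in continuous voxel space with 0-based voxel indices; a point
  exactly on a voxel boundary belongs to the higher-index voxel.
* **Binary transection.** A streamline counts as transected when at least
  one traversed voxel is lesioned.  No minimum-overlap criterion is applied;
  this is the natural reading of "proportion of streamlines intersecting
  lesions" and partial-overlap weighting is out of scope.
* **Undefined pairs.** Pairs that carry no atlas streamlines are flagged in
  a structural mask and excluded from all edge statistics (disconnection is
  only defined between structurally connected regions).

Group-level lesion and disconnection probability maps are voxel-wise means
of, respectively, the binary masks and the per-subject indicator of "any
transected streamline passes here".  Total lesion volume (TLV) is voxel
count × voxel volume, log(1 + x)-transformed for analysis because its
distribution is strongly right-skewed.

## Morphometric similarity (MIND)

Morphometric similarity between two cortical regions is computed from their
multivariate distributions of vertex-level features (cortical thickness, GM
volume, surface area, mean curvature, sulcal depth; exactly five features).
Features are standardized to pooled mean 0 / SD 1 across all vertices, each
region's vertices form a 5-D point cloud, and the similarity is

\[ s(i, j) = \frac{1}{1 + D_{KL}(i \| j) + D_{KL}(j \| i)} \in (0, 1], \]

where each divergence is a k-nearest-neighbour estimate computed from
ratios of within-cloud to cross-cloud kth-neighbour distances.  Choices:

* **k = 3 neighbours** by default: the usual bias/variance compromise for
  k-NN divergence estimation with tens-to-hundreds of vertices per region
  (configurable).
* **Clamping.** The raw estimator can go slightly negative; each direction
  is clamped at 0 before the transform, which guarantees \(s \le 1\).
* **Symmetry and diagonal.** The symmetrized divergence makes
  \(s(i,j) = s(j,i)\) exact by construction; the diagonal is set to 0 and
  excluded from all statistics (self-similarity is uninformative).
* Subcortical regions are excluded by construction — the method is defined
  on cortical surface features only.

The estimator is verified against closed-form Gaussian KL divergences: for
unit-variance Gaussian clouds at mean offset \(\delta\), the estimated
similarity tracks \(1/(1+\delta^2)\) within 10% at n = 5000 points.

## Network-based statistics

NBS controls family-wise error over edges by clustering in topological
space: (1) each edge is tested with a GLM; (2) edges with \(p\) strictly
below the primary threshold (default 0.01) are retained; (3) connected
components are extracted among suprathreshold edges; (4) each component's
statistic sum is referred to the permutation distribution of the maximum
component sum, giving \(p_{FWE}\) with the add-one rule
\((1 + \#\{\max^{(b)} \ge s\})/(B + 1)\).

* **Nuisance covariates** (baseline age, age², sex; optionally log(1+TLV)
  or BPF z-scores) are handled with Freedman–Lane residual permutation:
  residuals of the nuisance-only fit are permuted, the nuisance fit is
  added back, and the full model is refitted.  The scheme is standard best
  practice for permutation inference with covariates.
* **Sign-split components.** The primary threshold is two-sided and
  components are formed separately among positively and negatively signed
  edges, so subnetworks of increased and decreased connectivity are
  reported as distinct findings.  The component statistic is the sum of
  absolute edge t-values, consistent with the sign split.
* **Thresholding on p-values** (equivalent to a fixed t threshold at the
  model's degrees of freedom); strict inequality survives.

### Longitudinal models

Longitudinal change is tested edge-wise with linear mixed models: edge value
against follow-up time plus nuisance covariates, with a random intercept
and a random slope of time per subject.  Fits use REML with the
random-effect covariance profiled out through its Cholesky factor and
optimized by Nelder–Mead; the per-subject sufficient statistics make one
objective evaluation O(#subjects).  The reported statistic is the Wald t
for the time effect with \(n - p\) degrees of freedom (a normal-type
approximation; Satterthwaite corrections are deliberately out of scope).
When an edge's slope variance collapses to the boundary the fit falls back
to a random-intercept-only model and is flagged.  Fits agree with
`lme4::lmer` REML estimates to at least four significant digits on matched
problems; `lme4` serves only as a cross-check, never as the edge-wise
engine.  The permutation unit for longitudinal NBS is the subject:
within-subject time-centred trajectories are sign-flipped per subject,
preserving within-subject exchangeability under the null of no systematic
change.  Nuisance columns are standardized internally so that collinear
covariates (age and age²) keep the normal equations well conditioned.

## Prediction of confirmed disability progression

CDP is an EDSS increase of ≥ 1 point (baseline EDSS ≤ 5.5) or ≥ 0.5 points
(baseline EDSS > 5.5) at long-term follow-up, thresholds inclusive.
`run_nbs_predict()` embeds NBS-style feature selection in nested,
stratified, repeated cross-validation:

* per outer training fold: scaling and linear deconfounding parameters are
  estimated on the training data only and applied to the held-out fold
  (cross-validated deconfounding — no leakage);
* features are the edges of the largest connected component among
  suprathreshold edges of an edge-wise GLM on the class label (an
  "all components" option exists);
* the inner CV picks classifier and hyperparameters among logistic
  regression, linear SVM, and LDA by accuracy.  The hyperparameter search
  is a seeded random search over the same ranges a surrogate-model
  (Bayesian) optimizer would explore, with a configurable evaluation
  budget — at these problem sizes random search is budget-equivalent and
  keeps runs deterministic;
* accuracy is averaged over folds and repeats; the 95% CI is the
  2.5/97.5 percentile interval of repeat-level mean accuracies;
  sensitivity and specificity are pooled over held-out predictions; class
  assignment uses the 0.5 threshold; class imbalance is handled by
  stratification only;
* significance comes from label-permutation reruns (reduced repeats per
  permutation, documented in `predict_config()`), with the add-one p-value.

Training folds with no suprathreshold edges fall back to a majority-class
constant classifier and are counted in the output.  When a class is too
small for the requested inner split the inner fold count shrinks (with the
same constant-classifier fallback at the floor).

## Clinical summaries and coupling

Subnetworks that change over time are summarized per subject as the mean
of absolute edge z-scores relative to the healthy-population reference
(per-edge HC mean and SD), so effects of opposite sign cannot cancel.
Annualized change is computed between each subject's first and last visit
(a regression-slope option exists); associations with annualized EDSS
change use Spearman rank correlation, and partial Spearman (rank-residual
method) re-assesses them controlling for change in log(1+TLV) or BPF
z-scores.  Brain parenchymal fraction (brain volume / intracranial volume)
is expressed as z-scores against a linear age + sex model fitted on healthy
controls.  SDMT z-scores are inverted (higher = worse) for directional
consistency with EDSS.  Group comparisons use Welch's t test — computable
directly from printed mean/SD/n summaries with Satterthwaite degrees of
freedom — and Pearson's χ² without continuity correction.

Coupling between disconnection and similarity is computed over shared
cortical nodes at three scales: across subjects (global means), across
edges (group-mean matrices), and per region (row-profile correlations,
self-pairs excluded), with an option to exclude structurally absent and
zero-disconnection edges, and a median split on disease duration (median
subject assigned to the shorter-duration group).

## The synthetic cohort generator

The generator is a first-class, tested module.  It emulates:

* **Geometry.** An ellipsoidal "brain" on a 40 × 48 × 40 grid of 2 mm
  voxels: cortical regions as Voronoi cells of well-spaced seeds on an
  outer shell, subcortical regions around the centre, a ventricle proxy at
  the grid centre, and a white-matter corridor in between.  Every region is
  nonempty and 6-connected; cortical nodes are assigned to the seven
  canonical functional systems by azimuthal sector, subcortical nodes to
  SUBC.
* **Atlas.** A seeded random fraction of region pairs is connected; each
  connected pair carries a fixed number of streamlines jittering around the
  straight corridor between the regions.
* **Lesions.** Poisson counts scaled by a subject severity, centres biased
  towards the ventricle proxy (density \(\propto e^{-\beta d}\)),
  spherical, restricted to non-GM voxels so disconnection acts only through
  streamline transection; a Poisson process of new lesions makes masks
  nested over visits.
* **Planted disconnection effects.** Planted edges receive additional
  "corridor plug" lesions placed on corridor voxels that are traversed by
  the planted pair's own streamlines and, where possible, by no other
  pair's — keeping the planted transection focal so that recovery
  experiments measure the statistics, not corridor crowding.  Effects can
  be cross-sectional (carrier patients), progressive (a per-year Poisson
  rate), and tied to the subject's latent disability slope.
* **Vertex features.** Region-specific 5-D Gaussian templates shared across
  subjects, with a fixed template cloud, per-subject mean shifts, and
  planted similarity effects that move one endpoint's distribution towards
  (similarity increase) or away from (decrease) its partner's mean.
* **Clinical records.** EDSS on the 0–10 half-point grid through a latent
  baseline + slope + noise link, rounded half-up (matching the clinical
  granularity) and clipped; inverted SDMT z-scores; brain volumes with
  patient atrophy and a per-year z-scored BPF drift (default −0.095/year);
  long-term (5–17 year) follow-up EDSS with a stable-course subgroup, from
  which CDP labels are computed with the package's own rule; `cdp_effect`
  couples CDP odds to the baseline planted-component disconnection score.

Seeding is hierarchical: a single configuration seed derives per-subject,
per-stream seeds, so any subject's data are reproducible independently of
cohort size, and identical configuration + seed gives bit-identical output.

Generator defaults were fixed once, before the statistical experiments, to
the cohort conditions the package targets: baseline age 37.2 ± 10.6 years
in patients vs 42.4 ± 15.7 in controls, ~70% vs ~45% female, disease
duration 9.1 ± 7.9 years, baseline EDSS median ≈ 2.5, latent EDSS slope
0.084/year, BPF z drift −0.095/year, long-term CDP rate ≈ 45%.  Planted
effect sizes default to 2 expected corridor plugs per edge (baseline),
0.6 per year (progression) and a −0.5 relative mean shift (similarity).

**What the generator does not emulate** — and hence what passing tests do
not show about real data: realistic cortical folding and topology, scanner
noise and acquisition differences, registration error, relapse dynamics,
treatment effects, spatially realistic lesion shapes, and the anatomical
specificity of any real cohort's subnetworks.  Tests demonstrate that the
statistical machinery is calibrated and recovers known effects under the
generator's assumptions, not that any particular anatomical finding would
replicate.

## Numerical choices and degenerate inputs

* Permutation p-values always respect the add-one lower bound
  \(1/(B+1)\); doubling permutations never changes observed components.
* All-zero nuisance columns are dropped, making the "empty adjustment"
  identical to the unadjusted analysis; any other rank deficiency is an
  error.
* Edges with zero variance produce undefined edge statistics and can never
  become suprathreshold.
* k-NN divergences guard zero distances (coincident points contribute no
  evidence) and clamp at zero.
* Zero-SD reference edges are excluded from z-score summaries with a
  warning; an all-excluded component yields `NA`.
* EDSS values are validated against the half-point grid; off-grid input is
  an error, and generated EDSS uses round-half-up.

## Problem sizes used by the test-suite

The suite verifies calibration and recovery at sizes chosen to give stable
Monte-Carlo estimates while keeping a full run on one CPU comfortable:
FWE calibration on 200 global-null cohorts (n = 60, 200 edges,
200 permutations); cross-sectional recovery of a planted 10-edge component
in 100 cohorts of 120 patients on a 24-node geometry; longitudinal recovery
on 8 cohorts of 40 patients × 3 visits; mixed-model bias/coverage over
100 scalar and 25 × 20 edge-wise replicates; prediction calibration over
8 shuffled-label runs of n = 200.  The 24-node recovery geometry (half of
all pairs connected) is used because focal planted transection needs
corridor voxels unique to a pair, which the full 114-node atlas on a
compact grid cannot provide — corridor crowding there is a resolution
artifact, not a property of the statistics under test.

## Known limitations

* The disconnectome is atlas-based; individual tractography is out of
  scope, as are probabilistic tract-density weights and lesion filling or
  registration (inputs are assumed co-registered).
* Edge-wise LMM inference uses the normal-type Wald approximation; degrees
  of freedom are not Satterthwaite-corrected.
* The prediction module covers binary outcomes only; no probability
  calibration or regression targets.
* Whether the annualized structural-disconnection measure should be the
  z-summary change per year (implemented as primary) or the raw
  mean-disconnection change per year is ambiguous in the field; both can
  be computed and are labelled explicitly.
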