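# msconnectome

Structural disconnection and morphometric similarity networks from
conventional MRI in multiple sclerosis, with the statistics to analyze
them.

## The problem

Brain network analyses in multiple sclerosis (MS) usually require advanced
MRI (diffusion tractography, functional imaging) that clinical protocols
rarely include.  Two network constructions need only conventional images:

* **Structural disconnectomes** — a subject's binary lesion mask is
  intersected with a normative streamline atlas; for every structurally
  connected pair of gray-matter regions, the edge value is the proportion
  of that pair's streamlines transected by lesions, filling a node × node
  matrix (by default 114 regions: 100 cortical + 14 subcortical).
* **Morphometric similarity (MIND) networks** — each cortical region's
  vertices form a multivariate distribution over five surface features
  (thickness, GM volume, surface area, mean curvature, sulcal depth);
  similarity between regions i and j is
  `s(i,j) = 1 / (1 + D(i‖j) + D(j‖i))` with `D` a k-nearest-neighbour
  estimate of the Kullback–Leibler divergence, giving values in (0, 1].

On top of these containers the package implements the network-based
statistic (NBS): edge-wise general linear models (cross-sectional) or
linear mixed models with random intercept and slope per subject
(longitudinal), a primary threshold (p < 0.01), connected suprathreshold
components, and component-level family-wise-error control from the
permutation distribution of the maximum component statistic sum
(Freedman–Lane residual permutation under nuisance covariates; subject-level
sign-flips for longitudinal models).  `run_nbs_predict()` embeds the same
component feature selection inside nested, stratified, repeated
cross-validation with cross-validated deconfounding to predict long-term
confirmed disability progression (CDP: EDSS increase ≥ 1 if baseline
EDSS ≤ 5.5, ≥ 0.5 otherwise).  Clinical summaries (absolute z-score
subnetwork scores against a healthy reference, annualized-change Spearman
and partial correlations, Welch/χ² group tests, BPF z-scores) and
multi-scale disconnection–similarity coupling complete the pipeline.

Because cohorts of this kind cannot be shared, a fully seeded synthetic
cohort generator (parcellation, streamline atlas, lesion masks, vertex
features, clinical records, plantable subnetwork effects) makes every stage
testable end-to-end without any real MRI.  See the methods vignette
(`vignettes/msconnectome-methods.Rmd`) for the model details and design
decisions.

## Worked example

```r
library(msconnectome)

pe  <- default_planted_edges(24, hub = 3L)        # a 10-edge subnetwork
cfg <- sim_config(n_patients = 120, n_controls = 0,
                  n_cortical = 20, n_subcortical = 4,
                  connected_pair_fraction = 0.5,
                  visits_per_subject = c(1, 1), seed = 7001,
                  planted_disconnection_component =
                    list(edges = pe, carrier_fraction = 0.5))
co   <- simulate_cohort(cfg, compute_mind = FALSE)
base <- co$cohort[co$cohort$visit == 1, ]
st   <- stack_conn_matrices(co$disconnection[sprintf("%s_v1", base$subject)])
carr <- co$subjects$carrier_disc[match(base$subject, co$subjects$subject)]

res <- nbs_glm(st$Y, make_design(data.frame(g = as.integer(carr)), "g"),
               p_primary = 0.01, n_perm = 200, seed = 3,
               pairs = st$pairs, n_nodes = 24)
res
#> <nbs_result (glm): 1 component(s), 200 permutations>
#>   #1: 10 edges, stat sum 90.21, sign +1, p_fwe = 0.004975
```

The detected component contains exactly the 10 planted edges; its
statistic sum is the sum of absolute edge t-values, and
`p_fwe = (1 + 0) / (200 + 1)` says no permutation produced a larger
component.  Group comparisons work straight from printed summary
statistics:

```r
welch_t_summary(42.4, 15.7, 55, 37.2, 10.6, 461)$p   # age, HC vs patients
#> [1] 0.01989963
chisq_counts(matrix(c(25, 324, 30, 137), 2))$p       # sex distribution
#> [1] 0.0001993925
```

`run_pipeline(config, out_dir, seed)` executes the whole chain from one
configuration (simulation, matrices, probability maps, NBS analyses,
mixed-model slopes, summaries, coupling, CDP prediction) and writes every
output plus a `report.json`; identical config + seed reproduces every file
bit for bit.

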