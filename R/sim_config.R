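#' Synthetic cohort configuration
#'
#' Collects every knob of the synthetic data generator: geometry of the shared
#' voxel grid and parcellation, streamline atlas density, lesion model,
#' vertex-feature model, planted subnetwork effects, and the clinical
#' trajectory model.  Identical configuration plus seed yields bit-identical
#' outputs.
#'
#' @param n_patients,n_controls cohort sizes.
#' @param n_cortical,n_subcortical number of cortical / subcortical regions
#'   (defaults 100 and 14, giving the usual 114-node parcellation).
#' @param grid_shape voxel grid dimensions (default 40 x 48 x 40).
#' @param voxel_size isotropic voxel edge in mm (default 2).
#' @param streamlines_per_pair streamlines carried by each connected pair.
#' @param connected_pair_fraction fraction of node pairs that are structurally
#'   connected in the atlas.
#' @param vertices_per_region vertices drawn per cortical region (>= 50).
#' @param n_features number of vertex features (fixed at 5: cortical
#'   thickness, GM volume, surface area, mean curvature, sulcal depth).
#' @param lesion_rate expected lesion count per patient at severity 0.
#' @param lesion_radius_range lesion radius range in mm.
#' @param periventricular_bias nonnegative weight of the exponential density
#'   pulling lesion centres towards the ventricle proxy (per mm).
#' @param new_lesion_rate expected new lesions per follow-up year.
#' @param planted_disconnection_component `NULL` or a list with `edges`
#'   (two-column node index matrix), `effect` (expected planted corridor
#'   lesions per edge per carrier), `carrier_fraction` (fraction of patients
#'   carrying the effect) and `progression` (additional expected planted
#'   lesions per edge per follow-up year).
#' @param planted_similarity_component `NULL` or a list with `edges`,
#'   `effect` (signed; positive moves the first endpoint's feature
#'   distribution towards the second, increasing similarity; negative moves
#'   it away) and `progression` (per-year increment of the same shift).
#' @param visits_per_subject range (min, max) of MRI visits per patient.
#' @param followup_years range of total imaging follow-up in years.
#' @param edss_slope_mean,edss_slope_sd per-year latent EDSS slope
#'   distribution (default mean 0.084).
#' @param bpf_slope_mean per-year drift of the z-scored brain parenchymal
#'   fraction in patients (default -0.095).
#' @param cdp_effect log-odds of an extra long-term progression event per
#'   standard deviation of the baseline planted-component disconnection score.
#' @param seed integer master seed.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n_patients = 120, n_controls = 60,
                       n_cortical = 100, n_subcortical = 14,
                       grid_shape = c(40L, 48L, 40L), voxel_size = 2,
                       streamlines_per_pair = 8,
                       connected_pair_fraction = 0.25,
                       vertices_per_region = 60, n_features = 5L,
                       lesion_rate = 8, lesion_radius_range = c(2, 6),
                       periventricular_bias = 0.12,
                       new_lesion_rate = 0.6,
                       planted_disconnection_component = NULL,
                       planted_similarity_component = NULL,
                       visits_per_subject = c(2L, 4L),
                       followup_years = c(1, 6),
                       edss_slope_mean = 0.084, edss_slope_sd = 0.06,
                       bpf_slope_mean = -0.095,
                       cdp_effect = 1.0, seed = 1L) {
  counts <- c(n_patients = n_patients, n_controls = n_controls,
              n_cortical = n_cortical, n_subcortical = n_subcortical,
              vertices_per_region = vertices_per_region,
              n_features = n_features)
  if (any(counts < 0)) stop("counts must be nonnegative")
  if (n_cortical < 1) stop("need at least one cortical region")
  if (n_features != 5L) stop("the feature set is fixed at 5 features")
  if (connected_pair_fraction < 0 || connected_pair_fraction > 1)
    stop("connected_pair_fraction must lie in [0, 1]")
  if (periventricular_bias < 0) stop("periventricular_bias must be >= 0")
  if (length(grid_shape) != 3) stop("grid_shape must have 3 dimensions")
  if (streamlines_per_pair < 0) stop("streamlines_per_pair must be >= 0")
  n_nodes <- n_cortical + n_subcortical
  for (comp in list(planted_disconnection_component,
                    planted_similarity_component)) {
    if (!is.null(comp)) {
      if (is.null(comp$edges))
        stop("planted components need an `edges` matrix")
      if (any(comp$edges < 1) || any(comp$edges > n_nodes))
        stop("planted edges reference invalid node ids")
    }
  }
  cfg <- list(n_patients = as.integer(n_patients),
              n_controls = as.integer(n_controls),
              n_cortical = as.integer(n_cortical),
              n_subcortical = as.integer(n_subcortical),
              grid_shape = as.integer(grid_shape), voxel_size = voxel_size,
              streamlines_per_pair = as.integer(streamlines_per_pair),
              connected_pair_fraction = connected_pair_fraction,
              vertices_per_region = as.integer(vertices_per_region),
              n_features = as.integer(n_features),
              lesion_rate = lesion_rate,
              lesion_radius_range = lesion_radius_range,
              periventricular_bias = periventricular_bias,
              new_lesion_rate = new_lesion_rate,
              planted_disconnection_component =
                normalize_planted(planted_disconnection_component),
              planted_similarity_component =
                normalize_planted(planted_similarity_component,
                                  similarity = TRUE),
              visits_per_subject = as.integer(visits_per_subject),
              followup_years = followup_years,
              edss_slope_mean = edss_slope_mean,
              edss_slope_sd = edss_slope_sd,
              bpf_slope_mean = bpf_slope_mean,
              cdp_effect = cdp_effect, seed = as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}

# Default effect sizes: 2 expected corridor-plug lesions per planted edge
# (baseline disconnection), 0.6 per follow-up year (progression when
# requested), and a -0.5 mean shift away from the partner region
# (similarity disruption).
normalize_planted <- function(comp, similarity = FALSE) {
  if (is.null(comp)) return(NULL)
  edges <- matrix(as.integer(comp$edges), ncol = 2)
  edges <- t(apply(edges, 1, function(e) if (similarity) e else sort(e)))
  list(edges = edges,
       effect = comp$effect %||% (if (similarity) -0.5 else 2),
       carrier_fraction = comp$carrier_fraction %||% 1,
       progression = comp$progression %||% 0)
}

#' Default planted disconnection component
#'
#' A 10-edge connected subgraph (a star plus a short chain around one hub
#' node) among cortical regions, used as the default planted effect in
#' recovery experiments.
#'
#' @param n_nodes number of nodes in the parcellation.
#' @param hub hub node index.
#' @return two-column edge index matrix.
#' @export
default_planted_edges <- function(n_nodes = 114, hub = 5L) {
  others <- setdiff(seq(2, n_nodes, by = max(1L, n_nodes %/% 12L)), hub)[1:7]
  star <- cbind(hub, others)
  chain <- cbind(others[c(1, 2, 3)], others[c(2, 3, 4)])
  edges <- rbind(star, chain)[1:10, , drop = FALSE]
  t(apply(edges, 1, sort))
}
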