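#' Simulate vertex-level morphometric features
#'
#' Each cortical region has a template 5-D Gaussian (cortical thickness, GM
#' volume, surface area, mean curvature, sulcal depth) shared across
#' subjects: a fixed template vertex cloud is drawn once from it (seeded by
#' the configuration seed only).  A subject's cloud is the template cloud
#' plus a subject-specific random mean shift (`subject_noise_sd`; zero gives
#' the template exactly) and, for patients carrying a planted similarity
#' effect, a shift of the first endpoint's distribution along the line
#' towards (positive effect, similarity increase) or away from (negative
#' effect, similarity decrease) the second endpoint's template mean.
#'
#' @param parc parcellation (provides cortical region ids).
#' @param cfg the [sim_config].
#' @param subject_id integer id seeding the subject stream.
#' @param group `"control"` or `"patient"`.
#' @param carrier does this patient carry the planted similarity effect?
#' @param followup_time years since baseline (scales the planted
#'   `progression` term).
#' @param subject_noise_sd standard deviation of the per-region subject mean
#'   shift (standardized feature units).
#' @return object of class `vertex_features`: list with `features` (named
#'   list of `vertices_per_region x 5` matrices, cortical regions only) and
#'   `region_ids`.
#' @export
make_vertex_features <- function(parc, cfg, subject_id = 1L,
                                 group = c("patient", "control"),
                                 carrier = TRUE, followup_time = 0,
                                 subject_noise_sd = 0.15) {
  group <- match.arg(group)
  if (cfg$vertices_per_region < 2) stop("degenerate distribution: need >= 2 vertices per region")
  n_ctx <- cfg$n_cortical
  tpl <- feature_template(cfg)
  nv <- cfg$vertices_per_region
  nf <- cfg$n_features
  feats <- vector("list", n_ctx)
  shift <- matrix(0, n_ctx, nf)
  ps <- cfg$planted_similarity_component
  if (group == "patient" && carrier && !is.null(ps)) {
    eff <- ps$effect + ps$progression * followup_time
    for (e in seq_len(nrow(ps$edges))) {
      a <- ps$edges[e, 1]; b <- ps$edges[e, 2]
      if (a > n_ctx || b > n_ctx) next # similarity is cortical-only
      shift[a, ] <- shift[a, ] + eff * (tpl$means[b, ] - tpl$means[a, ])
    }
  }
  with_seed(derive_seed(cfg$seed, subject_id, "features"), {
    subj_shift <- matrix(rnorm(n_ctx * nf, sd = subject_noise_sd), n_ctx, nf)
    for (r in seq_len(n_ctx)) {
      feats[[r]] <- tpl$clouds[[r]] +
        matrix(subj_shift[r, ] + shift[r, ], nv, nf, byrow = TRUE)
    }
  })
  names(feats) <- parc$node_table$name[seq_len(n_ctx)]
  structure(list(features = feats,
                 region_ids = parc$node_table$id[seq_len(n_ctx)]),
            class = "vertex_features")
}

# Region-level template means, scales and a fixed template vertex cloud,
# identical across subjects (depends only on the configuration seed and
# geometry).  Cached per call chain via a small environment.
feature_template <- local({
  cache <- new.env(parent = emptyenv())
  function(cfg) {
    key <- paste(cfg$seed, cfg$n_cortical, cfg$vertices_per_region, sep = "_")
    if (!is.null(cache[[key]])) return(cache[[key]])
    nf <- cfg$n_features
    n_ctx <- cfg$n_cortical
    nv <- cfg$vertices_per_region
    tpl <- with_seed(derive_seed(cfg$seed, "feature_template"), {
      means <- matrix(rnorm(n_ctx * nf, sd = 1), n_ctx, nf)
      sds <- matrix(runif(n_ctx * nf, 0.6, 1.4), n_ctx, nf)
      clouds <- lapply(seq_len(n_ctx), function(r) {
        matrix(rnorm(nv * nf), nv, nf) * matrix(sds[r, ], nv, nf, byrow = TRUE) +
          matrix(means[r, ], nv, nf, byrow = TRUE)
      })
      list(means = means, sds = sds, clouds = clouds)
    })
    cache[[key]] <- tpl
    tpl
  }
})
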