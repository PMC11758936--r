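#' Lesion mask container
#'
#' @param data binary 3D array (0/1).
#' @param voxel_size isotropic voxel edge in mm.
#' @param space_tag identifier of the shared grid.
#' @return object of class `lesion_mask`.
#' @export
lesion_mask <- function(data, voxel_size, space_tag) {
  if (!all(data %in% c(0L, 1L))) stop("lesion mask must be binary")
  structure(list(data = data, voxel_size = voxel_size,
                 space_tag = space_tag, grid_shape = dim(data)),
            class = "lesion_mask")
}

#' Simulate a subject's lesion mask
#'
#' Lesion count follows Poisson(`lesion_rate * (1 + severity)`) at baseline
#' plus a Poisson process of new lesions over follow-up time; centres are
#' sampled among non-GM voxels with density proportional to
#' `exp(-periventricular_bias * distance to the ventricle proxy)`; each lesion
#' is a sphere with radius uniform in `lesion_radius_range`, restricted to
#' non-GM voxels so that disconnection arises only through streamline
#' transection.  If the subject carries a planted disconnection component,
#' additional small lesions are placed on the streamline corridors of the
#' planted edges (expected `effect` per edge at baseline, plus a
#' `progression`-rate Poisson process over follow-up).  Masks are nested over
#' visits and reproducible per (subject id, seed).
#'
#' @param severity nonnegative lesion-load severity multiplier.
#' @param parc parcellation from [make_parcellation].
#' @param cfg the [sim_config].
#' @param subject_id integer subject identifier (seeds the subject stream).
#' @param followup_time years since baseline for this visit.
#' @param carrier does this subject carry the planted disconnection effect?
#' @param atlas streamline atlas (required when a planted component with a
#'   carrier subject is requested).
#' @param prog_multiplier subject-level multiplier on the planted
#'   progression rate (used to tie planted progressive disconnection to the
#'   subject's latent disability slope).
#' @return a [lesion_mask].
#' @export
make_lesions <- function(severity, parc, cfg, subject_id = 1L,
                         followup_time = 0, carrier = FALSE, atlas = NULL,
                         prog_multiplier = 1) {
  if (severity < 0) stop("severity must be nonnegative")
  d <- parc$grid_shape
  mask <- logical(prod(d))
  w <- exp(-cfg$periventricular_bias * parc$lesionable_dist_mm)
  tmax <- max(cfg$followup_years[2], followup_time)

  with_seed(derive_seed(cfg$seed, subject_id, "lesions"), {
    n0 <- rpois(1, cfg$lesion_rate * (1 + severity))
    # homogeneous Poisson process of new lesions; events up to followup_time
    n_new_total <- rpois(1, cfg$new_lesion_rate * (1 + severity) * tmax)
    t_new <- if (n_new_total > 0) runif(n_new_total, 0, tmax) else numeric(0)
    n_total <- n0 + n_new_total
    centers <- radii <- NULL
    if (n_total > 0) {
      centers <- sample(parc$lesionable, n_total, replace = TRUE, prob = w)
      radii <- runif(n_total, cfg$lesion_radius_range[1],
                     cfg$lesion_radius_range[2])
    }
    active <- c(rep(TRUE, n0), t_new <= followup_time)
    if (n_total > 0 && any(active)) {
      for (i in which(active)) {
        mask[sphere_voxels(centers[i], radii[i], parc)] <- TRUE
      }
    }
    pd <- cfg$planted_disconnection_component
    if (carrier && !is.null(pd) && (pd$effect > 0 || pd$progression > 0)) {
      if (is.null(atlas)) stop("planted disconnection lesions need the atlas")
      n_nodes <- nrow(parc$node_table)
      for (e in seq_len(nrow(pd$edges))) {
        n_base <- rpois(1, pd$effect)
        n_prog_total <- rpois(1, pd$progression * prog_multiplier * tmax)
        t_prog <- if (n_prog_total > 0) runif(n_prog_total, 0, tmax)
          else numeric(0)
        ps <- atlas$planted_sites[[e]]
        if (is.null(ps) || !length(ps$sites)) next
        # coordinates of the pair's own corridor voxels
        ov <- ps$own_vox
        i0 <- ov - 1L
        oxyz <- cbind(i0 %% d[1], (i0 %/% d[1]) %% d[2], i0 %/% (d[1] * d[2]))
        for (l in seq_len(n_base + n_prog_total)) {
          # draw placement unconditionally so masks stay nested across visits
          lin <- ps$sites[sample.int(length(ps$sites), 1)]
          window <- runif(1, 2.5, 4.5) # voxels along the corridor
          keep <- l <= n_base || t_prog[l - n_base] <= followup_time
          if (!keep) next
          # corridor plug: the pair's own (preferably pair-exclusive)
          # streamline voxels within the window around the site
          c0 <- lin - 1L
          cx <- c0 %% d[1]; cy <- (c0 %/% d[1]) %% d[2]; cz <- c0 %/% (d[1] * d[2])
          near <- which((oxyz[, 1] - cx)^2 + (oxyz[, 2] - cy)^2 +
                          (oxyz[, 3] - cz)^2 <= window^2)
          mask[ov[near]] <- TRUE
        }
      }
    }
  })
  lesion_mask(array(as.integer(mask), dim = d), parc$voxel_size,
              parc$space_tag)
}

match_pair <- function(pairs, edge) {
  edge <- sort(edge)
  which(pairs[, 1] == edge[1] & pairs[, 2] == edge[2])[1]
}

# Voxels (flat indices) within `radius_mm` of the centre voxel's centre,
# optionally restricted to lesionable (non-GM) voxels.
sphere_voxels <- function(center_lin, radius_mm, parc, restrict = TRUE) {
  d <- parc$grid_shape
  vs <- parc$voxel_size
  r_vox <- radius_mm / vs
  i0 <- center_lin - 1L
  cx <- i0 %% d[1]; cy <- (i0 %/% d[1]) %% d[2]; cz <- i0 %/% (d[1] * d[2])
  rng <- function(c0, dm) max(0, floor(c0 - r_vox)):min(dm - 1, ceiling(c0 + r_vox))
  xs <- rng(cx, d[1]); ys <- rng(cy, d[2]); zs <- rng(cz, d[3])
  g <- expand.grid(x = xs, y = ys, z = zs)
  keep <- (g$x - cx)^2 + (g$y - cy)^2 + (g$z - cz)^2 <= r_vox^2
  lin <- 1L + g$x[keep] + d[1] * (g$y[keep] + d[2] * g$z[keep])
  if (restrict) lin[lin %in% parc$lesionable] else lin
}
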