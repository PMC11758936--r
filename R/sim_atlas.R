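#' Synthetic streamline atlas
#'
#' Stands in for a normative tractography atlas: a seeded random subset of
#' region pairs is declared structurally connected, and each connected pair
#' carries exactly `streamlines_per_pair` polylines that start inside one
#' endpoint region, end inside the other, and jitter around the straight
#' corridor between them.  Edges of a planted disconnection component are
#' always included among the connected pairs so planted effects have a
#' substrate.  Streamline voxel traversals are precomputed and cached.
#'
#' @param parc a [make_parcellation] result.
#' @param cfg the [sim_config] used to build `parc`.
#' @return object of class `streamline_atlas` with `streamlines` (list of
#'   `list(pair, points)`), `pairs` (connected pair matrix), `pair_counts`
#'   (node x node integer matrix), cached `voxels` (0-based flat indices per
#'   streamline), `pair_index`, and grid metadata.
#' @export
make_streamline_atlas <- function(parc, cfg) {
  stopifnot(inherits(parc, "parcellation"))
  d <- parc$grid_shape
  n_nodes <- nrow(parc$node_table)
  all_pairs <- upper_tri_pairs(n_nodes)
  labels_flat <- as.integer(parc$labels)
  region_vox <- split(seq_along(labels_flat), factor(labels_flat,
                                                     levels = seq_len(n_nodes)))
  if (any(lengths(region_vox) == 0)) stop("endpoint region empty")

  with_seed(derive_seed(cfg$seed, "atlas"), {
    n_sel <- round(cfg$connected_pair_fraction * nrow(all_pairs))
    sel <- sort(sample.int(nrow(all_pairs), n_sel))
    pairs <- all_pairs[sel, , drop = FALSE]
    pd <- cfg$planted_disconnection_component
    if (!is.null(pd)) {
      key <- function(p) (p[, 1] - 1) * n_nodes + p[, 2]
      miss <- !(key(pd$edges) %in% key(pairs))
      if (any(miss)) pairs <- rbind(pairs, pd$edges[miss, , drop = FALSE])
      pairs <- pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
    }
    spp <- cfg$streamlines_per_pair
    streamlines <- vector("list", nrow(pairs) * spp)
    pair_index <- integer(length(streamlines))
    k <- 0L
    vox_center <- function(lin) {
      i0 <- lin - 1L
      cbind(i0 %% d[1], (i0 %/% d[1]) %% d[2], i0 %/% (d[1] * d[2])) + 0.5
    }
    for (pr in seq_len(nrow(pairs))) {
      i <- pairs[pr, 1]; j <- pairs[pr, 2]
      vi <- region_vox[[i]]; vj <- region_vox[[j]]
      for (s in seq_len(spp)) {
        a <- vox_center(vi[sample.int(length(vi), 1)]) +
          runif(3, -0.35, 0.35)
        b <- vox_center(vj[sample.int(length(vj), 1)]) +
          runif(3, -0.35, 0.35)
        len <- sqrt(sum((b - a)^2))
        n_inner <- max(1L, as.integer(round(len / 4)))
        tfrac <- seq_len(n_inner) / (n_inner + 1)
        inner <- outer(tfrac, as.vector(b - a)) +
          matrix(a, n_inner, 3, byrow = TRUE)
        # corridor jitter, tapered towards the endpoints
        taper <- sqrt(tfrac * (1 - tfrac)) * 2
        inner <- inner + matrix(rnorm(3 * n_inner, sd = 0.9), n_inner, 3) * taper
        pts <- rbind(a, inner, b)
        pts <- cbind(clip(pts[, 1], 1e-3, d[1] - 1e-3),
                     clip(pts[, 2], 1e-3, d[2] - 1e-3),
                     clip(pts[, 3], 1e-3, d[3] - 1e-3))
        k <- k + 1L
        streamlines[[k]] <- list(pair = c(i, j), points = pts)
        pair_index[k] <- pr
      }
    }
    length(streamlines) <- k
    pair_index <- pair_index[seq_len(k)]
    pair_counts <- matrix(0L, n_nodes, n_nodes)
    if (k > 0) {
      for (pr in seq_len(nrow(pairs))) {
        pair_counts[pairs[pr, 1], pairs[pr, 2]] <- spp
        pair_counts[pairs[pr, 2], pairs[pr, 1]] <- spp
      }
    }
    voxels <- if (k > 0)
      voxelize_polylines_cpp(lapply(streamlines, `[[`, "points"), d)
    else list()
    vox_flat <- unlist(voxels) + 1L
    vox_sl <- rep(seq_along(voxels), lengths(voxels))
    # candidate lesion sites for planted edges: corridor voxels traversed by
    # many of the pair's own streamlines but few other pairs, so planted
    # transection stays focal
    planted_sites <- NULL
    if (!is.null(pd) && k > 0) {
      planted_sites <- vector("list", nrow(pd$edges))
      vox_pair <- pair_index[vox_sl]
      for (e in seq_len(nrow(pd$edges))) {
        pr <- match_pair(pairs, pd$edges[e, ])
        sel_own <- vox_pair == pr
        own <- table(vox_flat[sel_own])
        cand <- as.integer(names(own))
        idx <- which(vox_flat %in% cand & vox_pair != pr)
        cross_key <- unique(paste(vox_flat[idx], vox_pair[idx]))
        cross_vox <- as.integer(sub(" .*", "", cross_key))
        cross <- table(factor(cross_vox, levels = cand))
        excl <- cand[as.numeric(cross) == 0]
        if (length(excl) >= 5) {
          # corridor voxels traversed by no other pair: planted transection
          # stays perfectly focal
          planted_sites[[e]] <- list(sites = excl, own_vox = excl)
        } else {
          score <- as.numeric(own) - 1.5 * as.numeric(cross)
          keep <- cand[score >= quantile(score, 0.8)]
          planted_sites[[e]] <- list(
            sites = if (length(keep)) keep else cand, own_vox = cand)
        }
      }
    }
    structure(list(streamlines = streamlines,
                   vox_flat = vox_flat,
                   vox_sl = vox_sl,
                   planted_sites = planted_sites,
                   pairs = if (spp > 0) pairs else all_pairs[0, , drop = FALSE],
                   pair_counts = pair_counts, pair_index = pair_index,
                   voxels = voxels, grid_shape = d,
                   voxel_size = parc$voxel_size, space_tag = parc$space_tag),
              class = "streamline_atlas")
  })
}

#' @export
print.streamline_atlas <- function(x, ...) {
  cat(sprintf("<streamline_atlas: %d streamlines over %d connected pairs>\n",
              length(x$streamlines), nrow(x$pairs)))
  invisible(x)
}
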