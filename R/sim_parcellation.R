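#' Synthetic brain parcellation
#'
#' Builds a label volume on the shared voxel grid hosting `n_cortical`
#' cortical regions (Voronoi cells of well-spaced seeds on an ellipsoidal
#' shell) and `n_subcortical` subcortical regions (Voronoi cells of central
#' seeds), with a ventricle proxy reserved at the grid centre and a white
#' matter corridor left as background between the subcortical zone and the
#' cortical shell.  Every region is nonempty and contiguous
#' (6-connectivity); background carries label 0.  Cortical nodes are assigned
#' to the 7 canonical functional systems by azimuthal sector; subcortical
#' nodes to the system `SUBC`.
#'
#' @param cfg a [sim_config].
#' @return list of class `parcellation` with elements `labels` (3D integer
#'   array), `node_table` (data.frame: id, name, system), `centroids`
#'   (continuous 0-based voxel coordinates, one row per region), `grid_shape`,
#'   `voxel_size`, `space_tag`, plus internal geometry fields used by the
#'   lesion generator.
#' @export
make_parcellation <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  d <- cfg$grid_shape
  n_ctx <- cfg$n_cortical
  n_sub <- cfg$n_subcortical
  n_nodes <- n_ctx + n_sub

  # voxel centres in continuous 0-based voxel space
  gx <- seq_len(d[1]) - 0.5
  gy <- seq_len(d[2]) - 0.5
  gz <- seq_len(d[3]) - 0.5
  ctr <- d / 2
  R <- 0.45 * d
  X <- (rep(gx, times = d[2] * d[3]) - ctr[1]) / R[1]
  Y <- (rep(rep(gy, each = d[1]), times = d[3]) - ctr[2]) / R[2]
  Z <- (rep(gz, each = d[1] * d[2]) - ctr[3]) / R[3]
  r <- sqrt(X^2 + Y^2 + Z^2)

  shell <- r >= 0.72 & r <= 1.0
  subzone <- r > 0.14 & r <= 0.34
  ventricle <- r <= 0.14
  if (sum(shell) < 4 * n_ctx || (n_sub > 0 && sum(subzone) < 4 * n_sub))
    stop("grid too small to host the requested regions")

  fib <- function(n) {
    i <- seq_len(n) - 0.5
    z <- 1 - 2 * i / n
    phi <- (seq_len(n) - 1) * (pi * (3 - sqrt(5)))
    s <- sqrt(pmax(0, 1 - z^2))
    cbind(s * cos(phi), s * sin(phi), z)
  }
  seeds_ctx <- fib(n_ctx) * 0.86
  labels_flat <- integer(length(r))
  # nearest-seed assignment in normalized ellipsoid space
  assign_zone <- function(zone_idx, seeds, offset) {
    P <- cbind(X[zone_idx], Y[zone_idx], Z[zone_idx])
    d2 <- outer(rowSums(P^2), rowSums(seeds^2), "+") - 2 * P %*% t(seeds)
    offset + max.col(-d2)
  }
  labels_flat[shell] <- assign_zone(which(shell), seeds_ctx, 0L)
  if (n_sub > 0) {
    seeds_sub <- fib(n_sub) * 0.24
    labels_flat[subzone] <- assign_zone(which(subzone), seeds_sub, n_ctx)
  }
  labels_flat <- repair_contiguity(labels_flat, d, n_nodes)

  counts <- tabulate(labels_flat, n_nodes)
  if (any(counts == 0))
    stop("grid too small to host the requested regions (empty region)")

  # centroids in continuous 0-based voxel coordinates
  vx <- rep(gx, times = d[2] * d[3])
  vy <- rep(rep(gy, each = d[1]), times = d[3])
  vz <- rep(gz, each = d[1] * d[2])
  centroids <- cbind(
    tapply(vx, factor(labels_flat, levels = seq_len(n_nodes)), mean),
    tapply(vy, factor(labels_flat, levels = seq_len(n_nodes)), mean),
    tapply(vz, factor(labels_flat, levels = seq_len(n_nodes)), mean))

  systems7 <- c("VIS", "SM", "DAN", "VAN", "limbic", "CONT", "DMN")
  az <- atan2(seeds_ctx[, 2], seeds_ctx[, 1])
  sector <- ceiling(rank(az, ties.method = "first") * 7 / n_ctx)
  sys_ctx <- systems7[pmin(pmax(sector, 1L), 7L)]
  node_table <- data.frame(
    id = seq_len(n_nodes),
    name = c(sprintf("CTX_%03d", seq_len(n_ctx)),
             if (n_sub > 0) sprintf("SUBC_%02d", seq_len(n_sub))),
    system = c(sys_ctx, rep("SUBC", n_sub)),
    stringsAsFactors = FALSE)

  lesionable <- labels_flat == 0L & r <= 1.0
  dist_mm <- sqrt(((vx - ctr[1]))^2 + ((vy - ctr[2]))^2 +
                  ((vz - ctr[3]))^2) * cfg$voxel_size

  structure(list(labels = array(labels_flat, dim = d),
                 node_table = node_table, centroids = unname(centroids),
                 grid_shape = d, voxel_size = cfg$voxel_size,
                 space_tag = paste0("simgrid-", paste(d, collapse = "x"),
                                    "-", cfg$voxel_size, "mm"),
                 lesionable = which(lesionable),
                 lesionable_dist_mm = dist_mm[lesionable],
                 voxel_centers = cbind(vx, vy, vz),
                 ventricle = which(ventricle)),
            class = "parcellation")
}

# 6-connectivity neighbour offsets in flat indexing, with face guards.
flat_neighbors <- function(idx, d) {
  nxy <- d[1] * d[2]
  i0 <- idx - 1L
  x <- i0 %% d[1]
  y <- (i0 %/% d[1]) %% d[2]
  z <- i0 %/% nxy
  out <- cbind(ifelse(x > 0, idx - 1L, NA),
               ifelse(x < d[1] - 1, idx + 1L, NA),
               ifelse(y > 0, idx - d[1], NA),
               ifelse(y < d[2] - 1, idx + d[1], NA),
               ifelse(z > 0, idx - nxy, NA),
               ifelse(z < d[3] - 1, idx + nxy, NA))
  out
}

# Reassign voxels outside each label's largest 6-connected component to the
# dominant neighbouring label; a few sweeps suffice for Voronoi cells.
repair_contiguity <- function(labels_flat, d, n_nodes) {
  for (sweep in 1:6) {
    idx <- which(labels_flat > 0L)
    comp <- label_components(idx, d, labels_flat)
    lab <- labels_flat[idx]
    main_comp <- tapply(comp, lab, function(cs) {
      tt <- table(cs); as.integer(names(tt))[which.max(tt)]
    })
    stray <- idx[comp != main_comp[as.character(lab)]]
    if (!length(stray)) break
    nb <- flat_neighbors(stray, d)
    changed <- FALSE
    for (row in seq_along(stray)) {
      nl <- labels_flat[na.omit(nb[row, ])]
      nl <- nl[nl != labels_flat[stray[row]] & nl != 0]
      if (length(nl)) {
        labels_flat[stray[row]] <- as.integer(names(
          sort(table(nl), decreasing = TRUE))[1])
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  labels_flat
}

# Connected components (6-connectivity) of a voxel index set, optionally
# refusing to cross label boundaries; one igraph call over the whole set.
label_components <- function(idx, d, labels_flat = NULL) {
  n <- length(idx)
  if (n == 0) return(integer(0))
  pos <- integer(prod(d))
  pos[idx] <- seq_len(n)
  nxy <- d[1] * d[2]
  i0 <- idx - 1L
  x <- i0 %% d[1]; y <- (i0 %/% d[1]) %% d[2]; z <- i0 %/% nxy
  from <- to <- integer(0)
  for (k in 1:3) {
    off <- c(1L, d[1], nxy)[k]
    ok <- switch(k, x < d[1] - 1, y < d[2] - 1, z < d[3] - 1)
    a <- idx[ok]; b <- a + off
    keep <- pos[b] > 0L
    if (!is.null(labels_flat))
      keep <- keep & labels_flat[b] == labels_flat[a]
    from <- c(from, pos[a[keep]]); to <- c(to, pos[b[keep]])
  }
  gr <- igraph::graph_from_edgelist(cbind(from, to), directed = FALSE)
  if (igraph::vcount(gr) < n) gr <- igraph::add_vertices(gr, n - igraph::vcount(gr))
  as.integer(igraph::components(gr)$membership)
}

# TRUE iff the voxel index set is 6-connected.
is_contiguous <- function(idx, d) {
  if (length(idx) <= 1) return(TRUE)
  max(label_components(idx, d)) == 1
}
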