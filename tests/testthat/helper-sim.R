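# Shared fixtures and independent oracles, built in code.

# Compact cohort geometry used across tests: 20 cortical + 4 subcortical
# regions, half of all pairs connected.
small_cfg <- function(seed = 1, ...) {
  sim_config(n_cortical = 20, n_subcortical = 4,
             connected_pair_fraction = 0.5, seed = seed, ...)
}

edge_key <- function(pairs, n) (pmin(pairs[, 1], pairs[, 2]) - 1) * n +
  pmax(pairs[, 1], pairs[, 2])

edge_jaccard <- function(detected, planted, n_nodes) {
  kd <- edge_key(detected, n_nodes)
  kp <- edge_key(planted, n_nodes)
  length(intersect(kd, kp)) / length(union(kd, kp))
}

toy_node_table <- function(n) {
  data.frame(id = seq_len(n), name = sprintf("R%02d", seq_len(n)),
             system = rep(c("VIS", "SM", "DAN", "VAN", "limbic", "CONT",
                            "DMN"), length.out = n))
}

# Hand-built streamline atlas from a list of list(pair =, points =).
toy_atlas <- function(streamlines, grid_shape, voxel_size = 1,
                      space_tag = "toy") {
  n_nodes <- if (length(streamlines))
    max(vapply(streamlines, function(s) max(s$pair), 0)) else 0
  pair_counts <- matrix(0L, n_nodes, n_nodes)
  keys <- vapply(streamlines, function(s)
    paste(sort(s$pair), collapse = "_"), "")
  upairs <- unique(keys)
  pair_index <- match(keys, upairs)
  pairs <- do.call(rbind, lapply(strsplit(upairs, "_"), as.integer))
  for (s in streamlines) {
    i <- min(s$pair); j <- max(s$pair)
    pair_counts[i, j] <- pair_counts[i, j] + 1L
    pair_counts[j, i] <- pair_counts[i, j]
  }
  atlas <- structure(list(streamlines = streamlines, pairs = pairs,
                          pair_counts = pair_counts, pair_index = pair_index,
                          grid_shape = as.integer(grid_shape),
                          voxel_size = voxel_size, space_tag = space_tag),
                     class = "streamline_atlas")
  msconnectome:::atlas_cache(atlas)
}

toy_mask <- function(grid_shape, lesioned = integer(0), voxel_size = 1,
                     space_tag = "toy") {
  m <- array(0L, dim = grid_shape)
  m[lesioned] <- 1L
  lesion_mask(m, voxel_size, space_tag)
}

# Independent oracle for streamline voxel traversal: exhaustive per-voxel
# slab-interval test over each segment's bounding box (backed up by dense
# 0.01-voxel point sampling for the interior of the traversal, which the
# slab scan strictly contains).
dense_voxels <- function(points, grid_shape) {
  vox <- integer(0)
  for (s in seq_len(max(1, nrow(points) - 1))) {
    a <- points[min(s, nrow(points)), ]
    b <- points[min(s + 1, nrow(points)), ]
    # endpoint voxels always count
    vox <- c(vox, 1L + floor(a[1]) + grid_shape[1] *
               (floor(a[2]) + grid_shape[2] * floor(a[3])),
             1L + floor(b[1]) + grid_shape[1] *
               (floor(b[2]) + grid_shape[2] * floor(b[3])))
    d <- b - a
    bb <- expand.grid(x = floor(min(a[1], b[1])):floor(max(a[1], b[1])),
                      y = floor(min(a[2], b[2])):floor(max(a[2], b[2])),
                      z = floor(min(a[3], b[3])):floor(max(a[3], b[3])))
    tE <- rep(0, nrow(bb)); tX <- rep(1, nrow(bb))
    ok <- rep(TRUE, nrow(bb))
    for (c in 1:3) {
      lo <- bb[[c]]; hi <- lo + 1
      if (abs(d[c]) < 1e-14) {
        ok <- ok & a[c] >= lo & a[c] < hi
      } else {
        t1 <- (lo - a[c]) / d[c]; t2 <- (hi - a[c]) / d[c]
        tE <- pmax(tE, pmin(t1, t2)); tX <- pmin(tX, pmax(t1, t2))
      }
    }
    hit <- ok & (tX - tE > 1e-12)
    vox <- c(vox, 1L + bb$x[hit] + grid_shape[1] *
               (bb$y[hit] + grid_shape[2] * bb$z[hit]))
  }
  unique(vox)
}

brute_disconnection <- function(mask, atlas, node_table) {
  n <- nrow(node_table)
  vals <- matrix(0, n, n)
  mflat <- as.logical(mask$data)
  for (pr in seq_len(nrow(atlas$pairs))) {
    sel <- which(atlas$pair_index == pr)
    hit <- vapply(sel, function(k) {
      any(mflat[dense_voxels(atlas$streamlines[[k]]$points,
                             atlas$grid_shape)])
    }, TRUE)
    i <- atlas$pairs[pr, 1]; j <- atlas$pairs[pr, 2]
    vals[i, j] <- vals[j, i] <- mean(hit)
  }
  vals
}

# Union-find oracle for connected components over an edge list.
uf_components <- function(pairs, n_nodes) {
  parent <- seq_len(n_nodes)
  find <- function(x) {
    while (parent[x] != x) x <- parent[x]
    x
  }
  for (r in seq_len(nrow(pairs))) {
    a <- find(pairs[r, 1]); b <- find(pairs[r, 2])
    if (a != b) parent[a] <- b
  }
  vapply(seq_len(n_nodes), find, 0L)
}

# Random edge-level cohort for NBS-level tests (no imaging).
random_edges <- function(n, n_edges, seed) {
  set.seed(seed)
  matrix(rnorm(n * n_edges), n, n_edges)
}
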