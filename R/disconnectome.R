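#' Voxels traversed by a streamline polyline
#'
#' Exact Amanatides-Woo segment traversal of a polyline through the voxel
#' grid: the result contains every voxel any segment passes through, in
#' first-traversal order.  Points live in continuous voxel space with 0-based
#' voxel indices; a point exactly on a voxel boundary belongs to the
#' higher-index voxel.
#'
#' @param polyline numeric matrix (points x 3) in continuous voxel space.
#' @param grid_shape integer grid dimensions.
#' @return integer matrix (voxels x 3) of 0-based voxel indices.
#' @export
voxelize_streamline <- function(polyline, grid_shape) {
  polyline <- matrix(as.numeric(polyline), ncol = 3)
  lin <- voxelize_polyline_cpp(polyline, as.integer(grid_shape))
  cbind(lin %% grid_shape[1],
        (lin %/% grid_shape[1]) %% grid_shape[2],
        lin %/% (grid_shape[1] * grid_shape[2]))
}

# Ensure an atlas carries the cached traversal vectors (they are rebuilt for
# atlases read back from disk).
atlas_cache <- function(atlas) {
  if (!is.null(atlas$vox_flat) && length(atlas$vox_flat)) return(atlas)
  if (!length(atlas$streamlines)) {
    atlas$voxels <- list(); atlas$vox_flat <- integer(0)
    atlas$vox_sl <- integer(0)
    return(atlas)
  }
  atlas$voxels <- voxelize_polylines_cpp(
    lapply(atlas$streamlines, `[[`, "points"), as.integer(atlas$grid_shape))
  atlas$vox_flat <- unlist(atlas$voxels) + 1L
  atlas$vox_sl <- rep(seq_along(atlas$voxels), lengths(atlas$voxels))
  atlas
}

check_same_space <- function(a, b) {
  if (!identical(as.integer(a$grid_shape), as.integer(b$grid_shape)) ||
      !identical(a$space_tag, b$space_tag))
    stop("objects do not share the same voxel grid / space")
}

#' Structural disconnection matrix
#'
#' For every structurally connected region pair, the proportion of that
#' pair's atlas streamlines that intersect the subject's lesion mask (a
#' streamline counts as transected when at least one traversed voxel is
#' lesioned).  Pairs absent from the atlas are undefined: stored as 0 with
#' `structural_mask` FALSE.
#'
#' @param mask a [lesion_mask] on the atlas grid.
#' @param atlas a [make_streamline_atlas] result (or one read from disk).
#' @param node_table data.frame with columns id, name, system (as produced
#'   by [make_parcellation]).
#' @return a [conn_matrix] of kind `"disconnection"`.
#' @export
disconnection_matrix <- function(mask, atlas, node_table) {
  check_same_space(mask, atlas)
  atlas <- atlas_cache(atlas)
  n <- nrow(node_table)
  values <- matrix(0, n, n)
  smask <- matrix(FALSE, n, n)
  if (nrow(atlas$pairs) > 0) {
    if (max(atlas$pairs) > n)
      stop("atlas references nodes beyond the node table")
    smask[atlas$pairs] <- TRUE
    smask[atlas$pairs[, 2:1, drop = FALSE]] <- TRUE
  }
  n_sl <- length(atlas$streamlines)
  if (n_sl > 0) {
    mflat <- as.logical(mask$data)
    hit_sl <- tabulate(atlas$vox_sl[mflat[atlas$vox_flat]], nbins = n_sl) > 0
    n_pairs <- nrow(atlas$pairs)
    transected <- tabulate(atlas$pair_index[hit_sl], nbins = n_pairs)
    for (pr in seq_len(n_pairs)) {
      i <- atlas$pairs[pr, 1]; j <- atlas$pairs[pr, 2]
      v <- transected[pr] / atlas$pair_counts[i, j]
      values[i, j] <- v
      values[j, i] <- v
    }
  }
  conn_matrix(values, node_table$id, node_table$system,
              kind = "disconnection", structural_mask = smask)
}

#' Group-level lesion probability map
#'
#' Voxel-wise mean of binary lesion masks: the probability of each voxel
#' containing a lesion across subjects.
#'
#' @param masks list of [lesion_mask] objects on a shared grid.
#' @return numeric 3D array with values in \[0, 1\].
#' @export
lesion_probability_map <- function(masks) {
  if (!length(masks)) stop("need at least one lesion mask")
  d <- masks[[1]]$grid_shape
  for (m in masks) check_same_space(masks[[1]], m)
  acc <- array(0, dim = d)
  for (m in masks) acc <- acc + m$data
  acc / length(masks)
}

#' Group-level disconnection probability map
#'
#' Per subject, every voxel traversed by any streamline that intersects that
#' subject's lesions is marked; the map is the across-subject mean of these
#' indicator volumes: the probability of each voxel containing at least one
#' streamline intersecting a lesion.
#'
#' @param masks list of [lesion_mask] objects.
#' @param atlas streamline atlas on the same grid.
#' @return numeric 3D array with values in \[0, 1\].
#' @export
disconnection_probability_map <- function(masks, atlas) {
  if (!length(masks)) stop("need at least one lesion mask")
  atlas <- atlas_cache(atlas)
  d <- atlas$grid_shape
  acc <- numeric(prod(d))
  n_sl <- length(atlas$streamlines)
  for (m in masks) {
    check_same_space(m, atlas)
    ind <- logical(prod(d))
    if (n_sl > 0) {
      mflat <- as.logical(m$data)
      hit_sl <- tabulate(atlas$vox_sl[mflat[atlas$vox_flat]], nbins = n_sl) > 0
      if (any(hit_sl)) ind[atlas$vox_flat[hit_sl[atlas$vox_sl]]] <- TRUE
    }
    acc <- acc + ind
  }
  array(acc / length(masks), dim = d)
}

#' Total lesion volume
#'
#' @param mask a [lesion_mask].
#' @return lesion volume in cubic millimetres (voxel count times voxel
#'   volume).
#' @export
total_lesion_volume <- function(mask) {
  sum(mask$data) * mask$voxel_size^3
}

#' log(x + 1) transform for total lesion volume
#'
#' TLV distributions are positively skewed; analyses use the natural
#' log(1 + x) transform.
#'
#' @param tlv nonnegative lesion volume(s).
#' @return transformed value(s).
#' @export
log1p_tlv <- function(tlv) {
  if (any(tlv < 0, na.rm = TRUE)) stop("TLV must be nonnegative")
  log1p(tlv)
}
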