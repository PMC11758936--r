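# Readers/writers for the on-disk interchange formats: NIfTI volumes
# (lesion masks, parcellations, probability maps), JSON-lines streamline
# atlases, and TSV tables (matrices, node tables, cohort, vertex features).

#' Write / read a volume as NIfTI
#'
#' @param vol 3D array (mask, label volume or probability map).
#' @param path output file (`.nii` or `.nii.gz`).
#' @param voxel_size isotropic voxel edge in mm.
#' @return `read_volume_nifti` returns a list with `data` and `voxel_size`.
#' @export
write_volume_nifti <- function(vol, path, voxel_size = 1) {
  img <- RNifti::asNifti(vol)
  RNifti::pixdim(img) <- rep(voxel_size, 3)
  invisible(RNifti::writeNifti(img, path))
}

#' @rdname write_volume_nifti
#' @export
read_volume_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  list(data = array(as.vector(img), dim = dim(img)),
       voxel_size = RNifti::pixdim(img)[1])
}

#' Write / read a lesion mask as NIfTI
#'
#' @param mask a [lesion_mask].
#' @param path file path.
#' @param space_tag grid identifier to stamp on the mask read back.
#' @export
write_lesion_mask <- function(mask, path) {
  write_volume_nifti(mask$data, path, mask$voxel_size)
}

#' @rdname write_lesion_mask
#' @export
read_lesion_mask <- function(path, space_tag) {
  v <- read_volume_nifti(path)
  lesion_mask(array(as.integer(v$data > 0.5), dim = dim(v$data)),
              v$voxel_size, space_tag)
}

#' Write / read a streamline atlas as JSON-lines
#'
#' One streamline per line: `{"pair": [i, j], "points": [[x,y,z], ...]}`;
#' a header line carries the grid metadata.  Voxel traversals are recomputed
#' on read.
#'
#' @param atlas a `streamline_atlas`.
#' @param path file path (`.jsonl`).
#' @export
write_streamline_atlas <- function(atlas, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(jsonlite::toJSON(list(
    grid_shape = atlas$grid_shape, voxel_size = atlas$voxel_size,
    space_tag = atlas$space_tag,
    streamlines_per_pair = max(atlas$pair_counts)), auto_unbox = TRUE), con)
  for (sl in atlas$streamlines) {
    writeLines(jsonlite::toJSON(list(pair = sl$pair,
                                     points = round(sl$points, 6)),
                                auto_unbox = FALSE, digits = NA), con)
  }
}

#' @rdname write_streamline_atlas
#' @export
read_streamline_atlas <- function(path) {
  lines <- readLines(path)
  hdr <- jsonlite::fromJSON(lines[1])
  streamlines <- lapply(lines[-1], function(l) {
    o <- jsonlite::fromJSON(l)
    list(pair = as.integer(o$pair), points = matrix(o$points, ncol = 3))
  })
  n_nodes <- if (length(streamlines))
    max(vapply(streamlines, function(s) max(s$pair), 0L)) else 0L
  pair_key <- vapply(streamlines, function(s)
    (s$pair[1] - 1) * n_nodes + s$pair[2], 0)
  upairs <- sort(unique(pair_key))
  pair_index <- match(pair_key, upairs)
  pairs <- cbind((upairs - 1) %/% n_nodes + 1, (upairs - 1) %% n_nodes + 1)
  pair_counts <- matrix(0L, n_nodes, n_nodes)
  for (k in seq_along(pair_key)) {
    i <- streamlines[[k]]$pair[1]; j <- streamlines[[k]]$pair[2]
    pair_counts[i, j] <- pair_counts[i, j] + 1L
    pair_counts[j, i] <- pair_counts[i, j]
  }
  atlas <- structure(list(streamlines = streamlines,
                          pairs = matrix(as.integer(pairs), ncol = 2),
                          pair_counts = pair_counts,
                          pair_index = pair_index,
                          grid_shape = as.integer(hdr$grid_shape),
                          voxel_size = hdr$voxel_size,
                          space_tag = hdr$space_tag),
                     class = "streamline_atlas")
  atlas_cache(atlas)
}

#' Write / read a connectivity matrix as TSV
#'
#' Node ids in the header; disconnection matrices get a companion
#' `*.mask.tsv` carrying the structural mask.
#'
#' @param m a [conn_matrix].
#' @param path file path (`.tsv`).
#' @export
write_conn_matrix <- function(m, path) {
  df <- as.data.frame(m$values)
  names(df) <- as.character(m$node_ids)
  write.table(cbind(node = m$node_ids, system = m$system_labels, df), path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  if (m$kind == "disconnection") {
    write.table(as.data.frame(m$structural_mask * 1L),
                sub("\\.tsv$", ".mask.tsv", path), sep = "\t",
                quote = FALSE, row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_conn_matrix
#' @param kind matrix kind expected on read.
#' @export
read_conn_matrix <- function(path, kind = c("disconnection", "similarity")) {
  kind <- match.arg(kind)
  df <- read.delim(path, check.names = FALSE)
  ids <- df$node; systems <- df$system
  v <- as.matrix(df[, -(1:2)])
  dimnames(v) <- NULL
  smask <- NULL
  maskfile <- sub("\\.tsv$", ".mask.tsv", path)
  if (kind == "disconnection" && file.exists(maskfile)) {
    smask <- as.matrix(read.delim(maskfile, header = FALSE)) > 0
    dimnames(smask) <- NULL
  }
  conn_matrix(v, ids, systems, kind = kind, structural_mask = smask)
}

#' Write vertex features as a long TSV
#'
#' Columns: region, vertex, thickness, volume, area, curvature, sulc.
#'
#' @param vf a `vertex_features` object.
#' @param path file path.
#' @export
write_vertex_features <- function(vf, path) {
  feat_names <- c("thickness", "volume", "area", "curvature", "sulc")
  rows <- lapply(names(vf$features), function(rn) {
    m <- vf$features[[rn]]
    colnames(m) <- feat_names
    data.frame(region = rn, vertex = seq_len(nrow(m)), m,
               stringsAsFactors = FALSE)
  })
  write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname write_vertex_features
#' @export
read_vertex_features <- function(path) {
  df <- read.delim(path)
  feats <- lapply(split(df, factor(df$region, levels = unique(df$region))),
                  function(d) as.matrix(d[order(d$vertex), 3:7]))
  structure(list(features = feats, region_ids = unique(df$region)),
            class = "vertex_features")
}

#' Write / read TSV tables (node table, cohort table)
#'
#' @param df data.frame.
#' @param path file path.
#' @export
write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tsv
#' @export
read_tsv <- function(path) read.delim(path, stringsAsFactors = FALSE)
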