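#' Connectivity matrix container
#'
#' A symmetric node-by-node matrix holding either structural disconnection
#' (proportion of atlas streamlines between two regions transected by lesions,
#' in \[0, 1\]) or morphometric similarity (in (0, 1\]).  Nodes carry region
#' ids and functional-system labels (the seven canonical cortical systems
#' VIS, SM, DAN, VAN, limbic, CONT, DMN plus SUBC for subcortical regions).
#' For disconnection matrices, `structural_mask` records which node pairs are
#' structurally connected in the atlas at all; pairs outside the mask are
#' undefined (stored as 0) and excluded from edge statistics.
#'
#' @param values symmetric numeric matrix with zero diagonal.
#' @param node_ids character or integer vector of region ids.
#' @param system_labels per-node system assignment.
#' @param kind `"disconnection"` or `"similarity"`.
#' @param structural_mask optional symmetric logical matrix of defined pairs
#'   (disconnection only; defaults to all off-diagonal pairs).
#' @return An object of class `conn_matrix`.
#' @export
conn_matrix <- function(values, node_ids, system_labels,
                        kind = c("disconnection", "similarity"),
                        structural_mask = NULL) {
  kind <- match.arg(kind)
  values <- as.matrix(values)
  n <- nrow(values)
  if (ncol(values) != n) stop("values must be square")
  if (max(abs(values - t(values))) > 1e-8) stop("values must be symmetric")
  if (length(node_ids) != n || length(system_labels) != n)
    stop("node_ids and system_labels must match matrix dimension")
  if (is.null(structural_mask)) {
    structural_mask <- matrix(TRUE, n, n)
    diag(structural_mask) <- FALSE
  }
  if (kind == "disconnection") {
    if (any(values < -1e-12) || any(values > 1 + 1e-12))
      stop("disconnection values must lie in [0, 1]")
    if (any(abs(values[!structural_mask]) > 1e-12))
      stop("values outside the structural mask must be 0")
  }
  if (any(abs(diag(values)) > 1e-12)) stop("diagonal must be zero")
  dimnames(values) <- list(node_ids, node_ids)
  structure(list(values = values, node_ids = node_ids,
                 system_labels = as.character(system_labels), kind = kind,
                 structural_mask = structural_mask),
            class = "conn_matrix")
}

#' @export
print.conn_matrix <- function(x, ...) {
  cat(sprintf("<conn_matrix: %s, %d nodes, %d defined edges>\n", x$kind,
              nrow(x$values), sum(x$structural_mask[upper.tri(x$structural_mask)])))
  invisible(x)
}

#' Node strength
#'
#' Sums all edge values attached to each node (row sums excluding the
#' diagonal), the region-level aggregation used for both disconnection and
#' similarity matrices.
#'
#' @param m a [conn_matrix].
#' @return named numeric vector, one entry per node.
#' @export
node_strength <- function(m) {
  stopifnot(inherits(m, "conn_matrix"))
  v <- m$values
  diag(v) <- 0
  rowSums(v)
}

#' System-block mean matrix
#'
#' Averages edge values over every ordered pair of functional systems
#' (within-system blocks exclude the diagonal), producing the network-level
#' aggregated representation.
#'
#' @param m a [conn_matrix].
#' @param systems system ordering for the output; defaults to the canonical
#'   eight (VIS, SM, DAN, VAN, limbic, CONT, DMN, SUBC) restricted to those
#'   present.
#' @return symmetric matrix of block means.
#' @export
system_block_means <- function(m, systems = NULL) {
  stopifnot(inherits(m, "conn_matrix"))
  canonical <- c("VIS", "SM", "DAN", "VAN", "limbic", "CONT", "DMN", "SUBC")
  present <- unique(m$system_labels)
  if (!all(present %in% canonical)) {
    bad <- setdiff(present, canonical)
    stop("unknown system label(s): ", paste(bad, collapse = ", "))
  }
  if (is.null(systems)) systems <- canonical[canonical %in% present]
  k <- length(systems)
  out <- matrix(NA_real_, k, k, dimnames = list(systems, systems))
  v <- m$values
  for (a in seq_len(k)) {
    for (b in a:k) {
      ia <- which(m$system_labels == systems[a])
      ib <- which(m$system_labels == systems[b])
      block <- v[ia, ib, drop = FALSE]
      if (a == b) {
        vals <- block[upper.tri(block)]
      } else {
        vals <- as.vector(block)
      }
      out[a, b] <- mean(vals)
      out[b, a] <- out[a, b]
    }
  }
  out
}

#' Vectorize the masked upper triangle of a connectivity matrix
#'
#' Extracts the defined edges of a symmetric matrix as a vector together with
#' the inverse map; `devectorize_edges()` restores a symmetric matrix with
#' masked-out entries set to 0.  For disconnection matrices the natural mask
#' is the structural mask; for similarity matrices all off-diagonal pairs.
#'
#' @param m a [conn_matrix] or plain symmetric matrix.
#' @param edge_mask symmetric logical matrix restricted to the upper triangle
#'   when used (defaults to the matrix's own structural mask).
#' @return list with `values`, `pairs` (two-column node index matrix),
#'   `mask` and `n_nodes`.
#' @export
vectorize_edges <- function(m, edge_mask = NULL) {
  if (inherits(m, "conn_matrix")) {
    v <- m$values
    if (is.null(edge_mask)) edge_mask <- m$structural_mask
  } else {
    v <- as.matrix(m)
    if (max(abs(v - t(v))) > 1e-8) stop("matrix must be symmetric")
    if (is.null(edge_mask)) {
      edge_mask <- matrix(TRUE, nrow(v), ncol(v))
    }
  }
  n <- nrow(v)
  keep <- edge_mask & upper.tri(v)
  pairs <- which(keep, arr.ind = TRUE)
  list(values = v[keep], pairs = unname(pairs), mask = keep, n_nodes = n)
}

#' @rdname vectorize_edges
#' @param values edge vector as produced by `vectorize_edges()`.
#' @param ev the list returned by `vectorize_edges()` (provides mask/shape).
#' @export
devectorize_edges <- function(values, ev) {
  n <- ev$n_nodes
  out <- matrix(0, n, n)
  out[ev$mask] <- values
  out + t(out)
}
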