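#' Standardize vertex features across all vertices
#'
#' Centres and scales each of the 5 morphometric features to pooled mean 0
#' and SD 1 across the vertices of all regions (region membership is
#' untouched).  Standardization makes the multivariate divergences
#' scale-free, so any affine rescaling of a raw feature leaves the output
#' unchanged.
#'
#' @param fs a `vertex_features` object (list of region matrices).
#' @return a `vertex_features` object with standardized features.
#' @export
standardize_features <- function(fs) {
  mats <- fs$features
  pooled <- do.call(rbind, mats)
  mu <- colMeans(pooled)
  sdv <- apply(pooled, 2, sd)
  if (any(sdv < 1e-12)) stop("degenerate feature: zero variance across pooled vertices")
  fs$features <- lapply(mats, function(m)
    sweep(sweep(m, 2, mu, "-"), 2, sdv, "/"))
  fs$standardized <- TRUE
  fs
}

#' k-nearest-neighbour Kullback-Leibler divergence estimate
#'
#' Nonparametric estimate of D(P || Q) between two point clouds via kth
#' nearest-neighbour distances, clamped at zero (the raw estimator can go
#' slightly negative).
#'
#' @param P,Q numeric matrices (points x dimensions) of equal dimension.
#' @param k neighbour count; must be smaller than both cloud sizes.
#' @return nonnegative scalar divergence estimate.
#' @export
kl_knn <- function(P, Q, k = 3L) {
  P <- as.matrix(P); Q <- as.matrix(Q)
  if (ncol(P) != ncol(Q)) stop("dimension mismatch between point clouds")
  if (k >= min(nrow(P), nrow(Q))) stop("k must be smaller than both cloud sizes")
  max(0, kl_knn_cpp(P, Q, as.integer(k)))
}

#' Morphometric similarity between two regions
#'
#' `s = 1 / (1 + D_sym)` where `D_sym` is the symmetrized (clamped)
#' k-nearest-neighbour KL divergence between the two standardized vertex
#' clouds; s lies in (0, 1], with 1 meaning identical distributions.
#'
#' @inheritParams kl_knn
#' @return similarity in (0, 1].
#' @export
mind_value <- function(P, Q, k = 3L) {
  1 / (1 + kl_knn(P, Q, k) + kl_knn(Q, P, k))
}

#' Morphometric similarity (MIND) matrix
#'
#' Pairwise similarity between all cortical regions of a standardized vertex
#' feature set.  The symmetrized divergence makes `s(i,j) = s(j,i)` exact by
#' construction; the diagonal is set to 0 and excluded from all downstream
#' statistics (self-similarity is uninformative).
#'
#' @param fs a `vertex_features` object; standardized with
#'   [standardize_features()] first unless `standardize = FALSE`.
#' @param k divergence neighbour count (default 3).
#' @param node_table optional node table for labels; defaults to region names
#'   with system `"VIS"` placeholder-free assignment from attributes when
#'   available.
#' @param standardize standardize features first (default TRUE).
#' @return a [conn_matrix] of kind `"similarity"`.
#' @export
mind_matrix <- function(fs, k = 3L, node_table = NULL, standardize = TRUE) {
  if (standardize && is.null(fs$standardized)) fs <- standardize_features(fs)
  nv <- vapply(fs$features, nrow, 0L)
  if (any(nv <= k)) stop("degenerate distribution: region with <= k vertices")
  S <- mind_matrix_cpp(fs$features, as.integer(k))
  nms <- names(fs$features)
  if (is.null(node_table)) {
    ids <- nms %||% as.character(seq_along(fs$features))
    systems <- rep(c("VIS", "SM", "DAN", "VAN", "limbic", "CONT", "DMN"),
                   length.out = length(ids))
  } else {
    keep <- match(nms, node_table$name)
    ids <- node_table$id[keep]
    systems <- node_table$system[keep]
  }
  conn_matrix(S, ids, systems, kind = "similarity")
}
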