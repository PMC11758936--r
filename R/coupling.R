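#' Coupling between structural disconnection and morphometric similarity
#'
#' Spearman associations between the two network domains over the cortical
#' nodes they share (subcortical rows are dropped from disconnection
#' matrices), at three scales:
#' \describe{
#'   \item{global}{across subjects, correlation of per-subject mean
#'     disconnection (over structurally connected cortical edges) with
#'     per-subject mean similarity.}
#'   \item{edge}{correlation of the vectorized group-mean disconnection and
#'     similarity matrices.}
#'   \item{node}{per cortical region, correlation of its paired row profiles
#'     (self-pairs excluded), returning one coupling value per region.}
#' }
#' `exclude_zero_disconnection` removes, at the edge/node scales, edges that
#' are structurally unconnected (mask FALSE) together with connected edges
#' whose (group-mean) disconnection is zero.
#'
#' @param disc list of disconnection [conn_matrix] objects (one per subject).
#' @param sim list of similarity [conn_matrix] objects (same subjects).
#' @param scale `"global"`, `"edge"` or `"node"`.
#' @param exclude_zero_disconnection drop zero/undefined-disconnection edges.
#' @return for `"global"`/`"edge"`: list with `rho`, `p`, `n`; for `"node"`:
#'   data.frame with per-node `rho` and `p`.
#' @export
coupling <- function(disc, sim, scale = c("global", "edge", "node"),
                     exclude_zero_disconnection = FALSE) {
  scale <- match.arg(scale)
  stopifnot(length(disc) == length(sim), length(disc) >= 1)
  d1 <- disc[[1]]; s1 <- sim[[1]]
  ctx <- intersect(as.character(d1$node_ids[d1$system_labels != "SUBC"]),
                   as.character(s1$node_ids))
  if (!length(ctx)) stop("alignment error: no overlapping cortical nodes")
  di <- match(ctx, as.character(d1$node_ids))
  si <- match(ctx, as.character(s1$node_ids))
  nd <- length(ctx)
  dmats <- lapply(disc, function(m) m$values[di, di, drop = FALSE])
  smats <- lapply(sim, function(m) m$values[si, si, drop = FALSE])
  smask <- d1$structural_mask[di, di, drop = FALSE]
  ut <- upper.tri(smask)

  if (scale == "global") {
    md <- vapply(dmats, function(m) mean(m[smask & ut]), 0)
    ms <- vapply(smats, function(m) mean(m[ut]), 0)
    out <- spearman(md, ms)
    out$n <- length(md)
    return(out)
  }
  dbar <- Reduce(`+`, dmats) / length(dmats)
  sbar <- Reduce(`+`, smats) / length(smats)
  if (scale == "edge") {
    keep <- ut
    if (exclude_zero_disconnection) keep <- keep & smask & dbar > 0
    out <- spearman(dbar[keep], sbar[keep])
    out$n <- sum(keep)
    return(out)
  }
  # node scale
  rho <- p <- rep(NA_real_, nd)
  for (r in seq_len(nd)) {
    keep <- seq_len(nd) != r
    if (exclude_zero_disconnection)
      keep <- keep & smask[r, ] & dbar[r, ] > 0
    if (sum(keep) >= 4 && sd(dbar[r, keep]) > 0 && sd(sbar[r, keep]) > 0) {
      sp <- spearman(dbar[r, keep], sbar[r, keep])
      rho[r] <- sp$rho; p[r] <- sp$p
    }
  }
  data.frame(node = ctx, rho = rho, p = p, stringsAsFactors = FALSE)
}

#' Coupling split by median disease duration
#'
#' Splits patients at the median disease duration (the median subject goes
#' to the shorter-duration group) and computes the requested coupling in
#' each half.
#'
#' @inheritParams coupling
#' @param disease_duration per-subject disease duration (years).
#' @return list with `shorter` and `longer` coupling results and the median.
#' @export
coupling_by_duration <- function(disc, sim, disease_duration,
                                 scale = "global",
                                 exclude_zero_disconnection = FALSE) {
  stopifnot(length(disease_duration) == length(disc))
  med <- median(disease_duration)
  short <- disease_duration <= med
  list(median = med,
       shorter = coupling(disc[short], sim[short], scale,
                          exclude_zero_disconnection),
       longer = coupling(disc[!short], sim[!short], scale,
                         exclude_zero_disconnection))
}
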