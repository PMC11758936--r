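#' Build a design matrix for edge-wise models
#'
#' Assembles intercept + variable of interest + nuisance covariates into a
#' full-column-rank design with a contrast selecting the tested effect.  The
#' conventional nuisance set is baseline age, age squared and sex, optionally
#' extended with log(1+x)-transformed total lesion volume (disconnection
#' models) or z-scored brain parenchymal fraction (similarity models).
#' All-zero nuisance columns are dropped silently (so an "empty" adjustment
#' is the unadjusted model); any other rank deficiency is an error.
#'
#' @param data data.frame of per-observation covariates.
#' @param interest name of the variable of interest.
#' @param nuisance character vector of nuisance column names (may be empty).
#' @return list of class `design_matrix` with `X`, `contrast`, `interest`.
#' @export
make_design <- function(data, interest, nuisance = character(0)) {
  stopifnot(interest %in% names(data))
  xi <- data[[interest]]
  if (is.character(xi) || is.factor(xi)) xi <- as.numeric(factor(xi)) - 1
  X <- cbind(`(Intercept)` = 1, interest = xi)
  colnames(X)[2] <- interest
  for (nm in nuisance) {
    v <- data[[nm]]
    if (is.null(v)) stop("nuisance column not found: ", nm)
    if (is.character(v) || is.factor(v)) v <- as.numeric(factor(v)) - 1
    X <- cbind(X, v)
    colnames(X)[ncol(X)] <- nm
  }
  zero <- colnames(X)[-(1:2)][colSums(abs(X[, -(1:2), drop = FALSE])) == 0]
  if (length(zero)) X <- X[, setdiff(colnames(X), zero), drop = FALSE]
  if (qr(X)$rank < ncol(X))
    stop("design error: rank-deficient design matrix")
  contrast <- as.numeric(colnames(X) == interest)
  structure(list(X = X, contrast = contrast, interest = interest),
            class = "design_matrix")
}

#' Edge-wise general linear model
#'
#' Ordinary least squares of every edge on a common design; returns the
#' contrast t statistic and two-sided p-value per edge with
#' `n - rank(X)` degrees of freedom.
#'
#' @param Y numeric matrix, observations x edges.
#' @param design a [make_design] result (or a list with `X` and `contrast`).
#' @return list with `t`, `p`, `effect` (contrast estimate), `se`, `df`.
#' @export
edgewise_glm <- function(Y, design) {
  X <- design$X
  cvec <- design$contrast
  Y <- as.matrix(Y)
  n <- nrow(Y); p <- ncol(X)
  if (nrow(X) != n) stop("observation count mismatch")
  if (n < p + 2) stop("too few observations for the design")
  if (qr(X)$rank < p) stop("design error: rank-deficient design matrix")
  XtXinv <- chol2inv(chol(crossprod(X)))
  A <- XtXinv %*% t(X)
  beta <- A %*% Y
  res <- Y - X %*% beta
  df <- n - p
  sigma2 <- colSums(res^2) / df
  cvar <- drop(t(cvec) %*% XtXinv %*% cvec)
  eff <- drop(cvec %*% beta)
  se <- sqrt(sigma2 * cvar)
  tt <- eff / se
  list(t = tt, p = 2 * pt(-abs(tt), df), effect = eff, se = se, df = df)
}

#' Connected components among suprathreshold edges
#'
#' Edges whose p-value is strictly below the primary threshold form a graph
#' on the nodes; connected components are extracted (by default separately
#' for positive and negative test statistics, so that effects of opposite
#' sign are reported as distinct subnetworks) and scored by the sum of
#' absolute edge statistics.
#'
#' @param edge_stats per-edge test statistics.
#' @param p_values per-edge p-values.
#' @param p_primary primary threshold in (0, 1); strict inequality survives.
#' @param pairs two-column matrix mapping edges to node index pairs.
#' @param n_nodes number of nodes in the graph.
#' @param sign_split split suprathreshold edges by statistic sign before
#'   finding components (default TRUE).
#' @return list of components: each has `edge_idx`, `pairs`, `stat_sum`,
#'   `sign`, `n_edges`, ordered by decreasing `stat_sum`.
#' @export
suprathreshold_components <- function(edge_stats, p_values, p_primary, pairs,
                                      n_nodes, sign_split = TRUE) {
  if (p_primary <= 0 || p_primary >= 1) stop("p_primary must lie in (0, 1)")
  sel <- which(p_values < p_primary)
  if (!length(sel)) return(list())
  groups <- if (sign_split) split(sel, edge_stats[sel] > 0) else list(sel)
  comps <- list()
  for (g in groups) {
    gr <- igraph::graph_from_edgelist(pairs[g, , drop = FALSE],
                                      directed = FALSE)
    if (igraph::vcount(gr) < n_nodes)
      gr <- igraph::add_vertices(gr, n_nodes - igraph::vcount(gr))
    memb <- igraph::components(gr)$membership
    edge_comp <- memb[pairs[g, 1]]
    for (cid in unique(edge_comp)) {
      e <- g[edge_comp == cid]
      comps[[length(comps) + 1]] <- list(
        edge_idx = e, pairs = pairs[e, , drop = FALSE],
        stat_sum = sum(abs(edge_stats[e])), n_edges = length(e),
        sign = if (sign_split) sign(edge_stats[e][1]) else 0)
    }
  }
  comps[order(vapply(comps, `[[`, 0, "stat_sum"), decreasing = TRUE)]
}

#' Network-based statistic with a general linear model
#'
#' The four-step NBS procedure: (1) edge-wise GLM of every edge on the
#' design, (2) primary thresholding at `p < p_primary`, (3) connected
#' components among suprathreshold edges, (4) family-wise-error-corrected
#' p-value per component from the permutation distribution of the maximum
#' component statistic sum.  Nuisance covariates are handled by
#' Freedman-Lane residual permutation: residuals of the nuisance-only model
#' are permuted, the nuisance fit added back, and the full model refitted.
#'
#' @inheritParams edgewise_glm
#' @param p_primary primary edge threshold (default 0.01).
#' @param n_perm number of permutations (default 5000).
#' @param seed integer seed for the permutation stream.
#' @param pairs two-column edge-to-node-pair map (defaults to the upper
#'   triangle of an inferred complete graph).
#' @param n_nodes number of nodes.
#' @param sign_split report sign-split components (default TRUE).
#' @return object of class `nbs_result`: observed components with `p_fwe`,
#'   edge-level `t` and `p`, the permutation null of maximum component
#'   statistic sums, and the settings used.
#' @export
nbs_glm <- function(Y, design, p_primary = 0.01, n_perm = 5000, seed = 1L,
                    pairs = NULL, n_nodes = NULL, sign_split = TRUE) {
  if (n_perm < 1) stop("n_perm must be at least 1")
  Y <- as.matrix(Y)
  n <- nrow(Y)
  if (is.null(pairs)) {
    n_nodes <- n_nodes %||% ceiling((1 + sqrt(1 + 8 * ncol(Y))) / 2)
    pairs <- upper_tri_pairs(n_nodes)[seq_len(ncol(Y)), , drop = FALSE]
  }
  n_nodes <- n_nodes %||% max(pairs)
  obs <- edgewise_glm(Y, design)
  comps <- suprathreshold_components(obs$t, obs$p, p_primary, pairs, n_nodes,
                                     sign_split)
  X <- design$X
  cvec <- design$contrast
  p <- ncol(X)
  df <- n - p
  t_crit <- qt(1 - p_primary / 2, df)
  # Freedman-Lane machinery
  Z <- X[, cvec == 0, drop = FALSE]
  HzY <- Z %*% (chol2inv(chol(crossprod(Z))) %*% (t(Z) %*% Y))
  Rz <- Y - HzY
  XtXinv <- chol2inv(chol(crossprod(X)))
  w <- drop(t(cvec) %*% XtXinv %*% t(X)) # length n: contrast row of pinv
  Qx <- qr.Q(qr(X))
  cvar <- drop(t(cvec) %*% XtXinv %*% cvec)
  null_max <- numeric(n_perm)
  with_seed(seed, {
    for (b in seq_len(n_perm)) {
      Ystar <- HzY + Rz[sample.int(n), , drop = FALSE]
      num <- drop(w %*% Ystar)
      rss <- colSums(Ystar^2) - colSums((crossprod(Qx, Ystar))^2)
      tstar <- num / sqrt(pmax(rss, 1e-300) / df * cvar)
      null_max[b] <- max_component_sum(tstar, t_crit, pairs, n_nodes,
                                       sign_split)
    }
  })
  for (i in seq_along(comps)) {
    comps[[i]]$p_fwe <- (1 + sum(null_max >= comps[[i]]$stat_sum)) /
      (n_perm + 1)
  }
  structure(list(components = comps, t = obs$t, p = obs$p, df = df,
                 p_primary = p_primary, t_crit = t_crit, n_perm = n_perm,
                 null_max = null_max, pairs = pairs, n_nodes = n_nodes,
                 model = "glm"),
            class = "nbs_result")
}

# Maximum component |t| sum among suprathreshold edges of a permuted
# statistic vector (0 when no edge survives).
max_component_sum <- function(tstar, t_crit, pairs, n_nodes, sign_split) {
  sel <- which(abs(tstar) > t_crit)
  if (!length(sel)) return(0)
  best <- 0
  groups <- if (sign_split) split(sel, tstar[sel] > 0) else list(sel)
  for (g in groups) {
    gr <- igraph::graph_from_edgelist(pairs[g, , drop = FALSE],
                                      directed = FALSE)
    memb <- igraph::components(gr)$membership
    sums <- tapply(abs(tstar[g]), memb[pairs[g, 1]], sum)
    best <- max(best, max(sums))
  }
  best
}

#' @export
print.nbs_result <- function(x, ...) {
  cat(sprintf("<nbs_result (%s): %d component(s), %d permutations>\n",
              x$model, length(x$components), x$n_perm))
  for (i in seq_along(x$components)) {
    co <- x$components[[i]]
    cat(sprintf("  #%d: %d edges, stat sum %.2f, sign %+d, p_fwe = %.4g\n",
                i, co$n_edges, co$stat_sum, co$sign, co$p_fwe))
  }
  invisible(x)
}
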