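#' Configuration for connectome-based outcome prediction
#'
#' @param outer_folds,inner_folds stratified cross-validation folds
#'   (defaults 5 and 5).
#' @param repeats number of re-randomized repetitions of the whole CV
#'   structure (default 10).
#' @param p_primary primary threshold for component feature selection.
#' @param classifiers candidate model families: any of `"logistic"`,
#'   `"svm"` (linear support vector classifier), `"lda"`.
#' @param budget hyperparameter-search evaluations per inner loop
#'   (default 100); the search is a seeded random search over the same
#'   ranges a surrogate-model optimizer would explore.
#' @param n_perm label permutations for significance (default 500).
#' @param perm_repeats CV repeats used inside each permutation (reduced
#'   budget; default 1).
#' @param select `"largest"` component (default) or `"all"` components.
#' @param seed integer seed.
#' @return object of class `predict_config`.
#' @export
predict_config <- function(outer_folds = 5, inner_folds = 5, repeats = 10,
                           p_primary = 0.01,
                           classifiers = c("logistic", "svm", "lda"),
                           budget = 100, n_perm = 500, perm_repeats = 1,
                           select = c("largest", "all"), seed = 1L) {
  if (outer_folds < 2 || inner_folds < 2) stop("folds must be >= 2")
  if (budget < 1) stop("budget must be >= 1")
  if (!length(classifiers)) stop("need at least one classifier")
  classifiers <- match.arg(classifiers, c("logistic", "svm", "lda"),
                           several.ok = TRUE)
  structure(list(outer_folds = outer_folds, inner_folds = inner_folds,
                 repeats = repeats, p_primary = p_primary,
                 classifiers = classifiers, budget = budget, n_perm = n_perm,
                 perm_repeats = perm_repeats, select = match.arg(select),
                 seed = as.integer(seed)),
            class = "predict_config")
}

#' Cross-validated deconfounding
#'
#' Fits a linear confound model (with intercept) per edge on the training
#' data only and residualizes both training and test edges with the
#' training coefficients, preventing information leaking from test to train.
#'
#' @param train_x,test_x edge matrices (observations x edges).
#' @param train_c,test_c confound matrices (observations x confounds).
#' @return list with residualized `train` and `test` matrices.
#' @export
cv_deconfound <- function(train_x, train_c, test_x, test_c) {
  train_c <- as.matrix(train_c); test_c <- as.matrix(test_c)
  if (any(apply(train_c, 2, sd) < 1e-12))
    stop("design error: zero-variance confound column")
  C1 <- cbind(1, train_c)
  if (qr(C1)$rank < ncol(C1))
    stop("design error: rank-deficient confound matrix")
  B <- chol2inv(chol(crossprod(C1))) %*% crossprod(C1, as.matrix(train_x))
  list(train = as.matrix(train_x) - C1 %*% B,
       test = as.matrix(test_x) - cbind(1, test_c) %*% B)
}

#' Component-based feature selection on training data
#'
#' Edge-wise GLM of each edge on the class label (intercept + label),
#' primary thresholding, and extraction of the largest connected component
#' (or all components) among suprathreshold edges; the selected edges are
#' the classifier's features.
#'
#' @param train_x training edge matrix.
#' @param labels binary training labels (two classes required).
#' @param p_primary primary threshold.
#' @param pairs edge-to-node-pair map.
#' @param n_nodes node count.
#' @param select `"largest"` or `"all"`.
#' @return integer vector of selected edge indices (possibly empty).
#' @export
select_component_features <- function(train_x, labels, p_primary, pairs,
                                      n_nodes, select = "largest") {
  y <- as.numeric(factor(labels)) - 1
  if (length(unique(y)) < 2) stop("need two classes in training data")
  des <- list(X = cbind(1, y), contrast = c(0, 1))
  fit <- edgewise_glm(train_x, des)
  comps <- suprathreshold_components(fit$t, fit$p, p_primary, pairs, n_nodes,
                                     sign_split = FALSE)
  if (!length(comps)) return(integer(0))
  if (select == "largest") {
    sizes <- vapply(comps, `[[`, 0L, "n_edges")
    sort(comps[[which.max(sizes)]]$edge_idx)
  } else {
    sort(unique(unlist(lapply(comps, `[[`, "edge_idx"))))
  }
}

# stratified fold assignment
stratified_folds <- function(labels, k) {
  fold <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- sample(which(labels == cl))
    if (length(idx) < k) stop("stratification error: class absent from a fold")
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

train_classifier <- function(kind, par, x, y) {
  df <- data.frame(y = factor(y), x)
  switch(kind,
    logistic = {
      m <- suppressWarnings(glm(y ~ ., data = df, family = "binomial"))
      list(kind = kind, model = m)
    },
    svm = {
      m <- e1071::svm(y ~ ., data = df, kernel = "linear",
                      cost = par$cost %||% 1, scale = FALSE)
      list(kind = kind, model = m)
    },
    lda = {
      m <- MASS::lda(y ~ ., data = df)
      list(kind = kind, model = m)
    })
}

predict_classifier <- function(cl, x) {
  df <- data.frame(x)
  switch(cl$kind,
    logistic = as.integer(predict(cl$model, df, type = "response") > 0.5),
    svm = as.integer(as.character(predict(cl$model, df))),
    lda = as.integer(as.character(predict(cl$model, df)$class)))
}

# candidate (classifier, hyperparameter) draws for the random search
draw_candidates <- function(classifiers, budget) {
  cands <- list()
  for (k in classifiers) {
    if (k %in% c("logistic", "lda")) {
      cands[[length(cands) + 1]] <- list(kind = k, par = list())
    }
  }
  n_svm <- max(0, budget - length(cands))
  if ("svm" %in% classifiers) {
    for (i in seq_len(max(1, n_svm))) {
      cands[[length(cands) + 1]] <-
        list(kind = "svm", par = list(cost = 10^runif(1, -3, 2)))
    }
  }
  cands[seq_len(min(length(cands), max(budget, length(cands))))]
}

#' Predict a long-term binary outcome from baseline connectomes
#'
#' Nested, stratified, repeated cross-validation: within each outer training
#' fold the edges are scaled and deconfounded with training-only parameters,
#' a connected-component feature set is selected by edge-wise GLM at the
#' primary threshold, and the inner CV picks the best
#' classifier/hyperparameter pair by accuracy; the winner is refitted on the
#' outer training fold and evaluated on the held-out fold.  Accuracy is
#' averaged over folds and repeats (95% CI from the 2.5/97.5 percentiles of
#' repeat-level means); per-edge weights are the fraction of outer folds
#' selecting each edge.  Significance comes from label-permutation reruns at
#' reduced budget with the add-one permutation p-value.
#'
#' When a training fold yields no suprathreshold edges the fold falls back
#' to a majority-class constant classifier (counted in `n_empty_folds`).
#'
#' @param edges observations x edges matrix of baseline connectome values.
#' @param labels binary outcome (e.g. confirmed disability progression).
#' @param confounds matrix/data.frame of confounds, or NULL.
#' @param cfg a [predict_config].
#' @param pairs,n_nodes edge-to-node map (defaults to a complete graph
#'   inferred from the edge count).
#' @return object of class `predict_result`: `accuracy`, `ci`, `sensitivity`,
#'   `specificity`, `p_perm`, `weights`, `winners`, `repeat_accuracy`,
#'   `n_empty_folds`.
#' @export
run_nbs_predict <- function(edges, labels, confounds = NULL, cfg,
                            pairs = NULL, n_nodes = NULL) {
  edges <- as.matrix(edges)
  y <- as.integer(factor(labels)) - 1L
  if (is.null(pairs)) {
    n_nodes <- n_nodes %||% ceiling((1 + sqrt(1 + 8 * ncol(edges))) / 2)
    pairs <- upper_tri_pairs(n_nodes)[seq_len(ncol(edges)), , drop = FALSE]
  }
  n_nodes <- n_nodes %||% max(pairs)
  if (min(table(y)) < cfg$outer_folds)
    stop("stratification error: need >= outer_folds observations per class")
  res <- with_seed(derive_seed(cfg$seed, "nbs_predict"), {
    nbs_predict_core(edges, y, confounds, cfg, pairs, n_nodes,
                     repeats = cfg$repeats)
  })
  p_perm <- NA_real_
  if (cfg$n_perm >= 1) {
    perm_acc <- with_seed(derive_seed(cfg$seed, "nbs_predict_perm"), {
      vapply(seq_len(cfg$n_perm), function(b) {
        yb <- sample(y)
        nbs_predict_core(edges, yb, confounds, cfg, pairs, n_nodes,
                         repeats = cfg$perm_repeats)$accuracy
      }, 0)
    })
    p_perm <- (1 + sum(perm_acc >= res$accuracy)) / (cfg$n_perm + 1)
  }
  structure(c(res, list(p_perm = p_perm, cfg = cfg)),
            class = "predict_result")
}

nbs_predict_core <- function(edges, y, confounds, cfg, pairs, n_nodes,
                             repeats) {
  n <- nrow(edges)
  sel_count <- numeric(ncol(edges))
  n_outer_total <- 0
  rep_acc <- numeric(repeats)
  winners <- character(0)
  pred_all <- integer(0); truth_all <- integer(0)
  n_empty <- 0
  for (r in seq_len(repeats)) {
    fold <- stratified_folds(y, cfg$outer_folds)
    pred_rep <- integer(n)
    for (f in seq_len(cfg$outer_folds)) {
      tr <- fold != f; te <- !tr
      xtr <- edges[tr, , drop = FALSE]; xte <- edges[te, , drop = FALSE]
      # training-only scaling
      mu <- colMeans(xtr); sdv <- apply(xtr, 2, sd); sdv[sdv < 1e-12] <- 1
      xtr <- sweep(sweep(xtr, 2, mu), 2, sdv, "/")
      xte <- sweep(sweep(xte, 2, mu), 2, sdv, "/")
      if (!is.null(confounds)) {
        dec <- cv_deconfound(xtr, as.matrix(confounds)[tr, , drop = FALSE],
                             xte, as.matrix(confounds)[te, , drop = FALSE])
        xtr <- dec$train; xte <- dec$test
      }
      feats <- select_component_features(xtr, y[tr], cfg$p_primary, pairs,
                                         n_nodes, cfg$select)
      n_outer_total <- n_outer_total + 1
      if (!length(feats)) {
        n_empty <- n_empty + 1
        maj <- as.integer(mean(y[tr]) > 0.5)
        pred_rep[te] <- maj
        winners <- c(winners, "constant")
        next
      }
      sel_count[feats] <- sel_count[feats] + 1
      xtr_f <- xtr[, feats, drop = FALSE]
      xte_f <- xte[, feats, drop = FALSE]
      cands <- draw_candidates(cfg$classifiers, cfg$budget)
      ytr <- y[tr]
      # inner folds shrink when a class is too small for the requested split
      k_inner <- min(cfg$inner_folds, min(table(ytr)))
      if (k_inner < 2) {
        n_empty <- n_empty + 1
        maj <- as.integer(mean(ytr) > 0.5)
        pred_rep[te] <- maj
        winners <- c(winners, "constant")
        next
      }
      inner_fold <- stratified_folds(ytr, k_inner)
      acc_c <- vapply(cands, function(cand) {
        accs <- vapply(seq_len(k_inner), function(g) {
          itr <- inner_fold != g
          m <- try(train_classifier(cand$kind, cand$par,
                                    xtr_f[itr, , drop = FALSE], ytr[itr]),
                   silent = TRUE)
          if (inherits(m, "try-error")) return(NA_real_)
          mean(predict_classifier(m, xtr_f[!itr, , drop = FALSE]) ==
                 ytr[!itr])
        }, 0)
        mean(accs, na.rm = TRUE)
      }, 0)
      best <- cands[[which.max(acc_c)]]
      winners <- c(winners, best$kind)
      model <- train_classifier(best$kind, best$par, xtr_f, ytr)
      pred_rep[te] <- predict_classifier(model, xte_f)
    }
    rep_acc[r] <- mean(pred_rep == y)
    pred_all <- c(pred_all, pred_rep); truth_all <- c(truth_all, y)
  }
  sens <- sum(pred_all == 1 & truth_all == 1) / sum(truth_all == 1)
  spec <- sum(pred_all == 0 & truth_all == 0) / sum(truth_all == 0)
  list(accuracy = mean(rep_acc),
       ci = unname(quantile(rep_acc, c(0.025, 0.975), type = 7)),
       sensitivity = sens, specificity = spec,
       weights = sel_count / n_outer_total, winners = winners,
       repeat_accuracy = rep_acc, n_empty_folds = n_empty)
}

#' @export
print.predict_result <- function(x, ...) {
  cat(sprintf(
    "<predict_result: accuracy %.3f [%.3f-%.3f], sens %.2f, spec %.2f, p_perm %s>\n",
    x$accuracy, x$ci[1], x$ci[2], x$sensitivity, x$specificity,
    format(x$p_perm)))
  invisible(x)
}
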