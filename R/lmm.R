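#' Edge-wise linear mixed models for longitudinal networks
#'
#' Fits, per edge, a restricted-maximum-likelihood linear mixed model of the
#' edge value on follow-up time plus nuisance covariates, with a random
#' intercept and a random slope of follow-up time per subject (time points
#' nested within participants).  The reported statistic is the Wald t for
#' the time effect with `n - p` degrees of freedom (a normal-type
#' approximation; Satterthwaite corrections are out of scope).  When the
#' slope variance is inestimable the edge falls back to a
#' random-intercept-only fit, flagged in the output.
#'
#' @param Y numeric matrix, observations (visits) x edges.
#' @param time follow-up time in years from baseline, one per observation.
#' @param subject subject identifier per observation.
#' @param nuisance optional data.frame/matrix of between-subject nuisance
#'   covariates (one row per observation).
#' @return list with `B` (time-slope estimate per edge), `se`, `t`, `p`,
#'   `df`, `flag` (0 = full model, 1 = random-intercept fallback, 2 = OLS
#'   last resort), `varcomp` (per-edge random-effect SDs/correlation and
#'   residual variance), and `beta` (all fixed effects).
#' @export
edgewise_lmm <- function(Y, time, subject, nuisance = NULL) {
  Y <- as.matrix(Y)
  n <- nrow(Y)
  subject <- factor(subject)
  if (length(time) != n || length(subject) != n)
    stop("time/subject length mismatch")
  if (max(table(subject)) < 2)
    stop("longitudinal-data error: no subject has repeated visits")
  X <- cbind(`(Intercept)` = 1, time = as.numeric(time))
  if (!is.null(nuisance)) {
    # centring and scaling the (between-subject) nuisance columns keeps the
    # normal equations well conditioned (age and age^2 are near-collinear
    # otherwise); the time contrast is unaffected
    X <- cbind(X, scale(as.matrix(nuisance)))
  }
  if (qr(X)$rank < ncol(X)) stop("design error: rank-deficient design matrix")
  fit <- fit_lmm_batch_cpp(Y, X, as.numeric(time),
                           as.integer(subject) - 1L, 1L)
  tt <- fit$t
  list(B = fit$beta[2, ], se = fit$se, t = tt,
       p = 2 * pt(-abs(tt), fit$df), df = fit$df, flag = fit$flag,
       beta = fit$beta,
       varcomp = data.frame(sd_intercept = fit$sd_intercept,
                            sd_slope = fit$sd_slope, re_corr = fit$re_corr,
                            sigma2 = fit$sigma2))
}

#' Network-based statistic for longitudinal change
#'
#' NBS over edge-wise linear mixed models of the time effect.  The
#' permutation unit is the subject: within-subject time-centred trajectories
#' are sign-flipped per subject (preserving within-subject exchangeability
#' under the null of no systematic change), all edges are refitted, and the
#' maximum component statistic sum forms the family-wise error null.
#'
#' @inheritParams edgewise_lmm
#' @inheritParams nbs_glm
#' @return an `nbs_result` (see [nbs_glm()]).
#' @export
nbs_lmm <- function(Y, time, subject, nuisance = NULL, p_primary = 0.01,
                    n_perm = 5000, seed = 1L, pairs = NULL, n_nodes = NULL,
                    sign_split = TRUE) {
  if (n_perm < 1) stop("n_perm must be at least 1")
  Y <- as.matrix(Y)
  subject <- factor(subject)
  if (is.null(pairs)) {
    n_nodes <- n_nodes %||% ceiling((1 + sqrt(1 + 8 * ncol(Y))) / 2)
    pairs <- upper_tri_pairs(n_nodes)[seq_len(ncol(Y)), , drop = FALSE]
  }
  n_nodes <- n_nodes %||% max(pairs)
  obs <- edgewise_lmm(Y, time, subject, nuisance)
  comps <- suprathreshold_components(obs$t, obs$p, p_primary, pairs, n_nodes,
                                     sign_split)
  t_crit <- qt(1 - p_primary / 2, obs$df)
  si <- as.integer(subject)
  S <- nlevels(subject)
  counts <- tabulate(si, S)
  means <- rowsum(Y, si) / counts
  dev <- Y - means[si, , drop = FALSE]
  X <- cbind(1, as.numeric(time))
  if (!is.null(nuisance)) X <- cbind(X, scale(as.matrix(nuisance)))
  null_max <- numeric(n_perm)
  with_seed(derive_seed(seed, "nbs_lmm"), {
    for (b in seq_len(n_perm)) {
      s <- sample(c(-1, 1), S, replace = TRUE)
      Ystar <- means[si, , drop = FALSE] + dev * s[si]
      fit <- fit_lmm_batch_cpp(Ystar, X, as.numeric(time), si - 1L, 1L)
      null_max[b] <- max_component_sum(fit$t, t_crit, pairs, n_nodes,
                                       sign_split)
    }
  })
  for (i in seq_along(comps)) {
    comps[[i]]$p_fwe <- (1 + sum(null_max >= comps[[i]]$stat_sum)) /
      (n_perm + 1)
  }
  structure(list(components = comps, t = obs$t, p = obs$p, df = obs$df,
                 p_primary = p_primary, t_crit = t_crit, n_perm = n_perm,
                 null_max = null_max, pairs = pairs, n_nodes = n_nodes,
                 flag = obs$flag, model = "lmm"),
            class = "nbs_result")
}

#' Scalar linear mixed model for a clinical or global-MRI outcome
#'
#' The same random-intercept + random-slope REML machinery as the edge-wise
#' models, applied to a single outcome series (EDSS, log(1+x)-transformed
#' TLV, z-scored BPF ...), reporting all fixed effects with Wald tests and
#' the random-effect variance components.
#'
#' @param outcome numeric outcome per observation.
#' @inheritParams edgewise_lmm
#' @return object of class `lmm_fit` with `B`, `se`, `t`, `p` (named per
#'   coefficient), `varcomp`, `df`, `flag`.
#' @export
fit_scalar_lmm <- function(outcome, time, subject, nuisance = NULL) {
  keep <- is.finite(outcome) & is.finite(time)
  outcome <- outcome[keep]; time <- time[keep]
  subject <- factor(subject[keep])
  if (!is.null(nuisance)) nuisance <- as.matrix(nuisance)[keep, , drop = FALSE]
  if (max(table(subject)) < 2)
    stop("longitudinal-data error: no subject has repeated visits")
  X <- cbind(`(Intercept)` = 1, time = as.numeric(time))
  # nuisance columns are mean-centred (coefficient scale preserved) so the
  # normal equations stay well conditioned
  if (!is.null(nuisance)) X <- cbind(X, scale(nuisance, scale = FALSE))
  fit <- fit_lmm_batch_cpp(matrix(outcome, ncol = 1), X, as.numeric(time),
                           as.integer(subject) - 1L, 1L)
  # per-coefficient Wald statistics need the full covariance; recompute SEs
  # coefficient-wise by re-calling the kernel with each contrast index
  ses <- vapply(seq_len(ncol(X)) - 1L, function(ci) {
    f <- fit_lmm_batch_cpp(matrix(outcome, ncol = 1), X, as.numeric(time),
                           as.integer(subject) - 1L, ci)
    f$se[1]
  }, 0)
  B <- drop(fit$beta)
  names(B) <- names(ses) <- colnames(X)
  tt <- B / ses
  structure(list(B = B, se = ses, t = tt, p = 2 * pt(-abs(tt), fit$df),
                 df = fit$df, flag = fit$flag[1],
                 varcomp = c(sd_intercept = fit$sd_intercept[1],
                             sd_slope = fit$sd_slope[1],
                             re_corr = fit$re_corr[1],
                             sigma2 = fit$sigma2[1])),
            class = "lmm_fit")
}

#' @export
print.lmm_fit <- function(x, ...) {
  cat("<lmm_fit>\n")
  print(data.frame(B = x$B, SE = x$se, t = x$t, p = x$p))
  invisible(x)
}
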