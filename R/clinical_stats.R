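#' Confirmed disability progression label
#'
#' CDP is an EDSS increase of at least 1 point when baseline EDSS is <= 5.5,
#' or at least 0.5 points when baseline EDSS is > 5.5 (inclusive
#' thresholds).
#'
#' @param edss_baseline,edss_followup EDSS scores on the 0-10 grid in 0.5
#'   steps.
#' @return logical.
#' @export
cdp_label <- function(edss_baseline, edss_followup) {
  for (v in c(edss_baseline, edss_followup)) {
    if (any(!is.finite(v)) || any(v < 0 | v > 10) || any(v * 2 != round(v * 2)))
      stop("EDSS values must lie on the 0-10 half-point grid")
  }
  ifelse(edss_baseline <= 5.5,
         edss_followup - edss_baseline >= 1,
         edss_followup - edss_baseline >= 0.5)
}

#' Age- and sex-adjusted brain parenchymal fraction z-score
#'
#' BPF = brain volume / intracranial volume.  A linear age + sex model is
#' fitted on the healthy-control reference; z-scores are deviations from the
#' fitted HC prediction divided by the HC residual SD, so the HC
#' distribution has mean 0 and SD ~1 by construction.
#'
#' @param brain_vol,icv volumes (same units); `icv` must be positive.
#' @param age,sex covariates of the scored subject(s); sex coded "F"/"M" (or
#'   0/1).
#' @param hc_reference data.frame with columns `brain_vol`, `icv`, `age`,
#'   `sex` for at least 10 healthy controls.
#' @return numeric z-score(s).
#' @export
bpf_z <- function(brain_vol, icv, age, sex, hc_reference) {
  if (any(icv <= 0)) stop("icv must be positive")
  if (nrow(hc_reference) < 10)
    stop("reference error: need >= 10 healthy controls")
  code_sex <- function(s) if (is.numeric(s)) s else as.integer(s == "M")
  hc <- data.frame(bpf = hc_reference$brain_vol / hc_reference$icv,
                   age = hc_reference$age, sex = code_sex(hc_reference$sex))
  fit <- lm(bpf ~ age + sex, data = hc)
  sd_res <- sqrt(sum(fit$residuals^2) / fit$df.residual)
  if (!is.finite(sd_res) || sd_res < 1e-12)
    stop("reference error: degenerate healthy-control reference")
  newd <- data.frame(age = age, sex = code_sex(sex))
  (brain_vol / icv - predict(fit, newd)) / sd_res
}

#' Absolute z-score summary of a subnetwork
#'
#' z-scores each component edge of a subject's matrix against the
#' healthy-population reference (per-edge HC mean and SD) and averages the
#' absolute z-values, quantifying overall deviation from the healthy norm
#' without letting effects of opposite sign cancel.  Edges with zero
#' reference SD are excluded with a warning.
#'
#' @param subject_matrix subject [conn_matrix] or plain symmetric matrix.
#' @param reference list with `mean` and `sd` matrices (from
#'   [reference_stats()]).
#' @param component two-column matrix of node index pairs (a component edge
#'   list).
#' @return nonnegative scalar summary.
#' @export
component_zscore_summary <- function(subject_matrix, reference, component) {
  v <- if (inherits(subject_matrix, "conn_matrix")) subject_matrix$values
    else as.matrix(subject_matrix)
  idx <- cbind(component[, 1], component[, 2])
  mu <- reference$mean[idx]; sdv <- reference$sd[idx]
  bad <- sdv <= 0 | !is.finite(sdv)
  if (any(bad)) {
    warning(sprintf("excluding %d component edge(s) with zero reference SD",
                    sum(bad)))
    if (all(bad)) return(NA_real_)
  }
  mean(abs((v[idx][!bad] - mu[!bad]) / sdv[!bad]))
}

#' Per-edge reference statistics from a healthy population
#'
#' @param matrices list of [conn_matrix] (or plain matrices) from the
#'   reference group.
#' @return list with `mean` and `sd` matrices.
#' @export
reference_stats <- function(matrices) {
  vals <- lapply(matrices, function(m)
    if (inherits(m, "conn_matrix")) m$values else as.matrix(m))
  arr <- simplify2array(vals)
  list(mean = apply(arr, c(1, 2), mean), sd = apply(arr, c(1, 2), sd))
}

#' Annualized change
#'
#' @param x_t1,x_t2 values at the two visits.
#' @param years elapsed time, strictly positive.
#' @return change per year.
#' @export
annualized_change <- function(x_t1, x_t2, years) {
  if (any(years <= 0)) stop("years must be positive")
  (x_t2 - x_t1) / years
}

#' Spearman rank correlation (with ties by average ranks)
#'
#' @param x,y numeric vectors, n >= 4.
#' @return list with `rho` and `p` (t-approximation, two-sided).
#' @export
spearman <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 4) stop("need at least 4 paired observations")
  if (sd(x) == 0 || sd(y) == 0)
    stop("undefined correlation: constant vector")
  rho <- cor(rank(x), rank(y))
  tt <- rho * sqrt((n - 2) / pmax(1 - rho^2, 1e-15))
  list(rho = rho, p = 2 * pt(-abs(tt), n - 2))
}

#' Partial Spearman correlation via rank residuals
#'
#' Ranks all three variables, removes the ranked covariate(s) from the
#' ranked x and y by linear regression, and correlates the residuals.
#'
#' @param x,y numeric vectors.
#' @param z covariate vector or matrix to partial out.
#' @return list with `rho` and `p`.
#' @export
partial_spearman <- function(x, y, z) {
  z <- as.matrix(z)
  ok <- is.finite(x) & is.finite(y) & apply(is.finite(z), 1, all)
  x <- x[ok]; y <- y[ok]; z <- z[ok, , drop = FALSE]
  n <- length(x)
  if (n < 4) stop("need at least 4 paired observations")
  if (sd(x) == 0 || sd(y) == 0) stop("undefined correlation: constant vector")
  rz <- apply(z, 2, rank)
  rx <- lm.fit(cbind(1, rz), rank(x))$residuals
  ry <- lm.fit(cbind(1, rz), rank(y))$residuals
  rho <- cor(rx, ry)
  df <- n - 2 - ncol(z)
  tt <- rho * sqrt(df / pmax(1 - rho^2, 1e-15))
  list(rho = rho, p = 2 * pt(-abs(tt), df))
}

#' Two-group comparison tests
#'
#' Welch's t test (unequal variances, Satterthwaite degrees of freedom)
#' computable either from raw values or directly from printed summary
#' statistics (mean, SD, n per group), and Pearson's chi-square test
#' (without continuity correction) for 2x2 counts.
#'
#' @param mean1,sd1,n1,mean2,sd2,n2 summary statistics per group.
#' @return list with `statistic`, `df`, `p`.
#' @export
welch_t_summary <- function(mean1, sd1, n1, mean2, sd2, n2) {
  if (n1 < 2 || n2 < 2) stop("sample-size error: need n >= 2 per group")
  v1 <- sd1^2 / n1; v2 <- sd2^2 / n2
  tt <- (mean1 - mean2) / sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  list(statistic = tt, df = df, p = 2 * pt(-abs(tt), df))
}

#' @rdname welch_t_summary
#' @param x,y raw values per group.
#' @export
welch_t_raw <- function(x, y) {
  welch_t_summary(mean(x), sd(x), length(x), mean(y), sd(y), length(y))
}

#' @rdname welch_t_summary
#' @param counts 2x2 contingency matrix (e.g. sex by group).
#' @export
chisq_counts <- function(counts) {
  counts <- as.matrix(counts)
  ht <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value)
}

#' Invert SDMT z-scores
#'
#' Flips the sign of demographically adjusted SDMT z-scores so that higher
#' values reflect poorer information-processing speed, consistent with the
#' direction of EDSS.
#'
#' @param z numeric z-score(s).
#' @return `-z`.
#' @export
invert_sdmt <- function(z) -z
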