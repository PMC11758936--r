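test_that("CDP rule: inclusive thresholds on both sides of EDSS 5.5", {
  expect_true(cdp_label(5.5, 6.5))
  expect_true(cdp_label(6.0, 6.5))
  expect_false(cdp_label(3.0, 3.5))
  expect_false(cdp_label(2.0, 2.5))
  expect_false(cdp_label(4.0, 3.0))
  expect_true(cdp_label(2.0, 3.0))
  expect_error(cdp_label(3.25, 4), "grid")
  expect_error(cdp_label(3, 11), "grid")
})

test_that("BPF z-scores are standard normal in the reference and negative in atrophy", {
  set.seed(1)
  n <- 200
  hc <- data.frame(age = runif(n, 20, 70), sex = sample(c("F", "M"), n, TRUE))
  hc$icv <- rnorm(n, 1.5e6, 1e5)
  bpf <- 0.85 - 0.0015 * (hc$age - 40) - 0.004 * (hc$sex == "M") +
    rnorm(n, 0, 0.012)
  hc$brain_vol <- bpf * hc$icv
  z_hc <- bpf_z(hc$brain_vol, hc$icv, hc$age, hc$sex, hc)
  expect_lt(abs(mean(z_hc)), 0.05)
  expect_lt(abs(sd(z_hc) - 1), 0.05)
  # a subject exactly at the reference prediction scores 0
  pred_bpf <- 0.85 - 0.0015 * (45 - 40)
  fit_pred <- bpf_z((pred_bpf) * 1.5e6, 1.5e6, 45, "F", hc)
  expect_lt(abs(fit_pred), 0.2) # within the reference fit noise
  # synthetic patients with atrophy
  z_pat <- bpf_z((bpf[1:50] - 0.03) * hc$icv[1:50], hc$icv[1:50],
                 hc$age[1:50], hc$sex[1:50], hc)
  expect_lt(mean(z_pat), -1)
  expect_error(bpf_z(1e6, 0, 40, "F", hc), "positive")
  expect_error(bpf_z(1e6, 1.5e6, 40, "F", hc[1:5, ]), "reference")
})

test_that("component z-score summary: absolute values, brute-force match, exclusions", {
  set.seed(2)
  n <- 6
  ref_mats <- lapply(1:20, function(i) {
    v <- matrix(rnorm(n * n), n); v <- (v + t(v)) / 2; diag(v) <- 0; v
  })
  ref <- reference_stats(ref_mats)
  comp <- rbind(c(1, 2), c(2, 3), c(4, 5))
  # subject at the reference mean everywhere -> 0
  expect_equal(component_zscore_summary(ref$mean, ref, comp), 0)
  # two edges at z = +2 and -2 -> summary 2
  ref2 <- list(mean = matrix(0, 3, 3), sd = matrix(1, 3, 3))
  subj <- matrix(0, 3, 3)
  subj[1, 2] <- subj[2, 1] <- 2
  subj[2, 3] <- subj[3, 2] <- -2
  expect_equal(component_zscore_summary(subj, ref2, rbind(c(1, 2), c(2, 3))),
               2)
  # random subject equals an explicit edge loop
  sv <- ref_mats[[1]]
  manual <- mean(vapply(seq_len(nrow(comp)), function(k)
    abs((sv[comp[k, 1], comp[k, 2]] - ref$mean[comp[k, 1], comp[k, 2]]) /
          ref$sd[comp[k, 1], comp[k, 2]]), 0))
  expect_equal(component_zscore_summary(sv, ref, comp), manual)
  # translation/scale equivariance with the reference
  shift <- 3; scl <- 2
  ref_shift <- list(mean = ref$mean * scl + shift, sd = ref$sd * scl)
  expect_equal(component_zscore_summary(sv * scl + shift, ref_shift, comp),
               component_zscore_summary(sv, ref, comp), tolerance = 1e-12)
  # zero reference SD edges are excluded with a warning
  ref0 <- ref; ref0$sd[1, 2] <- ref0$sd[2, 1] <- 0
  expect_warning(z0 <- component_zscore_summary(sv, ref0, comp),
                 "zero reference SD")
  manual0 <- mean(vapply(2:3, function(k)
    abs((sv[comp[k, 1], comp[k, 2]] - ref$mean[comp[k, 1], comp[k, 2]]) /
          ref$sd[comp[k, 1], comp[k, 2]]), 0))
  expect_equal(z0, manual0)
})

test_that("annualized change arithmetic and domain", {
  expect_equal(annualized_change(2, 3, 2), 0.5)
  expect_equal(annualized_change(2, 2, 5), 0)
  expect_error(annualized_change(1, 2, 0), "positive")
})

test_that("Spearman and partial Spearman behave correctly", {
  x <- 1:20
  expect_equal(spearman(x, x^3)$rho, 1)
  expect_error(spearman(rep(1, 10), 1:10), "constant")
  expect_error(spearman(1:3, 3:1), "at least 4")
  # a confound-induced correlation is removed by partialling
  set.seed(3)
  z <- rnorm(500)
  x <- z + rnorm(500, 0, 1)
  y <- z + rnorm(500, 0, 1)
  expect_gt(spearman(x, y)$rho, 0.3)
  expect_lt(abs(partial_spearman(x, y, z)$rho), 0.1)
  # null p-values roughly uniform over replicates
  ps <- vapply(1:200, function(r) {
    set.seed(400 + r)
    spearman(rnorm(30), rnorm(30))$p
  }, 0)
  # rank ties across replicates duplicate some p-values; the KS statistic
  # is still informative
  expect_gt(suppressWarnings(stats::ks.test(ps, "punif")$p.value), 0.01)
})

test_that("Welch t from summaries equals Welch t from raw data; chi-square matches", {
  # construct samples with exact moments
  mk <- function(n, m, s) {
    x <- rnorm(n); s * (x - mean(x)) / sd(x) + m
  }
  x <- mk(30, 5, 2); y <- mk(45, 4, 3)
  ws <- welch_t_summary(5, 2, 30, 4, 3, 45)
  wr <- welch_t_raw(x, y)
  expect_equal(ws$statistic, wr$statistic, tolerance = 1e-12)
  expect_equal(ws$df, wr$df, tolerance = 1e-10)
  bt <- t.test(x, y)
  expect_equal(wr$statistic, unname(bt$statistic), tolerance = 1e-10)
  expect_equal(wr$p, bt$p.value, tolerance = 1e-10)
  # equal groups -> t = 0, p = 1
  we <- welch_t_summary(3, 1, 10, 3, 1, 10)
  expect_equal(we$statistic, 0)
  expect_equal(we$p, 1)
  expect_error(welch_t_summary(1, 1, 1, 2, 1, 10), "sample-size")
  cs <- chisq_counts(matrix(c(25, 324, 30, 137), 2))
  expect_equal(cs$df, 1)
  expect_lt(cs$p, 0.001)
  expect_equal(invert_sdmt(-1.1), 1.1)
  expect_equal(invert_sdmt(invert_sdmt(0.7)), 0.7)
})

test_that("coupling: identity, null, zero-exclusion and relabeling invariance", {
  set.seed(4)
  n <- 20
  nt <- data.frame(id = 1:n, name = sprintf("R%02d", 1:n),
                   system = rep(c("VIS", "SM", "DAN", "VAN"), 5))
  mk_cm <- function(v, kind, smask = NULL)
    conn_matrix(v, nt$id, nt$system, kind, structural_mask = smask)
  rnd_sym <- function(lo = 0, hi = 1) {
    v <- matrix(runif(n * n, lo, hi), n); v <- (v + t(v)) / 2; diag(v) <- 0; v
  }
  # identical profiles -> node coupling 1 everywhere
  v <- rnd_sym()
  d <- mk_cm(v, "disconnection")
  vs <- pmin(v + 0.001, 1); diag(vs) <- 0
  s <- mk_cm(vs, "similarity") # same ordering of profiles
  nodecp <- coupling(list(d), list(s), "node")
  expect_true(all(abs(nodecp$rho - 1) < 1e-12))
  # independent random matrices -> near-zero mean coupling
  rhos <- replicate(3, {
    d2 <- mk_cm(rnd_sym(), "disconnection")
    s2 <- mk_cm(rnd_sym(0.01, 1), "similarity")
    mean(abs(coupling(list(d2), list(s2), "node")$rho), na.rm = TRUE)
  })
  expect_lt(mean(rhos), 0.25) # |rho| of 19-point profiles is noisy but small
  # exclude_zero_disconnection removes exactly mask-false plus zero edges
  v3 <- rnd_sym()
  smask <- matrix(TRUE, n, n); diag(smask) <- FALSE
  smask[1, 2] <- smask[2, 1] <- FALSE
  v3[1, 2] <- v3[2, 1] <- 0
  v3[3, 4] <- v3[4, 3] <- 0 # zero but structurally connected
  d3 <- mk_cm(v3, "disconnection", smask)
  s3 <- mk_cm(rnd_sym(0.01, 1), "similarity")
  ce_all <- coupling(list(d3), list(s3), "edge")
  ce_ex <- coupling(list(d3), list(s3), "edge",
                    exclude_zero_disconnection = TRUE)
  expect_equal(ce_all$n - ce_ex$n, 2)
  # simultaneous node relabeling leaves node coupling unchanged
  perm <- sample(n)
  ntp <- nt[perm, ]
  dp <- conn_matrix(v[perm, perm], ntp$id, ntp$system, "disconnection")
  sp <- conn_matrix(vs[perm, perm], ntp$id, ntp$system, "similarity")
  cp <- coupling(list(dp), list(sp), "node")
  expect_equal(cp$rho[match(nodecp$node, cp$node)], nodecp$rho,
               tolerance = 1e-12)
  # bounds
  cg <- coupling(lapply(1:6, function(i) mk_cm(rnd_sym(), "disconnection")),
                 lapply(1:6, function(i) mk_cm(rnd_sym(0.01, 1),
                                               "similarity")), "global")
  expect_true(abs(cg$rho) <= 1)
})

test_that("median split assigns the median subject to the shorter group", {
  set.seed(5)
  n <- 5
  nt <- data.frame(id = 1:6, name = sprintf("R%d", 1:6),
                   system = rep("VIS", 6))
  mk <- function() {
    v <- matrix(runif(36), 6); v <- (v + t(v)) / 2; diag(v) <- 0
    conn_matrix(v, nt$id, nt$system, "disconnection")
  }
  mks <- function() {
    v <- matrix(runif(36, 0.01, 1), 6); v <- (v + t(v)) / 2; diag(v) <- 0
    conn_matrix(v, nt$id, nt$system, "similarity")
  }
  disc <- lapply(1:9, function(i) mk())
  sim <- lapply(1:9, function(i) mks())
  dd <- 1:9
  out <- coupling_by_duration(disc, sim, dd, scale = "global")
  expect_equal(out$median, 5)
  expect_equal(out$shorter$n, 5) # subjects 1..5 (median inclusive)
  expect_equal(out$longer$n, 4)
})
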