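upper_tri_pairs_test <- function(n) {
  which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
}

test_that("vectorize/devectorize round-trip and masking", {
  set.seed(1)
  v <- matrix(rnorm(16), 4); v <- v + t(v); diag(v) <- 0
  ev <- vectorize_edges(v)
  expect_length(ev$values, choose(4, 2))
  expect_equal(devectorize_edges(ev$values, ev), v)
  mask <- matrix(TRUE, 4, 4); mask[1, 2] <- mask[2, 1] <- FALSE
  ev2 <- vectorize_edges(v, mask)
  back <- devectorize_edges(ev2$values, ev2)
  expect_equal(back[1, 2], 0)
  expect_equal(back[3, 4], v[3, 4])
  expect_error(vectorize_edges(matrix(rnorm(16), 4)), "symmetric")
})

test_that("edgewise GLM matches the closed-form t and calibrates under the null", {
  set.seed(2)
  n <- 30
  x <- rnorm(n); y <- 0.5 * x + rnorm(n)
  des <- make_design(data.frame(x = x), "x")
  fit <- edgewise_glm(matrix(y, ncol = 1), des)
  r <- cor(x, y)
  expect_equal(fit$t[1], r * sqrt((n - 2) / (1 - r^2)), tolerance = 1e-10)
  # constant variable of interest is inestimable
  expect_error(make_design(data.frame(x = rep(1, n)), "x"),
               "rank-deficient")
  # null p-values approximately uniform
  Y <- random_edges(40, 1000, seed = 3)
  des2 <- make_design(data.frame(x = rnorm(40)), "x")
  p <- edgewise_glm(Y, des2)$p
  expect_gt(stats::ks.test(p, "punif")$p.value, 0.01)
})

test_that("suprathreshold components agree with a union-find oracle", {
  expect_length(suprathreshold_components(numeric(0), numeric(0), 0.01,
                                          matrix(0, 0, 2), 5), 0)
  # chain a-b, b-c -> one 2-edge component
  comps <- suprathreshold_components(c(3, 3), c(0.001, 0.001), 0.01,
                                     rbind(c(1, 2), c(2, 3)), 3)
  expect_length(comps, 1)
  expect_equal(comps[[1]]$n_edges, 2)
  expect_equal(comps[[1]]$stat_sum, 6)
  expect_error(suprathreshold_components(1, 0.5, 1.2, cbind(1, 2), 2),
               "p_primary")
  set.seed(4)
  for (rep in 1:20) {
    n <- 8
    pairs <- upper_tri_pairs_test(n)
    tstat <- rnorm(nrow(pairs), 0, 2)
    p <- 2 * pnorm(-abs(tstat))
    comps <- suprathreshold_components(tstat, p, 0.2, pairs, n,
                                       sign_split = FALSE)
    sel <- which(p < 0.2)
    if (!length(sel)) {
      expect_length(comps, 0)
      next
    }
    memb <- uf_components(pairs[sel, , drop = FALSE], n)
    oracle_sizes <- sort(as.vector(table(memb[pairs[sel, 1]])))
    expect_equal(sort(vapply(comps, `[[`, 0L, "n_edges")), oracle_sizes)
    # total suprathreshold stat mass conserved across components
    expect_equal(sum(vapply(comps, `[[`, 0, "stat_sum")),
                 sum(abs(tstat[sel])))
  }
})

test_that("nbs_glm invariants: permutation bounds, zero nuisance, edge order, perm doubling", {
  Y <- random_edges(40, 45, seed = 5)
  x <- rep(0:1, 20)
  des <- make_design(data.frame(x = x), "x")
  expect_error(nbs_glm(Y, des, n_perm = 0), "at least 1")
  r <- nbs_glm(Y, des, p_primary = 0.2, n_perm = 99, seed = 7, n_nodes = 10)
  for (co in r$components) {
    expect_gte(co$p_fwe, 1 / 100)
    expect_lte(co$p_fwe, 1)
  }
  # all-zero nuisance columns equal the unadjusted analysis exactly
  des0 <- make_design(data.frame(x = x, z1 = 0, z2 = 0), "x",
                      nuisance = c("z1", "z2"))
  r0 <- nbs_glm(Y, des0, p_primary = 0.2, n_perm = 99, seed = 7,
                n_nodes = 10)
  expect_equal(r$t, r0$t)
  expect_equal(r$null_max, r0$null_max)
  # edge reordering permutes edge stats consistently
  perm <- sample(ncol(Y))
  pairs <- upper_tri_pairs_test(10)
  rp <- nbs_glm(Y[, perm], des, p_primary = 0.2, n_perm = 9, seed = 7,
                pairs = pairs[perm, ], n_nodes = 10)
  expect_equal(rp$t, r$t[perm])
  # doubling permutations changes only p_fwe precision, not the components
  r2 <- nbs_glm(Y, des, p_primary = 0.2, n_perm = 198, seed = 7,
                n_nodes = 10)
  expect_equal(lapply(r$components, `[[`, "edge_idx"),
               lapply(r2$components, `[[`, "edge_idx"))
})

test_that("TLV adjustment removes a global shift but keeps a focal component", {
  set.seed(6)
  n <- 80
  n_nodes <- 12
  pairs <- upper_tri_pairs_test(n_nodes)
  E <- nrow(pairs)
  tlv <- rnorm(n)
  grp <- rep(0:1, n / 2)
  # a global, TLV-mediated shift on every edge ...
  Y <- matrix(rnorm(n * E), n, E) + outer(0.8 * tlv + 0.8 * grp, rep(1, E))
  # ... plus a focal component beyond the global burden
  focal <- which(pairs[, 1] <= 4 & pairs[, 2] <= 5)
  Y[, focal] <- Y[, focal] + outer(1.2 * grp, rep(1, length(focal)))
  tlv <- tlv + 0.8 * grp # lesion burden itself differs by group
  des_un <- make_design(data.frame(g = grp), "g")
  des_ad <- make_design(data.frame(g = grp, tlv = tlv), "g", "tlv")
  r_un <- nbs_glm(Y, des_un, 0.01, 99, seed = 8, pairs = pairs,
                  n_nodes = n_nodes)
  r_ad <- nbs_glm(Y, des_ad, 0.01, 99, seed = 8, pairs = pairs,
                  n_nodes = n_nodes)
  # unadjusted: distributed effect spanning most edges
  expect_gt(r_un$components[[1]]$n_edges, length(focal) * 2)
  # adjusted: a significant component focused on the planted edges
  expect_true(length(r_ad$components) > 0)
  top <- r_ad$components[[1]]
  expect_lt(top$p_fwe, 0.05)
  expect_gte(edge_jaccard(top$pairs, pairs[focal, , drop = FALSE], n_nodes),
             0.5)
})

test_that("edgewise LMM agrees with lme4 and the OLS limit", {
  skip_if_not_installed("lme4")
  set.seed(9)
  S <- 30; ni <- 4
  subj <- rep(seq_len(S), each = ni)
  tim <- rep(seq(0, 3, length.out = ni), S)
  b0 <- rnorm(S, 0, 0.4); b1 <- rnorm(S, 0, 0.08)
  Y <- vapply(1:3, function(e)
    0.5 + 0.1 * tim + b0[subj] + b1[subj] * tim + rnorm(S * ni, 0, 0.15),
    numeric(S * ni))
  fit <- edgewise_lmm(Y, tim, subj)
  for (e in 1:3) {
    m <- lme4::lmer(y ~ tim + (1 + tim | s),
                    data = data.frame(y = Y[, e], tim = tim, s = subj),
                    REML = TRUE)
    expect_equal(fit$B[e], unname(lme4::fixef(m)["tim"]), tolerance = 1e-4)
    expect_equal(fit$se[e], summary(m)$coefficients["tim", 2],
                 tolerance = 1e-3)
  }
  # balanced data with zero random-effect variance -> matches pooled OLS
  set.seed(10)
  y_ols <- 1 + 0.2 * tim + rnorm(S * ni, 0, 0.3)
  f2 <- edgewise_lmm(matrix(y_ols, ncol = 1), tim, subj)
  ols <- lm(y_ols ~ tim)
  expect_equal(f2$B[1], unname(coef(ols)["tim"]), tolerance = 0.02)
  expect_error(edgewise_lmm(matrix(rnorm(5), ncol = 1), 1:5, 1:5),
               "longitudinal-data")
})

test_that("scalar LMM: exact interpolation and flat-trajectory null", {
  # two noise-free points per subject -> slope exact
  subj <- rep(1:10, each = 2)
  tim <- rep(c(0, 2), 10)
  y <- 1 + 0.3 * tim + rep(rnorm(10, 0, 0.5), each = 2)
  fit <- fit_scalar_lmm(y, tim, subj)
  expect_equal(unname(fit$B["time"]), 0.3, tolerance = 1e-6)
  # flat trajectories -> slope ~ 0, usually nonsignificant
  ns <- vapply(1:40, function(r) {
    set.seed(100 + r)
    yy <- rep(rnorm(10), each = 2) + rnorm(20, 0, 0.2)
    f <- fit_scalar_lmm(yy, tim, subj)
    f$p["time"] > 0.05
  }, TRUE)
  expect_gte(mean(ns), 0.85)
})

test_that("nbs_lmm: errors and null calibration at a liberal threshold", {
  subj <- rep(1:20, each = 3)
  tim <- rep(0:2, 20)
  Y <- random_edges(60, 15, seed = 11)
  expect_error(nbs_lmm(Y, tim, subj, n_perm = 0), "at least 1")
  expect_error(nbs_lmm(Y[1:20, ], rep(0, 20), 1:20, n_perm = 9),
               "longitudinal-data")
  # null longitudinal data: significant components are rare
  sig <- vapply(1:15, function(r) {
    Yr <- random_edges(60, 15, seed = 200 + r)
    res <- nbs_lmm(Yr, tim, subj, p_primary = 0.05, n_perm = 49,
                   seed = r, n_nodes = 6)
    length(res$components) > 0 && res$components[[1]]$p_fwe < 0.05
  }, TRUE)
  expect_lte(mean(sig), 0.2)
})

test_that("nbs_lmm recovers a planted progressive component end-to-end", {
  pe <- default_planted_edges(24, hub = 3L)
  hits <- vapply(1:8, function(rep) {
    cfg <- small_cfg(seed = 900 + rep, n_patients = 40, n_controls = 0,
                     visits_per_subject = c(3, 3), new_lesion_rate = 0,
                     planted_disconnection_component =
                       list(edges = pe, effect = 0.3, progression = 0.6))
    co <- simulate_cohort(cfg, compute_mind = FALSE)
    ch <- co$cohort[co$cohort$group == "patient", ]
    st <- stack_conn_matrices(
      co$disconnection[sprintf("%s_v%d", ch$subject, ch$visit)])
    r <- nbs_lmm(st$Y, ch$followup_time, ch$subject, p_primary = 0.01,
                 n_perm = 99, seed = 3, pairs = st$pairs, n_nodes = 24)
    length(r$components) > 0 && r$components[[1]]$p_fwe < 0.05 &&
      edge_jaccard(r$components[[1]]$pairs, pe, 24) >= 0.5
  }, TRUE)
  expect_gte(mean(hits), 0.8)
})
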