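test_that("parcellation hosts the requested regions, contiguous and labeled", {
  cfg <- sim_config(seed = 3)
  parc <- make_parcellation(cfg)
  counts <- tabulate(parc$labels, 114)
  expect_length(counts, 114)
  expect_true(all(counts > 0))
  expect_setequal(unique(parc$node_table$system),
                  c("VIS", "SM", "DAN", "VAN", "limbic", "CONT", "DMN",
                    "SUBC"))
  expect_equal(sum(parc$node_table$system == "SUBC"), 14)
  # labels partition the nonzero voxels
  expect_equal(sum(counts), sum(parc$labels > 0))
  # every region 6-connected
  lf <- as.vector(parc$labels)
  contig <- vapply(seq_len(114), function(l)
    msconnectome:::is_contiguous(which(lf == l), parc$grid_shape), TRUE)
  expect_true(all(contig))
})

test_that("parcellation minimal and error cases", {
  cfg2 <- sim_config(n_cortical = 2, n_subcortical = 0, seed = 1)
  parc2 <- make_parcellation(cfg2)
  expect_setequal(unique(as.vector(parc2$labels))[unique(as.vector(parc2$labels)) > 0],
                  1:2)
  expect_error(make_parcellation(sim_config(grid_shape = c(6L, 6L, 6L),
                                            seed = 1)),
               "too small")
})

test_that("streamline atlas endpoints lie inside their regions", {
  cfg <- small_cfg(seed = 5)
  parc <- make_parcellation(cfg)
  atlas <- make_streamline_atlas(parc, cfg)
  lf <- parc$labels
  ok <- vapply(atlas$streamlines, function(sl) {
    p1 <- floor(sl$points[1, ]) + 1L
    p2 <- floor(sl$points[nrow(sl$points), ]) + 1L
    lf[p1[1], p1[2], p1[3]] == sl$pair[1] &&
      lf[p2[1], p2[2], p2[3]] == sl$pair[2]
  }, TRUE)
  expect_true(all(ok))
  # each connected pair carries exactly streamlines_per_pair streamlines
  expect_true(all(table(atlas$pair_index) == cfg$streamlines_per_pair))
})

test_that("atlas degenerate cases: empty and complete", {
  cfg0 <- small_cfg(seed = 2, streamlines_per_pair = 0)
  parc <- make_parcellation(cfg0)
  expect_length(make_streamline_atlas(parc, cfg0)$streamlines, 0)
  cfg1 <- sim_config(n_cortical = 6, n_subcortical = 0,
                     connected_pair_fraction = 1, streamlines_per_pair = 2,
                     seed = 2)
  parc1 <- make_parcellation(cfg1)
  atlas1 <- make_streamline_atlas(parc1, cfg1)
  expect_equal(nrow(atlas1$pairs), choose(6, 2))
})

test_that("lesion model: severity trend, periventricular bias, empty case", {
  cfg <- small_cfg(seed = 8)
  parc <- make_parcellation(cfg)
  expect_error(make_lesions(-1, parc, cfg), "nonnegative")
  cfg0 <- small_cfg(seed = 8, lesion_rate = 0, new_lesion_rate = 0)
  expect_equal(total_lesion_volume(make_lesions(0, parc, cfg0)), 0)
  # mean TLV strictly increasing in severity over repeated draws
  sev <- c(0, 1, 3)
  mt <- vapply(sev, function(sv) {
    mean(vapply(1:70, function(i)
      total_lesion_volume(make_lesions(sv, parc, cfg, subject_id = i)), 0))
  }, 0)
  expect_true(all(diff(mt) > 0))
  # periventricular bias pulls lesion centres towards the grid centre
  ctr <- parc$grid_shape / 2
  mean_dist <- function(cfgx) {
    d <- vapply(1:50, function(i) {
      m <- make_lesions(1, parc, cfgx, subject_id = i)
      idx <- which(m$data == 1L)
      if (!length(idx)) return(NA_real_)
      i0 <- idx - 1L
      xyz <- cbind(i0 %% m$grid_shape[1] + 0.5,
                   (i0 %/% m$grid_shape[1]) %% m$grid_shape[2] + 0.5,
                   i0 %/% (m$grid_shape[1] * m$grid_shape[2]) + 0.5)
      mean(sqrt(colSums((t(xyz) - ctr)^2)))
    }, 0)
    mean(d, na.rm = TRUE)
  }
  d_bias <- mean_dist(small_cfg(seed = 8, periventricular_bias = 0.8))
  d_none <- mean_dist(small_cfg(seed = 8, periventricular_bias = 0))
  expect_lt(d_bias, d_none)
})

test_that("vertex features: 5 columns, template identity, planted shift", {
  cfg <- sim_config(n_cortical = 10, n_subcortical = 0,
                    vertices_per_region = 50, seed = 4)
  parc <- make_parcellation(cfg)
  vf <- make_vertex_features(parc, cfg, subject_id = 1)
  expect_true(all(vapply(vf$features, ncol, 0L) == 5))
  expect_error(make_vertex_features(
    parc, sim_config(n_cortical = 10, n_subcortical = 0,
                     vertices_per_region = 1, seed = 4), 1),
    "degenerate")
  # zero subject noise -> every subject's MIND equals the template MIND
  m1 <- mind_matrix(make_vertex_features(parc, cfg, 1, subject_noise_sd = 0),
                    node_table = parc$node_table)
  m2 <- mind_matrix(make_vertex_features(parc, cfg, 2, subject_noise_sd = 0),
                    node_table = parc$node_table)
  expect_equal(m1$values, m2$values, tolerance = 1e-12)
  # planted negative effect lowers the group mean on the planted edge
  cfgp <- sim_config(n_cortical = 10, n_subcortical = 0,
                     vertices_per_region = 50, seed = 4,
                     planted_similarity_component =
                       list(edges = cbind(2, 5), effect = -0.6))
  vals <- vapply(1:40, function(i) {
    pat <- mind_matrix(make_vertex_features(parc, cfgp, i, group = "patient"),
                       node_table = parc$node_table)$values[2, 5]
    ctl <- mind_matrix(make_vertex_features(parc, cfgp, i, group = "control"),
                       node_table = parc$node_table)$values[2, 5]
    c(pat, ctl)
  }, c(0, 0))
  expect_lt(mean(vals[1, ]), mean(vals[2, ]))
})

test_that("clinical generator: EDSS grid, CDP consistency, null coupling", {
  cfg <- sim_config(n_patients = 60, n_controls = 20, seed = 9)
  subs <- simulate_subjects(cfg)
  ch <- make_clinical(subs, cfg)
  pw <- ch[ch$group == "patient", ]
  expect_true(all(pw$EDSS %in% seq(0, 10, by = 0.5)))
  expect_true(all(pw$followup_time >= 0))
  base <- pw[pw$visit == 1, ]
  expect_true(all(base$followup_longterm >= 5 & base$followup_longterm <= 17))
  # CDP label agrees with the rule applied to its own generated pair
  expect_equal(base$CDP,
               cdp_label(base$EDSS, base$edss_longterm))
  # cdp_effect = 0 decouples CDP from the planted score
  cfg0 <- sim_config(n_patients = 500, n_controls = 0, cdp_effect = 0,
                     seed = 10)
  subs0 <- simulate_subjects(cfg0)
  sc <- rnorm(500)
  ch0 <- make_clinical(subs0, cfg0, planted_score = sc)
  b0 <- ch0[ch0$visit == 1, ]
  expect_lt(abs(cor(sc, as.numeric(b0$CDP), method = "spearman")), 0.1)
})

test_that("generator is bit-deterministic under a fixed seed", {
  cfg <- sim_config(n_patients = 4, n_controls = 2, n_cortical = 12,
                    n_subcortical = 2, connected_pair_fraction = 0.4,
                    vertices_per_region = 50, seed = 77)
  co1 <- simulate_cohort(cfg, compute_mind = TRUE, keep_masks = TRUE)
  co2 <- simulate_cohort(cfg, compute_mind = TRUE, keep_masks = TRUE)
  expect_identical(co1$cohort, co2$cohort)
  expect_identical(lapply(co1$masks, `[[`, "data"),
                   lapply(co2$masks, `[[`, "data"))
  expect_identical(lapply(co1$disconnection, `[[`, "values"),
                   lapply(co2$disconnection, `[[`, "values"))
  expect_identical(lapply(co1$mind, `[[`, "values"),
                   lapply(co2$mind, `[[`, "values"))
})
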