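v2lin <- function(vox, g) vox[, 1] + g[1] * (vox[, 2] + g[2] * vox[, 3])

test_that("voxelize_streamline handles degenerate, axis-aligned and reversed input", {
  g <- c(10L, 10L, 10L)
  # single point -> its containing voxel
  expect_equal(voxelize_streamline(matrix(c(2.5, 3.5, 4.5), 1), g),
               cbind(2L, 3L, 4L))
  # axis-aligned segment through 5 voxel centres
  seg <- rbind(c(0.5, 5.5, 5.5), c(4.5, 5.5, 5.5))
  v <- voxelize_streamline(seg, g)
  expect_equal(v[order(v[, 1]), , drop = FALSE],
               cbind(0:4, 5L, 5L))
  # dense-sampling oracle agreement on random polylines
  set.seed(11)
  for (i in 1:20) {
    pts <- matrix(runif(9, 0.2, 9.8), 3)
    lin <- sort(1L + v2lin(voxelize_streamline(pts, g), g))
    expect_equal(lin, sort(dense_voxels(pts, g)))
    # reversal symmetry
    lin_r <- sort(1L + v2lin(voxelize_streamline(pts[3:1, ], g), g))
    expect_equal(lin, lin_r)
  }
  expect_error(voxelize_streamline(matrix(c(-1, 2, 2), 1), g), "bounds")
})

test_that("disconnection_matrix matches hand-computed toy cases", {
  g <- c(10L, 10L, 10L)
  nt <- toy_node_table(3)
  # pair (1,2): 4 straight streamlines at different y rows
  sls <- lapply(1:4, function(k)
    list(pair = c(1L, 2L), points = rbind(c(0.5, k + 0.5, 1.5),
                                          c(8.5, k + 0.5, 1.5))))
  atlas <- toy_atlas(sls, g)
  # lesion covering rows y=1,2 at x=4 -> intersects streamlines 1 and 2
  les <- toy_mask(g, c(1L + 4L + 10L * (1L + 10L * 1L),
                       1L + 4L + 10L * (2L + 10L * 1L)))
  dm <- disconnection_matrix(les, atlas, nt)
  expect_equal(dm$values[1, 2], 0.5)
  expect_false(dm$structural_mask[1, 3])
  expect_equal(dm$values[1, 3], 0)
  # empty mask -> zeros; full mask -> ones on connected pairs
  expect_true(all(disconnection_matrix(toy_mask(g), atlas, nt)$values == 0))
  full <- lesion_mask(array(1L, g), 1, "toy")
  expect_equal(disconnection_matrix(full, atlas, nt)$values[1, 2], 1)
  # grid mismatch
  expect_error(disconnection_matrix(toy_mask(c(5L, 5L, 5L)), atlas, nt),
               "space")
})

test_that("disconnection_matrix equals the dense-sampling brute force on random toys", {
  set.seed(21)
  for (rep in 1:10) {
    g <- c(12L, 12L, 12L)
    n_nodes <- sample(4:8, 1)
    sls <- lapply(seq_len(sample(20:50, 1)), function(k) {
      pr <- sort(sample(n_nodes, 2))
      npts <- sample(2:5, 1)
      list(pair = pr, points = matrix(runif(3 * npts, 0.3, 11.7), npts))
    })
    atlas <- toy_atlas(sls, g)
    les <- toy_mask(g, sample(prod(g), 120))
    nt <- toy_node_table(n_nodes)
    dm <- disconnection_matrix(les, atlas, nt)
    expect_equal(unname(dm$values), brute_disconnection(les, atlas, nt),
                 tolerance = 1e-12)
  }
})

test_that("adding lesion voxels never decreases disconnection", {
  cfg <- small_cfg(seed = 31)
  parc <- make_parcellation(cfg)
  atlas <- make_streamline_atlas(parc, cfg)
  m1 <- make_lesions(1, parc, cfg, subject_id = 1)
  extra <- which(m1$data == 0L)[seq(1, 5000, by = 97)]
  m2 <- lesion_mask(array(pmax(m1$data, toy_mask(parc$grid_shape, extra)$data),
                          dim = parc$grid_shape), parc$voxel_size,
                    parc$space_tag)
  d1 <- disconnection_matrix(m1, atlas, parc$node_table)
  d2 <- disconnection_matrix(m2, atlas, parc$node_table)
  expect_true(all(d2$values - d1$values >= -1e-12))
})

test_that("mean disconnection increases with lesion severity across subjects", {
  cfg <- small_cfg(seed = 32)
  parc <- make_parcellation(cfg)
  atlas <- make_streamline_atlas(parc, cfg)
  sev <- rep(c(0.2, 0.7, 1.5, 3), each = 8)
  md <- vapply(seq_along(sev), function(i) {
    m <- make_lesions(sev[i], parc, cfg, subject_id = i)
    dm <- disconnection_matrix(m, atlas, parc$node_table)
    mean(dm$values[dm$structural_mask])
  }, 0)
  expect_gt(cor(sev, md, method = "spearman"), 0.5)
})

test_that("probability maps behave as voxel-wise means", {
  g <- c(8L, 8L, 8L)
  m1 <- toy_mask(g, 1:10)
  m2 <- toy_mask(g, 11:20)
  expect_error(lesion_probability_map(list()), "at least one")
  expect_equal(lesion_probability_map(list(m1, m1)), m1$data + 0)
  pm <- lesion_probability_map(list(m1, m2))
  expect_equal(sum(pm == 0.5), 20)
  expect_true(all(pm >= 0 & pm <= 1))
  expect_true(all(lesion_probability_map(list(toy_mask(g), toy_mask(g))) == 0))
})

test_that("disconnection probability map marks exactly the transected streamline", {
  g <- c(10L, 10L, 10L)
  sls <- list(list(pair = c(1L, 2L),
                   points = rbind(c(0.5, 2.5, 2.5), c(8.5, 2.5, 2.5))),
              list(pair = c(1L, 2L),
                   points = rbind(c(0.5, 7.5, 7.5), c(8.5, 7.5, 7.5))))
  atlas <- toy_atlas(sls, g)
  les <- toy_mask(g, 1L + 3L + 10L * (2L + 10L * 2L)) # on streamline 1 only
  dp <- disconnection_probability_map(list(les), atlas)
  tr <- sort(atlas$voxels[[1]] + 1L)
  expect_equal(sort(which(dp == 1)), tr)
  expect_true(all(dp[-tr] == 0))
  expect_true(all(disconnection_probability_map(list(toy_mask(g)), atlas) == 0))
})

test_that("node strength and system block means", {
  nt <- toy_node_table(3)
  v <- matrix(0, 3, 3)
  v[1, 2] <- v[2, 1] <- 0.5
  v[1, 3] <- v[3, 1] <- 0.25
  cm <- conn_matrix(v, nt$id, nt$system, "disconnection")
  expect_equal(unname(node_strength(cm)), c(0.75, 0.5, 0.25))
  # handshake identity
  expect_equal(sum(node_strength(cm)), 2 * sum(v[upper.tri(v)]))
  expect_equal(unname(node_strength(conn_matrix(matrix(0, 3, 3), nt$id,
                                                nt$system))), rep(0, 3))
  # block means: 2 systems x 2 nodes, hand-set edges
  sys <- c("VIS", "VIS", "SM", "SM")
  v4 <- matrix(0, 4, 4)
  v4[1, 2] <- 0.4; v4[3, 4] <- 0.2; v4[1, 3] <- 0.1; v4[2, 4] <- 0.3
  v4 <- v4 + t(v4)
  cm4 <- conn_matrix(v4, 1:4, sys, "disconnection")
  bm <- system_block_means(cm4)
  expect_equal(bm["VIS", "VIS"], 0.4)
  expect_equal(bm["SM", "SM"], 0.2)
  expect_equal(bm["VIS", "SM"], mean(c(0.1, 0.3, 0, 0)))
  expect_equal(bm, t(bm))
  # constant matrix -> constant blocks
  vc <- matrix(0.3, 4, 4); diag(vc) <- 0
  expect_true(all(abs(system_block_means(
    conn_matrix(vc, 1:4, sys, "disconnection")) - 0.3) < 1e-12))
  expect_error(system_block_means(conn_matrix(v4, 1:4,
                                              c("VIS", "VIS", "SM", "XXX"))),
               "unknown system")
})

test_that("total lesion volume and its log transform", {
  m <- toy_mask(c(5L, 5L, 5L), 1:10, voxel_size = 2)
  expect_equal(total_lesion_volume(m), 10 * 8)
  expect_equal(total_lesion_volume(toy_mask(c(5L, 5L, 5L))), 0)
  expect_equal(log1p_tlv(0), 0)
  expect_error(log1p_tlv(-5), "nonnegative")
  x <- c(3, 80, 900); expect_true(all(diff(log1p_tlv(x)) > 0))
})
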