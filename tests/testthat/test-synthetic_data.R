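test_that("voxelized primitives match their analytic volumes", {
  ball <- digital_ball(150, 7)
  expect_lt(abs(sum(ball) * 7^3 - 4 / 3 * pi * 150^3) / (4 / 3 * pi * 150^3),
            0.02)
  # degenerate ellipsoid equals the ball of the same radius
  ell <- digital_ellipsoid(c(150, 150, 150), 7)
  expect_identical(sum(ell != ball), 0L)
  # sub-voxel ball still owns its center voxel
  tiny <- voxelize_primitive("ball", list(diameter_nm = 3), 7)
  expect_equal(sum(tiny), 1L)
})

test_that("model synapses reproduce the stated extents and the ring/disk
           relationship", {
  disk <- get_phantom("disk")
  vox <- disk$volume$voxels
  psd <- vox == 2L
  rib <- vox == 1L
  # projected PSD extent: 1400/7 = 200 voxels (+-1)
  x_extent <- diff(range(which(apply(psd, 1, any)))) + 1L
  expect_lte(abs(x_extent - 200L), 1L)
  # ribbon extent: 300/7 ~ 43 voxels (+-1)
  rx <- diff(range(which(apply(rib, 1, any)))) + 1L
  expect_lte(abs(rx - 43L), 1L)

  ring <- get_phantom("ring")
  # identical masks outside the central hole cylinder
  stopifnot(all(dim(ring$volume$voxels) == dim(vox)))
  d <- dim(vox)
  ctr <- (d[c(1, 3)] + 1) / 2
  xs <- ((seq_len(d[1]) - ctr[1]) * 7)
  zs <- ((seq_len(d[3]) - ctr[2]) * 7)
  r2 <- outer(xs^2, zs^2, "+")
  outside <- array(rep(r2 > (125 + 14)^2, times = d[2]),
                   c(d[1], d[3], d[2]))
  outside <- aperm(outside, c(1, 3, 2))
  expect_identical(vox[outside], ring$volume$voxels[outside])
  # and the ring really has a hole
  expect_gt(sum(psd), sum(ring$volume$voxels == 2L))
})

test_that("hemisphere PSD voxels lie on a thin shell centered near the
           ribbon", {
  hemi <- get_phantom("hemisphere")
  sp <- hemi$volume$spacing_nm
  org <- hemi$geometry$origin_nm
  idx <- which(hemi$volume$voxels == 2L, arr.ind = TRUE)
  pts <- sweep((idx - 0.5) * sp, 2L, org, "+")
  r <- sqrt(rowSums(pts^2))  # bowl sphere centered at the local origin
  expect_true(all(r >= 700 - sp & r <= 714 + sp))
  # ribbon center close to the bowl sphere center relative to the radius
  expect_lt(sqrt(sum(hemi$geometry$ribbon_center_nm^2)), 700 / 4)
})

test_that("scene generation is deterministic and honors the spec counts", {
  spec <- scene_spec("p17-like", seed = 3L)
  light1 <- make_scene(spec, voxelize = FALSE)
  light2 <- make_scene(spec, voxelize = FALSE)
  expect_identical(light1$truth, light2$truth)
  expect_identical(light1$markers, light2$markers)
  # p17-like defaults: 38 synapses on 16+16+6
  expect_equal(length(unique(light1$truth$synapse_id)), 38L)
  expect_equal(as.vector(table(light1$truth$ihc_id[
    !duplicated(light1$truth$synapse_id)])), c(16L, 16L, 6L))

  none <- make_scene(scene_spec("p34-like", double_ribbon_fraction = 0,
                                seed = 5L), voxelize = FALSE)
  expect_true(all(table(none$truth$synapse_id) == 1L))

  sc1 <- get_small_scene()
  sc2 <- make_scene(scene_spec("p34-like", n_ihc = 2L,
                               synapses_per_ihc = c(4L, 4L), seed = 7L))
  expect_identical(sc1$volume$voxels, sc2$volume$voxels)
  expect_identical(sc1$truth, sc2$truth)
})

test_that("emitted voxel scenes agree with their ground truth
           (constructive truth)", {
  sc <- get_small_scene()
  # ribbon volumes: voxel recount must match the stored voxel volume
  # exactly and the analytic draw within voxelization error
  idx <- ribbonmorph:::label_index(sc$volume)
  dims <- dim(sc$volume$voxels)
  sp <- sc$volume$spacing_nm
  for (i in seq_len(nrow(sc$truth))) {
    lab <- sc$truth$label[i]
    cm <- ribbonmorph:::crop_mask(idx[[as.character(lab)]], dims)
    v <- volume_of(cm$mask, sp)
    expect_identical(v, sc$truth$voxel_volume_nm3[i])
    expect_lt(abs(v - sc$truth$true_volume_nm3[i]) /
                sc$truth$true_volume_nm3[i], 0.03)
  }
  # anchors recomputed from the volume equal the truth anchors
  a <- synapse_anchors(sc$volume, sc$table)
  tr <- unique(sc$truth[, c("synapse_id", "x_nm", "y_nm", "z_nm")])
  mm <- merge(a, tr, by = "synapse_id")
  expect_equal(mm$x_nm.x, mm$x_nm.y)
  expect_equal(mm$z_nm.x, mm$z_nm.y)
  # pool counts recomputed by the counting module equal the truth exactly
  pc <- count_pools(sc$volume, sc$table, sc$markers)
  tru <- unique(sc$truth[, c("synapse_id", "n_ribbon_pool_true",
                             "n_membrane_pool_true")])
  cmp <- merge(pc, tru, by = "synapse_id")
  expect_identical(cmp$ribbon_associated, as.integer(cmp$n_ribbon_pool_true))
  expect_identical(cmp$membrane_associated,
                   as.integer(cmp$n_membrane_pool_true))
})

test_that("place_vesicles hits its pool targets exactly and flags dual
           membership", {
  set.seed(11)
  rib <- digital_ball(100, 7)
  pv <- place_vesicles(rib, pd_mask = NULL, spacing_nm = 7,
                       n_ribbon_pool = 60L, n_distractors = 0L)
  expect_equal(pv$truth$n_ribbon_pool, 60L)
  d <- brute_surface_dist(pv$markers[, c("x_nm", "y_nm", "z_nm")], rib, 7)
  expect_equal(sum(d <= 80 + 1e-9), 60L)

  # with a PD slab close to the ribbon, dual-membership flags must agree
  # with brute-force distances to both surfaces
  n <- dim(rib)[1]
  dims2 <- c(n, n + 6L, n)
  pd <- array(FALSE, dims2)
  pd[, 1:2, ] <- TRUE
  rib2 <- array(FALSE, dims2)
  rib2[, 7:(n + 6L), ] <- rib
  set.seed(12)
  pv2 <- place_vesicles(rib2, pd, spacing_nm = 7, n_ribbon_pool = 30L,
                        n_membrane_pool = 15L, n_distractors = 5L)
  pts <- pv2$markers[, c("x_nm", "y_nm", "z_nm")]
  dr <- brute_surface_dist(pts, rib2, 7)
  dp <- brute_surface_dist(pts, pd, 7)
  expect_equal(pv2$truth$n_ribbon_pool, sum(dr <= 80 + 1e-9))
  expect_equal(pv2$truth$n_membrane_pool, sum(dp <= 20 + 1e-9))
  expect_equal(pv2$markers$dual, dr <= 80 + 1e-9 & dp <= 20 + 1e-9)
})
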