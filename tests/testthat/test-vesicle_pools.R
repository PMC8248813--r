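test_that("pool thresholds are inclusive at the boundary", {
  m <- array(FALSE, c(3, 3, 3)); m[1, 1, 1] <- TRUE
  # +X face center of voxel [1,1,1] at 7 nm spacing: (7, 3.5, 3.5)
  at80 <- vesicle_markers(cbind(87, 3.5, 3.5))
  at81 <- vesicle_markers(cbind(88, 3.5, 3.5))
  expect_equal(ribbon_associated(at80, m, 7), 1L)
  expect_equal(ribbon_associated(at81, m, 7), 0L)
  touching <- vesicle_markers(cbind(7, 3.5, 3.5))
  expect_equal(membrane_associated(touching, m, 7), 1L)
  far <- vesicle_markers(cbind(100, 100, 100))
  expect_equal(membrane_associated(far, m, 7), 0L)
})

test_that("counts match a brute-force distance oracle and grow with the
           threshold", {
  set.seed(21)
  rib <- digital_ball(80, 7)
  lim <- dim(rib) * 7
  pts <- cbind(runif(300, 0, lim[1]), runif(300, 0, lim[2]),
               runif(300, 0, lim[3]))
  mk <- vesicle_markers(pts)
  d_oracle <- brute_surface_dist(pts, rib, 7)
  for (thr in c(20, 50, 80, 120)) {
    expect_equal(ribbon_associated(mk, rib, 7, threshold_nm = thr),
                 sum(d_oracle <= thr + 1e-9))
  }
  counts <- vapply(c(10, 30, 60, 90), function(thr)
    ribbon_associated(mk, rib, 7, threshold_nm = thr), integer(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("sectioned counting emulates the every-5th-section protocol", {
  m <- array(TRUE, c(4, 4, 50))
  set.seed(31)
  pts <- cbind(runif(1000, 0, 28), runif(1000, 0, 28), runif(1000, 0, 350))
  mk <- vesicle_markers(pts)
  full <- sectioned_count(mk, m, spacing_nm = 7, section_period = 1L)
  expect_equal(full, 1000L)
  # markers confined to section index 3 never appear with period 5
  mk3 <- vesicle_markers(cbind(runif(20, 0, 28), runif(20, 0, 28),
                               runif(20, 3 * 7, 4 * 7 - 0.01)))
  expect_equal(sectioned_count(mk3, m, spacing_nm = 7, section_period = 5L),
               0L)
  # uniform markers: sectioned/full ratio ~ 1/5 within a binomial band
  frac <- sectioned_count(mk, m, spacing_nm = 7, section_period = 5L) / 1000
  expect_lt(abs(frac - 0.2), 0.045)
  expect_error(sectioned_count(mk, m, spacing_nm = 7,
                               section_period = 60L), "depth")
})

test_that("pools are defined independently and never deduplicated", {
  sc <- get_small_scene()
  pc <- count_pools(sc$volume, sc$table, sc$markers)
  dual <- tapply(sc$markers$dual, sc$markers$synapse_id, sum)
  # dual markers exist in the fixture and are counted by both pools
  expect_gt(sum(dual), 0)
  expect_true(all(pc$ribbon_associated + pc$membrane_associated >=
                    dual[as.character(pc$synapse_id)]))
  expect_true(all(pc$ribbon_threshold_nm == 80))
  expect_true(all(pc$membrane_threshold_nm == 20))
})

test_that("ribbon pool counts correlate with ribbon surface area on
           generated scenes", {
  sc <- make_scene(scene_spec("p34-like", seed = 17L), voxelize = FALSE)
  per_syn <- aggregate(true_surface_um2 ~ synapse_id, sc$truth, sum)
  pools <- unique(sc$truth[, c("synapse_id", "n_ribbon_pool_true")])
  mm <- merge(per_syn, pools, by = "synapse_id")
  g <- spearman_rho(mm$n_ribbon_pool_true, mm$true_surface_um2)
  expect_gt(unname(g["rho"]), 0)
  expect_lt(unname(g["p"]), 0.05)
})
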