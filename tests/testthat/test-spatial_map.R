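make_ribbon_volume <- function(voxels_idx, synapse_ids, spacing_nm = 7,
                               ihc_ids = 1L) {
  d <- c(24L, 24L, 24L)
  vox <- array(0L, d)
  labs <- seq_along(voxels_idx)
  for (i in labs) vox[matrix(voxels_idx[[i]], ncol = 3, byrow = TRUE)] <- i
  vol <- label_volume(vox, spacing_nm = spacing_nm)
  # one PSD voxel per synapse so the table validates
  psd_lab <- max(labs) + seq_along(unique(synapse_ids))
  for (k in seq_along(unique(synapse_ids))) vox[k, 24, 24] <- psd_lab[k]
  vol <- label_volume(vox, spacing_nm = spacing_nm)
  tab <- label_table(
    c(labs, psd_lab),
    c(rep("ribbon", length(labs)), rep("PSD", length(psd_lab))),
    synapse_id = c(synapse_ids, unique(synapse_ids)),
    ihc_id = rep(ihc_ids, length.out = length(labs) + length(psd_lab)))
  list(volume = vol, table = tab)
}

test_that("the synapse anchor is the ribbon-union centroid in voxel-center
           coordinates", {
  f <- make_ribbon_volume(list(c(11, 11, 11)), 1L)
  a <- synapse_anchors(f$volume, f$table)
  expect_equal(unlist(a[, c("x_nm", "y_nm", "z_nm")], use.names = FALSE),
               rep(73.5, 3))
  # double ribbon with equal masses at z centers 3.5 and 136.5 -> 70
  f2 <- make_ribbon_volume(list(c(5, 5, 1), c(5, 5, 20)), c(1L, 1L))
  a2 <- synapse_anchors(f2$volume, f2$table)
  expect_equal(a2$z_nm, 70)
  # a ball ribbon's anchor is its center within half a voxel
  ball <- digital_ball(70, 7)
  d <- dim(ball)
  vox <- array(0L, d + 2L)
  vox[1 + seq_len(d[1]), 1 + seq_len(d[2]), 1 + seq_len(d[3])] <-
    ball * 1L
  vox[1, 1, 1] <- 2L
  tab <- label_table(1:2, c("ribbon", "PSD"), 1L, 1L)
  a3 <- synapse_anchors(label_volume(vox, 7), tab)
  ctr <- (1 + (d + 1) / 2 - 0.5) * 7
  expect_true(all(abs(c(a3$x_nm, a3$y_nm, a3$z_nm) - ctr) <= 3.5))
})

test_that("the native frame zeroes the habenular minimum and centers the
           modiolar-pillar midrange", {
  anchors <- data.frame(synapse_id = 1:2, ihc_id = 1L,
                        x_nm = 0, y_nm = c(30, 70), z_nm = c(0, 100))
  nf <- native_frame(anchors)
  expect_equal(nf$y_hc, c(0, 40))
  expect_equal(nf$z_mp, c(-50, 50))
  bad <- anchors; bad$z_nm <- 5
  expect_error(native_frame(bad), "undefined")
})

test_that("the translated frame superimposes cells and reduces to the
           native frame for one cell", {
  base <- data.frame(synapse_id = 1:3, ihc_id = 1L, x_nm = 0,
                     y_nm = c(0, 500, 900), z_nm = c(-1000, 200, 1500))
  shifted <- base
  shifted$synapse_id <- 4:6
  shifted$ihc_id <- 2L
  shifted$z_nm <- shifted$z_nm + 2000
  both <- rbind(base, shifted)
  tf <- translated_frame(both)
  expect_equal(tf$z_mp[1:3], tf$z_mp[4:6])
  expect_equal(tf$y_hc[1:3], tf$y_hc[4:6])
  # one cell: translated equals native
  tf1 <- translated_frame(base)
  nf1 <- native_frame(base)
  expect_equal(tf1$z_mp, nf1$z_mp)
  expect_equal(tf1$y_hc, nf1$y_hc)
  # a single-synapse cell is flagged, not dropped
  lone <- rbind(base, data.frame(synapse_id = 7L, ihc_id = 3L, x_nm = 0,
                                 y_nm = 0, z_nm = 0))
  expect_warning(tf2 <- translated_frame(lone), "undefined")
  expect_false(tf2$frame_defined[4])
  expect_equal(sum(tf2$frame_defined), 3L)
})

test_that("modiolar/pillar groups follow the sign rule with a flagged
           boundary", {
  co <- data.frame(y_hc = c(0, 10, 20), z_mp = c(-500, 500, 0))
  g <- assign_groups(co)
  expect_equal(g$mp_group, c("M", "P", "P"))
  expect_equal(g$mp_boundary, c(FALSE, FALSE, TRUE))
  expect_equal(sum(g$mp_group %in% c("M", "P")), 3L)
})

test_that("axis gradients recover programmed monotone trends and stay
           small under the null", {
  z <- seq_len(20)
  g <- axis_gradient(rev(z), z)
  expect_equal(unname(g["rho"]), -1)
  expect_error(axis_gradient(rep(1, 10), 1:10), "constant")
  # permutation null: |rho| < 0.4 in at least 95% of shuffles at n = 30
  set.seed(99)
  vals <- rnorm(30)
  zz <- seq_len(30)
  hits <- vapply(1:1000, function(i)
    abs(axis_gradient(sample(vals), zz)["rho"]) < 0.4, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("recomputed frames and group flips match the scene ground truth", {
  sc <- get_small_scene()
  m <- map_synapses(sc$volume, sc$table)
  tr <- unique(sc$truth[, c("synapse_id", "z_mp_native", "z_mp_translated",
                            "mp_native", "mp_translated", "mp_flipped")])
  mm <- merge(m, tr, by = "synapse_id")
  expect_equal(mm$z_mp_native.x, mm$z_mp_native.y)
  expect_equal(mm$z_mp_translated.x, mm$z_mp_translated.y)
  expect_identical(mm$mp_translated.x, mm$mp_translated.y)
  expect_identical(sum(mm$mp_flipped.x), sum(mm$mp_flipped.y))
  # frames are pure translations: pairwise anchor distances preserved
  dz <- dist(m$z_nm)
  expect_equal(as.vector(dist(m$z_mp_native)), as.vector(dz))
})
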