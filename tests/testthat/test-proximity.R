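test_that("concentric shell distances are constant within a voxel", {
  rib <- digital_ball(100, 7)
  shell <- digital_shell(200, 214, 7)
  # embed the ribbon in the shell's (larger) grid, centered
  d <- dim(shell)
  rib_big <- array(FALSE, d)
  off <- (d - dim(rib)) %/% 2L
  rib_big[off[1] + seq_len(dim(rib)[1]), off[2] + seq_len(dim(rib)[2]),
          off[3] + seq_len(dim(rib)[3])] <- rib
  surf <- ribbon_facing_surface(shell, rib_big, 7)
  prof <- proximity_profile(surf, rib_big, 7)
  # the true gap is 100 nm; both surfaces are face-center quantized at
  # +-(sqrt(3)/2) voxel, so the bulk sits within one voxel of the gap with
  # only corner-face tails beyond
  expect_lt(abs(prof$median_nm - 100), 7 + 1e-9)
  expect_lt(sd(prof$distances_nm), 7)
  expect_gte(mean(abs(prof$distances_nm - prof$median_nm) <= 7), 0.95)
  expect_lt(abs(prof$p15_nm - prof$median_nm), 7 + 1e-9)
})

test_that("the ribbon-facing sheet of a flat PSD is its top surface only", {
  disk <- get_phantom("disk")
  vox <- disk$volume$voxels
  surf <- ribbon_facing_surface(vox == 2L, vox == 1L, 7)
  # analytic top-face count of a voxelized disk of radius 700 at 7 nm
  expected <- pi * (700 / 7)^2
  expect_lt(abs(nrow(surf$points) - expected) / expected, 0.03)
  expect_true(all(surf$normals[, 2] == 1))  # all +Y faces

  ring <- get_phantom("ring")
  surf_r <- ribbon_facing_surface(ring$volume$voxels == 2L,
                                  ring$volume$voxels == 1L, 7)
  # the ring's top sheet is the disk's top sheet minus the hole
  top <- sum(surf$normals[, 2] == 1)
  top_r <- sum(surf_r$normals[, 2] == 1)
  hole_faces <- pi * (125 / 7)^2
  expect_lt(abs((top - top_r) - hole_faces) / hole_faces, 0.03)

  expect_error(ribbon_facing_surface(vox == 2L, vox == 2L, 7), "overlap")
})

test_that("profile summaries follow the linear-interpolation quantile rule", {
  expect_equal(unname(profile_summary(rep(42, 10))), c(42, 42))
  s <- profile_summary(1:100)
  expect_equal(unname(s["median_nm"]), 50.5)
  expect_equal(unname(s["p15_nm"]), 15.85)
  expect_error(profile_summary(numeric(0)), "no distances")
})

test_that("mean cumulative curves average synapses with equal weight", {
  p1 <- proximity_profile(matrix(c(0, 0, 10), 1), matrix(c(0, 0, 0), 1), 7,
                          synapse_id = 1L)
  p2 <- proximity_profile(matrix(c(0, 0, 20), 1), matrix(c(0, 0, 0), 1), 7,
                          synapse_id = 2L)
  grid <- seq(0, 30, by = 1)
  mc <- mean_cum_pdf(list(p1, p2), grid)
  expect_equal(mc$cum_pdf[mc$distance_nm == 5], 0)
  expect_equal(mc$cum_pdf[mc$distance_nm == 15], 0.5)
  expect_equal(mc$cum_pdf[mc$distance_nm == 25], 1)
  # two identical profiles average to themselves
  mc2 <- mean_cum_pdf(list(p1, p1), grid)
  expect_equal(mc2$cum_pdf, ribbonmorph:::cum_pdf_at(p1, grid))
  # mean of several curves is bounded by the pointwise min and max
  profs <- lapply(c("disk", "ring"), get_phantom_profile)
  g2 <- seq(0, 700, by = 7)
  curves <- sapply(profs, ribbonmorph:::cum_pdf_at, at = g2)
  m2 <- mean_cum_pdf(profs, g2)
  expect_true(all(m2$cum_pdf >= apply(curves, 1, min) - 1e-12))
  expect_true(all(m2$cum_pdf <= apply(curves, 1, max) + 1e-12))
  expect_error(mean_cum_pdf(list()), "no profiles")
})

test_that("profiles are translation invariant and scale linearly with
           spacing", {
  rib <- digital_ball(50, 7)
  d <- c(48L, 48L, 48L)
  place <- function(off_r, off_p) {
    a <- array(FALSE, d); b <- array(FALSE, d)
    a[off_r[1] + seq_len(dim(rib)[1]), off_r[2] + seq_len(dim(rib)[2]),
      off_r[3] + seq_len(dim(rib)[3])] <- rib
    b[off_p[1] + (1:10), off_p[2] + (1:2), off_p[3] + (1:10)] <- TRUE
    list(rib = a, psd = b)
  }
  m1 <- place(c(10, 20, 10), c(12, 5, 12))
  m2 <- place(c(15, 25, 18), c(17, 10, 20))  # same relative offset
  s1 <- ribbon_facing_surface(m1$psd, m1$rib, 7)
  s2 <- ribbon_facing_surface(m2$psd, m2$rib, 7)
  pr1 <- proximity_profile(s1, m1$rib, 7)
  pr2 <- proximity_profile(s2, m2$rib, 7)
  expect_equal(pr1$distances_nm, pr2$distances_nm)
  # doubling the spacing doubles every distance exactly
  pr14 <- proximity_profile(ribbon_facing_surface(m1$psd, m1$rib, 14),
                            m1$rib, 14)
  expect_equal(pr14$distances_nm, 2 * pr1$distances_nm)
})
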