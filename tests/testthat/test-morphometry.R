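test_that("volume is foreground count times voxel volume", {
  m <- array(TRUE, c(10, 10, 10))
  expect_equal(volume_of(m, 7), 1000 * 343)
  ball <- digital_ball(150, 7)
  expect_lt(abs(volume_of(ball, 7) - 1.4137167e7) / 1.4137167e7, 0.02)
  expect_error(volume_of(array(FALSE, c(3, 3, 3)), 7), "empty")
})

test_that("voxel-face area counts exposed faces and converges to 1.5x the
           smooth sphere area", {
  single <- array(FALSE, c(3, 3, 3)); single[2, 2, 2] <- TRUE
  expect_equal(voxel_face_area(single, 7), 6 * 49)
  bar <- array(FALSE, c(3, 3, 4)); bar[2, 2, 2:3] <- TRUE
  expect_equal(voxel_face_area(bar, 7), 10 * 49)
  # staircase limit: |nx|+|ny|+|nz| averages 3/2 over the sphere
  r_vox <- 50
  ball <- digital_ball(r_vox * 7, 7)
  ratio <- voxel_face_area(ball, 7) / (4 * pi * (r_vox * 7)^2)
  expect_lt(abs(ratio - 1.5), 0.03)
})

test_that("Feret axes agree with closed forms for balls, boxes, and
           ellipsoids", {
  ball <- digital_ball(150, 7)
  ax <- feret_axes(ball, 7)
  expect_lt(abs(ax$long_nm - 300), 7 + 1e-9)
  expect_lt(abs(ax$short_nm - 300), 7 + 1e-9)

  box <- digital_box(c(70, 140, 280), 7)
  axb <- feret_axes(box, 7)
  expect_lt(abs(axb$long_nm - sqrt(70^2 + 140^2 + 280^2)), 10)
  expect_lt(abs(axb$short_nm - 70), 7 + 1e-9)

  ell <- digital_ellipsoid(c(250, 100, 75), 7)
  axe <- feret_axes(ell, 7)
  expect_lt(abs(axe$long_nm - 500), 14 + 1e-9)
  expect_lt(abs(axe$short_nm - 150), 14 + 1e-9)

  single <- array(FALSE, c(3, 3, 3)); single[2, 2, 2] <- TRUE
  axs <- feret_axes(single, 7)
  expect_equal(axs$long_nm, 7)
  expect_equal(axs$short_nm, 7)
})

test_that("axes are robust to lattice rotations and refine monotonically", {
  ell <- digital_ellipsoid(c(200, 90, 60), 7)
  ax0 <- feret_axes(ell, 7, n_directions = 512)
  for (perm in list(c(2, 1, 3), c(3, 2, 1), c(1, 3, 2))) {
    axp <- feret_axes(aperm(ell, perm), 7, n_directions = 512)
    expect_lte(abs(axp$long_nm - ax0$long_nm), 7 + 1e-9)
    expect_lte(abs(axp$short_nm - ax0$short_nm), 7 + 1e-9)
  }
  # nested direction sets: long never decreases, short never increases
  prev <- feret_axes(ell, 7, n_directions = 256)
  for (n in c(512, 1024, 2048)) {
    cur <- feret_axes(ell, 7, n_directions = n)
    expect_gte(cur$long_nm, prev$long_nm - 1e-9)
    expect_lte(cur$short_nm, prev$short_nm + 1e-9)
    prev <- cur
  }
})

test_that("planar Feret axes of a flat elliptical patch recover its
           diameters", {
  sp <- 14
  fun <- function(x, y, z) (x / 500)^2 + (z / 250)^2 <= 1 &
    y >= 0 & y < 2 * sp
  patch <- ribbonmorph:::voxelize_on_grid(
    fun, rbind(c(-520, 520), c(-sp, 3 * sp), c(-270, 270)), sp)$mask
  ax <- feret_axes_planar(patch, sp)
  expect_lt(abs(ax$long_nm - 1000), 2 * sp + 1e-9)
  expect_lt(abs(ax$short_nm - 500), 2 * sp + 1e-9)
  expect_gt(abs(ax$normal[2]), 0.99)  # sheet normal is Y
})

test_that("ellipse-model areas match the closed form", {
  expect_equal(round(ellipse_area(1120, 660), 3), 0.581)
  expect_equal(round(ellipse_area(1150, 360), 3), 0.325)
  d <- 800
  expect_equal(ellipse_area(d, d), pi * d^2 / 4 / 1e6)
  expect_error(ellipse_area(-1, 1), "positive")
  expect_error(ellipse_area(100, 200), "long")
})

test_that("measure_all emits one row per structure with class-appropriate
           metrics", {
  mp <- get_phantom("disk")
  rows <- measure_all(mp$volume, mp$table, n_directions = 512)
  expect_equal(nrow(rows), 2L)
  rib <- rows[rows$structure == "ribbon", ]
  expect_false(is.na(rib$voxelface_area_nm2))
  expect_true(is.na(rib$ellipse_area_um2))
  expect_true(rib$ls_ratio >= 1 && rib$ls_ratio <= 1.1)  # sphere symmetry
  psd <- rows[rows$structure == "PSD", ]
  expect_false(is.na(psd$ellipse_area_um2))
  expect_gte(psd$long_axis_nm, psd$short_axis_nm)

  # a tabulated structure with no voxels is reported by synapse id
  tab2 <- label_table(c(1L, 2L, 9L), c("ribbon", "PSD", "ribbon"),
                      synapse_id = c(1L, 1L, 1L), ihc_id = 1L)
  expect_error(measure_all(mp$volume, tab2), "absent.*synapse_id")
})
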