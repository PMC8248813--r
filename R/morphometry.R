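# Per-structure geometric measurement of voxelized objects.

#' Volume of a binary mask
#'
#' Foreground voxel count times the voxel volume.
#'
#' @param mask binary 3D array (nonempty).
#' @param spacing_nm isotropic voxel edge in nm.
#' @return volume in nm^3.
#' @export
volume_of <- function(mask, spacing_nm) {
  mask <- as_mask(mask)
  stopifnot_mask3d(mask)
  sum(mask) * spacing_nm^3
}

#' Voxel-face surface area
#'
#' Number of foreground voxel faces adjacent (6-connectivity) to background
#' times the face area. For a digitized smooth surface this overestimates
#' the smooth area by the staircase factor, which converges to 3/2 for a
#' sphere (the mean of |nx|+|ny|+|nz| over the unit sphere).
#'
#' @inheritParams volume_of
#' @return area in nm^2.
#' @export
voxel_face_area <- function(mask, spacing_nm) {
  mask <- as_mask(mask)
  stopifnot_mask3d(mask)
  count_boundary_faces(mask) * spacing_nm^2
}

#' Longest and shortest axes through the center of gravity
#'
#' Unconstrained (non-orthogonal) Feret-style axes of a voxelized object.
#' For each sampled direction `u`, the axis length is the span along `u` of
#' the foreground voxel centers lying within the capture radius
#' (`sqrt(3)/2 * spacing_nm`, half the voxel space diagonal) of the line
#' through the center of gravity, plus one voxel for the extent of the end
#' voxels. The long axis is the maximum over directions, the short axis the
#' minimum; they are not forced to be orthogonal. Directions come from a
#' deterministic nested low-discrepancy sequence expanded into whole orbits
#' of the octahedral group (all 48 signed axis permutations), so increasing
#' `n_directions` can only refine the estimates (long never decreases,
#' short never increases) and measurements are exactly invariant under
#' 90-degree lattice rotations of the mask. Among equal extrema the
#' lexicographically smallest direction vector is kept.
#'
#' A single-voxel mask degenerates to `long = short = spacing_nm`.
#'
#' @inheritParams volume_of
#' @param n_directions number of sampled directions (>= 162; default 2048).
#' @param capture_radius_nm capture radius; default half the voxel space
#'   diagonal.
#' @param mode `"chord"` (default): span of centroid-line-captured voxel
#'   centers. `"projection"`: span of all voxel centers projected on `u`
#'   (an alternative reading of the short axis as a minimal projected
#'   extent).
#' @param chunk directions per block in the vectorized scan (memory knob).
#' @return list with `long_nm`, `short_nm`, `long_dir`, `short_dir`.
#' @export
feret_axes <- function(mask, spacing_nm, n_directions = 2048L,
                       capture_radius_nm = sqrt(3) / 2 * spacing_nm,
                       mode = c("chord", "projection"), chunk = 256L) {
  mode <- match.arg(mode)
  mask <- as_mask(mask)
  stopifnot_mask3d(mask)
  if (n_directions < 162L) {
    stop("n_directions must be >= 162 for a stable axis estimate",
         call. = FALSE)
  }
  pts <- mask_coords(mask, spacing_nm)
  if (nrow(pts) == 1L) {
    d0 <- c(0, 0, 1)
    return(list(long_nm = spacing_nm, short_nm = spacing_nm,
                long_dir = d0, short_dir = d0))
  }
  ctr <- colMeans(pts)
  p <- sweep(pts, 2L, ctr)
  p_sq <- rowSums(p^2)
  dirs <- octahedral_directions(n_directions)
  n_directions <- nrow(dirs)
  spans <- rep(NA_real_, n_directions)
  cap2 <- capture_radius_nm^2
  for (start in seq(1L, n_directions, by = chunk)) {
    jj <- start:min(start + chunk - 1L, n_directions)
    proj <- p %*% t(dirs[jj, , drop = FALSE])   # n_pts x n_chunk
    if (mode == "chord") {
      keep <- (p_sq - proj^2) <= cap2 + 1e-9
      proj[!keep] <- NA_real_
    }
    rng_max <- suppressWarnings(apply(proj, 2L, max, na.rm = TRUE))
    rng_min <- suppressWarnings(apply(proj, 2L, min, na.rm = TRUE))
    s <- rng_max - rng_min
    s[!is.finite(s)] <- NA_real_
    spans[jj] <- s
  }
  lens <- spans + spacing_nm
  valid <- which(!is.na(lens))
  if (!length(valid)) {
    stop("no direction captured any voxels; mask degenerate for chord mode",
         call. = FALSE)
  }
  pick_extreme <- function(idx_set, value) {
    cand <- idx_set[which(abs(lens[idx_set] - value) < 1e-9)]
    if (length(cand) > 1L) {
      dd <- dirs[cand, , drop = FALSE]
      ord <- order(dd[, 1], dd[, 2], dd[, 3])
      cand <- cand[ord[1]]
    }
    cand[1]
  }
  long_v <- max(lens[valid])
  short_v <- min(lens[valid])
  i_long <- pick_extreme(valid, long_v)
  i_short <- pick_extreme(valid, short_v)
  list(long_nm = long_v, short_nm = short_v,
       long_dir = dirs[i_long, ], short_dir = dirs[i_short, ])
}

#' In-plane Feret axes of a membrane-density sheet
#'
#' PDs and PSDs are thin sheets: a fully 3D minimal axis degenerates to the
#' slab thickness, which is not what an axis-length summary of a membrane
#' density means. This variant fits the sheet's principal plane (PCA of the
#' voxel centers), samples directions within that plane through the center
#' of gravity, and returns the longest and shortest in-plane extents (plus
#' one voxel). For a flat elliptical patch this recovers the ellipse
#' diameters.
#'
#' @inheritParams volume_of
#' @param n_directions number of in-plane directions (default 720).
#' @return list with `long_nm`, `short_nm`, `long_dir`, `short_dir`,
#'   `normal` (unit sheet normal).
#' @export
feret_axes_planar <- function(mask, spacing_nm, n_directions = 720L) {
  mask <- as_mask(mask)
  stopifnot_mask3d(mask)
  pts <- mask_coords(mask, spacing_nm)
  if (nrow(pts) == 1L) {
    return(list(long_nm = spacing_nm, short_nm = spacing_nm,
                long_dir = c(1, 0, 0), short_dir = c(0, 0, 1),
                normal = c(0, 1, 0)))
  }
  p <- sweep(pts, 2L, colMeans(pts))
  ev <- eigen(crossprod(p) / nrow(p), symmetric = TRUE)
  e1 <- ev$vectors[, 1]; e2 <- ev$vectors[, 2]
  theta <- (seq_len(n_directions) - 1L) * pi / n_directions
  dirs <- outer(cos(theta), e1) + outer(sin(theta), e2)
  proj <- p %*% t(dirs)
  spans <- apply(proj, 2L, max) - apply(proj, 2L, min) + spacing_nm
  i_long <- which.max(spans)
  i_short <- which.min(spans)
  list(long_nm = spans[i_long], short_nm = spans[i_short],
       long_dir = dirs[i_long, ], short_dir = dirs[i_short, ],
       normal = ev$vectors[, 3])
}

#' Ellipse-model area of a membrane density
#'
#' Models the 2D projection of a PD or PSD as an ellipse with the measured
#' long and short axes as its diameters: area = pi * (long/2) * (short/2),
#' reported in um^2 as in the field's tables.
#'
#' @param long_nm,short_nm axis lengths in nm; `long_nm >= short_nm > 0`.
#' @return area in um^2.
#' @export
ellipse_area <- function(long_nm, short_nm) {
  if (any(long_nm <= 0) || any(short_nm <= 0)) {
    stop("axis lengths must be positive", call. = FALSE)
  }
  if (any(long_nm < short_nm)) {
    stop("long axis must be >= short axis", call. = FALSE)
  }
  pi * (long_nm / 2) * (short_nm / 2) / 1e6
}

#' Measure every synaptic structure in a label volume
#'
#' One row per ribbon, PD, and PSD (double-ribbon synapses yield one row per
#' ribbon). Ribbons get volume, voxel-face surface area, and 3D
#' chord-through-centroid Feret axes ([feret_axes()]); PDs and PSDs are
#' sheets and get in-plane Feret axes ([feret_axes_planar()]) and the
#' ellipse-model area from them. IHC labels are skipped (cell bodies are
#' not measured).
#'
#' @param volume a [label_volume()].
#' @param table the matching [label_table()].
#' @param n_directions directions for [feret_axes()].
#' @return data.frame in [write_measurements()] column order.
#' @export
measure_all <- function(volume, table, n_directions = 2048L) {
  validate_volume_table(volume, table)
  sp <- volume$spacing_nm
  idx <- label_index(volume)
  dims <- dim(volume$voxels)
  meas <- table[table$structure %in% c("ribbon", "PD", "PSD"), , drop = FALSE]
  # every synapse must have all its tabulated structures present in voxels
  missing_lab <- setdiff(meas$label, as.integer(names(idx)))
  if (length(missing_lab)) {
    sids <- unique(meas$synapse_id[meas$label %in% missing_lab])
    stop("structures absent from voxel data for synapse_id(s): ",
         paste(sids, collapse = ", "), call. = FALSE)
  }
  rows <- lapply(seq_len(nrow(meas)), function(i) {
    lab <- meas$label[i]
    cls <- meas$structure[i]
    cm <- crop_mask(idx[[as.character(lab)]], dims)
    ax <- if (cls == "ribbon") {
      feret_axes(cm$mask, sp, n_directions = n_directions)
    } else {
      feret_axes_planar(cm$mask, sp)
    }
    data.frame(
      label = lab, structure = cls,
      synapse_id = meas$synapse_id[i], ihc_id = meas$ihc_id[i],
      volume_nm3 = volume_of(cm$mask, sp),
      voxelface_area_nm2 = if (cls == "ribbon")
        voxel_face_area(cm$mask, sp) else NA_real_,
      ellipse_area_um2 = if (cls %in% c("PD", "PSD"))
        ellipse_area(ax$long_nm, ax$short_nm) else NA_real_,
      long_axis_nm = ax$long_nm, short_axis_nm = ax$short_nm,
      ls_ratio = ax$long_nm / ax$short_nm,
      long_dir_x = ax$long_dir[1], long_dir_y = ax$long_dir[2],
      long_dir_z = ax$long_dir[3],
      short_dir_x = ax$short_dir[1], short_dir_y = ax$short_dir[2],
      short_dir_z = ax$short_dir[3],
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}
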