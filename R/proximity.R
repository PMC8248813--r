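# PSD-to-ribbon proximity: the per-synapse shape descriptor.
#
# For every face center on the ribbon-facing surface of the PSD, the
# shortest Euclidean distance to the ribbon surface (ribbon boundary-face
# centers) is recorded; the sorted distances and their normalized
# cumulative histogram (Cum. PDF) summarize the size and shape of the
# synaptic apposition in a single curve.

#' Ribbon-facing surface of a PSD
#'
#' Extracts the boundary faces of the PSD mask that belong to the sheet
#' oriented toward the ribbon: faces whose outward normal has a positive
#' dot product with the direction from the face center to the nearest point
#' of the ribbon surface. If that rule selects nothing (pathological
#' curvature), the fallback keeps the faces on the ribbon-centroid side of
#' the plane through the PSD centroid perpendicular to the centroid-to-
#' centroid direction.
#'
#' @param psd_mask,ribbon_mask binary 3D arrays on a common grid, nonempty
#'   and disjoint.
#' @param spacing_nm voxel edge in nm.
#' @return list with `points` (n x 3 face centers, nm) and `normals`.
#' @export
ribbon_facing_surface <- function(psd_mask, ribbon_mask, spacing_nm) {
  psd_mask <- as_mask(psd_mask); ribbon_mask <- as_mask(ribbon_mask)
  stopifnot_mask3d(psd_mask); stopifnot_mask3d(ribbon_mask)
  if (any(psd_mask & ribbon_mask)) {
    stop("PSD and ribbon masks overlap", call. = FALSE)
  }
  psd_bf <- boundary_faces(psd_mask, spacing_nm)
  rib_bf <- boundary_faces(ribbon_mask, spacing_nm)
  ni <- nn_index(psd_bf$centers, rib_bf$centers)
  dirs <- rib_bf$centers[ni, , drop = FALSE] - psd_bf$centers
  keep <- rowSums(dirs * psd_bf$normals) > 0
  if (!any(keep)) {
    rib_ctr <- colMeans(mask_coords(ribbon_mask, spacing_nm))
    psd_ctr <- colMeans(mask_coords(psd_mask, spacing_nm))
    n <- rib_ctr - psd_ctr
    keep <- as.vector((psd_bf$centers - matrix(psd_ctr, nrow(psd_bf$centers),
                                               3, byrow = TRUE)) %*% n) >= 0
  }
  if (!any(keep)) stop("no ribbon-facing sheet found", call. = FALSE)
  list(points = psd_bf$centers[keep, , drop = FALSE],
       normals = psd_bf$normals[keep, , drop = FALSE])
}

#' Proximity profile of one synapse
#'
#' Shortest distance from each ribbon-facing PSD surface point to the
#' ribbon surface, sorted ascending, with the normalized cumulative curve
#' and percentile summaries. Distances are exact nearest-neighbor distances
#' to ribbon boundary-face centers (point-to-surface), not a sampled
#' distance transform.
#'
#' @param surface either the result of [ribbon_facing_surface()] or an
#'   n x 3 matrix of surface points in nm.
#' @param ribbon_mask binary ribbon mask on the same grid as the surface
#'   coordinates, or an n x 3 matrix of ribbon surface points in nm.
#' @param spacing_nm voxel edge in nm.
#' @param synapse_id optional id stored with the profile.
#' @return object of class `proximity_profile`: `distances_nm` (sorted),
#'   `median_nm`, `p15_nm`, `n`, `synapse_id`.
#' @export
proximity_profile <- function(surface, ribbon_mask, spacing_nm,
                              synapse_id = NA_integer_) {
  pts <- if (is.list(surface) && !is.null(surface$points)) surface$points
         else as.matrix(surface)
  if (nrow(pts) == 0L) stop("empty PSD surface", call. = FALSE)
  rib_pts <- if (is.matrix(ribbon_mask)) ribbon_mask
             else boundary_faces(ribbon_mask, spacing_nm)$centers
  new_proximity_profile(nn_dist(pts, rib_pts), synapse_id)
}

new_proximity_profile <- function(distances, synapse_id = NA_integer_) {
  d <- sort(distances)
  structure(list(
    synapse_id = synapse_id,
    distances_nm = d,
    n = length(d),
    median_nm = unname(stats::quantile(d, 0.5, type = 7)),
    p15_nm = unname(stats::quantile(d, 0.15, type = 7))
  ), class = "proximity_profile")
}

#' @export
print.proximity_profile <- function(x, ...) {
  cat(sprintf(
    "<proximity_profile> synapse %s: n=%d, median=%.1f nm, p15=%.1f nm, range [%.1f, %.1f]\n",
    x$synapse_id, x$n, x$median_nm, x$p15_nm,
    min(x$distances_nm), max(x$distances_nm)))
  invisible(x)
}

#' Percentile summary of a proximity profile
#'
#' Median and 15th-percentile distance (linear interpolation between order
#' statistics, quantile type 7).
#'
#' @param profile a `proximity_profile` or numeric vector of distances.
#' @return named vector `c(median_nm, p15_nm)`.
#' @export
profile_summary <- function(profile) {
  d <- if (inherits(profile, "proximity_profile")) profile$distances_nm
       else as.numeric(profile)
  if (length(d) < 1L) stop("profile has no distances", call. = FALSE)
  c(median_nm = unname(stats::quantile(d, 0.5, type = 7)),
    p15_nm = unname(stats::quantile(d, 0.15, type = 7)))
}

# Cumulative probability of a profile evaluated at arbitrary distances:
# empirical CDF with linear interpolation between sorted sample points
# (0 below the minimum, 1 above the maximum).
cum_pdf_at <- function(profile, at) {
  d <- if (inherits(profile, "proximity_profile")) profile$distances_nm
       else sort(as.numeric(profile))
  n <- length(d)
  if (n == 1L) return(as.numeric(at >= d))
  p <- seq_len(n) / n
  stats::approx(d, p, xout = at, method = "linear",
                yleft = 0, yright = 1, ties = "max")$y
}

#' Mean cumulative distance curve across synapses
#'
#' Interpolates each profile's cumulative curve onto a common distance grid
#' and averages with one unit of weight per synapse, regardless of how many
#' surface points each synapse contributed.
#'
#' @param profiles list of `proximity_profile` objects (>= 1).
#' @param grid_nm distance grid; default 0 to 1050 nm in 7 nm steps (and
#'   extended to cover the largest observed distance).
#' @return data.frame with columns `distance_nm` and `cum_pdf`.
#' @export
mean_cum_pdf <- function(profiles, grid_nm = NULL) {
  if (inherits(profiles, "proximity_profile")) profiles <- list(profiles)
  if (length(profiles) == 0L) stop("no profiles to average", call. = FALSE)
  dmax <- max(vapply(profiles, function(p) max(p$distances_nm), numeric(1)))
  if (is.null(grid_nm)) {
    grid_nm <- seq(0, max(1050, ceiling(dmax / 7) * 7), by = 7)
  } else if (max(grid_nm) < dmax) {
    stop("grid does not cover the largest observed distance", call. = FALSE)
  }
  curves <- vapply(profiles, cum_pdf_at, numeric(length(grid_nm)),
                   at = grid_nm)
  data.frame(distance_nm = grid_nm,
             cum_pdf = rowMeans(matrix(curves, nrow = length(grid_nm))))
}

#' Proximity profiles for every synapse of a label volume
#'
#' Convenience wrapper: for each synapse id in the table, extracts the PSD
#' and the union of the synapse's ribbons (double-ribbon synapses produce a
#' single profile against the union surface) and computes the profile.
#'
#' @param volume a [label_volume()].
#' @param table the matching [label_table()].
#' @return named list of `proximity_profile` objects keyed by synapse id.
#' @export
proximity_profiles <- function(volume, table) {
  validate_volume_table(volume, table)
  sp <- volume$spacing_nm
  idx <- label_index(volume)
  dims <- dim(volume$voxels)
  syn_ids <- sort(unique(stats::na.omit(
    table$synapse_id[table$structure == "PSD"])))
  out <- list()
  for (sid in syn_ids) {
    psd_lab <- table$label[table$structure == "PSD" & table$synapse_id == sid]
    rib_lab <- table$label[table$structure == "ribbon" &
                             table$synapse_id == sid]
    psd_cm <- crop_mask(idx[[as.character(psd_lab)]], dims)
    psd_bf <- boundary_faces(psd_cm$mask, sp)
    shift_p <- psd_cm$offset * sp
    psd_pts <- sweep(psd_bf$centers, 2L, shift_p, "+")
    rib_pts <- do.call(rbind, lapply(rib_lab, function(l) {
      cm <- crop_mask(idx[[as.character(l)]], dims)
      sweep(boundary_faces(cm$mask, sp)$centers, 2L, cm$offset * sp, "+")
    }))
    nn <- nn_min(psd_pts, rib_pts)
    dirs <- rib_pts[nn$index, , drop = FALSE] - psd_pts
    keep <- rowSums(dirs * psd_bf$normals) > 0
    if (!any(keep)) keep <- rep(TRUE, nrow(psd_pts))
    out[[as.character(sid)]] <- new_proximity_profile(nn$dist[keep],
                                                      synapse_id = sid)
  }
  out
}
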