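# Vesicle pool counting by distance thresholds.

# Distance from marker points (nm) to the surface of a mask: exact nearest
# neighbor over boundary-face centers. `origin_nm` shifts the mask into the
# markers' frame when the mask is a crop of a larger volume.
marker_surface_dist <- function(markers, mask, spacing_nm, origin_nm = c(0, 0, 0)) {
  pts <- as.matrix(as.data.frame(markers)[, c("x_nm", "y_nm", "z_nm")])
  surf <- boundary_faces(mask, spacing_nm)$centers
  surf <- sweep(surf, 2L, origin_nm, "+")
  nn_dist(pts, surf)
}

#' Ribbon-associated vesicle count
#'
#' Number of markers whose distance to the ribbon surface is at most
#' `threshold_nm` (inclusive; 80 nm default). Distances run from the marker
#' point (vesicle center) to the nearest ribbon boundary-face center; a
#' vesicle-radius offset can be applied by adjusting the threshold.
#'
#' @param markers a [vesicle_markers()] data.frame (columns x_nm,y_nm,z_nm).
#' @param ribbon_mask binary 3D ribbon mask (nonempty).
#' @param spacing_nm voxel edge in nm.
#' @param threshold_nm inclusive distance threshold (default 80).
#' @param origin_nm nm offset of the mask's grid origin in the marker frame.
#' @return integer count.
#' @export
ribbon_associated <- function(markers, ribbon_mask, spacing_nm,
                              threshold_nm = 80, origin_nm = c(0, 0, 0)) {
  d <- marker_surface_dist(markers, ribbon_mask, spacing_nm, origin_nm)
  sum(d <= threshold_nm + 1e-9)
}

#' Membrane-associated vesicle count
#'
#' As [ribbon_associated()] but against the presynaptic density (PD)
#' surface with a 20 nm default threshold.
#'
#' @inheritParams ribbon_associated
#' @param pd_mask binary 3D PD mask (nonempty).
#' @export
membrane_associated <- function(markers, pd_mask, spacing_nm,
                                threshold_nm = 20, origin_nm = c(0, 0, 0)) {
  d <- marker_surface_dist(markers, pd_mask, spacing_nm, origin_nm)
  sum(d <= threshold_nm + 1e-9)
}

#' Sectioned vesicle count
#'
#' Emulates the manual counting protocol in which vesicles are marked in
#' every k-th section only (every 5th section, 35 nm spacing, at 7 nm
#' voxels): counts markers lying in Z sections with index 0, k, 2k, ...
#' (0-based; section index `floor(z_nm / spacing_nm)`), optionally within a
#' distance threshold of a structure surface. With `section_period = 1`
#' this equals the full-3D count.
#'
#' @inheritParams ribbon_associated
#' @param mask binary structure mask, or NULL to count markers regardless
#'   of distance.
#' @param section_period count every k-th section (>= 1).
#' @param n_sections total number of Z sections in the volume (for
#'   validation); default taken from the mask.
#' @export
sectioned_count <- function(markers, mask = NULL, spacing_nm,
                            threshold_nm = Inf, section_period = 5L,
                            origin_nm = c(0, 0, 0), n_sections = NULL) {
  if (section_period < 1L) stop("section_period must be >= 1", call. = FALSE)
  if (is.null(n_sections) && !is.null(mask)) n_sections <- dim(mask)[3]
  if (!is.null(n_sections) && section_period > n_sections) {
    stop("section_period larger than the volume depth", call. = FALSE)
  }
  z_idx <- floor(as.data.frame(markers)$z_nm / spacing_nm)
  in_section <- (z_idx %% section_period) == 0
  if (is.null(mask) || !is.finite(threshold_nm)) {
    return(sum(in_section))
  }
  d <- marker_surface_dist(markers, mask, spacing_nm, origin_nm)
  sum(in_section & d <= threshold_nm + 1e-9)
}

#' Pool counts for every synapse of a volume
#'
#' Ribbon-associated (<= 80 nm of the synapse's ribbon surface; union for
#' double ribbons) and membrane-associated (<= 20 nm of the PD) counts per
#' synapse. Pools are defined independently and never deduplicated: a
#' vesicle may belong to both. Markers must carry a `synapse_id`.
#'
#' @param volume a [label_volume()].
#' @param table the matching [label_table()].
#' @param markers a [vesicle_markers()] with synapse ids.
#' @param thresholds_nm named vector `c(ribbon = 80, membrane = 20)`.
#' @param mode `"full-3D"` (default) or `"sectioned"` (every 5th section).
#' @return data.frame: synapse_id, ribbon_associated, membrane_associated,
#'   thresholds, mode.
#' @export
count_pools <- function(volume, table, markers,
                        thresholds_nm = c(ribbon = 80, membrane = 20),
                        mode = c("full-3D", "sectioned")) {
  mode <- match.arg(mode)
  validate_volume_table(volume, table)
  # bound check against the volume
  vesicle_markers(as.data.frame(markers)[, c("x_nm", "y_nm", "z_nm")],
                  synapse_id = markers$synapse_id, volume = volume)
  sp <- volume$spacing_nm
  idx <- label_index(volume)
  dims <- dim(volume$voxels)
  sids <- sort(unique(stats::na.omit(markers$synapse_id)))
  rows <- lapply(sids, function(sid) {
    mk <- markers[!is.na(markers$synapse_id) & markers$synapse_id == sid, ,
                  drop = FALSE]
    rib_lab <- table$label[table$structure == "ribbon" &
                             table$synapse_id == sid]
    pd_lab <- table$label[table$structure == "PD" & table$synapse_id == sid]
    rib_surf <- do.call(rbind, lapply(rib_lab, function(l) {
      cm <- crop_mask(idx[[as.character(l)]], dims)
      sweep(boundary_faces(cm$mask, sp)$centers, 2L, cm$offset * sp, "+")
    }))
    pts <- as.matrix(as.data.frame(mk)[, c("x_nm", "y_nm", "z_nm")])
    dr <- nn_dist(pts, rib_surf)
    in_section <- if (mode == "sectioned") {
      (floor(mk$z_nm / sp) %% 5L) == 0
    } else rep(TRUE, nrow(mk))
    ra <- sum(in_section & dr <= thresholds_nm[["ribbon"]] + 1e-9)
    ma <- NA_integer_
    if (length(pd_lab) == 1L) {
      cm <- crop_mask(idx[[as.character(pd_lab)]], dims)
      pd_surf <- sweep(boundary_faces(cm$mask, sp)$centers, 2L,
                       cm$offset * sp, "+")
      dp <- nn_dist(pts, pd_surf)
      ma <- sum(in_section & dp <= thresholds_nm[["membrane"]] + 1e-9)
    }
    data.frame(synapse_id = sid, ribbon_associated = ra,
               membrane_associated = ma,
               ribbon_threshold_nm = thresholds_nm[["ribbon"]],
               membrane_threshold_nm = thresholds_nm[["membrane"]],
               mode = mode, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
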