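# Synapse position mapping: native and translated coordinate frames along
# the habenular-cuticular (Y) and modiolar-pillar (Z) axes.

#' Anchor coordinates of a synapse
#'
#' The synapse anchor is the center of gravity of the union of the
#' synapse's ribbon voxels (the measurable common denominator across
#' structures; double ribbons contribute jointly). Returned in nm using the
#' voxel-center convention.
#'
#' @param volume a [label_volume()].
#' @param table the matching [label_table()].
#' @return data.frame with columns `synapse_id`, `ihc_id`, `x_nm`, `y_nm`,
#'   `z_nm`.
#' @export
synapse_anchors <- function(volume, table) {
  validate_volume_table(volume, table)
  sp <- volume$spacing_nm
  idx <- label_index(volume)
  dims <- dim(volume$voxels)
  rib <- table[table$structure == "ribbon" & !is.na(table$synapse_id), ,
               drop = FALSE]
  if (nrow(rib) == 0L) stop("no ribbons: synapse anchors undefined",
                            call. = FALSE)
  sids <- sort(unique(rib$synapse_id))
  rows <- lapply(sids, function(sid) {
    labs <- rib$label[rib$synapse_id == sid]
    present <- labs[as.character(labs) %in% names(idx)]
    if (!length(present)) {
      stop("synapse ", sid, " has no ribbon voxels", call. = FALSE)
    }
    arr <- do.call(rbind, lapply(present, function(l)
      arrayInd(idx[[as.character(l)]], dims)))
    ctr <- (colMeans(arr) - 0.5) * sp
    data.frame(synapse_id = sid,
               ihc_id = rib$ihc_id[rib$synapse_id == sid][1],
               x_nm = ctr[1], y_nm = ctr[2], z_nm = ctr[3])
  })
  do.call(rbind, rows)
}

#' Native coordinate frame
#'
#' Pure translation of anchor coordinates relative to the full range of
#' positions in the tissue: Y (habenular-cuticular) shifted so the most
#' habenular synapse is at 0; Z (modiolar-pillar) shifted so the most
#' modiolar and most pillar synapses are equidistant from the origin
#' (midrange at 0). No scaling or rotation.
#'
#' @param anchors data.frame with `y_nm` and `z_nm` (>= 2 synapses spanning
#'   Z).
#' @return the input with `y_hc` and `z_mp` columns added.
#' @export
native_frame <- function(anchors) {
  if (nrow(anchors) < 2L) stop("need >= 2 synapses for a frame",
                               call. = FALSE)
  if (diff(range(anchors$z_nm)) == 0) {
    stop("all anchors share one Z position: modiolar-pillar frame undefined",
         call. = FALSE)
  }
  anchors$y_hc <- anchors$y_nm - min(anchors$y_nm)
  anchors$z_mp <- anchors$z_nm - mean(range(anchors$z_nm))
  anchors
}

#' Translated (cell-centric) coordinate frame
#'
#' Applies the native-frame shifts per inner hair cell independently (min Y
#' at 0, midrange Z at 0 for each cell), then pools the coordinates, so the
#' synapses of all cells are superimposed on a common cell-centric frame.
#' A cell whose synapses do not span Z (single synapse) has an undefined
#' cell frame: its rows are flagged (`frame_defined = FALSE`, coordinates
#' NA) rather than silently dropped.
#'
#' @param anchors data.frame with `y_nm`, `z_nm`, and `ihc_id`.
#' @return the input with `y_hc`, `z_mp`, `frame_defined` columns added.
#' @export
translated_frame <- function(anchors) {
  if (is.null(anchors$ihc_id)) stop("anchors need an ihc_id column",
                                    call. = FALSE)
  anchors$y_hc <- NA_real_
  anchors$z_mp <- NA_real_
  anchors$frame_defined <- TRUE
  for (cell in unique(anchors$ihc_id)) {
    i <- which(anchors$ihc_id == cell)
    if (length(i) < 2L || diff(range(anchors$z_nm[i])) == 0) {
      anchors$frame_defined[i] <- FALSE
      warning("IHC ", cell, ": cell frame undefined (needs >= 2 synapses ",
              "spanning Z); rows flagged", call. = FALSE)
      next
    }
    anchors$y_hc[i] <- anchors$y_nm[i] - min(anchors$y_nm[i])
    anchors$z_mp[i] <- anchors$z_nm[i] - mean(range(anchors$z_nm[i]))
  }
  anchors
}

#' Modiolar/pillar and habenular/cuticular group assignment
#'
#' Z < 0 is modiolar (`"M"`), Z > 0 pillar (`"P"`). Z exactly 0 is assigned
#' `"P"` and flagged (`mp_boundary`), a documented convention — the
#' published rule covers only strict inequalities. The habenular/cuticular
#' split is at the midrange of the frame's Y coordinates (a reporting
#' convenience; the H-C axis is analyzed continuously elsewhere).
#'
#' @param coords data.frame with `y_hc` and `z_mp`.
#' @return the input with `mp_group`, `mp_boundary`, `hc_group` added.
#' @export
assign_groups <- function(coords) {
  z <- coords$z_mp
  coords$mp_group <- ifelse(is.na(z), NA_character_,
                            ifelse(z < 0, "M", "P"))
  coords$mp_boundary <- !is.na(z) & z == 0
  y <- coords$y_hc
  ymid <- mean(range(y, na.rm = TRUE))
  coords$hc_group <- ifelse(is.na(y), NA_character_,
                            ifelse(y <= ymid, "habenular-half",
                                   "cuticular-half"))
  coords
}

#' Spatial gradient of a metric along one axis
#'
#' Spearman rank correlation between a per-synapse metric and a coordinate,
#' with the two-tailed t-test p-value (see [spearman_rho()]).
#'
#' @param values per-synapse metric (n >= 5, not constant).
#' @param coords coordinate along one axis, same length.
#' @return named vector `c(rho, p)`.
#' @export
axis_gradient <- function(values, coords) {
  keep <- !is.na(values) & !is.na(coords)
  spearman_rho(values[keep], coords[keep])
}

#' Map all synapses of a volume in both views
#'
#' Computes anchors, native and translated frames, and group assignments.
#'
#' @param volume a [label_volume()].
#' @param table the matching [label_table()].
#' @return data.frame with native and translated coordinates and groups
#'   (`y_hc_native`, `z_mp_native`, `mp_native`, `hc_native`,
#'   `y_hc_translated`, `z_mp_translated`, `mp_translated`,
#'   `hc_translated`).
#' @export
map_synapses <- function(volume, table) {
  anchors <- synapse_anchors(volume, table)
  map_anchors(anchors)
}

# Frame + group computation on a prebuilt anchor table (also used on
# generator ground truth).
map_anchors <- function(anchors) {
  nat <- assign_groups(native_frame(anchors))
  tra <- assign_groups(translated_frame(anchors))
  out <- anchors
  out$y_hc_native <- nat$y_hc
  out$z_mp_native <- nat$z_mp
  out$mp_native <- nat$mp_group
  out$hc_native <- nat$hc_group
  out$y_hc_translated <- tra$y_hc
  out$z_mp_translated <- tra$z_mp
  out$mp_translated <- tra$mp_group
  out$hc_translated <- tra$hc_group
  out$frame_defined <- tra$frame_defined
  out$mp_flipped <- !is.na(out$mp_native) & !is.na(out$mp_translated) &
    out$mp_native != out$mp_translated
  out
}
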