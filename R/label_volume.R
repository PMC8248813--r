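#' Label volume container
#'
#' Bundles a 3D array of non-negative integer labels with its isotropic voxel
#' spacing and the anatomical axis convention. Label 0 is background. The
#' axis convention is fixed: X runs along the tonotopic (cochlear spiral)
#' axis, Y from the habenular (basal, synaptic) pole toward the cuticular
#' (apical) pole, and Z from the modiolar side (negative) toward the pillar
#' side (positive). Files carry this convention in their metadata and
#' readers re-map when a file states a different order; the array axes are
#' never silently permuted.
#'
#' @param voxels 3D array of non-negative integers, `dim = c(nx, ny, nz)`.
#' @param spacing_nm isotropic voxel edge length in nm (> 0). Default 7, the
#'   acquisition resolution the package is designed around.
#' @param axes named character vector recording the axis convention.
#' @return An object of class `label_volume`.
#' @export
label_volume <- function(voxels,
                         spacing_nm = 7,
                         axes = c(X = "tonotopic",
                                  Y = "habenular-cuticular",
                                  Z = "modiolar-pillar")) {
  if (length(dim(voxels)) != 3L) {
    stop("`voxels` must be a 3D array", call. = FALSE)
  }
  if (!is.numeric(spacing_nm) || length(spacing_nm) != 1L || spacing_nm <= 0) {
    stop("`spacing_nm` must be a single positive number", call. = FALSE)
  }
  v <- voxels
  if (is.double(v)) {
    if (any(v != round(v)) || any(v < 0)) {
      stop("voxel data must be non-negative integers (label map)",
           call. = FALSE)
    }
    storage.mode(v) <- "integer"
  }
  if (!is.integer(v)) {
    stop("voxel data must be integer-valued", call. = FALSE)
  }
  if (any(v < 0L)) stop("labels must be non-negative", call. = FALSE)
  structure(
    list(voxels = v, spacing_nm = as.numeric(spacing_nm), axes = axes),
    class = "label_volume"
  )
}

#' @export
print.label_volume <- function(x, ...) {
  d <- dim(x$voxels)
  labs <- setdiff(sort(present_labels(x$voxels)), 0L)
  cat(sprintf("<label_volume> %d x %d x %d voxels @ %g nm, %d labels\n",
              d[1], d[2], d[3], x$spacing_nm, length(labs)))
  invisible(x)
}

#' Label table
#'
#' Maps each nonzero label of a [label_volume()] to a structure class
#' (`ribbon`, `PD`, `PSD`, or `IHC`), a synapse id, and an inner-hair-cell
#' id. Labels must be unique. Within one synapse the table must contain
#' exactly one PSD, at most one PD (the geometric model synapses carry no
#' PD), and at least one ribbon (double-ribbon synapses are allowed). Every
#' synapse belongs to exactly one IHC.
#'
#' @param label integer vector of nonzero labels.
#' @param structure character vector, one of `"ribbon"`, `"PD"`, `"PSD"`,
#'   `"IHC"`.
#' @param synapse_id integer vector or NA (e.g., for IHC labels).
#' @param ihc_id integer vector or NA.
#' @return A `data.frame` of class `label_table`.
#' @export
label_table <- function(label, structure, synapse_id = NA_integer_,
                        ihc_id = NA_integer_) {
  tab <- data.frame(
    label = as.integer(label),
    structure = as.character(structure),
    synapse_id = as.integer(synapse_id),
    ihc_id = as.integer(ihc_id),
    stringsAsFactors = FALSE
  )
  class(tab) <- c("label_table", "data.frame")
  validate_label_table(tab)
  tab
}

validate_label_table <- function(tab) {
  ok <- c("ribbon", "PD", "PSD", "IHC")
  bad <- setdiff(unique(tab$structure), ok)
  if (length(bad)) {
    stop("unknown structure class(es): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(tab$label)) {
    stop("labels must be unique in the label table", call. = FALSE)
  }
  if (any(tab$label == 0L)) {
    stop("label 0 is reserved for background", call. = FALSE)
  }
  syn <- tab[!is.na(tab$synapse_id) & tab$structure != "IHC", , drop = FALSE]
  for (sid in unique(syn$synapse_id)) {
    rows <- syn[syn$synapse_id == sid, , drop = FALSE]
    n_psd <- sum(rows$structure == "PSD")
    n_pd <- sum(rows$structure == "PD")
    n_rib <- sum(rows$structure == "ribbon")
    if (n_psd != 1L || n_pd > 1L || n_rib < 1L) {
      stop(sprintf(
        "synapse %d must have exactly one PSD, at most one PD and >= 1 ribbon (found %d PSD, %d PD, %d ribbon)",
        sid, n_psd, n_pd, n_rib), call. = FALSE)
    }
    if (length(unique(stats::na.omit(rows$ihc_id))) > 1L) {
      stop(sprintf("synapse %d maps to more than one ihc_id", sid),
           call. = FALSE)
    }
  }
  invisible(tab)
}

# Cross-check that every nonzero label present in the voxel data appears in
# the table; returns orphan labels in the error message when not.
validate_volume_table <- function(volume, table) {
  stopifnot(inherits(volume, "label_volume"))
  validate_label_table(table)
  present <- setdiff(sort(present_labels(volume$voxels)), 0L)
  orphan <- setdiff(present, table$label)
  if (length(orphan)) {
    stop("labels present in volume but missing from label table: ",
         paste(orphan, collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}

# Distinct voxel values, computed in blocks so that large volumes never
# need a second full-array temporary.
present_labels <- function(voxels, block = 2^24) {
  n <- length(voxels)
  acc <- integer(0)
  for (start in seq(1L, n, by = block)) {
    acc <- unique(c(acc, unique(voxels[start:min(start + block - 1, n)])))
  }
  acc
}

# Logical mask of one label (or a set of labels).
label_mask <- function(volume, labels) {
  stopifnot(inherits(volume, "label_volume"))
  array(volume$voxels %in% as.integer(labels), dim = dim(volume$voxels))
}

# Sparse decomposition of a label volume: voxel array indices per label.
# One pass over the array; downstream measurement works on cropped
# per-structure masks so the full array is touched only once.
label_index <- function(volume) {
  fg <- which(volume$voxels != 0L)
  labs <- volume$voxels[fg]
  split(fg, labs)
}

# Build a tight cropped logical mask (plus its index offset) from linear
# indices into the full array.
crop_mask <- function(lin_idx, dims) {
  arr_idx <- arrayInd(lin_idx, dims)
  lo <- apply(arr_idx, 2L, min)
  hi <- apply(arr_idx, 2L, max)
  m <- array(FALSE, hi - lo + 1L)
  m[cbind(arr_idx[, 1] - lo[1] + 1L,
          arr_idx[, 2] - lo[2] + 1L,
          arr_idx[, 3] - lo[3] + 1L)] <- TRUE
  list(mask = m, offset = lo - 1L)  # offset in voxels; add to local indices
}

#' Vesicle marker set
#'
#' Point markers (vesicle centers) in nm, optionally tagged with a synapse
#' id. Coordinates must fall inside the bounding box of the volume they
#' accompany when one is supplied.
#'
#' @param points numeric matrix or data.frame with columns x_nm, y_nm, z_nm.
#' @param synapse_id optional integer vector, one per point.
#' @param volume optional [label_volume()] used to bound-check coordinates.
#' @return data.frame of class `vesicle_markers`.
#' @export
vesicle_markers <- function(points, synapse_id = NA_integer_, volume = NULL) {
  pts <- as.data.frame(points)
  if (ncol(pts) < 3L) stop("markers need x, y, z columns", call. = FALSE)
  names(pts)[1:3] <- c("x_nm", "y_nm", "z_nm")
  pts$synapse_id <- as.integer(synapse_id)
  if (!is.null(volume)) {
    lim <- dim(volume$voxels) * volume$spacing_nm
    out <- pts$x_nm < 0 | pts$y_nm < 0 | pts$z_nm < 0 |
      pts$x_nm > lim[1] | pts$y_nm > lim[2] | pts$z_nm > lim[3]
    if (any(out)) {
      stop("marker(s) outside volume bounding box at rows: ",
           paste(which(out), collapse = ", "), call. = FALSE)
    }
  }
  class(pts) <- c("vesicle_markers", "data.frame")
  pts
}
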