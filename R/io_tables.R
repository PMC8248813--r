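# Measurement tables and mesh export.

# Stable column order for morphometry CSVs; units are part of the names.
MORPHOMETRY_COLUMNS <- c(
  "label", "structure", "synapse_id", "ihc_id",
  "volume_nm3", "voxelface_area_nm2", "ellipse_area_um2",
  "long_axis_nm", "short_axis_nm", "ls_ratio",
  "long_dir_x", "long_dir_y", "long_dir_z",
  "short_dir_x", "short_dir_y", "short_dir_z"
)

#' Write a morphometry table to CSV
#'
#' One row per measured structure, fixed column order, units encoded in the
#' column names (nm, nm2, um2). An empty input produces a header-only CSV.
#' Values survive a write/read round trip to at least 6 significant digits.
#'
#' @param rows data.frame of morphometry rows (see [measure_all()]).
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
write_measurements <- function(rows, path) {
  if (is.null(rows) || nrow(rows) == 0L) {
    rows <- as.data.frame(
      setNames(rep(list(numeric(0)), length(MORPHOMETRY_COLUMNS)),
               MORPHOMETRY_COLUMNS))
  }
  miss <- setdiff(MORPHOMETRY_COLUMNS, names(rows))
  for (m in miss) rows[[m]] <- NA_real_
  utils::write.csv(rows[, MORPHOMETRY_COLUMNS, drop = FALSE], path,
                   row.names = FALSE)
  invisible(path)
}

#' @rdname write_measurements
#' @export
read_measurements <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Export a binary mask as a triangle mesh
#'
#' Writes the voxel boundary faces of a mask as a triangle mesh (two
#' triangles per exposed voxel face), in nm coordinates, to ASCII PLY or
#' OBJ. This is a visualization aid: the mesh is the exact voxel surface,
#' not a smoothed isosurface, so its area equals the voxel-face area.
#'
#' @param mask binary 3D array (nonempty).
#' @param spacing_nm voxel edge in nm.
#' @param path output path ending in `.ply` or `.obj`.
#' @return the path, invisibly.
#' @export
export_mesh <- function(mask, spacing_nm, path) {
  mask <- as_mask(mask)
  stopifnot_mask3d(mask)  # errors on empty mask
  bf <- boundary_faces(mask, spacing_nm)
  n_face <- nrow(bf$centers)
  h <- spacing_nm / 2
  # for a face with outward normal n, the 4 corners span the two axes
  # orthogonal to n
  verts <- matrix(0, 4L * n_face, 3L)
  for (i in seq_len(n_face)) {
    nrm <- bf$normals[i, ]
    ax <- which(nrm != 0)
    others <- setdiff(1:3, ax)
    u <- c(0, 0, 0); u[others[1]] <- h
    v <- c(0, 0, 0); v[others[2]] <- h
    ctr <- bf$centers[i, ]
    verts[4L * i - 3L, ] <- ctr - u - v
    verts[4L * i - 2L, ] <- ctr + u - v
    verts[4L * i - 1L, ] <- ctr + u + v
    verts[4L * i, ] <- ctr - u + v
  }
  tri <- matrix(0L, 2L * n_face, 3L)
  for (i in seq_len(n_face)) {
    b <- 4L * (i - 1L)
    tri[2L * i - 1L, ] <- b + c(1L, 2L, 3L)
    tri[2L * i, ] <- b + c(1L, 3L, 4L)
  }
  ext <- tolower(tools::file_ext(path))
  if (ext == "ply") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c(
      "ply", "format ascii 1.0",
      paste("element vertex", nrow(verts)),
      "property float x", "property float y", "property float z",
      paste("element face", nrow(tri)),
      "property list uchar int vertex_indices", "end_header"), con)
    utils::write.table(format(verts, trim = TRUE, scientific = FALSE),
                       con, row.names = FALSE, col.names = FALSE,
                       quote = FALSE)
    utils::write.table(cbind(3L, tri - 1L), con, row.names = FALSE,
                       col.names = FALSE, quote = FALSE)
  } else if (ext == "obj") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("v %g %g %g", verts[, 1], verts[, 2], verts[, 3]), con)
    writeLines(sprintf("f %d %d %d", tri[, 1], tri[, 2], tri[, 3]), con)
  } else {
    stop("unsupported mesh format: ", ext, " (use .ply or .obj)",
         call. = FALSE)
  }
  invisible(path)
}

# Read back an ASCII PLY written by export_mesh (used in tests).
read_ply <- function(path) {
  lines <- readLines(path)
  end <- which(lines == "end_header")
  nv <- as.integer(sub("element vertex ", "",
                       grep("^element vertex", lines, value = TRUE)))
  nf <- as.integer(sub("element face ", "",
                       grep("^element face", lines, value = TRUE)))
  verts <- do.call(rbind, lapply(lines[end + seq_len(nv)], function(l)
    as.numeric(strsplit(l, "\\s+")[[1]])))
  faces <- do.call(rbind, lapply(lines[end + nv + seq_len(nf)], function(l)
    as.integer(strsplit(l, "\\s+")[[1]])[-1] + 1L))
  list(vertices = verts, faces = faces)
}
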