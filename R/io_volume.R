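# Label-volume file I/O: multi-page TIFF (pages are Z slices) and NRRD.

#' Read a label volume and its label table
#'
#' Reads an unsigned-integer label map from a multi-page TIFF (`.tif`,
#' `.tiff`; pages are Z slices) or an NRRD file (`.nrrd`), together with a
#' CSV label table (columns `label,structure,synapse_id,ihc_id`). Every
#' nonzero label present in the voxel data must appear in the table;
#' otherwise the orphan labels are named in the error.
#'
#' @param volume_path path to the TIFF or NRRD file.
#' @param table_path path to the label-table CSV.
#' @param spacing_nm voxel spacing override in nm. For NRRD the header
#'   spacing is used unless overridden; TIFF files do not carry spacing, so
#'   the default (7 nm) or the override applies.
#' @return list with elements `volume` ([label_volume()]) and `table`
#'   ([label_table()]).
#' @export
read_label_volume <- function(volume_path, table_path, spacing_nm = NULL) {
  ext <- tolower(tools::file_ext(volume_path))
  if (ext %in% c("tif", "tiff")) {
    vox <- read_tiff_volume(volume_path)
    sp <- if (is.null(spacing_nm)) 7 else spacing_nm
  } else if (ext == "nrrd") {
    nr <- read_nrrd(volume_path)
    vox <- nr$data
    sp <- if (is.null(spacing_nm)) nr$spacing_nm else spacing_nm
  } else {
    stop("unsupported volume format: ", ext, " (use TIFF or NRRD)",
         call. = FALSE)
  }
  vol <- label_volume(vox, spacing_nm = sp)
  tab <- read_label_table(table_path)
  validate_volume_table(vol, tab)
  list(volume = vol, table = tab)
}

read_tiff_volume <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (any(!vapply(pages, is.matrix, logical(1)))) {
    stop("TIFF pages must be single-channel integer matrices", call. = FALSE)
  }
  d1 <- dim(pages[[1]])
  # page matrices are Y (rows) x X (cols); assemble as [x, y, z]
  vox <- array(0L, c(d1[2], d1[1], length(pages)))
  for (k in seq_along(pages)) {
    p <- pages[[k]]
    if (!is.integer(p)) {
      stop("non-integer voxel data in TIFF page ", k, call. = FALSE)
    }
    vox[, , k] <- t(p)
  }
  vox
}

#' Write a label volume to disk
#'
#' Writes multi-page TIFF (16-bit unsigned; pages are Z slices) or NRRD
#' (raw encoding, with the voxel spacing recorded in the header).
#'
#' @param volume a [label_volume()].
#' @param path output path; format chosen by extension (.tif/.tiff/.nrrd).
#' @return the path, invisibly.
#' @export
write_label_volume <- function(volume, path) {
  stopifnot(inherits(volume, "label_volume"))
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    v <- volume$voxels
    if (max(v) > 65535L) stop("labels exceed 16-bit TIFF range", call. = FALSE)
    pages <- lapply(seq_len(dim(v)[3]), function(k) t(v[, , k]) / 65535)
    tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "LZW")
  } else if (ext == "nrrd") {
    write_nrrd(volume$voxels, path, spacing_nm = volume$spacing_nm)
  } else {
    stop("unsupported volume format: ", ext, call. = FALSE)
  }
  invisible(path)
}

# Minimal NRRD support (detached headers not supported): raw and gzip
# encodings, little-endian, integer types.
read_nrrd <- function(path) {
  bytes <- readBin(path, "raw", n = file.size(path))
  # header ends at the first blank line (\n\n); parse it as text
  nl <- which(bytes == as.raw(10L))
  blank <- nl[which(diff(nl) == 1L)[1] + 1L]
  if (is.na(blank)) stop("malformed NRRD: no blank line after header",
                         call. = FALSE)
  hdr <- strsplit(rawToChar(bytes[seq_len(blank - 1L)]), "\n")[[1]]
  if (!grepl("^NRRD", hdr[1])) stop("not an NRRD file", call. = FALSE)
  fields <- list()
  for (line in hdr[-1]) {
    if (grepl("^#", line) || !nzchar(line)) next
    kv <- regmatches(line, regexpr(":", line), invert = TRUE)[[1]]
    if (length(kv) == 2L) {
      fields[[tolower(trimws(kv[1]))]] <- trimws(sub("^=", "", kv[2]))
    }
  }
  sizes <- as.integer(strsplit(fields[["sizes"]], "\\s+")[[1]])
  type <- fields[["type"]]
  enc <- fields[["encoding"]]
  n <- prod(sizes)
  rtype <- switch(type,
    "uint8" = list(size = 1L, signed = FALSE),
    "uint16" = list(size = 2L, signed = FALSE),
    "int16" = list(size = 2L, signed = TRUE),
    "int32" = , "int" = list(size = 4L, signed = TRUE),
    stop("unsupported NRRD type: ", type, call. = FALSE)
  )
  raw_bytes <- bytes[(blank + 1L):length(bytes)]
  if (enc %in% c("gzip", "gz")) {
    raw_bytes <- memDecompress(raw_bytes, type = "gzip")
  } else if (!identical(enc, "raw")) {
    stop("unsupported NRRD encoding: ", enc, call. = FALSE)
  }
  vals <- readBin(raw_bytes, what = "integer", n = n, size = rtype$size,
                  signed = if (rtype$size >= 4L) TRUE else rtype$signed,
                  endian = "little")
  spacing <- NA_real_
  if (!is.null(fields[["spacings"]])) {
    spacing <- as.numeric(strsplit(fields[["spacings"]], "\\s+")[[1]])[1]
  }
  list(data = array(as.integer(vals), sizes),
       spacing_nm = if (is.na(spacing)) 7 else spacing)
}

write_nrrd <- function(arr, path, spacing_nm = 7, encoding = "raw") {
  sizes <- dim(arr)
  type <- if (max(arr) < 65536L) "uint16" else "int32"
  size <- if (type == "uint16") 2L else 4L
  hdr <- c(
    "NRRD0004",
    paste0("type: ", type),
    paste0("dimension: ", length(sizes)),
    paste0("sizes: ", paste(sizes, collapse = " ")),
    paste0("spacings: ", paste(rep(spacing_nm, length(sizes)), collapse = " ")),
    paste0("encoding: ", encoding),
    "endian: little"
  )
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(paste0(paste(hdr, collapse = "\n"), "\n\n")), con)
  payload <- writeBin(as.integer(arr), raw(), size = size, endian = "little")
  if (encoding == "gzip") payload <- memCompress(payload, "gzip")
  writeBin(payload, con)
  invisible(path)
}

#' Read a label table CSV
#'
#' @param path CSV with columns `label,structure,synapse_id,ihc_id`.
#' @return a [label_table()].
#' @export
read_label_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("label", "structure", "synapse_id", "ihc_id")
  miss <- setdiff(need, names(tab))
  if (length(miss)) {
    stop("label table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  label_table(tab$label, tab$structure, tab$synapse_id, tab$ihc_id)
}

#' @rdname read_label_table
#' @param table a [label_table()] to write.
#' @export
write_label_table <- function(table, path) {
  utils::write.csv(as.data.frame(table)[, c("label", "structure",
                                            "synapse_id", "ihc_id")],
                   path, row.names = FALSE)
  invisible(path)
}

#' Read / write vesicle marker CSVs
#'
#' Markers are vesicle-center coordinates in nm with an optional synapse id
#' (columns `x_nm,y_nm,z_nm,synapse_id`).
#'
#' @param path CSV path.
#' @param volume optional [label_volume()] for bound checking.
#' @return a [vesicle_markers()] data.frame.
#' @export
read_markers <- function(path, volume = NULL) {
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("x_nm", "y_nm", "z_nm")
  if (!all(need %in% names(m))) {
    stop("marker CSV needs columns x_nm, y_nm, z_nm", call. = FALSE)
  }
  sid <- if ("synapse_id" %in% names(m)) m$synapse_id else NA_integer_
  vesicle_markers(m[, need], synapse_id = sid, volume = volume)
}

#' @rdname read_markers
#' @param markers a [vesicle_markers()] object to write.
#' @export
write_markers <- function(markers, path) {
  utils::write.csv(as.data.frame(markers), path, row.names = FALSE)
  invisible(path)
}
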