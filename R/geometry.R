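# Internal voxel-geometry helpers shared across modules.
#
# Conventions: masks are 3D logical (or 0/1) arrays with dim = c(nx, ny, nz)
# in the X (tonotopic), Y (habenular -> cuticular), Z (modiolar -> pillar)
# axis order. Physical coordinates are voxel centers,
# pos_nm = (index - 0.5) * spacing_nm for R's 1-based indices, so a single
# voxel object is treated symmetrically about its center.

as_mask <- function(x) {
  if (is.logical(x)) {
    x[is.na(x)] <- FALSE
    return(x)
  }
  if (!is.numeric(x) && !is.integer(x)) {
    stop("mask must be a logical or numeric array", call. = FALSE)
  }
  x != 0
}

stopifnot_mask3d <- function(mask, allow_empty = FALSE) {
  if (length(dim(mask)) != 3L) {
    stop("mask must be a 3D array", call. = FALSE)
  }
  if (!allow_empty && !any(mask)) {
    stop("mask is empty: structure must contain at least one voxel",
         call. = FALSE)
  }
  invisible(mask)
}

# Voxel-center coordinates (nm) of foreground voxels, as an n x 3 matrix.
mask_coords <- function(mask, spacing_nm) {
  mask <- as_mask(mask)
  stopifnot_mask3d(mask)
  idx <- which(mask, arr.ind = TRUE)
  (idx - 0.5) * spacing_nm
}

# Pad-and-shift neighbor lookup: for each foreground voxel, which of the six
# faces touch background (or the array edge)?  Returns the boundary-face
# centers and outward unit normals.  Face centers sit half a voxel out from
# the voxel center along the face normal.
boundary_faces <- function(mask, spacing_nm) {
  mask <- as_mask(mask)
  stopifnot_mask3d(mask)
  d <- dim(mask)
  # padded array so edge voxels see background outside
  pad <- array(FALSE, d + 2L)
  pad[2:(d[1] + 1L), 2:(d[2] + 1L), 3:(d[3] + 2L) - 1L] <- mask
  core <- pad[2:(d[1] + 1L), 2:(d[2] + 1L), 2:(d[3] + 1L)]

  shifts <- list(
    c(-1L, 0L, 0L), c(1L, 0L, 0L),
    c(0L, -1L, 0L), c(0L, 1L, 0L),
    c(0L, 0L, -1L), c(0L, 0L, 1L)
  )
  centers <- vector("list", 6L)
  normals <- vector("list", 6L)
  for (k in seq_along(shifts)) {
    s <- shifts[[k]]
    nb <- pad[2:(d[1] + 1L) + s[1], 2:(d[2] + 1L) + s[2], 2:(d[3] + 1L) + s[3],
              drop = FALSE]
    dim(nb) <- d
    face <- core & !nb
    if (!any(face)) next
    idx <- which(face, arr.ind = TRUE)
    ctr <- (idx - 0.5) * spacing_nm
    ctr <- sweep(ctr, 2L, s * 0.5 * spacing_nm, "+")
    centers[[k]] <- ctr
    normals[[k]] <- matrix(s, nrow = nrow(ctr), ncol = 3L, byrow = TRUE)
  }
  keep <- !vapply(centers, is.null, logical(1))
  if (!any(keep)) stop("mask has no boundary faces", call. = FALSE)
  list(
    centers = do.call(rbind, centers[keep]),
    normals = do.call(rbind, normals[keep])
  )
}

# Number of foreground faces adjacent to background (6-connectivity),
# counting array edges as background.
count_boundary_faces <- function(mask) {
  mask <- as_mask(mask)
  stopifnot_mask3d(mask)
  d <- dim(mask)
  pad <- array(FALSE, d + 2L)
  pad[2:(d[1] + 1L), 2:(d[2] + 1L), 2:(d[3] + 1L)] <- mask
  n <- 0
  for (s in list(c(-1L, 0L, 0L), c(1L, 0L, 0L), c(0L, -1L, 0L), c(0L, 1L, 0L),
                 c(0L, 0L, -1L), c(0L, 0L, 1L))) {
    nb <- pad[2:(d[1] + 1L) + s[1], 2:(d[2] + 1L) + s[2], 2:(d[3] + 1L) + s[3],
              drop = FALSE]
    n <- n + sum(mask & !nb)
  }
  n
}

# Exact nearest-neighbor distances from each row of `from` to the point set
# `to`, chunked to bound the transient n x m distance matrix.
nn_dist <- function(from, to, chunk = 2048L) {
  from <- as.matrix(from)
  to <- as.matrix(to)
  if (nrow(from) == 0L || nrow(to) == 0L) {
    stop("nearest-neighbor query on an empty point set", call. = FALSE)
  }
  nn_min(from, to, chunk)$dist
}

# Nearest neighbor in `to` for each row of `from`: distance and index in a
# single chunked pass.
nn_min <- function(from, to, chunk = NULL) {
  from <- as.matrix(from)
  to <- as.matrix(to)
  if (nrow(from) == 0L || nrow(to) == 0L) {
    stop("nearest-neighbor query on an empty point set", call. = FALSE)
  }
  n <- nrow(from)
  m <- nrow(to)
  if (is.null(chunk)) chunk <- max(16L, min(4096L, 2^22 %/% m))
  dist <- numeric(n)
  index <- integer(n)
  to_sq <- rowSums(to^2)
  f_sq <- rowSums(from^2)
  for (start in seq(1L, n, by = chunk)) {
    idx <- start:min(start + chunk - 1L, n)
    # h[i, j] = |t_i|^2 - 2 t_i . f_j ; argmin_i h + |f_j|^2 = squared dist
    h <- to %*% t(from[idx, , drop = FALSE])
    h <- h * -2
    h <- h + to_sq                 # recycles down columns
    for (k in seq_along(idx)) {
      jm <- which.min(h[, k])
      index[idx[k]] <- jm
      dist[idx[k]] <- sqrt(max(h[jm, k] + f_sq[idx[k]], 0))
    }
  }
  list(dist = dist, index = index)
}

nn_index <- function(from, to, chunk = 2048L) {
  nn_min(from, to, chunk)$index
}

# Radical-inverse (van der Corput) sequence in the given base; i >= 1.
radical_inverse <- function(i, base) {
  out <- numeric(length(i))
  f <- 1 / base
  k <- i
  while (any(k > 0)) {
    out <- out + f * (k %% base)
    k <- k %/% base
    f <- f / base
  }
  out
}

# Deterministic nested low-discrepancy direction set on the unit sphere:
# Halton(2,3) pairs mapped by the area-preserving cylindrical projection.
# The first n directions of a longer set are exactly the shorter set, so
# axis estimates refine monotonically with n.
sphere_directions <- function(n) {
  i <- seq_len(n)
  z <- 2 * radical_inverse(i, 2L) - 1
  phi <- 2 * pi * radical_inverse(i, 3L)
  r <- sqrt(pmax(1 - z^2, 0))
  cbind(r * cos(phi), r * sin(phi), z)
}

# Direction set closed under the full octahedral group: each base direction
# is expanded into its 48 signed axis permutations. Closure makes axis
# measurements exactly invariant under 90-degree lattice rotations of the
# mask; expansion in whole orbits preserves the nesting (and hence the
# refinement monotonicity) of the base sequence.
octahedral_directions <- function(n) {
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
                c(3, 1, 2), c(3, 2, 1))
  signs <- as.matrix(expand.grid(c(1, -1), c(1, -1), c(1, -1)))
  n_orbit <- ceiling(n / 48)
  base <- sphere_directions(n_orbit)
  out <- matrix(NA_real_, n_orbit * 48L, 3L)
  k <- 0L
  for (i in seq_len(n_orbit)) {
    for (p in perms) {
      img <- base[i, p]
      for (s in seq_len(8L)) {
        k <- k + 1L
        out[k, ] <- img * signs[s, ]
      }
    }
  }
  out
}

# Deterministic rotation matrix from three angles (intrinsic ZYX).
rotation_matrix <- function(ax, ay, az) {
  cx <- cos(ax); sx <- sin(ax)
  cy <- cos(ay); sy <- sin(ay)
  cz <- cos(az); sz <- sin(az)
  rz <- matrix(c(cz, -sz, 0, sz, cz, 0, 0, 0, 1), 3, 3, byrow = TRUE)
  ry <- matrix(c(cy, 0, sy, 0, 1, 0, -sy, 0, cy), 3, 3, byrow = TRUE)
  rx <- matrix(c(1, 0, 0, 0, cx, -sx, 0, sx, cx), 3, 3, byrow = TRUE)
  rz %*% ry %*% rx
}

# Random rotation (uniform-ish via random angles; adequate for scrambling
# phantom orientations).
random_rotation <- function() {
  rotation_matrix(stats::runif(1, 0, 2 * pi),
                  acos(stats::runif(1, -1, 1)) - pi / 2,
                  stats::runif(1, 0, 2 * pi))
}
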