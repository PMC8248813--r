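# Shared fixtures. Phantoms and their proximity profiles are expensive
# (tens of seconds at 7 nm), so they are built lazily and cached for the
# whole test run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- builder()
  .fixture_cache[[key]]
}

get_phantom <- function(kind) {
  cached(paste0("phantom_", kind),
         function() make_model_synapse(phantom_spec(kind)))
}

get_phantom_profile <- function(kind) {
  cached(paste0("profile_", kind), function() {
    mp <- get_phantom(kind)
    proximity_profiles(mp$volume, mp$table)[[1]]
  })
}

# A small voxelized scene shared by the recovery-style tests.
get_small_scene <- function() {
  cached("small_scene", function() {
    make_scene(scene_spec("p34-like", n_ihc = 2L,
                          synapses_per_ihc = c(4L, 4L), seed = 7L))
  })
}

# Digital ball mask of the given radius (nm).
digital_ball <- function(radius_nm, spacing_nm) {
  voxelize_primitive("ball", list(diameter_nm = 2 * radius_nm), spacing_nm)
}

# Solid axis-aligned box mask with the given edge lengths (nm).
digital_box <- function(edges_nm, spacing_nm) {
  n <- round(edges_nm / spacing_nm)
  array(TRUE, n)
}

# Digital ellipsoid mask with the given semi-axes (nm).
digital_ellipsoid <- function(semi_nm, spacing_nm, rotation = NULL) {
  params <- list(semi_axes_nm = semi_nm)
  if (!is.null(rotation)) params$rotation <- rotation
  voxelize_primitive("ellipsoid", params, spacing_nm)
}

# Spherical shell mask: voxels whose center radius lies in [r_in, r_out].
digital_shell <- function(r_in_nm, r_out_nm, spacing_nm) {
  n <- 2L * ceiling(r_out_nm / spacing_nm) + 3L
  ctr <- (n + 1) / 2
  idx <- which(array(TRUE, c(n, n, n)), arr.ind = TRUE)
  d <- sqrt(rowSums(((idx - ctr) * spacing_nm)^2))
  array(d >= r_in_nm & d <= r_out_nm, c(n, n, n))
}

# Independent brute-force distance from points to a mask surface (oracle
# used against the package's chunked nearest-neighbor path).
brute_surface_dist <- function(pts, mask, spacing_nm, origin_nm = c(0, 0, 0)) {
  surf <- ribbonmorph:::boundary_faces(mask, spacing_nm)$centers
  surf <- sweep(surf, 2L, origin_nm, "+")
  apply(as.matrix(pts), 1L, function(p)
    sqrt(min(colSums((t(surf) - p)^2))))
}
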