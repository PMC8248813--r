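# Geometric model synapses: voxel phantoms with known analytic geometry.
#
# All phantoms use a Y-up local frame: the PSD sheet is centered on the
# origin with its reference plane at y = 0 and the ribbon sphere sits above
# it on the +Y axis. X and Z span the sheet.

# Evaluate an analytic inequality on a voxel grid. `extent` is a 3x2 matrix
# of nm bounds (rows x, y, z); bounds are snapped outward to whole voxels.
# `fun(x, y, z)` receives voxel-center coordinates and returns logical.
voxelize_on_grid <- function(fun, extent, spacing_nm) {
  lo <- floor(extent[, 1] / spacing_nm)
  hi <- ceiling(extent[, 2] / spacing_nm)
  n <- as.integer(hi - lo)
  if (any(n < 1L)) stop("degenerate voxelization extent", call. = FALSE)
  cx <- (lo[1] + seq_len(n[1]) - 0.5) * spacing_nm
  cy <- (lo[2] + seq_len(n[2]) - 0.5) * spacing_nm
  cz <- (lo[3] + seq_len(n[3]) - 0.5) * spacing_nm
  x <- array(rep(cx, times = n[2] * n[3]), n)
  y <- array(rep(rep(cy, each = n[1]), times = n[3]), n)
  z <- array(rep(cz, each = n[1] * n[2]), n)
  mask <- array(fun(x, y, z), n)
  list(mask = mask, origin_nm = lo * spacing_nm)
}

primitive_fun <- function(shape, params) {
  p <- params
  switch(shape,
    ball = {
      r <- p$diameter_nm / 2
      function(x, y, z) x^2 + y^2 + z^2 <= r^2
    },
    ellipsoid = {
      a <- p$semi_axes_nm
      rot <- if (is.null(p$rotation)) diag(3) else p$rotation
      function(x, y, z) {
        q <- cbind(as.vector(x), as.vector(y), as.vector(z)) %*% rot
        (q[, 1] / a[1])^2 + (q[, 2] / a[2])^2 + (q[, 3] / a[3])^2 <= 1
      }
    },
    annulus = {
      # flat sheet in the XZ plane: top surface at y = 0, thickness below
      ro <- p$outer_diameter_nm / 2
      ri <- if (is.null(p$hole_diameter_nm)) 0 else p$hole_diameter_nm / 2
      t <- p$thickness_nm
      function(x, y, z) {
        r2 <- x^2 + z^2
        r2 <= ro^2 & r2 >= ri^2 & y <= 0 & y >= -t
      }
    },
    `capped-shell` = {
      # spherical bowl opening toward +Y: sphere center at origin, shell
      # thickness outward, cut at the mouth plane y = 0
      R <- p$radius_nm
      t <- p$thickness_nm
      function(x, y, z) {
        d <- sqrt(x^2 + y^2 + z^2)
        d >= R & d <= R + t & y <= 0
      }
    },
    `torus-cap` = {
      # upper half of a torus shell (ring radius c, tube radius rho),
      # thickness inward from the outer tube surface
      cc <- p$ring_radius_nm
      rho <- p$tube_radius_nm
      t <- p$thickness_nm
      function(x, y, z) {
        r <- sqrt(x^2 + z^2)
        d <- sqrt((r - cc)^2 + y^2)
        d <= rho & d >= rho - t & y >= 0
      }
    },
    `donut-sheet` = {
      # surface of revolution with a central hole: descending radial
      # profile, concave (curvature center above the sheet) near the hole
      # and convex (center below) peripherally; thickness downward
      prof <- donut_profile(p$hole_diameter_nm / 2, p$outer_diameter_nm / 2,
                            p$inner_radius_nm, p$outer_radius_nm)
      t <- p$thickness_nm
      function(x, y, z) {
        r <- sqrt(x^2 + z^2)
        ys <- prof(r)
        ok <- !is.na(ys) & y <= ys & y >= ys - t
        ok & r >= p$hole_diameter_nm / 2 & r <= p$outer_diameter_nm / 2
      }
    },
    stop("unknown primitive shape: ", shape, call. = FALSE)
  )
}

# Radial height profile of the donut sheet. Inner section: circular arc of
# radius `r_in` entered at the hole edge at a fixed 25-degree downward
# angle, descending to its lowest point; outer section: convex parabolic
# fall-off with curvature radius `r_out`; C1-continuous at the junction.
donut_profile <- function(hole_r, outer_r, r_in, r_out) {
  theta0 <- 25 * pi / 180
  a <- r_in * sin(theta0)      # radial run of the concave section
  b <- r_in * cos(theta0)
  depth <- r_in - b            # depth at the junction
  function(r) {
    y <- rep(NA_real_, length(r))
    inside <- r >= hole_r & r <= outer_r
    inner <- inside & r <= hole_r + a
    outer <- inside & r > hole_r + a
    y[inner] <- b - sqrt(r_in^2 - (r[inner] - hole_r - a)^2)
    y[outer] <- -depth - (r[outer] - hole_r - a)^2 / (2 * r_out)
    y
  }
}

#' Voxelize an analytic primitive
#'
#' Rasterizes one of the package's analytic shapes onto an isotropic voxel
#' grid: the mask contains exactly the voxels whose centers satisfy the
#' shape's inequality. Shapes: `ball` (`diameter_nm`), `ellipsoid`
#' (`semi_axes_nm`, optional `rotation` matrix), `annulus` (flat sheet;
#' `outer_diameter_nm`, optional `hole_diameter_nm`, `thickness_nm`),
#' `capped-shell` (spherical bowl; `radius_nm`, `thickness_nm`),
#' `torus-cap` (`ring_radius_nm`, `tube_radius_nm`, `thickness_nm`), and
#' `donut-sheet` (`hole_diameter_nm`, `outer_diameter_nm`,
#' `inner_radius_nm`, `outer_radius_nm`, `thickness_nm`).
#'
#' A ball smaller than one voxel still contains its center voxel.
#'
#' @param shape shape name (see above).
#' @param params named list of shape parameters, lengths in nm (positive).
#' @param spacing_nm voxel edge in nm.
#' @param extent optional 3x2 matrix of nm bounds; default covers the shape.
#' @return binary 3D array.
#' @export
voxelize_primitive <- function(shape, params, spacing_nm, extent = NULL) {
  num <- unlist(Filter(is.numeric, params))
  if (any(num <= 0)) stop("primitive parameters must be positive",
                          call. = FALSE)
  if (is.null(extent)) {
    half <- switch(shape,
      ball = rep(params$diameter_nm / 2, 3),
      ellipsoid = rep(max(params$semi_axes_nm), 3),
      annulus = c(params$outer_diameter_nm / 2, params$thickness_nm,
                  params$outer_diameter_nm / 2),
      `capped-shell` = rep(params$radius_nm + params$thickness_nm, 3),
      `torus-cap` = rep(params$ring_radius_nm + params$tube_radius_nm, 3),
      `donut-sheet` = rep(params$outer_diameter_nm / 2, 3),
      stop("unknown primitive shape: ", shape, call. = FALSE)
    )
    margin <- spacing_nm
    extent <- cbind(-(half + margin), half + margin)
    if (shape == "annulus") extent[2, ] <- c(-params$thickness_nm - margin,
                                             margin)
    if (shape == "capped-shell") extent[2, 2] <- margin
    if (shape == "torus-cap") extent[2, 1] <- -margin
    if (shape == "donut-sheet") {
      extent[2, ] <- c(-(params$inner_radius_nm + params$outer_diameter_nm^2 /
                           (8 * params$outer_radius_nm)) - margin, margin)
    }
  }
  out <- voxelize_on_grid(primitive_fun(shape, params), extent, spacing_nm)
  if (!any(out$mask)) {
    # guarantee at least the center voxel for sub-voxel balls
    if (shape == "ball") {
      ctr <- round(-out$origin_nm / spacing_nm + 0.5)
      out$mask[ctr[1], ctr[2], ctr[3]] <- TRUE
    } else {
      stop("primitive produced an empty mask (shape smaller than grid?)",
           call. = FALSE)
    }
  }
  out$mask
}

#' Phantom specification for the four geometric model synapses
#'
#' Defaults reproduce the published virtual synapses: a spherical ribbon of
#' diameter 300 nm whose edge sits 84 nm (12 voxels at 7 nm) from the
#' center of the PSD sheet, a PSD whose 2D projection has diameter 1400 nm,
#' and (ring/donut) a central hole of diameter 250 nm. The hemisphere's
#' bowl radius and the donut's two curvature radii are not pinned down by
#' the published description and are exposed as parameters; the defaults
#' place the ribbon near the bowl's sphere center (distances constrained to
#' a narrow range) and give the donut a gently concave inner lip falling
#' away convexly toward the rim.
#'
#' @param kind `"hemisphere"`, `"disk"`, `"ring"`, or `"donut"`.
#' @param ribbon_diameter_nm sphere diameter of the ribbon (default 300).
#' @param ribbon_offset_nm edge-to-PSD-center offset (default 84).
#' @param psd_projected_diameter_nm projected PSD diameter (default 1400).
#' @param hole_diameter_nm central hole diameter, ring/donut (default 250).
#' @param psd_thickness_voxels sheet thickness in voxels (default 2).
#' @param spacing_nm voxel edge (default 7).
#' @param bowl_radius_nm hemisphere bowl sphere radius (default
#'   `psd_projected_diameter_nm / 2`).
#' @param donut_inner_radius_nm concave curvature radius near the hole
#'   (default 300).
#' @param donut_outer_radius_nm convex curvature radius of the periphery
#'   (default 600).
#' @return list of class `phantom_spec`.
#' @export
phantom_spec <- function(kind = c("hemisphere", "disk", "ring", "donut"),
                         ribbon_diameter_nm = 300,
                         ribbon_offset_nm = 84,
                         psd_projected_diameter_nm = 1400,
                         hole_diameter_nm = 250,
                         psd_thickness_voxels = 2L,
                         spacing_nm = 7,
                         bowl_radius_nm = psd_projected_diameter_nm / 2,
                         donut_inner_radius_nm = 300,
                         donut_outer_radius_nm = 600) {
  kind <- match.arg(kind)
  lens <- c(ribbon_diameter_nm, ribbon_offset_nm, psd_projected_diameter_nm,
            hole_diameter_nm, psd_thickness_voxels, spacing_nm,
            bowl_radius_nm, donut_inner_radius_nm, donut_outer_radius_nm)
  if (any(lens <= 0)) stop("all phantom lengths must be positive",
                           call. = FALSE)
  if (hole_diameter_nm >= psd_projected_diameter_nm) {
    stop("hole diameter must be smaller than the projected PSD diameter",
         call. = FALSE)
  }
  structure(list(
    kind = kind,
    ribbon_diameter_nm = ribbon_diameter_nm,
    ribbon_offset_nm = ribbon_offset_nm,
    psd_projected_diameter_nm = psd_projected_diameter_nm,
    hole_diameter_nm = hole_diameter_nm,
    psd_thickness_voxels = as.integer(psd_thickness_voxels),
    spacing_nm = spacing_nm,
    bowl_radius_nm = bowl_radius_nm,
    donut_inner_radius_nm = donut_inner_radius_nm,
    donut_outer_radius_nm = donut_outer_radius_nm
  ), class = "phantom_spec")
}

#' Build a geometric model synapse
#'
#' Constructs the labeled voxel volume for one of the four model synapses
#' (ribbon label 1, PSD label 2) plus the matching label table. The ribbon
#' is a sphere; the PSD is a sheet of the requested kind. Ribbon placement:
#' for the flat-plane models (disk, ring, donut) the ribbon sits on the
#' sheet's symmetry axis with its lowest point `ribbon_offset_nm` above the
#' central point of the sheet's reference plane; for the hemisphere the
#' offset is taken from the centroid of the bowl shell toward the mouth, so
#' the ribbon ends up near the bowl's sphere center and PSD-to-ribbon
#' distances span a narrow range.
#'
#' @param spec a [phantom_spec()].
#' @return list with `volume` ([label_volume()]), `table`, and `geometry`
#'   (nm positions of ribbon center and grid origin, for oracles).
#' @export
make_model_synapse <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  sp <- spec$spacing_nm
  t_nm <- spec$psd_thickness_voxels * sp
  rr <- spec$ribbon_diameter_nm / 2
  half <- spec$psd_projected_diameter_nm / 2
  margin <- 4 * sp

  if (spec$kind == "hemisphere") {
    # bowl sphere center at origin, mouth plane y = 0, shell centroid at
    # y = -R/2; ribbon center offset + rr above the centroid
    R <- spec$bowl_radius_nm
    ribbon_y <- -R / 2 + spec$ribbon_offset_nm + rr
    psd_par <- list(radius_nm = R, thickness_nm = t_nm)
    psd_kind <- "capped-shell"
    y_lo <- -(R + t_nm + margin)
    y_hi <- ribbon_y + rr + margin
  } else {
    ribbon_y <- spec$ribbon_offset_nm + rr
    if (spec$kind == "disk") {
      psd_par <- list(outer_diameter_nm = 2 * half, thickness_nm = t_nm)
      psd_kind <- "annulus"
      y_lo <- -(t_nm + margin)
    } else if (spec$kind == "ring") {
      psd_par <- list(outer_diameter_nm = 2 * half,
                      hole_diameter_nm = spec$hole_diameter_nm,
                      thickness_nm = t_nm)
      psd_kind <- "annulus"
      y_lo <- -(t_nm + margin)
    } else {  # donut
      psd_par <- list(hole_diameter_nm = spec$hole_diameter_nm,
                      outer_diameter_nm = 2 * half,
                      inner_radius_nm = spec$donut_inner_radius_nm,
                      outer_radius_nm = spec$donut_outer_radius_nm,
                      thickness_nm = t_nm)
      psd_kind <- "donut-sheet"
      droop <- spec$donut_inner_radius_nm +
        half^2 / (2 * spec$donut_outer_radius_nm)
      y_lo <- -(droop + t_nm + margin)
    }
    y_hi <- ribbon_y + rr + margin
  }
  if (ribbon_y - rr <= 0 && spec$kind != "hemisphere") {
    stop("geometrically impossible phantom: ribbon overlaps the PSD plane",
         call. = FALSE)
  }

  extent <- rbind(c(-(half + margin), half + margin),
                  c(y_lo, y_hi),
                  c(-(half + margin), half + margin))
  psd <- voxelize_on_grid(primitive_fun(psd_kind, psd_par), extent, sp)
  rb_fun <- function(x, y, z) x^2 + (y - ribbon_y)^2 + z^2 <= rr^2
  rb <- voxelize_on_grid(rb_fun, extent, sp)
  if (any(psd$mask & rb$mask)) {
    stop("geometrically impossible phantom: ribbon overlaps the PSD",
         call. = FALSE)
  }
  vox <- array(0L, dim(psd$mask))
  vox[rb$mask] <- 1L
  vox[psd$mask] <- 2L
  vol <- label_volume(vox, spacing_nm = sp)
  tab <- label_table(label = c(1L, 2L),
                     structure = c("ribbon", "PSD"),
                     synapse_id = c(1L, 1L), ihc_id = c(1L, 1L))
  list(volume = vol, table = tab,
       geometry = list(ribbon_center_nm = c(0, ribbon_y, 0),
                       ribbon_radius_nm = rr,
                       origin_nm = psd$origin_nm))
}
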