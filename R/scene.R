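# Synthetic multi-IHC scenes with programmed morphology distributions,
# spatial gradients, vesicle pools, and constructive ground truth.

#' Scene specification
#'
#' Describes a synthetic population of ribbon synapses on a short row of
#' inner hair cells. The defaults encode the study conditions the package
#' is designed around: three IHCs staggered along the modiolar-pillar (Z)
#' axis, 38 synapses (16+16+6) for a `p17-like` scene or 32 (16+8+8) for a
#' `p34-like` scene, log-normal ribbon volumes whose modiolar/pillar
#' medians differ at p34 (4.87 vs 2.38 x 10^6 nm^3) but not at p17
#' (4.3 x 10^6 both sides), log-normal PSD/PD areas (medians 0.58/0.75
#' um^2 at p17, 0.31/0.33 at p34) correlated across the cleft, and vesicle
#' pools whose ribbon-associated counts scale with ribbon surface area.
#'
#' Scenes are emitted at 14 nm spacing by default: it keeps a full
#' multi-cell volume comfortably in memory while rasterizing the smallest
#' ribbons with sub-3% volume error.
#'
#' @param age_profile `"p17-like"` (no ribbon-size gradient) or
#'   `"p34-like"` (modiolar > pillar ribbon sizes).
#' @param n_ihc number of cells (default 3).
#' @param synapses_per_ihc integer vector of per-cell synapse counts
#'   (default by age profile; at most 16 per cell).
#' @param ihc_mp_offsets_nm Z stagger of each cell's center (default
#'   alternating -3000/+3000 nm, the basolateral alternation of
#'   neighboring cells).
#' @param ribbon_volume_params list: `modiolar_median_nm3`,
#'   `pillar_median_nm3`, `sdlog`.
#' @param density_area_params list: `psd_median_um2`, `pd_median_um2`,
#'   `sdlog`, `axis_ratio_median`.
#' @param pd_psd_correlation correlation of log PD and log PSD areas
#'   (default 0.9).
#' @param vesicle_params list: `ribbon_pool_per_um2` (Poisson mean per um^2
#'   of analytic ribbon surface), `membrane_pool_mean` (per synapse),
#'   `distractors_per_synapse`.
#' @param double_ribbon_fraction fraction of synapses carrying two ribbons.
#' @param ribbon_axis_ratio_median median long:short ratio of ribbons.
#' @param spacing_nm voxel edge for emission (default 14).
#' @param seed default RNG seed used by [make_scene()].
#' @return list of class `scene_spec`.
#' @export
scene_spec <- function(age_profile = c("p34-like", "p17-like"),
                       n_ihc = 3L,
                       synapses_per_ihc = NULL,
                       ihc_mp_offsets_nm = NULL,
                       ribbon_volume_params = NULL,
                       density_area_params = NULL,
                       pd_psd_correlation = 0.9,
                       vesicle_params = NULL,
                       double_ribbon_fraction = NULL,
                       ribbon_axis_ratio_median = NULL,
                       spacing_nm = 14,
                       seed = 1L) {
  age_profile <- match.arg(age_profile)
  p34 <- age_profile == "p34-like"
  if (is.null(synapses_per_ihc)) {
    synapses_per_ihc <- if (p34) c(16L, 8L, 8L) else c(16L, 16L, 6L)
    synapses_per_ihc <- synapses_per_ihc[seq_len(min(n_ihc, 3L))]
    if (n_ihc > 3L) synapses_per_ihc <- c(synapses_per_ihc,
                                          rep(8L, n_ihc - 3L))
  }
  if (length(synapses_per_ihc) != n_ihc) {
    stop("synapses_per_ihc must have one entry per cell", call. = FALSE)
  }
  if (any(synapses_per_ihc > 16L)) {
    stop("at most 16 synapses per cell (placement grid)", call. = FALSE)
  }
  if (is.null(ihc_mp_offsets_nm)) {
    ihc_mp_offsets_nm <- rep(c(-3000, 3000), length.out = n_ihc)
  }
  if (is.null(ribbon_volume_params)) {
    ribbon_volume_params <- if (p34) {
      list(modiolar_median_nm3 = 4.87e6, pillar_median_nm3 = 2.38e6,
           sdlog = 0.45)
    } else {
      list(modiolar_median_nm3 = 4.3e6, pillar_median_nm3 = 4.3e6,
           sdlog = 0.45)
    }
  }
  if (is.null(density_area_params)) {
    density_area_params <- if (p34) {
      list(psd_median_um2 = 0.31, pd_median_um2 = 0.33, sdlog = 0.55,
           axis_ratio_median = 3.0)
    } else {
      list(psd_median_um2 = 0.58, pd_median_um2 = 0.75, sdlog = 0.55,
           axis_ratio_median = 1.65)
    }
  }
  if (is.null(vesicle_params)) {
    vesicle_params <- list(ribbon_pool_per_um2 = 1200,
                           membrane_pool_mean = if (p34) 30 else 53,
                           distractors_per_synapse = 8L)
  }
  if (is.null(double_ribbon_fraction)) {
    double_ribbon_fraction <- if (p34) 2 / 32 else 3 / 38
  }
  if (is.null(ribbon_axis_ratio_median)) {
    ribbon_axis_ratio_median <- if (p34) 2.2 else 1.7
  }
  if (ribbon_volume_params$sdlog < 0 || density_area_params$sdlog < 0) {
    stop("dispersions must be >= 0", call. = FALSE)
  }
  if (pd_psd_correlation < 0 || pd_psd_correlation > 1) {
    stop("pd_psd_correlation must be in [0, 1]", call. = FALSE)
  }
  structure(list(
    age_profile = age_profile, n_ihc = as.integer(n_ihc),
    synapses_per_ihc = as.integer(synapses_per_ihc),
    ihc_mp_offsets_nm = ihc_mp_offsets_nm,
    ribbon_volume_params = ribbon_volume_params,
    density_area_params = density_area_params,
    pd_psd_correlation = pd_psd_correlation,
    vesicle_params = vesicle_params,
    double_ribbon_fraction = double_ribbon_fraction,
    ribbon_axis_ratio_median = ribbon_axis_ratio_median,
    spacing_nm = spacing_nm, seed = as.integer(seed)
  ), class = "scene_spec")
}

# --- layout constants (nm) --------------------------------------------------
SCENE_CELL_DX <- 3800       # cell-to-cell pitch along X
SCENE_X_COLS <- c(-900, 900)  # two synapse columns per cell
SCENE_Z_HALF <- 4200        # per-cell synapse spread: Z in [-4200, 4200]
SCENE_N_ROWS <- 8L
SCENE_XY_JITTER <- 150
SCENE_PATCH_LONG_MAX <- 1600
SCENE_PATCH_SHORT_MAX <- 700

# Thomsen approximation of the ellipsoid surface area (nm^2).
ellipsoid_surface <- function(a, b, c) {
  p <- 1.6075
  4 * pi * (((a * b)^p + (a * c)^p + (b * c)^p) / 3)^(1 / p)
}

# Draw patch (PD/PSD) long/short axes from a target area and axis ratio,
# resampling the area until the capped axes fit the placement slot.
draw_patch_axes <- function(median_um2, sdlog, ratio_median) {
  for (i in 1:40) {
    area_nm2 <- median_um2 * 1e6 * exp(stats::rnorm(1, 0, sdlog))
    ratio <- ratio_median * exp(stats::rnorm(1, 0, 0.2))
    long <- sqrt(4 * area_nm2 * ratio / pi)
    short <- long / ratio
    if (long <= SCENE_PATCH_LONG_MAX && short <= SCENE_PATCH_SHORT_MAX &&
        short >= 100) {
      return(c(long = long, short = short))
    }
  }
  long <- min(long, SCENE_PATCH_LONG_MAX)
  short <- min(max(short, 100), SCENE_PATCH_SHORT_MAX)
  c(long = long, short = short)
}

# Correlated PD area draw given the PSD's log deviation from its median.
draw_pd_area_axes <- function(psd_dev_log, dp, rho) {
  dev <- rho * psd_dev_log +
    sqrt(1 - rho^2) * stats::rnorm(1, 0, dp$sdlog)
  for (i in 1:40) {
    area_nm2 <- dp$pd_median_um2 * 1e6 * exp(dev)
    ratio <- dp$axis_ratio_median * exp(stats::rnorm(1, 0, 0.2))
    long <- sqrt(4 * area_nm2 * ratio / pi)
    short <- long / ratio
    if (long <= SCENE_PATCH_LONG_MAX && short <= SCENE_PATCH_SHORT_MAX &&
        short >= 100) {
      return(c(long = long, short = short))
    }
    dev <- dev * 0.9
  }
  c(long = min(long, SCENE_PATCH_LONG_MAX),
    short = min(max(short, 100), SCENE_PATCH_SHORT_MAX))
}

# Uniform-ish sample of points on an ellipsoid surface (light mode surface
# stand-in for distance queries).
sample_ellipsoid_surface <- function(n, semi, rot, center) {
  u <- matrix(stats::rnorm(3 * n), n, 3)
  u <- u / sqrt(rowSums(u^2))
  p <- sweep(u, 2L, semi, "*")
  p %*% t(rot) + matrix(center, n, 3, byrow = TRUE)
}

#' Place vesicle markers around a synapse
#'
#' Samples point markers in the shell within `thresholds_nm["ribbon"]` of
#' the ribbon surface, within `thresholds_nm["membrane"]` of the PD
#' surface, and as distractors beyond both, then classifies every marker
#' against both surfaces (the recorded truth). Markers are kept away from
#' the exact threshold boundaries so that voxel-level recounting cannot
#' flip a classification. Pool membership is independent per definition:
#' markers in both shells are flagged `dual`, and each pool counts them.
#'
#' @param ribbon_mask binary ribbon mask (nonempty).
#' @param pd_mask binary PD mask or NULL (membrane pool requires a PD).
#' @param spacing_nm voxel edge in nm.
#' @param n_ribbon_pool,n_membrane_pool,n_distractors marker counts to
#'   place (targets; the truth records the resulting classified counts).
#' @param origin_nm grid origin of the masks in the output frame.
#' @param thresholds_nm named `c(ribbon = 80, membrane = 20)`.
#' @return list: `markers` ([vesicle_markers()] with `pool` and `dual`
#'   columns), `truth` (classified counts).
#' @export
place_vesicles <- function(ribbon_mask, pd_mask = NULL, spacing_nm,
                           n_ribbon_pool, n_membrane_pool = 0L,
                           n_distractors = 0L, origin_nm = c(0, 0, 0),
                           thresholds_nm = c(ribbon = 80, membrane = 20)) {
  rib_bf <- boundary_faces(ribbon_mask, spacing_nm)
  rib_surf <- sweep(rib_bf$centers, 2L, origin_nm, "+")
  rib_ctr <- colMeans(mask_coords(ribbon_mask, spacing_nm)) + origin_nm
  pd_surf <- NULL; pd_normals <- NULL
  if (!is.null(pd_mask)) {
    pd_bf <- boundary_faces(pd_mask, spacing_nm)
    pd_surf <- sweep(pd_bf$centers, 2L, origin_nm, "+")
    pd_normals <- pd_bf$normals
  }
  if (n_membrane_pool > 0L && is.null(pd_surf)) {
    stop("membrane pool requested without a PD mask", call. = FALSE)
  }
  place_vesicles_points(rib_surf, rib_ctr, pd_surf, pd_normals,
                        n_ribbon_pool, n_membrane_pool, n_distractors,
                        thresholds_nm)
}

place_vesicles_points <- function(rib_surf, rib_ctr, pd_surf, pd_normals,
                                  n_ribbon, n_membrane, n_distractors,
                                  thresholds_nm) {
  thr_r <- thresholds_nm[["ribbon"]]
  thr_m <- thresholds_nm[["membrane"]]
  min_dist_to <- function(p, cloud) {
    sqrt(min(colSums((t(cloud) - p)^2)))
  }
  place_one <- function(kind) {
    for (try in 1:80) {
      if (kind == "ribbon") {
        s <- rib_surf[sample.int(nrow(rib_surf), 1L), ]
        dir <- s - rib_ctr
        nd <- sqrt(sum(dir^2))
        dir <- if (nd > 0) dir / nd else c(0, 1, 0)
        cand <- s + dir * stats::runif(1, 0.1 * thr_r, 0.75 * thr_r)
        d <- min_dist_to(cand, rib_surf)
        if (d > 0.05 * thr_r && d <= 0.9 * thr_r) return(cand)
      } else if (kind == "membrane") {
        i <- sample.int(nrow(pd_surf), 1L)
        cand <- pd_surf[i, ] + pd_normals[i, ] *
          stats::runif(1, 0.1 * thr_m, 0.55 * thr_m)
        d <- min_dist_to(cand, pd_surf)
        if (d <= 0.85 * thr_m) return(cand)
      } else {
        s <- rib_surf[sample.int(nrow(rib_surf), 1L), ]
        dir <- s - rib_ctr
        nd <- sqrt(sum(dir^2))
        dir <- if (nd > 0) dir / nd else c(0, 1, 0)
        cand <- s + dir * stats::runif(1, 1.6 * thr_r, 3.0 * thr_r)
        d <- min_dist_to(cand, rib_surf)
        ok_pd <- is.null(pd_surf) || min_dist_to(cand, pd_surf) > 2 * thr_m
        if (d > 1.25 * thr_r && ok_pd) return(cand)
      }
    }
    stop("vesicle placement infeasible (no free space after 80 tries)",
         call. = FALSE)
  }
  kinds <- c(rep("ribbon", n_ribbon), rep("membrane", n_membrane),
             rep("distractor", n_distractors))
  pts <- matrix(NA_real_, length(kinds), 3L)
  for (i in seq_along(kinds)) pts[i, ] <- place_one(kinds[i])
  # classified truth: same distance definition the counting module uses
  d_rib <- if (nrow(pts)) nn_dist(pts, rib_surf) else numeric(0)
  in_rib <- d_rib <= thr_r + 1e-9
  in_mem <- if (!is.null(pd_surf) && nrow(pts)) {
    nn_dist(pts, pd_surf) <= thr_m + 1e-9
  } else rep(FALSE, nrow(pts))
  mk <- data.frame(x_nm = pts[, 1], y_nm = pts[, 2], z_nm = pts[, 3],
                   pool = kinds, dual = in_rib & in_mem,
                   stringsAsFactors = FALSE)
  list(markers = mk,
       truth = list(n_ribbon_pool = sum(in_rib),
                    n_membrane_pool = sum(in_mem),
                    n_dual = sum(in_rib & in_mem)))
}

#' Generate a synthetic multi-cell scene
#'
#' Builds the labeled voxel volume (or, with `voxelize = FALSE`, only the
#' analytic layout) for a [scene_spec()]: each synapse is an ellipsoid
#' ribbon above a PD/PSD patch pair, cells are staggered along Z, ribbon
#' volumes follow the programmed modiolar/pillar medians, and vesicle
#' markers are placed with recorded pool truth. Identical spec + seed give
#' identical output.
#'
#' The light (non-voxelized) mode is intended for statistical calibration
#' over many seeds: it returns the same ground truth and markers but no
#' voxel array, with anchors and volumes taken from the analytic draw
#' (voxelization perturbs volumes by under 3%).
#'
#' @param spec a [scene_spec()].
#' @param seed RNG seed (default from the spec).
#' @param voxelize emit the label volume (default TRUE).
#' @return list: `volume` (or NULL), `table`, `markers`, `truth`, `spec`.
#' @export
make_scene <- function(spec, seed = spec$seed, voxelize = TRUE) {
  stopifnot(inherits(spec, "scene_spec"))
  set.seed(seed)
  sp <- spec$spacing_nm
  rv <- spec$ribbon_volume_params
  dp <- spec$density_area_params
  vp <- spec$vesicle_params

  syn_rows <- list()   # synapse-level layout
  rib_rows <- list()   # ribbon-level truth
  marker_rows <- list()
  next_label <- 1L
  syn_id <- 0L

  for (cell in seq_len(spec$n_ihc)) {
    n_syn <- spec$synapses_per_ihc[cell]
    z_off <- spec$ihc_mp_offsets_nm[cell]
    x_cell <- (cell - 1L) * SCENE_CELL_DX
    # slot grid: 2 columns x 8 rows; sample without replacement
    slots <- expand.grid(col = SCENE_X_COLS,
                         row = seq_len(SCENE_N_ROWS))
    pick <- slots[sample.int(nrow(slots), n_syn), , drop = FALSE]
    z_slots <- -SCENE_Z_HALF + (pick$row - 0.5) * (2 * SCENE_Z_HALF /
                                                     SCENE_N_ROWS)
    for (k in seq_len(n_syn)) {
      syn_id <- syn_id + 1L
      z_t <- z_slots[k] + stats::runif(1, -SCENE_XY_JITTER, SCENE_XY_JITTER)
      x_s <- x_cell + pick$col[k] +
        stats::runif(1, -SCENE_XY_JITTER, SCENE_XY_JITTER)
      y_base <- 600 + stats::runif(1, 0, 1200)
      side <- if (z_t < 0) "M" else "P"
      med <- if (side == "M") rv$modiolar_median_nm3 else rv$pillar_median_nm3
      n_rib <- if (stats::runif(1) < spec$double_ribbon_fraction) 2L else 1L
      psd_ax <- draw_patch_axes(dp$psd_median_um2, dp$sdlog,
                                dp$axis_ratio_median)
      psd_dev <- unname(log((pi * psd_ax["long"] * psd_ax["short"] / 4) /
                              (dp$psd_median_um2 * 1e6)))
      pd_ax <- draw_pd_area_axes(psd_dev, dp, spec$pd_psd_correlation)
      ribbons <- list()
      for (r in seq_len(n_rib)) {
        v <- med * exp(stats::rnorm(1, 0, rv$sdlog))
        if (r == 2L) v <- v * stats::runif(1, 0.4, 0.9)
        q <- spec$ribbon_axis_ratio_median * exp(stats::rnorm(1, 0, 0.15))
        q <- min(q, 3.5)
        b <- (3 * v / (4 * pi * q))^(1 / 3)
        semi <- c(q * b, b, b)
        rot <- random_rotation()
        # support of the rotated ellipsoid along each world axis
        ext <- sqrt(rowSums((rot * matrix(semi, 3, 3, byrow = TRUE))^2))
        ribbons[[r]] <- list(volume = v, semi = semi, rot = rot, ext = ext)
      }
      # stack ribbons side by side along X above the PD
      x_off <- 0
      if (n_rib == 2L) {
        gap <- ribbons[[1]]$ext[1] + ribbons[[2]]$ext[1] + 3 * sp
        x_off <- c(-gap / 2, gap / 2)
      }
      for (r in seq_len(n_rib)) {
        rb <- ribbons[[r]]
        ctr <- c(x_s + if (n_rib == 2L) x_off[r] else 0,
                 y_base + 7 * sp + rb$ext[2],
                 z_off + z_t)
        ribbons[[r]]$center <- ctr
        ribbons[[r]]$label <- next_label
        next_label <- next_label + 1L
      }
      pd_label <- next_label; next_label <- next_label + 1L
      psd_label <- next_label; next_label <- next_label + 1L
      syn_rows[[syn_id]] <- list(
        synapse_id = syn_id, ihc_id = cell, x_nm = x_s,
        y_base = y_base, z_nm = z_off + z_t, z_t_true = z_t,
        side_true = side,
        psd_long = unname(psd_ax["long"]), psd_short = unname(psd_ax["short"]),
        pd_long = unname(pd_ax["long"]), pd_short = unname(pd_ax["short"]),
        pd_label = pd_label, psd_label = psd_label,
        ribbons = ribbons
      )
      for (r in seq_len(n_rib)) {
        rb <- ribbons[[r]]
        rib_rows[[length(rib_rows) + 1L]] <- data.frame(
          synapse_id = syn_id, ihc_id = cell, label = rb$label,
          double_ribbon = n_rib == 2L,
          true_volume_nm3 = rb$volume,
          true_long_nm = 2 * rb$semi[1], true_short_nm = 2 * rb$semi[3],
          true_surface_um2 = ellipsoid_surface(rb$semi[1], rb$semi[2],
                                               rb$semi[3]) / 1e6,
          center_x_nm = rb$center[1], center_y_nm = rb$center[2],
          center_z_nm = rb$center[3],
          stringsAsFactors = FALSE)
      }
    }
  }

  rib_truth <- do.call(rbind, rib_rows)
  syn_tab <- do.call(rbind, lapply(syn_rows, function(s) data.frame(
    synapse_id = s$synapse_id, ihc_id = s$ihc_id,
    z_t_true = s$z_t_true, side_true = s$side_true,
    psd_area_um2 = pi * s$psd_long * s$psd_short / 4e6,
    pd_area_um2 = pi * s$pd_long * s$pd_short / 4e6,
    psd_long_nm = s$psd_long, psd_short_nm = s$psd_short,
    pd_long_nm = s$pd_long, pd_short_nm = s$pd_short,
    stringsAsFactors = FALSE)))

  # ---- global frame shift so everything is positive --------------------
  margin <- 250
  x_lo <- min(rib_truth$center_x_nm - 1200,
              min(SCENE_X_COLS) - SCENE_XY_JITTER - SCENE_PATCH_LONG_MAX / 2)
  x_hi <- max(rib_truth$center_x_nm + 1200,
              (spec$n_ihc - 1) * SCENE_CELL_DX + max(SCENE_X_COLS) +
                SCENE_XY_JITTER + SCENE_PATCH_LONG_MAX / 2)
  z_all <- rib_truth$center_z_nm
  z_lo <- min(z_all) - 900; z_hi <- max(z_all) + 900
  y_hi <- max(rib_truth$center_y_nm) + 700
  shift <- c(-(x_lo - margin), 0, -(z_lo - margin))
  shift <- floor(shift / sp) * sp  # keep the lattice aligned
  dims <- as.integer(ceiling(c(x_hi + shift[1] + margin,
                               y_hi + margin,
                               z_hi + shift[3] + margin) / sp))

  vol <- NULL
  if (voxelize) vol <- array(0L, dims)

  label_rows <- list()
  vox_volume <- setNames(numeric(nrow(rib_truth)),
                         as.character(rib_truth$label))
  anchor_list <- list()
  struct_lin <- list()  # linear voxel indices per label (voxel mode)

  rasterize <- function(fun, extent) {
    out <- voxelize_on_grid(fun, extent, sp)
    idx <- which(out$mask, arr.ind = TRUE)
    off <- as.integer(round(out$origin_nm / sp))
    gi <- cbind(idx[, 1] + off[1], idx[, 2] + off[2], idx[, 3] + off[3])
    ok <- gi[, 1] >= 1L & gi[, 1] <= dims[1] &
      gi[, 2] >= 1L & gi[, 2] <= dims[2] &
      gi[, 3] >= 1L & gi[, 3] <= dims[3]
    gi[ok, , drop = FALSE]
  }

  for (s in syn_rows) {
    ctr2 <- c(s$x_nm + shift[1], 0, s$z_nm + shift[3])
    # PSD slab: y in [y_base, y_base + 2 sp); PD in [y_base+4sp, y_base+6sp)
    for (which_p in c("PSD", "PD")) {
      long <- if (which_p == "PSD") s$psd_long else s$pd_long
      short <- if (which_p == "PSD") s$psd_short else s$pd_short
      y0 <- if (which_p == "PSD") s$y_base else s$y_base + 4 * sp
      lab <- if (which_p == "PSD") s$psd_label else s$pd_label
      label_rows[[length(label_rows) + 1L]] <- data.frame(
        label = lab, structure = which_p, synapse_id = s$synapse_id,
        ihc_id = s$ihc_id, stringsAsFactors = FALSE)
      if (voxelize) {
        ext <- rbind(ctr2[1] + c(-long / 2 - sp, long / 2 + sp),
                     c(y0 - sp, y0 + 2 * sp + sp),
                     ctr2[3] + c(-short / 2 - sp, short / 2 + sp))
        fun <- local({
          cx <- ctr2[1]; cz <- ctr2[3]; L <- long / 2; S <- short / 2
          ylo <- y0; yhi <- y0 + 2 * sp
          function(x, y, z) {
            ((x - cx) / L)^2 + ((z - cz) / S)^2 <= 1 & y >= ylo & y < yhi
          }
        })
        gi <- rasterize(fun, ext)
        lin <- gi[, 1] + dims[1] * (gi[, 2] - 1L) +
          dims[1] * dims[2] * (gi[, 3] - 1L)
        if (any(vol[lin] != 0L)) {
          stop("scene placement overlap at synapse ", s$synapse_id,
               " (", which_p, ")", call. = FALSE)
        }
        vol[lin] <- lab
        struct_lin[[as.character(lab)]] <- lin
      }
    }
    for (rb in s$ribbons) {
      label_rows[[length(label_rows) + 1L]] <- data.frame(
        label = rb$label, structure = "ribbon", synapse_id = s$synapse_id,
        ihc_id = s$ihc_id, stringsAsFactors = FALSE)
      ctr <- rb$center + shift
      if (voxelize) {
        ext <- rbind(ctr[1] + c(-1, 1) * (rb$ext[1] + sp),
                     ctr[2] + c(-1, 1) * (rb$ext[2] + sp),
                     ctr[3] + c(-1, 1) * (rb$ext[3] + sp))
        fun <- local({
          c0 <- ctr; rot <- rb$rot; semi <- rb$semi
          function(x, y, z) {
            q <- cbind(as.vector(x) - c0[1], as.vector(y) - c0[2],
                       as.vector(z) - c0[3]) %*% rot
            (q[, 1] / semi[1])^2 + (q[, 2] / semi[2])^2 +
              (q[, 3] / semi[3])^2 <= 1
          }
        })
        gi <- rasterize(fun, ext)
        lin <- gi[, 1] + dims[1] * (gi[, 2] - 1L) +
          dims[1] * dims[2] * (gi[, 3] - 1L)
        if (any(vol[lin] != 0L)) {
          stop("scene placement overlap at synapse ", s$synapse_id,
               " (ribbon)", call. = FALSE)
        }
        vol[lin] <- rb$label
        struct_lin[[as.character(rb$label)]] <- lin
        vox_volume[as.character(rb$label)] <- length(lin) * sp^3
        anchor_list[[as.character(rb$label)]] <- colMeans((gi - 0.5) * sp)
      } else {
        vox_volume[as.character(rb$label)] <- rb$volume
        anchor_list[[as.character(rb$label)]] <- ctr
      }
    }
  }

  table <- do.call(rbind, label_rows)
  class(table) <- c("label_table", "data.frame")
  validate_label_table(table)

  # ---- vesicle markers -------------------------------------------------
  for (s in syn_rows) {
    sa_tot <- sum(vapply(s$ribbons, function(rb)
      ellipsoid_surface(rb$semi[1], rb$semi[2], rb$semi[3]) / 1e6,
      numeric(1)))
    n_r <- max(1L, stats::rpois(1, vp$ribbon_pool_per_um2 * sa_tot))
    n_m <- stats::rpois(1, vp$membrane_pool_mean)
    n_d <- vp$distractors_per_synapse
    if (voxelize) {
      rib_labs <- vapply(s$ribbons, function(rb) rb$label, integer(1))
      rib_mask_idx <- unlist(struct_lin[as.character(rib_labs)],
                             use.names = FALSE)
      cmR <- crop_mask(rib_mask_idx, dims)
      rib_surf <- sweep(boundary_faces(cmR$mask, sp)$centers, 2L,
                        cmR$offset * sp, "+")
      rib_ctr <- colMeans(mask_coords(cmR$mask, sp)) + cmR$offset * sp
      pd_idx <- struct_lin[[as.character(s$pd_label)]]
      cmP <- crop_mask(pd_idx, dims)
      pd_bf <- boundary_faces(cmP$mask, sp)
      pd_surf <- sweep(pd_bf$centers, 2L, cmP$offset * sp, "+")
      pd_normals <- pd_bf$normals
    } else {
      rib_surf <- do.call(rbind, lapply(s$ribbons, function(rb)
        sample_ellipsoid_surface(1200L, rb$semi, rb$rot, rb$center + shift)))
      rib_ctr <- colMeans(rib_surf)
      # top face of the PD slab plus rim
      nx <- max(8L, ceiling(s$pd_long / 25)); nz <- max(6L,
                                                        ceiling(s$pd_short / 25))
      gx <- seq(-s$pd_long / 2, s$pd_long / 2, length.out = nx)
      gz <- seq(-s$pd_short / 2, s$pd_short / 2, length.out = nz)
      gg <- expand.grid(x = gx, z = gz)
      keep <- (gg$x / (s$pd_long / 2))^2 + (gg$z / (s$pd_short / 2))^2 <= 1
      gg <- gg[keep, , drop = FALSE]
      pd_surf <- cbind(gg$x + s$x_nm + shift[1],
                       s$y_base + 6 * sp, gg$z + s$z_nm + shift[3])
      pd_normals <- matrix(rep(c(0, 1, 0), nrow(pd_surf)), ncol = 3,
                           byrow = TRUE)
    }
    pv <- place_vesicles_points(rib_surf, rib_ctr, pd_surf, pd_normals,
                                n_r, n_m, n_d,
                                c(ribbon = 80, membrane = 20))
    mk <- pv$markers
    mk$synapse_id <- s$synapse_id
    mk$n_ribbon_pool_true <- pv$truth$n_ribbon_pool
    mk$n_membrane_pool_true <- pv$truth$n_membrane_pool
    marker_rows[[length(marker_rows) + 1L]] <- mk
  }
  markers_all <- do.call(rbind, marker_rows)

  # ---- ground truth ----------------------------------------------------
  rib_truth$center_x_nm <- rib_truth$center_x_nm + shift[1]
  rib_truth$center_z_nm <- rib_truth$center_z_nm + shift[3]
  rib_truth$voxel_volume_nm3 <- vox_volume[as.character(rib_truth$label)]
  # synapse anchors: centroid of the ribbon voxel union (voxel mode) or the
  # volume-weighted analytic centroid (light mode)
  anchors <- do.call(rbind, lapply(syn_rows, function(s) {
    labs <- vapply(s$ribbons, function(rb) rb$label, integer(1))
    if (voxelize) {
      w <- vox_volume[as.character(labs)] / sp^3
    } else {
      w <- vapply(s$ribbons, function(rb) rb$volume, numeric(1))
    }
    ctrs <- do.call(rbind, anchor_list[as.character(labs)])
    a <- colSums(ctrs * w) / sum(w)
    data.frame(synapse_id = s$synapse_id, ihc_id = s$ihc_id,
               x_nm = a[1], y_nm = a[2], z_nm = a[3])
  }))
  mapped <- map_anchors(anchors)
  truth <- merge(rib_truth, syn_tab, by = c("synapse_id", "ihc_id"))
  truth <- merge(truth, mapped, by = c("synapse_id", "ihc_id"))
  pool_truth <- unique(markers_all[, c("synapse_id", "n_ribbon_pool_true",
                                       "n_membrane_pool_true")])
  truth <- merge(truth, pool_truth, by = "synapse_id")
  truth <- truth[order(truth$label), ]
  rownames(truth) <- NULL

  volume <- if (voxelize) label_volume(vol, spacing_nm = sp) else NULL
  markers <- vesicle_markers(markers_all[, c("x_nm", "y_nm", "z_nm")],
                             synapse_id = markers_all$synapse_id,
                             volume = volume)
  markers$pool <- markers_all$pool
  markers$dual <- markers_all$dual
  list(volume = volume, table = table, markers = markers, truth = truth,
       spec = spec, seed = seed)
}
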