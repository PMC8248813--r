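# End-to-end orchestration: measure -> map -> proximity -> pools -> stats.

#' Receptor-count estimate from membrane-density area
#'
#' Converts a PSD area to an expected AMPA-type glutamate receptor count by
#' assuming a constant packing density (900 receptors per um^2 by default).
#'
#' @param area_um2 PSD area(s) in um^2.
#' @param density_per_um2 receptor packing density (default 900).
#' @return receptor count(s).
#' @export
receptor_count <- function(area_um2, density_per_um2 = 900) {
  if (any(area_um2 < 0)) stop("area must be non-negative", call. = FALSE)
  area_um2 * density_per_um2
}

#' Pipeline configuration
#'
#' Bundles the inputs and parameters of one [run_pipeline()] invocation.
#' `input` may be (a) a list with `volume_path`, `table_path` and optional
#' `markers_path`; (b) a [scene_spec()] (the scene is generated with the
#' pipeline seed); or (c) a character vector of phantom kinds (each built
#' with [make_model_synapse()] defaults).
#'
#' @param input see above.
#' @param out_dir output directory (created if missing); NULL for no files.
#' @param seed RNG seed for generated inputs.
#' @param thresholds_nm vesicle pool thresholds `c(ribbon = 80,
#'   membrane = 20)`.
#' @param n_directions direction count for [feret_axes()].
#' @param quantile_grid_nm distance grid for [mean_cum_pdf()] (NULL: 0 to
#'   1050 nm in 7 nm steps, extended to the data).
#' @param receptor_density_per_um2 packing density for [receptor_count()].
#' @param spacing_nm spacing override for file inputs.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(input, out_dir = NULL, seed = 1L,
                            thresholds_nm = c(ribbon = 80, membrane = 20),
                            n_directions = 2048L,
                            quantile_grid_nm = NULL,
                            receptor_density_per_um2 = 900,
                            spacing_nm = NULL) {
  structure(list(input = input, out_dir = out_dir, seed = as.integer(seed),
                 thresholds_nm = thresholds_nm,
                 n_directions = as.integer(n_directions),
                 quantile_grid_nm = quantile_grid_nm,
                 receptor_density_per_um2 = receptor_density_per_um2,
                 spacing_nm = spacing_nm),
            class = "pipeline_config")
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", name,
                 conditionMessage(e)), call. = FALSE)
  })
}

#' Run the full analysis pipeline
#'
#' Measures every structure, maps synapse positions in the native and
#' translated views, computes proximity profiles and their group-mean
#' cumulative curve, counts vesicle pools (when markers are available), and
#' builds the group-summary/contrast tables. All stage outputs are pure
#' functions of (input, config, seed); rerunning with the same seed
#' reproduces the same tables. When `out_dir` is set, writes
#' `morphometry.csv`, `positions.csv`, `profiles/`, `profile_summary.csv`,
#' `mean_cumpdf.csv`, `pools.csv`, `table1.csv`, `comparisons.csv`, and
#' `manifest.json`.
#'
#' @param config a [pipeline_config()].
#' @return list (report bundle): `morphometry`, `positions`, `profiles`,
#'   `profile_summary`, `mean_cum_pdf`, `pools`, `per_ribbon`, `table1`,
#'   `comparisons`, `truth` (scenes only), `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  inp <- config$input
  truth <- NULL
  markers <- NULL

  if (inherits(inp, "scene_spec")) {
    sc <- stage("generate", make_scene(inp, seed = config$seed))
    volumes <- list(list(volume = sc$volume, table = sc$table))
    markers <- sc$markers
    truth <- sc$truth
  } else if (is.character(inp)) {
    volumes <- stage("generate", lapply(seq_along(inp), function(i) {
      mp <- make_model_synapse(phantom_spec(kind = inp[i]))
      # keep synapse ids distinct across phantoms
      mp$table$synapse_id <- i
      mp$table$ihc_id <- i
      list(volume = mp$volume, table = mp$table, kind = inp[i])
    }))
  } else {
    pair <- stage("read", read_label_volume(inp$volume_path, inp$table_path,
                                            spacing_nm = config$spacing_nm))
    volumes <- list(pair)
    if (!is.null(inp$markers_path)) {
      markers <- stage("read", read_markers(inp$markers_path,
                                            volume = pair$volume))
    }
  }

  morph <- stage("measure", do.call(rbind, lapply(volumes, function(v) {
    m <- measure_all(v$volume, v$table, n_directions = config$n_directions)
    if (!is.null(v$kind)) m$phantom <- v$kind
    m
  })))
  morph$receptor_count <- NA_real_
  is_psd <- morph$structure == "PSD"
  morph$receptor_count[is_psd] <- receptor_count(
    morph$ellipse_area_um2[is_psd], config$receptor_density_per_um2)

  positions <- NULL
  if (length(volumes) == 1L &&
      sum(volumes[[1]]$table$structure == "ribbon") >= 2L) {
    positions <- stage("map", map_synapses(volumes[[1]]$volume,
                                           volumes[[1]]$table))
  }

  profiles <- stage("proximity", do.call(c, lapply(volumes, function(v)
    proximity_profiles(v$volume, v$table))))
  if (is.character(inp)) names(profiles) <- inp
  prof_sum <- do.call(rbind, lapply(seq_along(profiles), function(i) {
    p <- profiles[[i]]
    data.frame(synapse = names(profiles)[i], n_points = p$n,
               median_nm = p$median_nm, p15_nm = p$p15_nm,
               min_nm = min(p$distances_nm), max_nm = max(p$distances_nm),
               stringsAsFactors = FALSE)
  }))
  mean_curve <- stage("proximity",
                      mean_cum_pdf(profiles, config$quantile_grid_nm))

  pools <- NULL
  if (!is.null(markers)) {
    pools <- stage("pools", count_pools(volumes[[1]]$volume,
                                        volumes[[1]]$table, markers,
                                        thresholds_nm = config$thresholds_nm))
  }

  # per-ribbon analysis table joining morphometry, position, proximity and
  # pools (ribbons count per ribbon; synapse-level values repeated)
  per_ribbon <- NULL
  table1 <- NULL
  comparisons <- NULL
  if (!is.null(positions)) {
    rib <- morph[morph$structure == "ribbon", , drop = FALSE]
    psd <- morph[morph$structure == "PSD",
                 c("synapse_id", "ellipse_area_um2", "long_axis_nm",
                   "short_axis_nm", "receptor_count")]
    names(psd) <- c("synapse_id", "psd_area_um2", "psd_long_nm",
                    "psd_short_nm", "receptor_count")
    per_ribbon <- merge(rib, positions, by = c("synapse_id", "ihc_id"))
    per_ribbon <- merge(per_ribbon, psd, by = "synapse_id", all.x = TRUE)
    pr_sum <- data.frame(
      synapse_id = as.integer(prof_sum$synapse),
      prox_median_nm = prof_sum$median_nm,
      prox_p15_nm = prof_sum$p15_nm)
    per_ribbon <- merge(per_ribbon, pr_sum, by = "synapse_id", all.x = TRUE)
    if (!is.null(pools)) {
      per_ribbon <- merge(per_ribbon,
                          pools[, c("synapse_id", "ribbon_associated",
                                    "membrane_associated")],
                          by = "synapse_id", all.x = TRUE)
    }
    metrics <- intersect(
      c("volume_nm3", "voxelface_area_nm2", "long_axis_nm", "short_axis_nm",
        "ls_ratio", "psd_area_um2", "prox_median_nm", "prox_p15_nm",
        "ribbon_associated", "membrane_associated"),
      names(per_ribbon))
    gt <- stage("stats", group_table(per_ribbon, metrics, "mp_translated"))
    table1 <- gt$summary
    comparisons <- gt$comparisons
  }

  manifest <- list(
    package = "ribbonmorph",
    version = as.character(utils::packageVersion("ribbonmorph")),
    seed = config$seed,
    thresholds_nm = as.list(config$thresholds_nm),
    n_directions = config$n_directions,
    receptor_density_per_um2 = config$receptor_density_per_um2,
    input = if (inherits(inp, "scene_spec")) {
      c(list(type = "scene"), inp[setdiff(names(inp), "seed")])
    } else if (is.character(inp)) {
      list(type = "phantoms", kinds = inp)
    } else {
      c(list(type = "files"), inp)
    },
    timestamp = format(Sys.time(), tz = "UTC")
  )

  bundle <- list(morphometry = morph, positions = positions,
                 profiles = profiles, profile_summary = prof_sum,
                 mean_cum_pdf = mean_curve, pools = pools,
                 per_ribbon = per_ribbon, table1 = table1,
                 comparisons = comparisons, truth = truth,
                 manifest = manifest)

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    od <- config$out_dir
    write_measurements(morph, file.path(od, "morphometry.csv"))
    if (!is.null(positions)) {
      utils::write.csv(positions, file.path(od, "positions.csv"),
                       row.names = FALSE)
    }
    pdir <- file.path(od, "profiles")
    dir.create(pdir, showWarnings = FALSE)
    for (i in seq_along(profiles)) {
      utils::write.csv(
        data.frame(distance_nm = profiles[[i]]$distances_nm),
        file.path(pdir, paste0("synapse_", names(profiles)[i], ".csv")),
        row.names = FALSE)
    }
    utils::write.csv(prof_sum, file.path(od, "profile_summary.csv"),
                     row.names = FALSE)
    utils::write.csv(mean_curve, file.path(od, "mean_cumpdf.csv"),
                     row.names = FALSE)
    if (!is.null(pools)) {
      utils::write.csv(pools, file.path(od, "pools.csv"), row.names = FALSE)
    }
    if (!is.null(table1)) {
      utils::write.csv(table1, file.path(od, "table1.csv"),
                       row.names = FALSE)
      utils::write.csv(comparisons, file.path(od, "comparisons.csv"),
                       row.names = FALSE)
    }
    if (!is.null(truth)) {
      utils::write.csv(truth, file.path(od, "truth.csv"), row.names = FALSE)
      write_markers(markers, file.path(od, "markers.csv"))
    }
    jsonlite::write_json(manifest, file.path(od, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  invisible(bundle)
}
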