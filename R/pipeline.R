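#' Assemble a pipeline run configuration
#'
#' Collects every tunable of the assessment in one validated object: the
#' criterion ranges, weights and zero rules of the priority index, the priority
#' and sensitivity class thresholds, the grid cell size, air density and the
#' protected-site buffer. Defaults are the published values; weights are
#' checked to sum to 0.90 (positive criteria) and 0.10 (the forest penalty),
#' and malformed settings fail here, before any computation.
#'
#' @param priority criterion ranges/weights, see [priority_config()].
#' @param bat_scale published class scale applied to bats (see
#'   [sensitivity_thresholds()]).
#' @param cellsize analysis cell edge, metres (default 1000).
#' @param rho air density for power densities, kg/m^3.
#' @param natura_buffer_m buffer around protected-site footprints, metres.
#' @param z_target,z10,z0 log-profile heights for the wind stage, metres.
#' @return a validated `run_config` list.
#' @export
run_config <- function(priority = priority_config(),
                       bat_scale = "migratory_bird",
                       cellsize = 1000, rho = 1.225, natura_buffer_m = 0,
                       z_target = 50, z10 = 10, z0 = 0.03) {
  w <- priority$weights
  pos <- sum(w[w > 0]); neg <- -sum(w[w < 0])
  if (abs(pos - 0.90) > 1e-9 || abs(neg - 0.10) > 1e-9)
    stop("priority weights malformed: positive weights must sum to 0.90 and ",
         "the forest penalty to 0.10 (got ", pos, " and ", neg, ")")
  for (r in priority$ranges) if (r[2] <= r[1]) stop("criterion range with hi <= lo")
  if (cellsize <= 0 || rho <= 0) stop("cellsize and rho must be positive")
  structure(list(priority = priority, bat_scale = bat_scale,
                 cellsize = cellsize, rho = rho,
                 natura_buffer_m = natura_buffer_m,
                 z_target = z_target, z10 = z10, z0 = z0),
            class = "run_config")
}

#' Run the full conflict-assessment pipeline
#'
#' Executes the stages in order — wind resource fitting, municipal priority
#' scoring, sensitivity rasterization, conflict combination, zonal statistics —
#' on in-memory inputs (typically a [generate_scenario()] bundle or data read
#' with [read_geojson()] / [read_municipalities()] / [read_wind_csv()]).
#' Every intermediate is written to `out_dir` when given: `wind_fits.csv`,
#' `priorities.csv`, `sensitivity.asc` (+ `sensitivity_cells.csv` audit),
#' `conflict.asc`, `zonal_stats.csv` and the effective configuration
#' `config.json`. Re-running with identical inputs and configuration is
#' idempotent.
#'
#' @param municipalities `wc_features` of municipality polygons with a
#'   `municipality` property.
#' @param criteria data frame of raw priority criteria per municipality; if it
#'   lacks `wind_density_wm2`, the column is filled from the fitted wind
#'   regimes.
#' @param obs `wc_features` of wildlife observations.
#' @param mask optional survey-coverage `wc_features`.
#' @param winds optional data frame `region`/`timestamp`/`speed_ms` of
#'   measured 10 m speeds per region (region names matching municipalities).
#' @param config a [run_config()].
#' @param out_dir optional output directory.
#' @param catalog a `species_catalog`.
#' @return list with `wind_fits`, `priority` (a `priority_table`),
#'   `sensitivity` grid, `conflict` grid and `zonal` summary.
#' @export
run_pipeline <- function(municipalities, criteria, obs, mask = NULL,
                         winds = NULL, config = run_config(), out_dir = NULL,
                         catalog = load_catalog()) {
  if (!inherits(config, "run_config")) stop("config must come from run_config()")

  ## stage 1: wind resources
  wind_fits <- NULL
  if (!is.null(winds)) {
    regions <- unique(winds$region)
    wind_fits <- do.call(rbind, lapply(regions, function(rg) {
      sp <- winds$speed_ms[winds$region == rg]
      fit <- tryCatch(
        fit_weibull(extrapolate_speed(sp, config$z_target, config$z10, config$z0),
                    rho = config$rho),
        error = function(e) stop("wind stage failed for region ", rg, ": ",
                                 conditionMessage(e)))
      data.frame(region = rg, k = fit$k, c = fit$c,
                 mean_speed = fit$mean_speed, power_density = fit$power_density)
    }))
    if (!"wind_density_wm2" %in% names(criteria)) {
      idx <- match(criteria$municipality, wind_fits$region)
      if (anyNA(idx))
        stop("wind stage: no wind series for municipality ",
             criteria$municipality[which(is.na(idx))[1]])
      criteria$wind_density_wm2 <- wind_fits$power_density[idx]
    }
  }

  ## stage 2: municipal priority
  prio <- tryCatch(priority_index(criteria, config$priority),
                   error = function(e) stop("priority stage: ", conditionMessage(e)))
  mp <- municipalities$properties
  mp$priority_class <- prio$priority_class[match(mp$municipality, prio$municipality)]
  if (anyNA(mp$priority_class))
    stop("priority stage: municipality without criteria row: ",
         mp$municipality[which(is.na(mp$priority_class))[1]])
  municipalities <- feature_collection(municipalities$geometry, mp)

  ## stage 3: sensitivity raster over the municipal extent
  bb <- Reduce(function(a, b) c(xmin = min(a[1], b[1]), ymin = min(a[2], b[2]),
                                xmax = max(a[3], b[3]), ymax = max(a[4], b[4])),
               lapply(municipalities$geometry, geom_bbox))
  spec <- grid_spec(bb[1], bb[2],
                    ceiling((bb[3] - bb[1]) / config$cellsize),
                    ceiling((bb[4] - bb[2]) / config$cellsize),
                    config$cellsize)
  sens <- rasterize_sensitivity(obs, spec, catalog, mask = mask,
                                thresholds = sensitivity_thresholds(config$bat_scale),
                                natura_buffer_m = config$natura_buffer_m)

  ## stage 4: conflict grid
  confl <- combine_conflict(sens, municipalities)

  ## stage 5: zonal statistics
  zonal <- zonal_conflict_stats(confl, municipalities)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    if (!is.null(wind_fits))
      utils::write.csv(wind_fits, file.path(out_dir, "wind_fits.csv"), row.names = FALSE)
    utils::write.csv(as.data.frame(prio), file.path(out_dir, "priorities.csv"),
                     row.names = FALSE)
    write_class_asc(sens, file.path(out_dir, "sensitivity.asc"))
    utils::write.csv(as.data.frame(sens), file.path(out_dir, "sensitivity_cells.csv"),
                     row.names = FALSE)
    write_class_asc(confl, file.path(out_dir, "conflict.asc"))
    utils::write.csv(as.data.frame(zonal), file.path(out_dir, "zonal_stats.csv"),
                     row.names = FALSE)
    jsonlite::write_json(unclass(config), file.path(out_dir, "config.json"),
                         auto_unbox = TRUE, digits = NA)
  }

  list(wind_fits = wind_fits, priority = prio, sensitivity = sens,
       conflict = confl, zonal = zonal)
}
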