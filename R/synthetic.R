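#' Specify a synthetic assessment landscape
#'
#' Defines a seeded, fully synthetic study region so every pipeline stage can
#' run without external data: municipalities as a Voronoi tessellation of the
#' extent, species observations drawn from the packaged catalog with counts
#' spanning all three abundance bands, protected and dump sites, a survey-
#' coverage mask, per-region Weibull wind regimes and criterion values drawn
#' within the published national ranges. The generator makes no claim of
#' geographic realism; it emulates the data *shapes* the assessment consumes.
#'
#' @param seed integer seed; identical seeds give identical scenarios.
#' @param n_municipalities number of Voronoi municipalities (>= 1).
#' @param extent_km side length of the square study extent, km.
#' @param n_species_obs number of species observation features.
#' @param n_natura protected-site polygons.
#' @param n_dumps dump-site polygons.
#' @param wind_hours hourly wind records per region.
#' @param origin lower-left corner of the projected extent, metres.
#' @return a `scenario_spec` list.
#' @export
scenario_spec <- function(seed = 42, n_municipalities = 6, extent_km = 100,
                          n_species_obs = 60, n_natura = 3, n_dumps = 1,
                          wind_hours = 2000, origin = c(300000, 6000000)) {
  if (n_municipalities < 1) stop("need at least one municipality")
  if (extent_km < sqrt(n_municipalities))
    stop("extent too small for ", n_municipalities, " municipalities")
  structure(as.list(environment()), class = "scenario_spec")
}

#' Generate a synthetic scenario
#'
#' Draws the landscape defined by a [scenario_spec()]. Geometry is generated
#' before attributes from a single seeded stream, so municipality shapes are
#' stable when only attribute settings change downstream.
#'
#' @param spec a `scenario_spec`.
#' @param out_dir optional directory; when given, writes
#'   `municipalities.geojson`, `observations.geojson`, `mask.geojson`,
#'   `winds.csv` and `criteria.csv` there.
#' @param catalog a `species_catalog`.
#' @return list with elements `municipalities` (`wc_features` with criteria
#'   properties), `observations` (`wc_features`), `mask` (`wc_features`),
#'   `winds` (data frame region/timestamp/speed_ms), `criteria` (data frame),
#'   `wind_regimes` (true per-region k and c) and `extent`.
#' @examples
#' sc <- generate_scenario(scenario_spec(seed = 1, n_municipalities = 3,
#'                                       extent_km = 40, n_species_obs = 10))
#' sc$municipalities
#' @export
generate_scenario <- function(spec = scenario_spec(), out_dir = NULL,
                              catalog = load_catalog()) {
  set.seed(spec$seed)
  ext_m <- spec$extent_km * 1000
  extent <- c(spec$origin[1], spec$origin[2],
              spec$origin[1] + ext_m, spec$origin[2] + ext_m)

  ## --- geometry first ---
  seeds <- cbind(stats::runif(spec$n_municipalities, extent[1], extent[3]),
                 stats::runif(spec$n_municipalities, extent[2], extent[4]))
  muni_polys <- voronoi_polygons(seeds, extent)
  muni_names <- sprintf("muni_%02d", seq_len(spec$n_municipalities))

  rand_rect_poly <- function(cx, cy, half_w, half_h) {
    geom_polygon(rbind(c(cx - half_w, cy - half_h), c(cx + half_w, cy - half_h),
                       c(cx + half_w, cy + half_h), c(cx - half_w, cy + half_h)))
  }

  natura <- lapply(seq_len(spec$n_natura), function(i) {
    rand_rect_poly(stats::runif(1, extent[1] + 5000, extent[3] - 5000),
                   stats::runif(1, extent[2] + 5000, extent[4] - 5000),
                   stats::runif(1, 1000, 4000), stats::runif(1, 1000, 4000))
  })
  dumps <- lapply(seq_len(spec$n_dumps), function(i) {
    rand_rect_poly(stats::runif(1, extent[1] + 5000, extent[3] - 5000),
                   stats::runif(1, extent[2] + 5000, extent[4] - 5000),
                   stats::runif(1, 200, 600), stats::runif(1, 200, 600))
  })
  # survey coverage: a band across the extent (part of the extent stays
  # unsurveyed so not_estimated cells occur)
  mask_poly <- geom_polygon(rbind(
    c(extent[1], extent[2]), c(extent[3], extent[2]),
    c(extent[3], extent[2] + 0.7 * ext_m), c(extent[1], extent[2] + 0.7 * ext_m)))

  obs_pts <- cbind(stats::runif(spec$n_species_obs, extent[1], extent[3]),
                   stats::runif(spec$n_species_obs, extent[2], extent[4]))

  ## --- attributes ---
  groups <- sample(c("breeding_bird", "migratory_bird", "bat"),
                   spec$n_species_obs, replace = TRUE, prob = c(0.45, 0.35, 0.2))
  band <- sample(1:3, spec$n_species_obs, replace = TRUE)
  species <- character(spec$n_species_obs)
  count <- numeric(spec$n_species_obs)
  season <- character(spec$n_species_obs)
  for (i in seq_len(spec$n_species_obs)) {
    if (groups[i] == "breeding_bird") {
      rec <- catalog$breeding_birds[sample(nrow(catalog$breeding_birds), 1), ]
      species[i] <- rec$species; season[i] <- "breeding"
      count[i] <- switch(band[i], max(1, rec$pairs_0_1pct - 1),
                         rec$pairs_0_1pct, rec$pairs_0_5pct)
    } else if (groups[i] == "migratory_bird") {
      rec <- catalog$migratory_birds[sample(nrow(catalog$migratory_birds), 1), ]
      species[i] <- rec$species; season[i] <- "migration"
      count[i] <- switch(band[i], max(1, rec$minimal_abundance - 1),
                         rec$minimal_abundance, rec$significant_abundance)
    } else {
      rec <- catalog$bats[sample(nrow(catalog$bats), 1), ]
      species[i] <- rec$species
      season[i] <- sample(c("breeding", "wintering"), 1)
      count[i] <- sample(1:20, 1)
    }
  }
  obs <- observations(
    lapply(seq_len(spec$n_species_obs), function(i) geom_point(obs_pts[i, 1], obs_pts[i, 2])),
    species = species, group = groups, count = count, season = season)
  site_feats <- observations(
    c(natura, dumps),
    kind = c(rep("natura2000_site", spec$n_natura), rep("dump_site", spec$n_dumps)))
  obs <- feature_collection(c(obs$geometry, site_feats$geometry),
                            rbind(obs$properties, site_feats$properties))

  # per-region wind regimes within the national envelope of shape/scale
  k_true <- stats::runif(spec$n_municipalities, 1.6, 2.4)
  c_true <- stats::runif(spec$n_municipalities, 5, 9)
  winds <- do.call(rbind, lapply(seq_len(spec$n_municipalities), function(m) {
    data.frame(region = muni_names[m],
               timestamp = seq_len(spec$wind_hours),
               speed_ms = stats::rweibull(spec$wind_hours, shape = k_true[m],
                                          scale = c_true[m]))
  }))

  criteria <- data.frame(
    municipality = muni_names,
    area_km2 = vapply(muni_polys, geom_area, 0) / 1e6,
    installed_mw = ifelse(stats::runif(spec$n_municipalities) < 0.5, 0,
                          round(stats::runif(spec$n_municipalities, 5, 110), 1)),
    wind_density_wm2 = round(power_density(c_true, k_true), 1),
    grid_capacity_mw = ifelse(stats::runif(spec$n_municipalities) < 0.2, 0,
                              round(stats::runif(spec$n_municipalities, 10, 295))),
    special_plan = as.integer(stats::runif(spec$n_municipalities) < 0.4),
    planned_mw = ifelse(stats::runif(spec$n_municipalities) < 0.4, NA,
                        round(stats::runif(spec$n_municipalities, 1, 213), 2)),
    forest_pct = round(stats::runif(spec$n_municipalities, 11, 69), 1))

  munis <- feature_collection(muni_polys, criteria)
  mask <- feature_collection(list(mask_poly),
                             data.frame(kind = "survey_mask",
                                        stringsAsFactors = FALSE))
  out <- list(municipalities = munis, observations = obs, mask = mask,
              winds = winds, criteria = criteria,
              wind_regimes = data.frame(region = muni_names, k = k_true, c = c_true),
              extent = extent)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_geojson(munis, file.path(out_dir, "municipalities.geojson"))
    write_geojson(obs, file.path(out_dir, "observations.geojson"))
    write_geojson(mask, file.path(out_dir, "mask.geojson"))
    utils::write.csv(winds, file.path(out_dir, "winds.csv"), row.names = FALSE)
    utils::write.csv(criteria, file.path(out_dir, "criteria.csv"), row.names = FALSE)
  }
  out
}
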