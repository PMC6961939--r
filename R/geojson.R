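# GeoJSON I/O via jsonlite. Coordinates are treated as already projected to a
# metre-unit reference system (e.g. a national TM grid); no reprojection is
# performed, and geographic (degree) coordinates are rejected where a buffer
# in metres would be meaningless.

#' Build a feature collection
#'
#' @param geometries list of `wc_geom` objects.
#' @param properties data frame with one row per geometry (may be
#'   zero-column).
#' @return a `wc_features` object.
#' @export
feature_collection <- function(geometries, properties = NULL) {
  if (is.null(properties))
    properties <- data.frame(row.names = seq_along(geometries))
  if (nrow(properties) != length(geometries))
    stop("properties must have one row per geometry")
  structure(list(geometry = geometries, properties = properties),
            class = "wc_features")
}

#' @export
length.wc_features <- function(x) length(x$geometry)

#' @export
print.wc_features <- function(x, ...) {
  types <- vapply(x$geometry, function(g) g$type, "")
  cat(sprintf("Feature collection: %d features (%d points, %d polygons)\n",
              length(types), sum(types == "point"), sum(types == "polygon")))
  if (ncol(x$properties))
    cat("  properties:", paste(names(x$properties), collapse = ", "), "\n")
  invisible(x)
}

geom_to_geojson <- function(g) {
  if (g$type == "point") {
    list(type = "Point", coordinates = unname(g$coords))
  } else {
    ring <- rbind(g$coords, g$coords[1, , drop = FALSE])  # closed ring
    list(type = "Polygon", coordinates = list(unname(split(ring, row(ring)))))
  }
}

geojson_to_geom <- function(gj) {
  switch(gj$type,
    Point = geom_point(gj$coordinates[[1]], gj$coordinates[[2]]),
    Polygon = {
      ring <- gj$coordinates[[1]]
      geom_polygon(do.call(rbind, lapply(ring, unlist)))
    },
    stop("unsupported GeoJSON geometry type: ", gj$type))
}

#' Write a feature collection as GeoJSON
#' @param features a `wc_features`.
#' @param file output path.
#' @export
write_geojson <- function(features, file) {
  feats <- lapply(seq_along(features$geometry), function(i) {
    props <- as.list(features$properties[i, , drop = FALSE])
    props <- props[!vapply(props, function(v) is.na(v)[1], TRUE)]
    list(type = "Feature",
         properties = props,
         geometry = geom_to_geojson(features$geometry[[i]]))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       file, auto_unbox = TRUE, digits = NA, pretty = FALSE)
  invisible(file)
}

#' Read a GeoJSON feature collection
#'
#' Point and Polygon features are supported; coordinates are checked to be in
#' a projected (metre) system — values that all look like longitude/latitude
#' degrees are rejected.
#'
#' @param file GeoJSON path.
#' @param require_projected reject degree-scale coordinates (default TRUE).
#' @return a `wc_features`.
#' @export
read_geojson <- function(file, require_projected = TRUE) {
  gj <- jsonlite::read_json(file, simplifyVector = FALSE)
  if (is.null(gj$type) || gj$type != "FeatureCollection")
    stop("not a GeoJSON FeatureCollection: ", file)
  geoms <- lapply(gj$features, function(f) geojson_to_geom(f$geometry))
  if (require_projected && length(geoms)) {
    xs <- unlist(lapply(geoms, function(g) if (g$type == "point") g$coords[1] else g$coords[, 1]))
    ys <- unlist(lapply(geoms, function(g) if (g$type == "point") g$coords[2] else g$coords[, 2]))
    if (all(abs(xs) <= 180) && all(abs(ys) <= 90))
      stop("coordinates look geographic (degrees); buffers need a projected metre-unit system")
  }
  keys <- unique(unlist(lapply(gj$features, function(f) names(f$properties))))
  props <- as.data.frame(
    stats::setNames(lapply(keys, function(k) {
      vals <- lapply(gj$features, function(f) {
        v <- f$properties[[k]]
        if (is.null(v)) NA else v
      })
      unlist(vals)
    }), keys),
    stringsAsFactors = FALSE, optional = TRUE)
  if (length(keys) == 0) props <- data.frame(row.names = seq_along(geoms))
  feature_collection(geoms, props)
}

#' Assemble wildlife observations as a feature collection
#'
#' @param geometries list of `wc_geom` (points or polygons, projected metres).
#' @param species character; latin binomial (NA for protected sites/dumps).
#' @param group `"breeding_bird"`, `"migratory_bird"` or `"bat"` (NA for
#'   non-species features).
#' @param count individuals or breeding pairs (>= 1 for species records).
#' @param season `"breeding"`, `"migration"` or `"wintering"`.
#' @param kind `"species_obs"`, `"natura2000_site"` or `"dump_site"`.
#' @return a `wc_features` with the observation property columns.
#' @export
observations <- function(geometries, species = NA, group = NA, count = 1,
                         season = "breeding", kind = "species_obs") {
  n <- length(geometries)
  props <- data.frame(
    species = rep_len(as.character(species), n),
    group   = rep_len(as.character(group), n),
    count   = rep_len(as.numeric(count), n),
    season  = rep_len(as.character(season), n),
    kind    = rep_len(as.character(kind), n),
    stringsAsFactors = FALSE)
  bad_kind <- !props$kind %in% c("species_obs", "natura2000_site", "dump_site")
  if (any(bad_kind)) stop("unknown observation kind: ", props$kind[bad_kind][1])
  bad_season <- !props$season %in% c("breeding", "migration", "wintering")
  if (any(bad_season)) stop("unknown season: ", props$season[bad_season][1])
  sp <- props$kind == "species_obs"
  if (any(sp & (is.na(props$count) | props$count < 1)))
    stop("species observations need count >= 1")
  feature_collection(geometries, props)
}
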