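# Shared fixtures: the packaged catalog and national table are loaded once;
# small geometric scenes are built in code.

the_catalog <- load_catalog()
the_munis <- read_municipalities()

# a 10x10 km grid of 1-km cells at a round projected origin
small_grid <- function(nx = 10, ny = 10, x0 = 500000, y0 = 6100000) {
  grid_spec(x0, y0, nx, ny, cellsize = 1000)
}

# one square municipality covering a grid exactly
square_muni <- function(spec, name = "unit_a", priority = "I") {
  ext <- c(spec$xmin, spec$ymin,
           spec$xmin + spec$nx * spec$cellsize,
           spec$ymin + spec$ny * spec$cellsize)
  poly <- geom_polygon(rbind(c(ext[1], ext[2]), c(ext[3], ext[2]),
                             c(ext[3], ext[4]), c(ext[1], ext[4])))
  feature_collection(list(poly),
                     data.frame(municipality = name, priority_class = priority,
                                stringsAsFactors = FALSE))
}

obs_point <- function(spec, dx_cells, dy_cells, ...) {
  observations(list(geom_point(spec$xmin + dx_cells * spec$cellsize,
                               spec$ymin + dy_cells * spec$cellsize)), ...)
}
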