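# 1-km analysis grid. Cells are half-open [x, x+cell) x [y, y+cell), indexed
# (col i, row j) with the origin cell at the lower-left corner; class rasters
# use integer codes 0 = not_estimated, 1 = low, 2 = medium, 3 = high.

CLASS_CODES <- c(not_estimated = 0L, low = 1L, medium = 2L, high = 3L)

class_to_code <- function(cls) {
  CLASS_CODES[match(as.character(cls), names(CLASS_CODES))]
}

code_to_class <- function(code) {
  factor(names(CLASS_CODES)[match(code, CLASS_CODES)], levels = names(CLASS_CODES))
}

#' Define the analysis grid
#'
#' @param xmin,ymin lower-left corner of the grid, metres.
#' @param nx,ny number of columns / rows.
#' @param cellsize cell edge length in metres; the sensitivity and conflict
#'   analyses are defined at 1000 m.
#' @return a `grid_spec` list.
#' @export
grid_spec <- function(xmin, ymin, nx, ny, cellsize = 1000) {
  if (nx < 1 || ny < 1) stop("grid must have at least one cell")
  if (cellsize <= 0) stop("cellsize must be positive")
  structure(list(xmin = xmin, ymin = ymin, nx = as.integer(nx),
                 ny = as.integer(ny), cellsize = cellsize),
            class = "grid_spec")
}

#' Rectangle of one grid cell
#' @param spec a `grid_spec`.
#' @param i column index (1-based), `j` row index.
#' @param j row index.
#' @return `c(xmin, ymin, xmax, ymax)`.
#' @export
cell_rect <- function(spec, i, j) {
  x0 <- spec$xmin + (i - 1) * spec$cellsize
  y0 <- spec$ymin + (j - 1) * spec$cellsize
  c(x0, y0, x0 + spec$cellsize, y0 + spec$cellsize)
}

# column/row ranges of cells whose rectangles can touch a bbox
cells_touching_bbox <- function(spec, bbox) {
  i0 <- max(1L, floor((bbox[["xmin"]] - spec$xmin) / spec$cellsize) + 1L)
  i1 <- min(spec$nx, floor((bbox[["xmax"]] - spec$xmin) / spec$cellsize) + 1L)
  j0 <- max(1L, floor((bbox[["ymin"]] - spec$ymin) / spec$cellsize) + 1L)
  j1 <- min(spec$ny, floor((bbox[["ymax"]] - spec$ymin) / spec$cellsize) + 1L)
  if (i0 > i1 || j0 > j1) return(NULL)
  list(i = i0:i1, j = j0:j1)
}

new_class_grid <- function(spec, subclass, score = NULL) {
  structure(list(
    spec = spec,
    class = matrix(CLASS_CODES[["not_estimated"]], nrow = spec$ny, ncol = spec$nx),
    score = if (is.null(score)) matrix(NA_real_, nrow = spec$ny, ncol = spec$nx) else score),
    class = c(subclass, "class_grid"))
}

#' @export
print.class_grid <- function(x, ...) {
  lab <- if (inherits(x, "sensitivity_grid")) "Wildlife sensitivity grid"
         else if (inherits(x, "conflict_grid")) "Conflict grid" else "Class grid"
  tab <- table(code_to_class(x$class))
  cat(sprintf("%s: %d x %d cells of %g m\n", lab, x$spec$nx, x$spec$ny, x$spec$cellsize))
  cat("  cells per class:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

#' Tabulate class shares of a grid
#' @param grid a `sensitivity_grid` or `conflict_grid`.
#' @return data frame of class, cell count and percent of all cells.
#' @export
grid_class_table <- function(grid) {
  tab <- table(code_to_class(grid$class))
  data.frame(class = names(tab), cells = as.integer(tab),
             pct = as.numeric(tab) / length(grid$class) * 100)
}

#' Plot a class grid
#' @param x a `class_grid`.
#' @param ... passed to [graphics::image()].
#' @export
plot.class_grid <- function(x, ...) {
  cols <- c(not_estimated = "grey85", low = "#2c9e4b", medium = "#f2c45f",
            high = "#c23b22")
  sp <- x$spec
  xs <- sp$xmin + (0:sp$nx) * sp$cellsize
  ys <- sp$ymin + (0:sp$ny) * sp$cellsize
  graphics::image(xs, ys, t(x$class), zlim = c(-0.5, 3.5),
                  col = cols, asp = 1, xlab = "x (m)", ylab = "y (m)", ...)
  invisible(x)
}

#' Write a class grid as an ESRI ASCII raster
#'
#' Plain-text raster interchange format readable by standard GIS software:
#' a six-line header followed by the cell codes row by row from the top.
#'
#' @param grid a `class_grid`.
#' @param file output path (conventionally `.asc`).
#' @export
write_class_asc <- function(grid, file) {
  sp <- grid$spec
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", sp$nx), sprintf("nrows %d", sp$ny),
    sprintf("xllcorner %.6f", sp$xmin), sprintf("yllcorner %.6f", sp$ymin),
    sprintf("cellsize %.6f", sp$cellsize), "NODATA_value -9999"), con)
  for (j in sp$ny:1)
    writeLines(paste(grid$class[j, ], collapse = " "), con)
  invisible(file)
}

#' Read a class grid from an ESRI ASCII raster
#' @param file path written by [write_class_asc()].
#' @param subclass S3 class to restore (`"sensitivity_grid"` or
#'   `"conflict_grid"`).
#' @return a `class_grid`.
#' @export
read_class_asc <- function(file, subclass = "sensitivity_grid") {
  lines <- readLines(file)
  hdr <- strsplit(trimws(lines[1:6]), "\\s+")
  kv <- stats::setNames(vapply(hdr, `[`, "", 2), tolower(vapply(hdr, `[`, "", 1)))
  sp <- grid_spec(as.numeric(kv[["xllcorner"]]), as.numeric(kv[["yllcorner"]]),
                  as.integer(kv[["ncols"]]), as.integer(kv[["nrows"]]),
                  as.numeric(kv[["cellsize"]]))
  vals <- lapply(lines[-(1:6)], function(l) as.integer(strsplit(trimws(l), "\\s+")[[1]]))
  m <- do.call(rbind, vals)            # top row first
  g <- new_class_grid(sp, subclass)
  g$class <- m[sp$ny:1, , drop = FALSE]
  g
}

#' Per-cell audit table of a class grid
#'
#' One row per cell with its column/row index, cell-centre coordinates, class
#' label and (for sensitivity grids) the retained numeric overall score.
#'
#' @param x a `class_grid`.
#' @param row.names,optional,... standard [as.data.frame()] arguments, unused.
#' @return data frame.
#' @export
as.data.frame.class_grid <- function(x, row.names = NULL, optional = FALSE, ...) {
  sp <- x$spec
  ij <- expand.grid(i = seq_len(sp$nx), j = seq_len(sp$ny))
  data.frame(
    i = ij$i, j = ij$j,
    x = sp$xmin + (ij$i - 0.5) * sp$cellsize,
    y = sp$ymin + (ij$j - 0.5) * sp$cellsize,
    class = code_to_class(x$class[cbind(ij$j, ij$i)]),
    score = x$score[cbind(ij$j, ij$i)])
}
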