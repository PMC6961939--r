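# Planar geometry primitives for a projected, metre-unit reference system.
# Geometries are points c(x, y) and simple polygons (two-column coordinate
# matrices, ring closure implicit). Buffers are kept implicit: a buffered
# geometry intersects a region iff the Euclidean distance from the base
# geometry to the region is at most the radius, which is exact Minkowski-sum
# semantics without constructing offset rings.

#' Create a point geometry
#' @param x,y coordinates in metres (projected reference system).
#' @return a `wc_geom` of type point.
#' @export
geom_point <- function(x, y) {
  if (!is.finite(x) || !is.finite(y)) stop("point coordinates must be finite")
  structure(list(type = "point",
                 coords = c(x = as.numeric(x), y = as.numeric(y))),
            class = "wc_geom")
}

#' Create a polygon geometry
#' @param coords two-column matrix of ring vertices (metres); the ring is
#'   closed implicitly and must have at least 3 distinct vertices.
#' @return a `wc_geom` of type polygon.
#' @export
geom_polygon <- function(coords) {
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"   # integer coords overflow the shoelace sum
  if (ncol(coords) != 2 || nrow(coords) < 3)
    stop("polygon needs a two-column matrix with at least 3 vertices")
  if (anyNA(coords) || !all(is.finite(coords))) stop("polygon coordinates must be finite")
  # drop an explicitly repeated closing vertex
  n <- nrow(coords)
  if (all(coords[1, ] == coords[n, ])) coords <- coords[-n, , drop = FALSE]
  if (nrow(coords) < 3) stop("polygon degenerate after closing-vertex removal")
  dimnames(coords) <- list(NULL, c("x", "y"))
  structure(list(type = "polygon", coords = coords), class = "wc_geom")
}

#' Shoelace area of a geometry
#' @param g a `wc_geom`.
#' @return area in square metres (0 for points).
#' @export
geom_area <- function(g) {
  if (g$type == "point") return(0)
  p <- g$coords
  n <- nrow(p)
  j <- c(2:n, 1)
  abs(sum(p[, 1] * p[j, 2] - p[j, 1] * p[, 2])) / 2
}

geom_bbox <- function(g, pad = 0) {
  if (g$type == "point") {
    c(xmin = g$coords[["x"]] - pad, ymin = g$coords[["y"]] - pad,
      xmax = g$coords[["x"]] + pad, ymax = g$coords[["y"]] + pad)
  } else {
    c(xmin = min(g$coords[, 1]) - pad, ymin = min(g$coords[, 2]) - pad,
      xmax = max(g$coords[, 1]) + pad, ymax = max(g$coords[, 2]) + pad)
  }
}

# even-odd ray casting; boundary points count as inside
point_in_polygon <- function(pt, poly) {
  x <- pt[1]; y <- pt[2]
  px <- poly[, 1]; py <- poly[, 2]
  n <- length(px)
  j <- c(n, seq_len(n - 1))
  inside <- FALSE
  for (i in seq_len(n)) {
    xi <- px[i]; yi <- py[i]; xj <- px[j[i]]; yj <- py[j[i]]
    # boundary check
    if (seg_point_dist(c(xi, yi), c(xj, yj), c(x, y)) < 1e-9) return(TRUE)
    if ((yi > y) != (yj > y)) {
      xcross <- xi + (y - yi) * (xj - xi) / (yj - yi)
      if (x < xcross) inside <- !inside
    }
  }
  inside
}

seg_point_dist <- function(a, b, p) {
  ab <- b - a
  len2 <- sum(ab^2)
  t <- if (len2 == 0) 0 else max(0, min(1, sum((p - a) * ab) / len2))
  sqrt(sum((a + t * ab - p)^2))
}

segments_intersect <- function(a, b, c, d) {
  orient <- function(p, q, r) {
    v <- (q[1] - p[1]) * (r[2] - p[2]) - (q[2] - p[2]) * (r[1] - p[1])
    if (abs(v) < 1e-12) 0 else sign(v)
  }
  o1 <- orient(a, b, c); o2 <- orient(a, b, d)
  o3 <- orient(c, d, a); o4 <- orient(c, d, b)
  if (o1 != o2 && o3 != o4) return(TRUE)
  on_seg <- function(p, q, r) {
    orient(p, q, r) == 0 &&
      min(p[1], q[1]) - 1e-12 <= r[1] && r[1] <= max(p[1], q[1]) + 1e-12 &&
      min(p[2], q[2]) - 1e-12 <= r[2] && r[2] <= max(p[2], q[2]) + 1e-12
  }
  on_seg(a, b, c) || on_seg(a, b, d) || on_seg(c, d, a) || on_seg(c, d, b)
}

seg_seg_dist <- function(a, b, c, d) {
  if (segments_intersect(a, b, c, d)) return(0)
  min(seg_point_dist(a, b, c), seg_point_dist(a, b, d),
      seg_point_dist(c, d, a), seg_point_dist(c, d, b))
}

rect_corners <- function(rect) {
  rbind(c(rect[1], rect[2]), c(rect[3], rect[2]),
        c(rect[3], rect[4]), c(rect[1], rect[4]))
}

rect_point_dist <- function(rect, pt) {
  dx <- max(rect[1] - pt[1], 0, pt[1] - rect[3])
  dy <- max(rect[2] - pt[2], 0, pt[2] - rect[4])
  sqrt(dx^2 + dy^2)
}

rect_polygon_intersects <- function(rect, poly) {
  # vertex containment either way
  if (any(poly[, 1] >= rect[1] & poly[, 1] <= rect[3] &
          poly[, 2] >= rect[2] & poly[, 2] <= rect[4])) return(TRUE)
  rc <- rect_corners(rect)
  for (i in seq_len(4)) if (point_in_polygon(rc[i, ], poly)) return(TRUE)
  # edge crossings
  n <- nrow(poly)
  nxt <- c(2:n, 1)
  for (i in seq_len(n)) {
    for (j in seq_len(4)) {
      if (segments_intersect(poly[i, ], poly[nxt[i], ],
                             rc[j, ], rc[if (j == 4) 1 else j + 1, ])) return(TRUE)
    }
  }
  FALSE
}

#' Distance from an axis-aligned rectangle to a geometry
#'
#' Zero when they intersect; otherwise the minimum Euclidean separation. A
#' geometry buffered by radius r intersects the rectangle exactly when this
#' distance is at most r.
#'
#' @param rect numeric `c(xmin, ymin, xmax, ymax)` in metres.
#' @param g a `wc_geom`.
#' @return distance in metres.
#' @export
rect_geom_distance <- function(rect, g) {
  if (g$type == "point") return(rect_point_dist(rect, g$coords))
  poly <- g$coords
  if (rect_polygon_intersects(rect, poly)) return(0)
  rc <- rect_corners(rect)
  n <- nrow(poly)
  nxt <- c(2:n, 1)
  best <- Inf
  for (i in seq_len(n)) {
    for (j in seq_len(4)) {
      d <- seg_seg_dist(poly[i, ], poly[nxt[i], ],
                        rc[j, ], rc[if (j == 4) 1 else j + 1, ])
      if (d < best) best <- d
    }
  }
  best
}

# Sutherland-Hodgman clip of a simple polygon by the half-plane a.p <= b.
clip_halfplane <- function(coords, a, b) {
  n <- nrow(coords)
  if (n == 0) return(coords)
  val <- coords %*% a - b
  out <- matrix(numeric(0), ncol = 2)
  for (i in seq_len(n)) {
    j <- if (i == n) 1 else i + 1
    vi <- val[i]; vj <- val[j]
    if (vi <= 1e-9) out <- rbind(out, coords[i, ])
    if ((vi <= 1e-9) != (vj <= 1e-9)) {
      t <- vi / (vi - vj)
      out <- rbind(out, coords[i, ] + t * (coords[j, ] - coords[i, ]))
    }
  }
  out
}

#' Clip a polygon to an axis-aligned rectangle
#'
#' @param g polygon `wc_geom`.
#' @param rect `c(xmin, ymin, xmax, ymax)`.
#' @return polygon `wc_geom` of the intersection, or NULL when empty.
#' @export
clip_polygon_rect <- function(g, rect) {
  stopifnot(g$type == "polygon")
  cc <- g$coords
  cc <- clip_halfplane(cc, c(-1, 0), -rect[1])
  cc <- clip_halfplane(cc, c(1, 0), rect[3])
  if (nrow(cc)) cc <- clip_halfplane(cc, c(0, -1), -rect[2])
  if (nrow(cc)) cc <- clip_halfplane(cc, c(0, 1), rect[4])
  if (nrow(cc) < 3) return(NULL)
  geom_polygon(cc)
}

#' Area of the intersection of a polygon with a rectangle
#' @inheritParams clip_polygon_rect
#' @return area in square metres (0 when disjoint).
#' @export
rect_polygon_intersection_area <- function(g, rect) {
  clipped <- clip_polygon_rect(g, rect)
  if (is.null(clipped)) 0 else geom_area(clipped)
}

#' Voronoi tessellation of a rectangle around seed points
#'
#' Each cell is the set of locations nearer its seed than any other, clipped to
#' the extent: the intersection of the extent rectangle with the bisector
#' half-planes against every other seed. Cells are convex and tile the extent
#' exactly.
#'
#' @param seeds two-column matrix of seed coordinates (metres).
#' @param extent rectangle `c(xmin, ymin, xmax, ymax)`.
#' @return list of polygon `wc_geom`s, one per seed, in seed order.
#' @export
voronoi_polygons <- function(seeds, extent) {
  seeds <- as.matrix(seeds)
  n <- nrow(seeds)
  if (n < 1) stop("need at least one seed")
  if (anyDuplicated(seeds)) stop("duplicate seed points")
  base <- rect_corners(extent)
  lapply(seq_len(n), function(i) {
    cc <- base
    for (j in seq_len(n)[-i]) {
      a <- 2 * (seeds[j, ] - seeds[i, ])
      b <- sum(seeds[j, ]^2) - sum(seeds[i, ]^2)
      cc <- clip_halfplane(cc, a, b)
      if (nrow(cc) < 3) break
    }
    if (nrow(cc) < 3) stop("empty Voronoi cell for seed ", i)
    geom_polygon(cc)
  })
}
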