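#' Conflict class from priority and sensitivity
#'
#' 3x3 lookup combining a municipality's wind-development priority (I best to
#' III low) with the wildlife sensitivity class of a location. Priorities I and
#' II map sensitivity straight through (high conflict where sensitivity is
#' high); priority III downgrades by one level (high sensitivity gives medium
#' conflict, medium and low give low). Where sensitivity is `not_estimated`
#' the conflict is `not_estimated` too — low conflict is never inferred from
#' missing surveys.
#'
#' @param priority factor/character of priority classes (`"I"`, `"II"`,
#'   `"III"`).
#' @param sensitivity factor/character of sensitivity classes (`"high"`,
#'   `"medium"`, `"low"`, `"not_estimated"`).
#' @return factor of conflict classes with levels
#'   `not_estimated`, `low`, `medium`, `high`.
#' @examples
#' conflict_class("III", "high")  # medium
#' @export
conflict_class <- function(priority, sensitivity) {
  priority <- as.character(priority)
  sensitivity <- as.character(sensitivity)
  if (any(!priority %in% c("I", "II", "III")))
    stop("priority must be I, II or III")
  if (any(!sensitivity %in% c("high", "medium", "low", "not_estimated")))
    stop("unknown sensitivity class")
  m <- rbind(I   = c(high = "high",   medium = "medium", low = "low"),
             II  = c(high = "high",   medium = "medium", low = "low"),
             III = c(high = "medium", medium = "low",    low = "low"))
  out <- ifelse(sensitivity == "not_estimated", "not_estimated",
                m[cbind(priority, sensitivity)])
  factor(out, levels = c("not_estimated", "low", "medium", "high"))
}

#' Combine a sensitivity grid with municipal priorities into a conflict grid
#'
#' Each estimated cell takes the conflict class of its sensitivity class and
#' the priority of the municipality containing the cell centre; cells whose
#' centre lies in no municipality, and cells with unestimated sensitivity,
#' stay `not_estimated`.
#'
#' @param sensitivity a `sensitivity_grid`.
#' @param municipalities a `wc_features` of municipality polygons whose
#'   properties include `municipality` and `priority_class`.
#' @return a `conflict_grid` on the same grid spec.
#' @export
combine_conflict <- function(sensitivity, municipalities) {
  if (!"priority_class" %in% names(municipalities$properties))
    stop("municipality features need a priority_class property")
  spec <- sensitivity$spec
  out <- new_class_grid(spec, "conflict_grid")
  prio <- as.character(municipalities$properties$priority_class)

  for (j in seq_len(spec$ny)) for (i in seq_len(spec$nx)) {
    s_code <- sensitivity$class[j, i]
    if (s_code == CLASS_CODES[["not_estimated"]]) next
    ctr <- c(spec$xmin + (i - 0.5) * spec$cellsize,
             spec$ymin + (j - 0.5) * spec$cellsize)
    m <- which_municipality(ctr, municipalities)
    if (is.na(m)) next
    cls <- conflict_class(prio[m], names(CLASS_CODES)[match(s_code, CLASS_CODES)])
    out$class[j, i] <- CLASS_CODES[[as.character(cls)]]
  }
  out$score <- sensitivity$score
  out
}

which_municipality <- function(pt, municipalities) {
  for (m in seq_along(municipalities$geometry)) {
    g <- municipalities$geometry[[m]]
    if (g$type == "polygon" && point_in_polygon(pt, g$coords)) return(m)
  }
  NA_integer_
}

#' Zonal conflict statistics per municipality
#'
#' For every municipality polygon, the share of its area in high, medium and
#' low conflict, and the estimated share (their sum). Cells straddling a
#' border contribute by their exact intersection area with the polygon, so no
#' area is double-counted. Cross-municipality unweighted means and min--max
#' ranges are attached.
#'
#' @param conflict a `conflict_grid`.
#' @param municipalities a `wc_features` of municipality polygons with a
#'   `municipality` name property.
#' @return object of class `zonal_summary`: data frame with columns
#'   `municipality`, `area_km2`, `high_pct`, `medium_pct`, `low_pct`,
#'   `estimated_pct`; summary statistics via [summary()] /
#'   [zonal_overview()].
#' @export
zonal_conflict_stats <- function(conflict, municipalities) {
  spec <- conflict$spec
  names_m <- municipalities$properties$municipality
  if (is.null(names_m)) names_m <- paste0("unit_", seq_along(municipalities$geometry))

  rows <- lapply(seq_along(municipalities$geometry), function(m) {
    g <- municipalities$geometry[[m]]
    if (g$type != "polygon") stop("municipality features must be polygons")
    total <- geom_area(g)
    if (total <= 0) stop("municipality with zero area: ", names_m[m])
    acc <- c(not_estimated = 0, low = 0, medium = 0, high = 0)
    hit <- cells_touching_bbox(spec, geom_bbox(g))
    if (!is.null(hit)) {
      for (j in hit$j) for (i in hit$i) {
        a <- rect_polygon_intersection_area(g, cell_rect(spec, i, j))
        if (a > 0) {
          cls <- names(CLASS_CODES)[match(conflict$class[j, i], CLASS_CODES)]
          acc[cls] <- acc[cls] + a
        }
      }
    }
    data.frame(municipality = names_m[m],
               area_km2 = total / 1e6,
               high_pct = acc[["high"]] / total * 100,
               medium_pct = acc[["medium"]] / total * 100,
               low_pct = acc[["low"]] / total * 100,
               estimated_pct = (acc[["high"]] + acc[["medium"]] + acc[["low"]]) / total * 100)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("zonal_summary", "data.frame")
  out
}

#' Cross-municipality overview of conflict shares
#'
#' Unweighted means and ranges of the per-municipality high/medium/low conflict
#' percentages — the headline statistics of a national assessment.
#'
#' @param zs a `zonal_summary`, or any data frame with columns `high_pct`,
#'   `medium_pct`, `low_pct` (e.g. the packaged national table from
#'   [read_municipalities()]).
#' @return data frame with one row per class: mean, min, max (percent).
#' @export
zonal_overview <- function(zs) {
  need <- c("high_pct", "medium_pct", "low_pct")
  if (!all(need %in% names(zs))) stop("need columns ", paste(need, collapse = ", "))
  do.call(rbind, lapply(need, function(cl) {
    v <- zs[[cl]]
    data.frame(conflict = sub("_pct", "", cl),
               mean_pct = mean(v), min_pct = min(v), max_pct = max(v))
  }))
}

#' @export
summary.zonal_summary <- function(object, ...) {
  ov <- zonal_overview(object)
  cat(sprintf("Zonal conflict shares over %d municipalities\n", nrow(object)))
  print(ov, row.names = FALSE, digits = 3)
  invisible(ov)
}
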