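#' Default criterion ranges and weights for the municipal priority index
#'
#' The five development criteria are scored 0--3 by splitting each criterion's
#' published national range into three equal parts: A wind power density at
#' 50 m (60--342 W/m^2), B free 110 kV grid capacity (0--295 MW), C special-plan
#' status (0/1), D planned wind-farm capacity (0--213 MW), E forest share of the
#' municipal area (11--69 %). Grid and planned capacity score 0 when the raw
#' value is zero (or missing, for planned capacity). The index combines the
#' scores as `I = 0.35 A + 0.25 B + 0.20 C + 0.10 D - 0.10 E`.
#'
#' @return list with `ranges` (named list of `c(lo, hi)`), `weights` and
#'   `zero_is_zero` flags per criterion.
#' @export
priority_config <- function() {
  list(
    ranges = list(
      wind_density  = c(60, 342),
      grid_capacity = c(0, 295),
      planned_mw    = c(0, 213),
      forest_pct    = c(11, 69)),
    weights = c(wind_density = 0.35, grid_capacity = 0.25, special_plan = 0.20,
                planned_mw = 0.10, forest_pct = -0.10),
    zero_is_zero = c(wind_density = FALSE, grid_capacity = TRUE,
                     planned_mw = TRUE, forest_pct = FALSE))
}

#' Score one criterion on thirds of its range
#'
#' Maps a raw criterion value to an integer score: 1, 2 or 3 by which third of
#' `[lo, hi]` contains it, with intervals closed on the right
#' (`(lo, lo+d]`, `(lo+d, lo+2d]`, `(lo+2d, Inf)` for `d = (hi-lo)/3`). Values
#' at or below `lo` score 1 and values above `hi` score 3, so out-of-range
#' inputs clamp rather than fail. With `zero_is_zero`, a raw value of exactly 0
#' (or NA) scores 0 — used for grid and planned capacity, where "none" removes
#' the criterion's contribution entirely.
#'
#' @param value raw criterion value(s).
#' @param lo,hi the criterion's published range (`hi > lo`).
#' @param zero_is_zero logical; score 0 for raw 0/NA.
#' @return integer score(s) in 0..3.
#' @examples
#' score_criterion(157, 60, 342)          # 2
#' score_criterion(0, 0, 295, zero_is_zero = TRUE)  # 0
#' @export
score_criterion <- function(value, lo, hi, zero_is_zero = FALSE) {
  if (!is.numeric(lo) || !is.numeric(hi) || hi <= lo)
    stop("criterion range must satisfy hi > lo")
  d <- (hi - lo) / 3
  v <- as.numeric(value)
  s <- ifelse(is.na(v), NA_integer_,
       ifelse(v <= lo + d, 1L, ifelse(v <= lo + 2 * d, 2L, 3L)))
  if (zero_is_zero) s[is.na(v) | v == 0] <- 0L
  if (anyNA(s)) stop("missing criterion value where zero_is_zero is not set")
  s
}

#' Municipal wind-development priority index
#'
#' Computes the weighted five-criterion index and priority class for each
#' municipality. Input rows need columns `municipality`, `wind_density_wm2`,
#' `grid_capacity_mw`, `special_plan` (0/1 or logical), `planned_mw` (NA for
#' none) and `forest_pct`; an `installed_mw` column, if present, is carried
#' through for the installed-power summaries.
#'
#' @param municipalities data frame of raw criteria, one row per municipality
#'   (see [read_municipalities()] for the CSV layout).
#' @param config ranges/weights, by default the published values
#'   ([priority_config()]).
#' @return object of class `priority_table`: the input plus integer score
#'   columns `score_A` (wind), `score_B` (grid), `score_C` (plan), `score_D`
#'   (planned), `score_E` (forest), the index `index_I` (rounded to 2 decimals)
#'   and `priority_class` (factor I/II/III).
#' @examples
#' tab <- read_municipalities()
#' head(priority_index(tab))
#' @export
priority_index <- function(municipalities, config = priority_config()) {
  m <- municipalities
  need <- c("municipality", "wind_density_wm2", "grid_capacity_mw",
            "special_plan", "planned_mw", "forest_pct")
  miss <- setdiff(need, names(m))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  if (any(m$forest_pct < 0 | m$forest_pct > 100))
    stop("forest_pct must lie in [0, 100]")
  neg <- c("wind_density_wm2", "grid_capacity_mw", "planned_mw")
  for (cl in neg) if (any(m[[cl]] < 0, na.rm = TRUE)) stop(cl, " must be >= 0")

  r <- config$ranges; z <- config$zero_is_zero; w <- config$weights
  sA <- score_criterion(m$wind_density_wm2, r$wind_density[1],  r$wind_density[2],  z[["wind_density"]])
  sB <- score_criterion(m$grid_capacity_mw, r$grid_capacity[1], r$grid_capacity[2], z[["grid_capacity"]])
  sC <- as.integer(as.logical(m$special_plan))
  sD <- score_criterion(m$planned_mw, r$planned_mw[1], r$planned_mw[2], z[["planned_mw"]])
  sE <- score_criterion(m$forest_pct, r$forest_pct[1], r$forest_pct[2], z[["forest_pct"]])

  I <- round(w[["wind_density"]] * sA + w[["grid_capacity"]] * sB +
             w[["special_plan"]] * sC + w[["planned_mw"]] * sD +
             w[["forest_pct"]] * sE, 2)

  out <- m
  out$score_A <- sA; out$score_B <- sB; out$score_C <- sC
  out$score_D <- sD; out$score_E <- sE
  out$index_I <- I
  out$priority_class <- classify_priority(I)
  class(out) <- c("priority_table", "data.frame")
  out
}

#' Classify a priority index into classes I/II/III
#'
#' Class I (best prospects) above 1.1 points, class II for 0.6--1.1 inclusive,
#' class III below 0.6.
#'
#' @param index_I numeric index values.
#' @return factor with levels `I`, `II`, `III`.
#' @examples
#' classify_priority(c(1.15, 0.6, 0.55))
#' @export
classify_priority <- function(index_I) {
  cls <- ifelse(index_I > 1.1, "I", ifelse(index_I >= 0.6, "II", "III"))
  factor(cls, levels = c("I", "II", "III"))
}

#' Installed wind power share per priority class
#'
#' Shares of the table's total installed capacity (farms above 350 kW) falling
#' in each priority class, in percent of the table total.
#'
#' @param priority a `priority_table` (needs `installed_mw`), or any data frame
#'   with `installed_mw` and `priority_class`.
#' @return data frame with columns `priority_class`, `installed_mw`,
#'   `share_pct`.
#' @export
installed_power_by_priority <- function(priority) {
  if (!all(c("installed_mw", "priority_class") %in% names(priority)))
    stop("need columns installed_mw and priority_class")
  tot <- sum(priority$installed_mw)
  if (tot <= 0) stop("total installed capacity is zero; shares undefined")
  mw <- tapply(priority$installed_mw, priority$priority_class, sum, default = 0)
  data.frame(priority_class = factor(names(mw), levels = c("I", "II", "III")),
             installed_mw = as.numeric(mw),
             share_pct = as.numeric(mw) / tot * 100,
             row.names = NULL)
}

#' Read a municipal criteria table
#'
#' Reads a CSV with one row per municipality. Required columns:
#' `municipality`, `wind_density_wm2`, `grid_capacity_mw`, `special_plan`,
#' `planned_mw`, `forest_pct`; optional `area_km2`, `installed_mw`, and — in
#' the packaged national table — the published index (`index_printed`),
#' priority class and per-municipality conflict-area percentages
#' (`estimated_pct`, `high_pct`, `medium_pct`, `low_pct`).
#'
#' @param file CSV path; defaults to the packaged national table of all 51
#'   municipalities assessed for wind development.
#' @return data frame.
#' @export
read_municipalities <- function(file = system.file("extdata", "municipalities_lt.csv",
                                                   package = "windconflict")) {
  df <- utils::read.csv(file, stringsAsFactors = FALSE, encoding = "UTF-8")
  if (!"municipality" %in% names(df)) stop("municipality column missing in ", file)
  df
}

#' @export
print.priority_table <- function(x, ...) {
  n <- table(x$priority_class)
  cat(sprintf("Municipal priority table: %d municipalities (I: %d, II: %d, III: %d)\n",
              nrow(x), n[["I"]], n[["II"]], n[["III"]]))
  NextMethod()
}

#' @export
summary.priority_table <- function(object, ...) {
  cat("Priority index summary\n")
  print(summary(object$index_I))
  print(table(object$priority_class))
  if ("installed_mw" %in% names(object) && sum(object$installed_mw) > 0)
    print(installed_power_by_priority(object))
  if ("index_printed" %in% names(object)) {
    agree <- sum(abs(object$index_I - object$index_printed) < 0.005)
    cat(sprintf("index matches the reference column for %d of %d municipalities\n",
                agree, nrow(object)))
    mism <- object$municipality[abs(object$index_I - object$index_printed) >= 0.005]
    if (length(mism)) cat("  mismatches:", paste(mism, collapse = ", "), "\n")
  }
  invisible(object)
}
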