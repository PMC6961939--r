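#' Overall wildlife sensitivity score
#'
#' Combines a species' conservation score B (1--3), its summed sensitivity to
#' wind-power effects C, and the local abundance score D (for birds; for bats D
#' is the per-cell bat species richness) into the overall score `A = D * (B + C)`.
#'
#' @param B conservation score, integer 1--3.
#' @param C summed effect sensitivity, non-negative integer.
#' @param D abundance score (birds: 1--3) or bat species richness (>= 1).
#' @return numeric overall score(s).
#' @examples
#' overall_score(B = 3, C = 4, D = 3)  # 21, a maximally sensitive breeder
#' @export
overall_score <- function(B, C, D) {
  if (any(!B %in% 1:3)) stop("conservation score B must be 1, 2 or 3")
  if (any(C < 0)) stop("summed sensitivity C must be non-negative")
  if (any(D < 1)) stop("abundance score D must be at least 1")
  D * (B + C)
}

#' Local abundance score for a breeding bird
#'
#' 3 when the local number of pairs reaches the species' 0.5%-of-national-
#' population count, 2 when it reaches the 0.1% count, else 1. Both published
#' thresholds floor at one pair, so any record of the rarest species scores 3.
#'
#' @param local_pairs breeding pairs observed locally.
#' @param record catalog row from [species_lookup()] (group `breeding_bird`).
#' @return integer score in 1..3.
#' @export
breeder_abundance_score <- function(local_pairs, record) {
  if (is.null(record$pairs_0_5pct))
    stop("record lacks breeding abundance thresholds; wrong group?")
  ifelse(local_pairs >= record$pairs_0_5pct, 3L,
         ifelse(local_pairs >= record$pairs_0_1pct, 2L, 1L))
}

#' Local abundance score for a migratory bird concentration
#'
#' 3 when the observed count reaches the species' significant stopover
#' abundance, 2 when it reaches the minimal abundance, else 1.
#'
#' @param count individuals observed.
#' @param record catalog row from [species_lookup()] (group `migratory_bird`).
#' @return integer score in 1..3.
#' @export
migrant_abundance_score <- function(count, record) {
  if (is.null(record$minimal_abundance))
    stop("record lacks migrant abundance thresholds; wrong group?")
  ifelse(count >= record$significant_abundance, 3L,
         ifelse(count >= record$minimal_abundance, 2L, 1L))
}

#' Buffer radius applicable to one observation
#'
#' Species observations take the species' published buffer; bats take 1000 m in
#' the breeding season and 2000 m at wintering sites; dump sites take 2000 m;
#' protected (Natura 2000) sites take a configured per-run buffer (default 0:
#' the site footprint itself is already high-sensitivity).
#'
#' @param species,group,season,kind observation properties (see
#'   [observations()]).
#' @param catalog a `species_catalog`.
#' @param natura_buffer_m metres added around protected-site footprints.
#' @return buffer radius in metres.
#' @export
observation_buffer_m <- function(species, group, season, kind, catalog,
                                 natura_buffer_m = 0) {
  if (kind == "dump_site") return(2000)
  if (kind == "natura2000_site") return(natura_buffer_m)
  if (group == "bat") return(if (identical(season, "wintering")) 2000 else 1000)
  rec <- species_lookup(catalog, species, group)
  rec$buffer_m
}

#' Buffer one observation feature
#'
#' Returns the observation's geometry together with its buffer radius as an
#' implicit (distance-predicate) dilation: the buffered feature covers every
#' location within `buffer_m` of the base geometry, which is the exact
#' Euclidean (Minkowski) buffer.
#'
#' @param geometry a `wc_geom` in projected metres.
#' @inheritParams observation_buffer_m
#' @return list with `geometry`, `buffer_m` and `area_m2` (exact for points
#'   and for zero-buffer polygons; for dilated polygons the convex Minkowski
#'   formula `A + P r + pi r^2` is used, an upper bound for non-convex rings).
#' @export
buffer_observation <- function(geometry, species = NA, group = NA,
                               season = "breeding", kind = "species_obs",
                               catalog = load_catalog(), natura_buffer_m = 0) {
  r <- observation_buffer_m(species, group, season, kind, catalog, natura_buffer_m)
  area <- if (geometry$type == "point") {
    pi * r^2
  } else if (r == 0) {
    geom_area(geometry)
  } else {
    p <- geometry$coords
    per <- sum(sqrt(rowSums((p - p[c(2:nrow(p), 1), , drop = FALSE])^2)))
    geom_area(geometry) + per * r + pi * r^2
  }
  list(geometry = geometry, buffer_m = r, area_m2 = area)
}

#' Rasterize scored observations to a 1-km sensitivity grid
#'
#' Each species observation is buffered by its species/season radius, scored
#' with the overall score `A = D * (B + C)` and classified on its group's
#' high/medium/low scale; every grid cell touched by the buffered feature
#' receives at least that class. Cells are combined conservatively by maximum
#' severity. Protected (Natura 2000) and dump-site footprints (the latter with
#' their fixed 2000 m buffer) force cells to high regardless of scores. Bats
#' are scored per cell: D is the number of distinct bat species whose buffered
#' observations touch the cell, combined with the largest (B + C) among them.
#'
#' Cells touched by no feature are `not_estimated` unless they fall inside the
#' survey-coverage mask, in which case they are `low`: absence of observations
#' only supports a low rating where surveys actually took place.
#'
#' @param obs a `wc_features` of observations (see [observations()]).
#' @param spec a [grid_spec()]; the published analysis uses 1000 m cells.
#' @param catalog a `species_catalog`.
#' @param mask optional `wc_features` (or list of `wc_geom`) of surveyed-area
#'   polygons.
#' @param thresholds class cutoffs, by default [sensitivity_thresholds()].
#' @param natura_buffer_m buffer around protected-site footprints (default 0).
#' @return a `sensitivity_grid` (subclass of `class_grid`): per-cell class
#'   codes plus the retained numeric score of the severest feature for audit.
#' @export
rasterize_sensitivity <- function(obs, spec, catalog = load_catalog(),
                                  mask = NULL,
                                  thresholds = sensitivity_thresholds(),
                                  natura_buffer_m = 0) {
  g <- new_class_grid(spec, "sensitivity_grid")
  if (length(obs) == 0) {
    warning("no observation features; sensitivity grid is entirely not_estimated")
  }

  # survey coverage: surveyed cells start as low
  mask_geoms <- if (is.null(mask)) list()
                else if (inherits(mask, "wc_features")) mask$geometry else mask
  for (mg in mask_geoms) {
    hit <- cells_touching_bbox(spec, geom_bbox(mg))
    if (is.null(hit)) next
    for (j in hit$j) for (i in hit$i) {
      if (g$class[j, i] < CLASS_CODES[["low"]] &&
          rect_geom_distance(cell_rect(spec, i, j), mg) <= 0)
        g$class[j, i] <- CLASS_CODES[["low"]]
    }
  }

  p <- obs$properties
  # accumulators for the per-cell bat rule
  bat_species <- list()   # cell key -> character vector of species
  bat_bc <- list()        # cell key -> max (B + C)

  apply_feature <- function(cells, code, score) {
    for (k in seq_len(nrow(cells))) {
      i <- cells[k, 1]; j <- cells[k, 2]
      if (code > g$class[j, i]) {
        g$class[j, i] <<- code
        g$score[j, i] <<- score
      } else if (code == g$class[j, i] &&
                 (is.na(g$score[j, i]) || (!is.na(score) && score > g$score[j, i]))) {
        g$score[j, i] <<- score
      }
    }
  }

  feature_cells <- function(geom, r) {
    hit <- cells_touching_bbox(spec, geom_bbox(geom, pad = r))
    if (is.null(hit)) return(matrix(integer(0), ncol = 2))
    out <- matrix(integer(0), ncol = 2)
    for (j in hit$j) for (i in hit$i) {
      if (rect_geom_distance(cell_rect(spec, i, j), geom) <= r)
        out <- rbind(out, c(i, j))
    }
    out
  }

  for (f in seq_along(obs$geometry)) {
    geom <- obs$geometry[[f]]
    kind <- p$kind[f]
    r <- observation_buffer_m(p$species[f], p$group[f], p$season[f], kind,
                              catalog, natura_buffer_m)
    cells <- feature_cells(geom, r)
    if (!nrow(cells)) next

    if (kind %in% c("natura2000_site", "dump_site")) {
      apply_feature(cells, CLASS_CODES[["high"]], NA_real_)
    } else if (p$group[f] == "bat") {
      rec <- species_lookup(catalog, p$species[f], "bat")
      bc <- rec$conservation_score + rec$sensitivity_score
      for (k in seq_len(nrow(cells))) {
        key <- paste(cells[k, 1], cells[k, 2])
        bat_species[[key]] <- union(bat_species[[key]], p$species[f])
        bat_bc[[key]] <- max(bat_bc[[key]], bc)
      }
    } else {
      rec <- species_lookup(catalog, p$species[f], p$group[f])
      D <- if (p$group[f] == "breeding_bird")
        breeder_abundance_score(p$count[f], rec)
      else migrant_abundance_score(p$count[f], rec)
      A <- overall_score(rec$conservation_score, rec$summed_sensitivity, D)
      cls <- as.character(sensitivity_class(A, p$group[f], thresholds))
      apply_feature(cells, CLASS_CODES[[cls]], A)
    }
  }

  # second pass: bat cells, D = per-cell species richness
  for (key in names(bat_species)) {
    ij <- as.integer(strsplit(key, " ")[[1]])
    D <- length(bat_species[[key]])
    A <- D * bat_bc[[key]]
    cls <- as.character(sensitivity_class(A, "bat", thresholds))
    apply_feature(matrix(ij, ncol = 2), CLASS_CODES[[cls]], A)
  }

  g
}

#' Wilcoxon signed-rank test for paired scores
#'
#' Two-sided (by default) signed-rank test on paired values. Zero differences
#' are dropped, the classic convention; if every difference is zero the test
#' degenerates and p = 1 is returned with a warning. Ties among the absolute
#' differences get midranks. For 25 or fewer non-zero pairs the p-value comes
#' from the exact null distribution of the rank sum under sign flips, computed
#' by dynamic programming on the (doubled, hence integer) midranks — valid
#' under ties, unlike the textbook no-tie tables. Larger samples use the
#' normal approximation with the tie-corrected variance.
#'
#' @param x,y paired numeric vectors (or give differences in `x` and leave
#'   `y` NULL).
#' @param alternative `"two.sided"`, `"greater"` (positive differences) or
#'   `"less"`.
#' @param exact_max largest n for the exact enumeration (default 25).
#' @return an object of class `htest` with the rank-sum statistic `V`
#'   (sum of ranks of positive differences), p-value and method.
#' @examples
#' signed_rank_test(c(3, 3, 3, 3, 3, 3), c(1, 1, 1, 1, 1, 1),
#'                  alternative = "greater")$p.value  # exact 1/64
#' @export
signed_rank_test <- function(x, y = NULL,
                             alternative = c("two.sided", "greater", "less"),
                             exact_max = 25) {
  alternative <- match.arg(alternative)
  dname <- if (is.null(y)) deparse(substitute(x))
           else paste(deparse(substitute(x)), "and", deparse(substitute(y)))
  d <- if (is.null(y)) x else x - y
  d <- d[!is.na(d)]
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) {
    warning("all paired differences are zero; returning p = 1")
    return(structure(list(statistic = c(V = NA_real_), p.value = 1,
                          alternative = alternative, n_pairs = 0L,
                          method = "Wilcoxon signed-rank test (degenerate: all ties)",
                          data.name = dname),
                     class = "htest"))
  }
  r <- rank(abs(d))
  V <- sum(r[d > 0])

  if (n <= exact_max) {
    # exact distribution of 2*V over all 2^n sign assignments
    r2 <- as.integer(round(2 * r))
    total <- sum(r2)
    ways <- numeric(total + 1)
    ways[1] <- 1
    for (ri in r2) {
      shifted <- c(numeric(ri), ways[seq_len(total + 1 - ri)])
      ways <- ways + shifted
    }
    denom <- 2^n
    v2 <- as.integer(round(2 * V))
    p_le <- sum(ways[seq_len(v2 + 1)]) / denom
    p_ge <- sum(ways[seq.int(v2 + 1, total + 1)]) / denom
    p <- switch(alternative,
      two.sided = min(1, 2 * min(p_le, p_ge)),
      greater   = p_ge,
      less      = p_le)
    method <- "Exact Wilcoxon signed-rank test (tie-aware enumeration)"
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (V - mu) / sqrt(sigma2)
    p <- switch(alternative,
      two.sided = 2 * stats::pnorm(-abs(z)),
      greater   = stats::pnorm(z, lower.tail = FALSE),
      less      = stats::pnorm(z))
    method <- "Wilcoxon signed-rank test (normal approximation, tie-corrected)"
  }
  structure(list(statistic = c(V = V), p.value = p, alternative = alternative,
                 n_pairs = n, method = method, data.name = dname),
            class = "htest")
}

#' Compare breeding- and migration-season sensitivity of shared species
#'
#' Pairs the summed effect-sensitivity scores C of every species present in
#' both the breeding and migratory catalog tables (synonyms resolved through
#' the packaged map) and runs the paired signed-rank test on them.
#'
#' @param catalog a `species_catalog`.
#' @param alternative passed to [signed_rank_test()] (default two-sided).
#' @return the `htest` from [signed_rank_test()], with the paired table
#'   attached as attribute `"pairs"`.
#' @export
paired_breeder_migrant_test <- function(catalog = load_catalog(),
                                        alternative = "two.sided") {
  bb <- catalog$breeding_birds
  mb <- catalog$migratory_birds
  bname <- canonical_name(catalog, bb$species)
  mname <- canonical_name(catalog, mb$species)
  shared <- intersect(bname, mname)
  pairs <- data.frame(
    species = shared,
    breeding = bb$summed_sensitivity[match(shared, bname)],
    migration = mb$summed_sensitivity[match(shared, mname)])
  nz <- sum(pairs$breeding != pairs$migration)
  if (nz < 6)
    stop("fewer than 6 species with differing seasonal scores (", nz,
         "); paired comparison not meaningful")
  ht <- signed_rank_test(pairs$breeding, pairs$migration,
                         alternative = alternative)
  ht$data.name <- sprintf("summed sensitivity of %d shared species (breeding vs migration)",
                          nrow(pairs))
  attr(ht, "pairs") <- pairs
  ht
}
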