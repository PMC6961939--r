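#' Species sensitivity catalog
#'
#' The package ships a frozen parameter base for wildlife sensitivity scoring:
#' 69 breeding bird species, 43 migratory bird species and 17 bat species, each
#' with a national conservation score (1--3), scores of sensitivity to the four
#' wind-power effects (collision, disturbance, barrier, habitat change/loss; birds
#' only), a summed sensitivity score, a disturbance-free buffer radius in metres,
#' and the abundance thresholds that drive the local-abundance score: national
#' breeding pairs plus the 0.5% and 0.1% population counts for breeders, and the
#' minimal/significant stopover abundances for migrants. Bats carry a single
#' 1--3 sensitivity score and season-dependent buffers (1000 m breeding roosts,
#' 2000 m wintering sites).
#'
#' `load_catalog()` reads the packaged CSV tables, validates every record and
#' returns a `species_catalog` object. All scores are frozen as published; no
#' taxonomic or red-list service is consulted at run time.
#'
#' @param path directory holding the catalog CSVs. Defaults to the copies
#'   installed with the package; point it elsewhere only to load a modified
#'   parameter base with the same layout.
#' @return An object of class `species_catalog`: a list with data frames
#'   `breeding_birds`, `migratory_birds`, `bats`, and a named character vector
#'   `synonyms` mapping alternative binomials to the catalog spelling.
#' @examples
#' cat <- load_catalog()
#' species_lookup(cat, "Ciconia nigra", "breeding_bird")$buffer_m
#' @export
load_catalog <- function(path = system.file("extdata", package = "windconflict")) {
  read_tbl <- function(file) {
    f <- file.path(path, file)
    if (!file.exists(f)) stop("catalog table not found: ", f)
    utils::read.csv(f, stringsAsFactors = FALSE, encoding = "UTF-8")
  }
  breeding  <- read_tbl("breeding_birds.csv")
  migratory <- read_tbl("migratory_birds.csv")
  bats      <- read_tbl("bats.csv")
  syn_tbl   <- read_tbl("species_synonyms.csv")
  synonyms  <- stats::setNames(syn_tbl$canonical, syn_tbl$name)

  cat <- structure(
    list(breeding_birds = breeding, migratory_birds = migratory,
         bats = bats, synonyms = synonyms),
    class = "species_catalog")
  validate_catalog(cat)
  cat
}

# Fail loudly at load time: every downstream score trusts these tables.
validate_catalog <- function(cat) {
  bb <- cat$breeding_birds; mb <- cat$migratory_birds; bt <- cat$bats

  chk_num <- function(df, cols, tbl) {
    for (cl in cols) {
      v <- df[[cl]]
      if (is.null(v)) stop("catalog table ", tbl, " lacks column ", cl)
      if (anyNA(v) || !is.numeric(v))
        stop("malformed value in ", tbl, " column ", cl,
             " (row ", which(is.na(v) | !is.finite(v))[1], ")")
    }
  }
  chk_num(bb, c("buffer_m", "conservation_score", "collision", "disturbance",
                "barrier", "habitat_change", "summed_sensitivity",
                "national_pairs", "pairs_0_5pct", "pairs_0_1pct"), "breeding_birds")
  chk_num(mb, c("buffer_m", "conservation_score", "collision", "disturbance",
                "barrier", "habitat_change", "summed_sensitivity",
                "minimal_abundance", "significant_abundance"), "migratory_birds")
  chk_num(bt, c("conservation_score", "sensitivity_score"), "bats")

  for (df in list(bb, mb)) {
    s <- df$collision + df$disturbance + df$barrier + df$habitat_change
    bad <- which(s != df$summed_sensitivity)
    if (length(bad))
      stop("summed sensitivity does not equal the sum of effect scores for: ",
           paste(df$species[bad], collapse = ", "))
    if (!all(df$conservation_score %in% 1:3))
      stop("conservation score outside 1..3 in bird table")
    if (!all(df$buffer_m %in% c(100, 200, 500, 1000, 2000)))
      stop("buffer radius outside the published set in bird table")
  }
  if (!all(bt$conservation_score %in% 1:3) || !all(bt$sensitivity_score %in% 1:3))
    stop("bat scores outside 1..3")

  bad <- which(!(bb$pairs_0_1pct <= bb$pairs_0_5pct &
                 bb$pairs_0_5pct <= bb$national_pairs))
  if (length(bad))
    stop("breeding abundance thresholds out of order for: ",
         paste(bb$species[bad], collapse = ", "))
  bad <- which(!(mb$minimal_abundance <= mb$significant_abundance))
  if (length(bad))
    stop("migrant abundance thresholds out of order for: ",
         paste(mb$species[bad], collapse = ", "))

  if (nrow(bb) != 69L) stop("expected 69 breeding bird records, found ", nrow(bb))
  if (nrow(mb) != 43L) stop("expected 43 migratory bird records, found ", nrow(mb))
  if (nrow(bt) != 17L) stop("expected 17 bat records, found ", nrow(bt))
  invisible(cat)
}

#' Resolve a species name to its catalog spelling
#'
#' Applies the packaged synonym map (e.g. *Egretta alba* is stored as
#' *Ardea alba* in the breeding table) so that records of the same species in
#' different season tables can be aligned.
#'
#' @param catalog a `species_catalog`.
#' @param name character vector of latin binomials.
#' @return character vector of canonical names.
#' @export
canonical_name <- function(catalog, name) {
  hit <- match(name, names(catalog$synonyms))
  out <- name
  out[!is.na(hit)] <- unname(catalog$synonyms[hit[!is.na(hit)]])
  out
}

#' Look up one species record
#'
#' @param catalog a `species_catalog` from [load_catalog()].
#' @param species latin binomial (synonyms are accepted for birds).
#' @param group one of `"breeding_bird"`, `"migratory_bird"`, `"bat"`. The same
#'   species may occur in both bird tables with different scores; the pair
#'   (species, group) identifies a record.
#' @return A one-row data frame (the record as stored) with an added
#'   `group` column.
#' @export
species_lookup <- function(catalog, species,
                           group = c("breeding_bird", "migratory_bird", "bat")) {
  group <- match.arg(group)
  tbl <- switch(group,
    breeding_bird  = catalog$breeding_birds,
    migratory_bird = catalog$migratory_birds,
    bat            = catalog$bats)
  i <- match(species, tbl$species)
  if (is.na(i) && group != "bat") {
    # retry through the synonym map in both directions
    i <- match(canonical_name(catalog, species), canonical_name(catalog, tbl$species))
  }
  if (is.na(i))
    stop("species not in catalog for group ", group, ": ", species)
  rec <- tbl[i, , drop = FALSE]
  rec$group <- group
  rownames(rec) <- NULL
  rec
}

#' Class thresholds for the overall sensitivity score
#'
#' Cutoffs translating the overall score A into high/medium/low sensitivity.
#' Breeding birds: high above 12, medium 7--12, low 1--6. Migratory birds:
#' high above 20, medium 9--20, low 2--8. No separate bat scale is published;
#' by default bats are classified on the migrant scale (see the methods
#' vignette), which can be overridden here.
#'
#' @param bat_scale which published scale to apply to bats.
#' @return named list with `high_above` and `medium_from` per group.
#' @export
sensitivity_thresholds <- function(bat_scale = c("migratory_bird", "breeding_bird")) {
  bat_scale <- match.arg(bat_scale)
  th <- list(
    breeding_bird  = c(high_above = 12, medium_from = 7),
    migratory_bird = c(high_above = 20, medium_from = 9))
  th$bat <- th[[bat_scale]]
  th
}

#' Classify an overall sensitivity score
#'
#' @param A numeric vector of overall scores (D x (B + C)).
#' @param group species group the scores belong to (scalar).
#' @param thresholds output of [sensitivity_thresholds()].
#' @return factor with levels `low`, `medium`, `high`.
#' @export
sensitivity_class <- function(A, group, thresholds = sensitivity_thresholds()) {
  th <- thresholds[[group]]
  if (is.null(th)) stop("unknown species group: ", group)
  cls <- ifelse(A > th["high_above"], "high",
                ifelse(A >= th["medium_from"], "medium", "low"))
  factor(cls, levels = c("low", "medium", "high"))
}

#' @export
print.species_catalog <- function(x, ...) {
  cat("Species sensitivity catalog\n")
  cat(sprintf("  breeding birds : %d species (buffers %s m)\n",
              nrow(x$breeding_birds),
              paste(sort(unique(x$breeding_birds$buffer_m)), collapse = "/")))
  cat(sprintf("  migratory birds: %d species\n", nrow(x$migratory_birds)))
  cat(sprintf("  bats           : %d species (buffers 1000 m breeding / 2000 m wintering)\n",
              nrow(x$bats)))
  invisible(x)
}
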