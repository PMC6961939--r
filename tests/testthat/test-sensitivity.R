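test_that("overall score multiplies abundance into conservation plus effects", {
  expect_equal(overall_score(B = 3, C = 4, D = 3), 21)  # maximal breeder
  expect_equal(overall_score(B = 1, C = 0, D = 1), 1)   # minimal case
  expect_equal(overall_score(B = 1, C = 3, D = 2), 8)   # bat with richness 2
  expect_equal(overall_score(2, 3, 2), 2 * overall_score(2, 3, 1))
  expect_error(overall_score(0, 2, 1), "B")
  expect_error(overall_score(2, -1, 1), "C")
  expect_error(overall_score(2, 2, 0), "D")
})

test_that("breeder abundance scores compare pairs to the national thresholds", {
  cn <- species_lookup(the_catalog, "Ciconia nigra", "breeding_bird")
  cc <- species_lookup(the_catalog, "Ciconia ciconia", "breeding_bird")
  expect_equal(breeder_abundance_score(5, cn), 3L)    # thresholds 3 / 1
  expect_equal(breeder_abundance_score(8, cc), 1L)    # thresholds 100 / 20
  expect_equal(breeder_abundance_score(20, cc), 2L)   # boundary inclusive
  expect_equal(breeder_abundance_score(100, cc), 3L)
  expect_error(breeder_abundance_score(5, species_lookup(the_catalog, "Grus grus",
                                                         "migratory_bird")),
               "wrong group")
})

test_that("migrant abundance scores compare counts to stopover thresholds", {
  gg <- species_lookup(the_catalog, "Grus grus", "migratory_bird")
  ha <- species_lookup(the_catalog, "Haliaeetus albicilla", "migratory_bird")
  expect_equal(migrant_abundance_score(60, gg), 2L)
  expect_equal(migrant_abundance_score(250, gg), 3L)
  expect_equal(migrant_abundance_score(4, ha), 1L)
})

test_that("buffers follow species, season and site rules", {
  b <- buffer_observation(geom_point(0, 0), "Ciconia nigra", "breeding_bird",
                          catalog = the_catalog)
  expect_equal(b$buffer_m, 2000)
  expect_equal(b$area_m2 / 1e6, pi * 4, tolerance = 1e-12)  # ~12.57 km2

  expect_equal(observation_buffer_m("Myotis myotis", "bat", "breeding",
                                    "species_obs", the_catalog), 1000)
  expect_equal(observation_buffer_m("Myotis myotis", "bat", "wintering",
                                    "species_obs", the_catalog), 2000)
  expect_equal(observation_buffer_m(NA, NA, NA, "dump_site", the_catalog), 2000)
  expect_equal(observation_buffer_m(NA, NA, NA, "natura2000_site", the_catalog), 0)
  expect_equal(observation_buffer_m(NA, NA, NA, "natura2000_site", the_catalog,
                                    natura_buffer_m = 500), 500)

  sq <- geom_polygon(rbind(c(0, 0), c(100, 0), c(100, 100), c(0, 100)))
  expect_equal(buffer_observation(sq, NA, NA, kind = "natura2000_site",
                                  catalog = the_catalog)$area_m2, 1e4)
})

test_that("buffered area grows monotonically with the radius", {
  areas <- vapply(c(100, 500, 1000, 2000), function(r) pi * r^2, 0)
  expect_true(all(diff(areas) > 0))
  sq <- geom_polygon(rbind(c(0, 0), c(1000, 0), c(1000, 1000), c(0, 1000)))
  a <- vapply(c("breeding", "wintering"), function(s)
    buffer_observation(sq, "Nyctalus noctula", "bat", season = s,
                       catalog = the_catalog)$area_m2, 0)
  expect_lt(a[["breeding"]], a[["wintering"]])
})

test_that("a high-scoring colony rasterizes to high cells over its buffer", {
  spec <- small_grid()
  # 5 pairs of Ciconia nigra: D = 3, A = 3 * (3 + 4) = 21 > 12 -> high
  obs <- obs_point(spec, 5, 5, species = "Ciconia nigra",
                   group = "breeding_bird", count = 5, season = "breeding")
  g <- rasterize_sensitivity(obs, spec, the_catalog)
  centre <- g$class[6, 6]
  expect_equal(centre, 3L)
  expect_equal(g$score[6, 6], 21)
  # all touched cells lie within 2000 m of the point; cells beyond stay unknown
  expect_equal(g$class[1, 1], 0L)
  touched <- which(g$class == 3L, arr.ind = TRUE)
  d <- vapply(seq_len(nrow(touched)), function(r)
    rect_geom_distance(cell_rect(spec, touched[r, 2], touched[r, 1]),
                       geom_point(spec$xmin + 5000, spec$ymin + 5000)), 0)
  expect_true(all(d <= 2000))
})

test_that("class boundaries at scores 12 and 7 follow the breeder scale", {
  spec <- small_grid()
  # Ciconia ciconia: B = 1, C = 3; 100 pairs -> D = 3, A = 12 -> medium
  obs <- obs_point(spec, 5, 5, species = "Ciconia ciconia",
                   group = "breeding_bird", count = 100, season = "breeding")
  g <- rasterize_sensitivity(obs, spec, the_catalog)
  expect_equal(g$class[6, 6], 2L)
  expect_equal(g$score[6, 6], 12)
  # 8 pairs -> D = 1, A = 4 -> low
  obs <- obs_point(spec, 5, 5, species = "Ciconia ciconia",
                   group = "breeding_bird", count = 8, season = "breeding")
  g <- rasterize_sensitivity(obs, spec, the_catalog)
  expect_equal(g$class[6, 6], 1L)
})

test_that("cells combine by maximum severity and order does not matter", {
  spec <- small_grid()
  high <- obs_point(spec, 5, 5, species = "Ciconia nigra",
                    group = "breeding_bird", count = 5, season = "breeding")
  med <- obs_point(spec, 5.2, 5.2, species = "Ciconia ciconia",
                   group = "breeding_bird", count = 100, season = "breeding")
  both <- feature_collection(c(high$geometry, med$geometry),
                             rbind(high$properties, med$properties))
  rev_ <- feature_collection(rev(both$geometry), both$properties[2:1, ])
  g1 <- rasterize_sensitivity(both, spec, the_catalog)
  g2 <- rasterize_sensitivity(rev_, spec, the_catalog)
  expect_equal(g1$class[6, 6], 3L)
  expect_identical(g1$class, g2$class)
  expect_identical(g1$score, g2$score)
})

test_that("protected sites and dumps force high regardless of scores", {
  spec <- small_grid()
  natura <- observations(
    list(geom_polygon(rbind(c(spec$xmin + 2000, spec$ymin + 2000),
                            c(spec$xmin + 4000, spec$ymin + 2000),
                            c(spec$xmin + 4000, spec$ymin + 4000),
                            c(spec$xmin + 2000, spec$ymin + 4000)))),
    kind = "natura2000_site")
  g <- rasterize_sensitivity(natura, spec, the_catalog)
  expect_equal(g$class[3, 3], 3L)
  expect_true(is.na(g$score[3, 3]))  # rule-forced, not score-derived

  dump <- observations(list(geom_point(spec$xmin + 8000, spec$ymin + 8000)),
                       kind = "dump_site")
  g <- rasterize_sensitivity(dump, spec, the_catalog)
  # 2000 m buffer around the dump reaches neighbouring cells
  expect_equal(g$class[9, 9], 3L)
  expect_equal(g$class[7, 9], 3L)
  expect_equal(g$class[1, 1], 0L)
})

test_that("bat cells are scored by per-cell species richness", {
  spec <- small_grid()
  two_bats <- observations(
    list(geom_point(spec$xmin + 5500, spec$ymin + 5500),
         geom_point(spec$xmin + 5600, spec$ymin + 5600)),
    species = c("Pipistrellus nathusii", "Nyctalus noctula"),
    group = "bat", count = 1, season = "breeding")
  g <- rasterize_sensitivity(two_bats, spec, the_catalog)
  # richness 2, max(B+C) = max(1+3, 2+3) = 5 -> A = 10 -> medium on migrant scale
  expect_equal(g$score[6, 6], 10)
  expect_equal(g$class[6, 6], 2L)
  one <- observations(list(geom_point(spec$xmin + 5500, spec$ymin + 5500)),
                      species = "Pipistrellus nathusii", group = "bat",
                      count = 1, season = "breeding")
  g1 <- rasterize_sensitivity(one, spec, the_catalog)
  expect_equal(g1$score[6, 6], 4)  # richness 1 * (1 + 3)
  expect_equal(g1$class[6, 6], 1L)
})

test_that("unsurveyed cells stay not_estimated; masked empty cells become low", {
  spec <- small_grid()
  expect_warning(g0 <- rasterize_sensitivity(
    feature_collection(list(), data.frame()), spec, the_catalog), "not_estimated")
  expect_true(all(g0$class == 0L))

  mask <- feature_collection(
    list(geom_polygon(rbind(c(spec$xmin, spec$ymin),
                            c(spec$xmin + 3000, spec$ymin),
                            c(spec$xmin + 3000, spec$ymin + 3000),
                            c(spec$xmin, spec$ymin + 3000)))),
    data.frame(kind = "survey_mask", stringsAsFactors = FALSE))
  expect_warning(g <- rasterize_sensitivity(
    feature_collection(list(), data.frame()), spec, the_catalog, mask = mask))
  expect_equal(g$class[2, 2], 1L)
  expect_equal(g$class[8, 8], 0L)
})

test_that("cells classified high through scores retain a score above threshold", {
  set.seed(9)
  sc <- generate_scenario(scenario_spec(seed = 9, n_municipalities = 3,
                                        extent_km = 30, n_species_obs = 25,
                                        n_natura = 0, n_dumps = 0,
                                        wind_hours = 50))
  spec <- grid_spec(sc$extent[1], sc$extent[2], 30, 30, 1000)
  g <- rasterize_sensitivity(sc$observations, spec, the_catalog)
  hi <- which(g$class == 3L)
  expect_true(length(hi) > 0)
  expect_true(all(g$score[hi] > 12))  # every high cell exceeds the laxest high cutoff
})

test_that("the exact signed-rank test reproduces enumerable cases", {
  # six identical positive differences: one-sided p = 1 / 2^6
  ht <- signed_rank_test(rep(3, 6), rep(1, 6), alternative = "greater")
  expect_equal(ht$p.value, 1 / 64)
  expect_equal(unname(ht$statistic), 21)  # all midranks 3.5 summed
  # two-sided doubles it
  expect_equal(signed_rank_test(rep(3, 6), rep(1, 6))$p.value, 1 / 32)
  # untied case agrees with the classical exact distribution
  x <- c(1.1, 2.3, 0.7, 4.2, 3.1, 2.9, 1.0)
  y <- c(0.8, 1.1, 1.8, 0.2, 1.0, 3.3, 0.1)
  ours <- signed_rank_test(x, y)
  ref <- stats::wilcox.test(x, y, paired = TRUE, exact = TRUE)
  expect_equal(ours$p.value, ref$p.value)
  expect_equal(unname(ours$statistic), unname(ref$statistic))
})

test_that("all-zero differences degenerate to p = 1 with a warning", {
  expect_warning(ht <- signed_rank_test(c(2, 2, 2), c(2, 2, 2)), "zero")
  expect_equal(ht$p.value, 1)
})

test_that("the large-sample branch matches the tie-corrected normal reference", {
  set.seed(21)
  x <- sample(1:4, 40, replace = TRUE)
  y <- sample(1:4, 40, replace = TRUE)
  keep <- x != y
  ours <- signed_rank_test(x, y, exact_max = 10)  # force the normal branch
  ref <- suppressWarnings(
    stats::wilcox.test(x[keep], y[keep], paired = TRUE, exact = FALSE, correct = FALSE))
  expect_equal(ours$p.value, ref$p.value, tolerance = 1e-10)
})

test_that("breeding and migration sensitivity of shared species differ significantly", {
  ht <- paired_breeder_migrant_test(the_catalog)
  expect_lt(ht$p.value, 0.05)
  pairs <- attr(ht, "pairs")
  expect_gte(nrow(pairs), 25)  # shared species resolved through synonyms
  expect_true("Ardea alba" %in% pairs$species)  # Egretta alba aligned
  expect_gte(ht$n_pairs, 6)
})
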