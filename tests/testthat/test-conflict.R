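test_that("the conflict matrix maps all nine priority/sensitivity pairs as published", {
  expect_equal(as.character(conflict_class("I", "high")), "high")
  expect_equal(as.character(conflict_class("III", "high")), "medium")
  expect_equal(as.character(conflict_class("III", "low")), "low")
  m <- expand.grid(priority = c("I", "II", "III"),
                   sensitivity = c("high", "medium", "low"),
                   stringsAsFactors = FALSE)
  got <- as.character(conflict_class(m$priority, m$sensitivity))
  expect_equal(got, c("high", "high", "medium",
                      "medium", "medium", "low",
                      "low", "low", "low"))
})

test_that("conflict severity is monotone in both inputs over all nine cells", {
  sev <- c(low = 1, medium = 2, high = 3)
  for (s in c("low", "medium", "high")) {
    by_prio <- sev[as.character(conflict_class(c("III", "II", "I"), rep(s, 3)))]
    expect_true(all(diff(by_prio) >= 0))
  }
  for (p in c("I", "II", "III")) {
    by_sens <- sev[as.character(conflict_class(rep(p, 3), c("low", "medium", "high")))]
    expect_true(all(diff(by_sens) >= 0))
  }
})

test_that("not_estimated sensitivity propagates and bad enums error", {
  expect_equal(as.character(conflict_class("I", "not_estimated")), "not_estimated")
  expect_error(conflict_class("IV", "high"), "priority")
  expect_error(conflict_class("I", "extreme"), "sensitivity")
})

test_that("combining a grid applies the municipality's priority per cell", {
  spec <- small_grid()
  obs <- obs_point(spec, 5, 5, species = "Ciconia nigra",
                   group = "breeding_bird", count = 5, season = "breeding")
  sens <- rasterize_sensitivity(obs, spec, the_catalog)
  for (p in c("I", "III")) {
    confl <- combine_conflict(sens, square_muni(spec, priority = p))
    expected <- if (p == "I") 3L else 2L  # III downgrades high to medium
    expect_equal(confl$class[6, 6], expected)
  }
  confl <- combine_conflict(sens, square_muni(spec, priority = "I"))
  expect_equal(which(confl$class == 0L), which(sens$class == 0L))
})

test_that("a fully high single municipality summarises to 100% high", {
  spec <- small_grid(4, 4)
  munis <- square_muni(spec, priority = "I")
  natura <- observations(list(munis$geometry[[1]]), kind = "natura2000_site")
  sens <- rasterize_sensitivity(natura, spec, the_catalog)
  confl <- combine_conflict(sens, munis)
  zs <- zonal_conflict_stats(confl, munis)
  expect_equal(zs$high_pct, 100)
  expect_equal(zs$medium_pct, 0)
  expect_equal(zs$low_pct, 0)
  expect_equal(zs$estimated_pct, 100)
})

test_that("border cells are apportioned by exact intersection area", {
  spec <- small_grid(4, 4)
  # municipality covering the left half of the grid, splitting no cell,
  # and a second one offset by half a cell
  half <- geom_polygon(rbind(c(spec$xmin, spec$ymin),
                             c(spec$xmin + 1500, spec$ymin),
                             c(spec$xmin + 1500, spec$ymin + 4000),
                             c(spec$xmin, spec$ymin + 4000)))
  munis <- feature_collection(list(half),
                              data.frame(municipality = "m", priority_class = "I",
                                         stringsAsFactors = FALSE))
  # site ends at 900 m so it touches only the first cell column (a site
  # reaching exactly 1000 m would touch the second column's boundary too)
  natura <- observations(
    list(geom_polygon(rbind(c(spec$xmin, spec$ymin), c(spec$xmin + 900, spec$ymin),
                            c(spec$xmin + 900, spec$ymin + 4000),
                            c(spec$xmin, spec$ymin + 4000)))),
    kind = "natura2000_site")
  sens <- rasterize_sensitivity(natura, spec, the_catalog)
  confl <- combine_conflict(sens, munis)
  zs <- zonal_conflict_stats(confl, munis)
  # first cell column is high (4 km2), second is not_estimated but only
  # half of it lies inside: estimated share = 4 / 6
  expect_equal(zs$high_pct, 400 / 6, tolerance = 1e-6)
  expect_equal(zs$estimated_pct, 400 / 6, tolerance = 1e-6)
})

test_that("zonal shares recomputed from the national table match the published summary", {
  ov <- zonal_overview(the_munis)
  expect_equal(ov$mean_pct[ov$conflict == "high"], 21.2, tolerance = 0.005)
  expect_equal(ov$mean_pct[ov$conflict == "medium"], 19.6, tolerance = 0.005)
  expect_equal(ov$mean_pct[ov$conflict == "low"], 22.7, tolerance = 0.005)
  expect_equal(c(ov$min_pct[ov$conflict == "high"], ov$max_pct[ov$conflict == "high"]),
               c(0, 67.4))
  expect_equal(c(ov$min_pct[ov$conflict == "medium"], ov$max_pct[ov$conflict == "medium"]),
               c(2.6, 64.3))
})

test_that("per-municipality class shares sum to the estimated share", {
  resid <- with(the_munis, high_pct + medium_pct + low_pct - estimated_pct)
  expect_true(all(abs(resid) <= 0.1 + 1e-9))
})

test_that("zero-area municipalities are rejected", {
  spec <- small_grid(2, 2)
  sliver <- geom_polygon(rbind(c(0, 0), c(1, 0), c(2, 0)))
  munis <- feature_collection(list(sliver),
                              data.frame(municipality = "z", priority_class = "I",
                                         stringsAsFactors = FALSE))
  g <- windconflict:::new_class_grid(spec, "conflict_grid")
  expect_error(zonal_conflict_stats(g, munis), "zero area")
})
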