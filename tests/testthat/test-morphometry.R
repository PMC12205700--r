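bowl3 <- function() terrain_grid(matrix(c(2, 2, 2, 2, 0, 2, 2, 2, 2), 3, 3),
                                 cell_size = 1)

test_that("a single submerged cell is one body with hand-counted measures", {
  g <- bowl3()
  mask <- inundate(g, 1)
  expect_equal(attr(mask, "n_bodies"), 1L)
  expect_equal(sum(mask > 0), 1L)
  m <- measure_waterbody(g, mask, 1)
  expect_equal(m$surface_area_m2, 1)
  expect_equal(m$volume_m3, 1)
  expect_equal(m$shoreline_length_m, 4)
})

test_that("water requires elevation strictly below the level", {
  g <- bowl3()
  expect_equal(attr(inundate(g, -5), "n_bodies"), 0L)  # below the minimum
  mask0 <- inundate(g, 0)                              # level == minimum
  m0 <- measure_waterbody(g, mask0, 0)
  expect_equal(m0$surface_area_m2, 0)
  expect_equal(m0$volume_m3, 0)
  expect_equal(m0$shoreline_length_m, 0)
  expect_equal(m0$n_bodies, 0L)
})

test_that("separated pits label as distinct bodies, matching a flood fill", {
  e <- matrix(5, 8, 8)
  e[2:3, 2:3] <- 1
  e[6:7, 5:7] <- 2
  g <- terrain_grid(e, 10)
  mask <- inundate(g, 4)
  expect_equal(attr(mask, "n_bodies"), 2L)
  oracle <- flood_fill_labels(!is.na(e) & e < 4)
  expect_equal(attr(oracle, "n_bodies"), 2L)
  expect_equal(mask > 0, oracle > 0)
  # identical partition up to label names
  expect_equal(length(unique(paste(mask[mask > 0], oracle[oracle > 0]))), 2L)
})

test_that("diagonal water cells connect (8-connectivity)", {
  e <- matrix(5, 4, 4)
  e[1, 1] <- 0
  e[2, 2] <- 0
  g <- terrain_grid(e, 1)
  expect_equal(attr(inundate(g, 1), "n_bodies"), 1L)
})

test_that("nodata cells are never water and generate shoreline", {
  e <- matrix(0, 3, 3)
  e[2, 2] <- NA
  g <- terrain_grid(e, 1)
  mask <- inundate(g, 1)
  expect_equal(sum(mask > 0), 8L)
  m <- measure_waterbody(g, mask, 1)
  # outer border 12 edges + 4 edges facing the nodata hole
  expect_equal(m$shoreline_length_m, 16)
})

test_that("grid measures equal brute-force per-cell oracles exactly", {
  set.seed(41)
  for (i in 1:3) {
    e <- matrix(runif(50 * 50, 0, 10), 50, 50)
    e[sample(2500, 30)] <- NA
    g <- terrain_grid(e, 12.5)
    level <- runif(1, 2, 8)
    mask <- inundate(g, level)
    m <- measure_waterbody(g, mask, level)
    o <- brute_morphometry(e, level, 12.5)
    expect_identical(m$surface_area_m2, o$area)
    expect_equal(m$volume_m3, o$volume, tolerance = 1e-12)
    expect_identical(m$shoreline_length_m, o$shoreline)
    oracle <- flood_fill_labels(!is.na(e) & e < level)
    expect_equal(attr(mask, "n_bodies"), attr(oracle, "n_bodies"))
  }
})

test_that("area and volume grow with the water level; dV/dh ~ area", {
  g <- generate_terrain(nx = 60, ny = 60, n_depressions = 2,
                        relief_amplitude = 0.3, seed = 3)
  levels <- seq(16.5, 20, by = 0.25)
  mm <- waterbody_morphometry(g, stats::setNames(levels, paste0("L", levels)))
  expect_true(all(diff(mm$surface_area_m2) >= 0))
  expect_true(all(diff(mm$volume_m3) >= 0))
  dh <- 0.01
  for (lv in c(18, 19)) {
    v1 <- measure_waterbody(g, inundate(g, lv), lv)$volume_m3
    v2 <- measure_waterbody(g, inundate(g, lv + dh), lv + dh)$volume_m3
    area <- measure_waterbody(g, inundate(g, lv), lv)$surface_area_m2
    cell_vol <- g$cell_size^2 * dh
    expect_lt(abs((v2 - v1) / dh - area) * dh, g$cell_size^2 * 1)
  }
})

test_that("a paraboloid depression holds its closed-form volume", {
  g <- generate_terrain(nx = 60, ny = 60, n_depressions = 1,
                        depth_range = c(3, 3), radius_range = c(150, 150),
                        relief_amplitude = 0, seed = 2)
  dep <- attr(g, "depressions")
  mask <- inundate(g, dep$rim_level)
  v <- measure_waterbody(g, mask, dep$rim_level)$volume_m3
  expect_equal(v, dep$analytic_volume_m3, tolerance = 0.05)
})

test_that("ESRI ASCII grids round-trip through write and read", {
  g <- generate_terrain(nx = 15, ny = 12, n_depressions = 0, seed = 1)
  g$elevations[3, 4] <- NA
  f <- withr::local_tempfile(fileext = ".asc")
  write_esri_ascii(g, f)
  back <- read_esri_ascii(f)
  expect_equal(back$elevations, g$elevations, ignore_attr = TRUE)
  expect_equal(back$cell_size, g$cell_size)
})

test_that("half-up rounding breaks ties away from zero", {
  expect_equal(round_half_up(c(0.05, 0.15, 0.25), 1), c(0.1, 0.2, 0.3))
  expect_equal(round_half_up(-0.05, 1), -0.1)
  expect_equal(round_half_up(76.845, 1), 76.8)  # not a tie at 1 decimal
})

test_that("percent-change table handles identity, zero and bad labels", {
  m <- data.frame(scenario = c("a", "b", "zero"),
                  surface_area_m2 = c(100, 100, 0))
  ct <- change_table(m, list(c("a", "b")))
  expect_equal(ct$change_pct, 0)
  ct0 <- change_table(m, list(c("zero", "a")))
  expect_true(is.na(ct0$change_pct))
  expect_error(change_table(m, list(c("a", "nope"))), "unknown scenario")
})

test_that("percent changes reproduce the observed floodplain table", {
  f <- system.file("extdata", "waterbody_morphometry_observed.csv",
                   package = "phytoind")
  obs <- read.csv(f)
  ct <- change_table(obs, list(c("spring_before", "spring_after"),
                               c("summer_before", "summer_after")))
  expect_equal(ct$change_pct[ct$measure == "shoreline_length_m"],
               c(76.8, 79.2))
  expect_equal(ct$change_pct[ct$measure == "surface_area_m2"],
               c(85.6, 88.4))
})
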