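test_that("community scores average species scores by presence or cover", {
  tab <- indicator_table(data.frame(
    species = c("a sp", "b sp", "c sp"), Hd = c(10, 12, 14)))
  rs <- releve_set(data.frame(plot_id = "p1",
                              species = c("a sp", "b sp", "c sp"),
                              cover = c(50, 25, 25)))
  expect_equal(as.numeric(community_score(rs, tab, "Hd", "presence")), 12)
  # (50*10 + 25*12 + 25*14) / 100
  expect_equal(as.numeric(community_score(rs, tab, "Hd", "cover")), 11.5)
  expect_error(community_score(rs, tab, "Zz"), "unknown scale_id")
})

test_that("plots with too few scored species get a missing score", {
  tab <- indicator_table(data.frame(species = c("a sp", "b sp"),
                                    Hd = c(10, 14)))
  rs <- releve_set(data.frame(plot_id = "p1", species = c("a sp", "b sp"),
                              cover = c(10, 10)))
  expect_warning(v <- community_score(rs, tab, "Hd", min_species = 3),
                 "below min_species")
  expect_true(is.na(v["p1"]))
  expect_equal(unname(attr(v, "n_species_used")["p1"]), 2L)
})

test_that("presence scores ignore covers; cover scores are scale-free", {
  tab <- indicator_table(data.frame(
    species = paste("sp", 1:4), Hd = c(3, 9, 15, 21)))
  base <- data.frame(plot_id = "p1", species = paste("sp", 1:4),
                     cover = c(5, 10, 20, 40))
  rs1 <- releve_set(base)
  rs2 <- releve_set(transform(base, cover = cover / 2))
  expect_equal(community_score(rs1, tab, "Hd", "presence"),
               community_score(rs2, tab, "Hd", "presence"))
  expect_equal(community_score(rs1, tab, "Hd", "cover"),
               community_score(rs2, tab, "Hd", "cover"))
})

test_that("regime conversions reproduce their anchor points", {
  expect_equal(convert_regime("Rc", 1), 1.88)          # ln 1 = 0
  expect_equal(suppressWarnings(convert_regime("Sl", 0)), 2)             # 2^1
  expect_equal(convert_regime("Hd", 10), 18.65 * exp(1.5), tolerance = 1e-12)
  expect_equal(convert_regime("Nt", 11),
               5 * 11^3.7 / (11^3.7 + 345), tolerance = 1e-12)
  expect_equal(convert_regime("Cr", 10), 3.83 * 10 - 38.17)
  expect_equal(suppressWarnings(convert_regime("Nt", 0)), 0)
  expect_equal(suppressWarnings(convert_regime("Om", 0)), -7)
  expect_equal(suppressWarnings(convert_regime("Kn", 0)), 41)
  expect_error(suppressWarnings(convert_regime("Rc", 0)), "domain error")
})

test_that("every conversion is monotone over its scale range", {
  for (sc in scale_definitions("didukh")$scale_id) {
    grid <- seq(1, n_gradations(sc), length.out = 500)
    v <- suppressWarnings(convert_regime(sc, grid))
    d <- diff(v)
    if (sc == "Ae") {
      expect_true(all(d < 0), label = paste(sc, "decreasing"))
    } else {
      expect_true(all(d > 0), label = paste(sc, "increasing"))
    }
  }
})

test_that("saturating conversions approach their asymptotes", {
  expect_equal(suppressWarnings(convert_regime("Ca", 1e6)), 14,
               tolerance = 1e-3)
  expect_equal(suppressWarnings(convert_regime("Nt", 1e6)), 5,
               tolerance = 1e-3)
})

test_that("plot_regimes appends one converted column per factor", {
  gen <- generate_releves(community_scenario(), seed = 3)
  tab <- generate_indicator_table(community_scenario(), seed = 3)
  reg <- suppressWarnings(plot_regimes(gen$releves, tab))
  expect_true(all(c("Hd", "W_mm", "fH", "omega", "Rc", "pH", "Sl", "S_salt",
                    "Ca", "CaO_MgO_pct", "Nt", "N_gkg", "Tm", "RB", "Om",
                    "Hum_mm", "Kn", "SKn", "Cr", "Temp_coldest_C", "Lc",
                    "log_lighting", "Ae", "P_porosity") %in% names(reg)))
  expect_equal(reg$W_mm, 18.65 * exp(0.15 * reg$Hd))
  expect_true(all(reg$W_mm > 0, na.rm = TRUE))
  expect_true(all(reg$N_gkg >= 0 & reg$N_gkg < 5, na.rm = TRUE))
  expect_true(all(reg$CaO_MgO_pct >= 0 & reg$CaO_MgO_pct < 14,
                  na.rm = TRUE))
})

test_that("moisture classes honor the 60/90/130/160 mm thresholds", {
  expect_equal(as.character(classify_moisture(c(0, 59.9, 60, 89.9, 90,
                                                129.9, 130, 159.9, 160,
                                                200))),
               c("very_low", "very_low", "low", "low", "satisfactory",
                 "satisfactory", "good", "good", "very_good", "very_good"))
  expect_error(classify_moisture(-1), "non-negative")
})
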