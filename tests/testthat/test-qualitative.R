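test_that("source level follows the pathogen/major classification", {
  expect_equal(source_level(pathogen = FALSE, major = TRUE), 2L)   # tea plantation
  expect_equal(source_level(pathogen = TRUE, major = FALSE), 3L)   # residential dev.
  expect_equal(source_level(pathogen = FALSE, major = FALSE), 1L)  # recreation
  expect_equal(source_level(pathogen = TRUE, major = TRUE), 4L)
  expect_equal(source_characterization("tea", FALSE, TRUE)$s_level, 2L)
})

test_that("proximity level maps buffer zones 4 down to 1", {
  expect_equal(proximity_level(c("0-50 m", "50-250 m", "250-1000 m", ">1000 m")),
               c(4L, 3L, 2L, 1L))
  expect_equal(proximity_level(zone_of(c(10, 1200))), c(4L, 1L))
  expect_error(proximity_level("5 km"), class = "swrisk_domain_error")
})

test_that("extent level bins percentages lower-inclusively with a top clamp", {
  expect_equal(extent_level(c(0.6, 3.1, 6.8, 3.8)), c(3L, 4L, 4L, 4L))
  expect_equal(extent_level(c(0.005, 0.01, 0.1, 1)), c(1L, 2L, 3L, 4L))
  expect_equal(extent_level(c(0, 50)), c(1L, 4L))  # above 10% clamps to 4
  expect_error(extent_level(-0.1), class = "swrisk_domain_error")
})

test_that("zone risk is the product S x P x E on levels 1-4", {
  expect_equal(zone_risk(2, 4, 3), 24L)
  expect_equal(zone_risk(2, 1, 4), 8L)
  expect_equal(zone_risk(1, 1, 1), 1L)
  expect_equal(zone_risk(4, 4, 4), 64L)
  expect_error(zone_risk(0, 1, 1), class = "swrisk_domain_error")
  expect_error(zone_risk(2, 5, 1), class = "swrisk_domain_error")
})

test_that("aggregation averages occupied zones", {
  areas <- c(71267, 374034, 810881, 450905)
  expect_equal(aggregate_risk(c(24, 24, 16, 8), areas), 18)
  expect_equal(aggregate_risk(12, 5), 12)
  # an empty outer zone is excluded from the mean by default
  expect_equal(aggregate_risk(c(24, 24, 16, 8), c(areas[1:3], 0)),
               mean(c(24, 24, 16)))
  expect_equal(aggregate_risk(c(24, 24, 16, 8), c(areas[1:3], 0),
                              include_empty_zones = TRUE), 18)
  expect_true(is.na(aggregate_risk(c(24, 24, 16, 8), rep(0, 4))))
})

test_that("risk bands partition the score scale", {
  expect_equal(as.character(risk_band(18)), "very_high")
  expect_equal(as.character(risk_band(8)), "medium")
  expect_equal(as.character(risk_band(c(6, 9, 16, 16.01))),
               c("low", "medium", "high", "very_high"))
  expect_error(risk_band(-1), class = "swrisk_domain_error")
  # no gaps, monotone over the whole product scale
  r <- seq(0, 64, by = 0.25)
  b <- risk_band(r)
  expect_false(anyNA(b))
  expect_true(all(diff(as.integer(b)) >= 0))
})

test_that("the A002 tea-growing assessment reproduces every published cell", {
  fx <- paper_fixtures()
  a <- assess_qualitative(fx$table7_zone_areas, fx$table7_source)

  expect_equal(a$s_level, 2L)
  expect_equal(round_half_up(a$zones$percent, 1), c(0.6, 3.1, 6.8, 3.8))
  expect_equal(a$zones$e_level, c(3L, 4L, 4L, 4L))
  expect_equal(a$zones$p_level, c(4L, 3L, 2L, 1L))
  expect_equal(a$zones$r, c(24L, 24L, 16L, 8L))
  expect_equal(a$aggregate_r, 18)
  expect_equal(as.character(a$band), "very_high")

  # halving S halves every product: aggregate 9, band medium
  s1 <- source_characterization("tea-growing", pathogen = FALSE, major = FALSE)
  a1 <- assess_qualitative(fx$table7_zone_areas, s1)
  expect_equal(a1$zones$r, c(12L, 12L, 8L, 4L))
  expect_equal(a1$aggregate_r, 9)
  expect_equal(as.character(a1$band), "medium")

  # absent activity: no-exposure flag, banded low
  empty <- zone_exposure("A002", "tea", rep(0, 4), 12012334)
  a0 <- assess_qualitative(empty, fx$table7_source)
  expect_true(a0$no_exposure)
  expect_equal(as.character(a0$band), "low")
  expect_true(is.na(a0$aggregate_r))
})

test_that("declared P/E overrides replace computed levels", {
  # scattered recreation: extent declared 1, proximity declared 4
  rec <- source_characterization("recreation", pathogen = FALSE, major = FALSE,
                                 p_override = 4, e_override = 1)
  ze <- zone_exposure("B001", "recreation", c(100, 0, 0, 0), 1e6)
  a <- assess_qualitative(ze, rec)
  expect_equal(unique(a$zones$r), 4L)  # 1 x 4 x 1 in every zone
  expect_equal(a$aggregate_r, 4)
  expect_equal(as.character(a$band), "low")
  expect_error(source_characterization("x", FALSE, FALSE, p_override = 5),
               class = "swrisk_domain_error")
})

test_that("risk is monotone in each factor and aggregates stay bracketed", {
  for (s in 1:3) for (p in 1:3) for (e in 1:3) {
    expect_lt(zone_risk(s, p, e), zone_risk(s + 1, p, e))
    expect_lt(zone_risk(s, p, e), zone_risk(s, p + 1, e))
    expect_lt(zone_risk(s, p, e), zone_risk(s, p, e + 1))
  }
  set.seed(44)
  for (i in 1:25) {
    rs <- sample(1:64, 4, replace = TRUE)
    areas <- runif(4, 0, 100) * rbinom(4, 1, 0.8)
    agg <- aggregate_risk(rs, areas)
    if (!is.na(agg)) {
      expect_gte(agg, min(rs[areas > 0]))
      expect_lte(agg, max(rs[areas > 0]))
    }
  }
})

test_that("multiple sources roll up as the mean of their aggregate scores", {
  fx <- paper_fixtures()
  tea <- assess_qualitative(fx$table7_zone_areas, fx$table7_source)
  rec <- assess_qualitative(
    zone_exposure("A002", "recreation", c(1000, 0, 0, 0), 12012334),
    source_characterization("recreation", FALSE, FALSE,
                            p_override = 4, e_override = 1))
  ru <- rollup_sources(list(tea, rec))
  expect_equal(ru$mean_r, mean(c(18, 4)))
  expect_equal(ru$n_sources, 2L)
  other <- rec; other$subwatershed <- "B001"
  expect_error(rollup_sources(list(tea, other)), class = "swrisk_domain_error")

  tab <- qual_risk_table(list(rec, tea))
  expect_equal(tab$source, c("tea-growing", "recreation"))  # sorted by score
})
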