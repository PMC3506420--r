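test_that("buffer zone binning is upper-inclusive", {
  expect_equal(as.character(zone_of(0)), "0-50 m")
  expect_equal(as.character(zone_of(50)), "0-50 m")
  expect_equal(as.character(zone_of(50.001)), "50-250 m")
  expect_equal(as.character(zone_of(250)), "50-250 m")
  expect_equal(as.character(zone_of(1000)), "250-1000 m")
  expect_equal(as.character(zone_of(1200)), ">1000 m")
  expect_error(zone_of(-1), class = "swrisk_domain_error")
})

test_that("distance to stream is cell-centre Euclidean", {
  sm <- matrix(FALSE, 5, 5); sm[3, 3] <- TRUE
  g <- watershed_grid(matrix(1L, 5, 5), sm, cell_size = 10)
  d <- distance_to_stream(g)
  expect_equal(d[3, 3], 0)
  expect_equal(d[3, 4], 10)            # 4-neighbour
  expect_equal(d[2, 2], sqrt(2) * 10)  # diagonal
  expect_equal(d[1, 1], sqrt(8) * 10)

  g0 <- watershed_grid(matrix(1L, 5, 5), matrix(FALSE, 5, 5), cell_size = 10)
  expect_error(distance_to_stream(g0), class = "swrisk_domain_error")
})

test_that("distance transform equals the exhaustive oracle on random grids", {
  set.seed(31)
  for (i in 1:10) {
    g <- random_stream_grid(40, 40, 25)
    expect_equal(distance_to_stream(g), brute_force_distance(g$stream, 10),
                 tolerance = 1e-9)
  }
})

test_that("adding stream cells never increases any distance", {
  set.seed(17)
  for (i in 1:5) {
    g1 <- random_stream_grid(30, 30, 10)
    sm2 <- g1$stream
    sm2[sample(which(!sm2), 5)] <- TRUE
    g2 <- watershed_grid(matrix(1L, 30, 30), sm2, cell_size = 10)
    expect_true(all(distance_to_stream(g2) <= distance_to_stream(g1) + 1e-12))
  }
})

test_that("zone areas of a rectangle beside a straight stream match the analytic bands", {
  # vertical stream in column 1; an activity rectangle of 30 x 10 cells
  # (300 m x 100 m at 10 m cells) whose nearest column is 20 m away
  n <- 40
  lu <- matrix(1L, n, n)
  lu[1:10, 3:32] <- 2L  # columns 3..32 lie 20..310 m from the stream
  sm <- matrix(FALSE, n, n); sm[, 1] <- TRUE
  g <- watershed_grid(lu, sm, cell_size = 10)
  ze <- tabulate_zone_areas(g, 2L)
  # cell-centre distances 20,30,...,310 m: 4 columns in [0,50], 20 in
  # (50,250], 6 in (250,1000]; x 10 rows x 100 m^2 per cell
  expect_equal(ze$activity_area_m2, c(4, 20, 6, 0) * 10 * 100)
  expect_equal(sum(ze$activity_area_m2), 300 * 100)
  expect_equal(ze$subwatershed_area_m2[1], n * n * 100)
})

test_that("zone tabulation conserves area and handles absent classes", {
  set.seed(8)
  g <- gen_watershed(30, 40, 20, stream = rbind(c(1, 20), c(30, 20)),
                     patches = list(list(class = 2, rows = c(5, 14),
                                         cols = c(25, 34))),
                     sub_splits = 21)
  ze <- tabulate_zone_areas(g, 2L)
  # conservation within each sub-watershed: zones sum to the class total
  for (sw in unique(ze$subwatershed)) {
    in_sw <- g$subwatershed == sw
    expect_equal(sum(ze$activity_area_m2[ze$subwatershed == sw]),
                 sum(g$landuse[in_sw] == 2L) * 400)
    expect_equal(ze$subwatershed_area_m2[ze$subwatershed == sw][1],
                 sum(in_sw) * 400)
  }
  # class absent everywhere: four zero rows per sub-watershed, no error
  ze9 <- tabulate_zone_areas(g, 9L)
  expect_equal(nrow(ze9), 8)
  expect_true(all(ze9$activity_area_m2 == 0))
  # class covering a whole sub-watershed: zones sum to its area
  lu <- matrix(3L, 10, 10)
  sm <- matrix(FALSE, 10, 10); sm[5, 5] <- TRUE
  g3 <- watershed_grid(lu, sm, cell_size = 10)
  ze3 <- tabulate_zone_areas(g3, 3L)
  expect_equal(sum(ze3$activity_area_m2), ze3$subwatershed_area_m2[1])
})

test_that("ESRI ASCII grids round-trip and validate geometry", {
  set.seed(12)
  m <- matrix(sample(0:5, 400, replace = TRUE), 20, 20)
  attr(m, "xllcorner") <- 100; attr(m, "yllcorner") <- 200
  attr(m, "cellsize") <- 25
  path <- withr::local_tempfile(fileext = ".asc")
  write_ascii_grid(m, path)
  back <- read_ascii_grid(path)
  expect_equal(matrix(as.numeric(back), 20, 20),
               matrix(as.numeric(m), 20, 20))
  expect_equal(attr(back, "cellsize"), 25)
  expect_equal(attr(back, "xllcorner"), 100)

  # NODATA cells become NA and are excluded from tabulations
  m2 <- m; m2[1, 1:5] <- NA
  write_ascii_grid(m2, path)
  back2 <- read_ascii_grid(path)
  expect_true(all(is.na(back2[1, 1:5])))
  sm <- matrix(FALSE, 20, 20); sm[10, 10] <- TRUE
  g <- watershed_grid(back2, sm, cell_size = 25)
  ze <- tabulate_zone_areas(g, 1L)
  expect_equal(ze$subwatershed_area_m2[1], (400 - 5) * 625)

  # layers with mismatched geometry are refused
  s3 <- matrix(m > 2, 20, 20)
  attr(s3, "cellsize") <- 30; attr(s3, "xllcorner") <- 100
  attr(s3, "yllcorner") <- 200
  expect_error(watershed_grid(m, s3), class = "swrisk_geometry_error")
  expect_error(watershed_grid(m, matrix(FALSE, 10, 10)),
               class = "swrisk_geometry_error")
})

test_that("the published A002 zone areas sum to the printed tea-growing total", {
  fx <- paper_fixtures()
  expect_equal(sum(fx$table7_zone_areas$activity_area_m2), 1707087)
  expect_equal(fx$table7_zone_areas$subwatershed_area_m2[1], 12012334)
})
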