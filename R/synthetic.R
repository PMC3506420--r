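#' Generate a synthetic monthly monitoring series
#'
#' Emulates a routine source-water monitoring programme: one sample per
#' station per parameter per month. Concentrations are lognormal (strictly
#' positive and right-skewed, consistent with monitoring summaries whose
#' means sit far below their maxima) with an optional multiplicative seasonal
#' modulation `1 + amplitude * sin(2*pi*(month - phase)/12)`, which peaks
#' three months after `phase` (the default `phase = 3`, March, peaks in
#' June, giving the summer concentration rise seen in suspended solids).
#' Values below the detection limit become non-detects (value withheld,
#' limit recorded). Output is bit-reproducible for a given seed.
#'
#' @param stations character vector of station ids.
#' @param parameters named list; each element a list with `meanlog`, `sdlog`
#'   (lognormal parameters on the natural-log scale), and optionally
#'   `detection_limit` (default 0 = everything detected),
#'   `seasonal_amplitude` (fraction, default 0) and `phase` (month 1-12,
#'   default 3).
#' @param n_months number of consecutive months.
#' @param start first sampling date.
#' @param seed integer seed; the generator is deterministic given it.
#' @return a `monitoring_records` data frame (see [read_monitoring_csv()]).
#' @export
#' @examples
#' rec <- gen_monitoring("S1", list(TP = list(meanlog = -3.5, sdlog = 0.8,
#'                                            detection_limit = 0.013)),
#'                       n_months = 36, seed = 42)
gen_monitoring <- function(stations, parameters, n_months,
                           start = as.Date("2008-01-15"), seed = 1) {
  stopifnot(is.list(parameters), !is.null(names(parameters)), n_months >= 1)
  dates <- seq(start, by = "month", length.out = n_months)
  months <- as.integer(format(dates, "%m"))
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  rows <- list()
  for (st in stations) {
    for (p in names(parameters)) {
      spec <- parameters[[p]]
      stopifnot(spec$sdlog > 0)
      amp <- spec$seasonal_amplitude %||% 0
      phase <- spec$phase %||% 3
      dl <- spec$detection_limit %||% 0
      stopifnot(amp >= 0, dl >= 0)
      conc <- stats::rlnorm(n_months, spec$meanlog, spec$sdlog) *
        (1 + amp * sin(2 * pi * (months - phase) / 12))
      detected <- conc >= dl
      rows[[length(rows) + 1L]] <- data.frame(
        station = st, date = dates, parameter = normalize_parameter(p),
        value = ifelse(detected, conc, NA_real_), detected = detected,
        detection_limit = if (dl > 0) dl else NA_real_)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("monitoring_records", "data.frame")
  out
}

#' Generate a synthetic watershed grid
#'
#' Builds the raster inputs of the buffer-zone analysis with a controlled
#' layout: a background land-use class everywhere (forest, say), a stream
#' rasterized from a polyline, rectangular activity patches (later patches
#' overwrite earlier ones), and sub-watersheds as vertical column bands.
#'
#' @param n_rows,n_cols grid dimensions.
#' @param cell_size cell edge length in metres.
#' @param stream two-column matrix of (row, col) polyline vertices; every
#'   cell touched by a segment becomes a stream cell.
#' @param patches list of patches, each `list(class, rows = c(r1, r2),
#'   cols = c(c1, c2))`.
#' @param background background class code (default 1).
#' @param sub_splits increasing column indices at which new sub-watersheds
#'   start; `NULL` = a single sub-watershed.
#' @return a `watershed_grid`.
#' @export
gen_watershed <- function(n_rows, n_cols, cell_size, stream, patches = list(),
                          background = 1L, sub_splits = NULL) {
  landuse <- matrix(as.integer(background), n_rows, n_cols)
  for (p in patches) {
    if (min(p$rows) < 1 || max(p$rows) > n_rows ||
        min(p$cols) < 1 || max(p$cols) > n_cols)
      stop_swrisk("patch outside grid bounds", "swrisk_domain_error")
    landuse[p$rows[1]:p$rows[2], p$cols[1]:p$cols[2]] <- as.integer(p$class)
  }
  sm <- matrix(FALSE, n_rows, n_cols)
  stream <- as.matrix(stream)
  if (nrow(stream) == 1) {
    sm[stream[1, 1], stream[1, 2]] <- TRUE
  } else {
    for (k in seq_len(nrow(stream) - 1)) {
      a <- stream[k, ]; b <- stream[k + 1, ]
      n <- max(abs(b - a)) * 2 + 1   # dense sampling covers every crossed cell
      rr <- round(seq(a[1], b[1], length.out = n))
      cc <- round(seq(a[2], b[2], length.out = n))
      sm[cbind(rr, cc)] <- TRUE
    }
  }
  sw <- matrix(1L, n_rows, n_cols)
  if (!is.null(sub_splits)) {
    for (s in sort(sub_splits)) sw[, s:n_cols] <- sw[, s:n_cols] + 1L
  }
  watershed_grid(landuse, sm, sw, cell_size = cell_size)
}

#' Published-table fixtures
#'
#' The printed inputs of the study's worked examples, verbatim, as ready-made
#' pipeline inputs: land-use areas per basin, the default standard registry,
#' sub-watershed attributes, the three intake stations' monitoring summaries
#' with their printed hazard quotients, and the tea-growing zone areas of
#' sub-watershed A002. Nothing is interpolated from figures.
#'
#' @return list with elements `table1_landuse`, `table2_standards`,
#'   `table4_attributes`, `table5_summaries`, `table7_zone_areas` (a
#'   `zone_exposure`) and `table7_source` (the tea-growing
#'   `source_characterization`, S = 2).
#' @export
paper_fixtures <- function() {
  landuse <- data.frame(
    basin = rep(c("Bei-Shih", "Nan-Shih", "Sin-Dian"), each = 5),
    class = rep(c("Built-up area", "Forest", "Farmland",
                  "Non-irrigated farmland", "Water area"), 3),
    area_km2 = c(4.38, 277.14, 18.84, 4.24, 12.39,
                 1.75, 328.65, 1.44, 1.02, 2.58,
                 4.13, 33.66, 5.77, 0.12, 1.46),
    printed_pct = c(1.4, 87.5, 5.9, 1.3, 3.9,
                    0.5, 98.0, 0.4, 0.3, 0.8,
                    9.1, 74.6, 12.8, 0.3, 3.2))
  landuse$printed_total_pct <- c(1.5, 91.7, 3.7, 0.8, 2.3)[match(
    landuse$class, unique(landuse$class))]

  t5 <- function(station, parameter, n, n_det, mean, minimum, maximum,
                 hq_avg, hq_max) {
    data.frame(station = station, parameter = parameter, n = n,
               n_detected = n_det, mean = mean, minimum = minimum,
               maximum = maximum, policy = "as_published", no_data = FALSE,
               printed_hq_avg = hq_avg, printed_hq_max = hq_max)
  }
  summaries <- rbind(
    t5("A008", "coliforms", 32, 29, 2741.0, 30, 58000, 54.82, 1160.00),
    t5("A008", "TP",        32, 21, 0.028, 0.013, 0.093, 1.42, 4.65),
    t5("A008", "NH3-N",     32, 20, 0.048, 0.01, 0.2, 0.48, 2.00),
    t5("A008", "SS",        32, 29, 5.45, 1.3, 36.1, 0.22, 1.44),
    t5("A008", "BOD",       32, 32, 1.06, 0.3, 3.8, 1.06, 3.80),
    t5("A008", "DO",        32, 32, 7.49, 6.5, 8.8, NA, NA),
    t5("A008", "pH",        32, 32, 7.51, 6.7, 8.5, NA, NA),
    t5("B006", "coliforms", 32, 32, 3048.0, 95, 37000, 60.96, 740.00),
    t5("B006", "TP",        32, 29, 0.049, 0.015, 0.287, 2.45, 14.35),
    t5("B006", "NH3-N",     32, 22, 0.035, 0.01, 0.17, 0.35, 1.70),
    t5("B006", "SS",        32, 29, 30.02, 1.1, 345, 1.20, 13.80),
    t5("B006", "BOD",       32, 32, 0.94, 0.4, 3.3, 0.94, 3.30),
    t5("B006", "DO",        32, 32, 7.78, 6.6, 8.6, NA, NA),
    t5("B006", "pH",        32, 32, 8.11, 7, 9, NA, NA),
    t5("C003", "coliforms", 36, 36, 1111.1, 25, 7500, 22.22, 150.00),
    t5("C003", "TP",        35, 29, 0.093, 0.015, 0.58, 4.65, 29.00),
    t5("C003", "NH3-N",     36, 26, 0.135, 0.01, 1.7, 1.35, 17.00),
    t5("C003", "SS",        36, 35, 15.66, 0.6, 126, 0.63, 5.04),
    t5("C003", "BOD",       36, 36, 1.04, 0.3, 6.9, 1.04, 6.90),
    t5("C003", "DO",        36, 36, 7.85, 6.3, 10.2, NA, NA),
    t5("C003", "pH",        36, 36, 7.54, 6.5, 8.7, NA, NA))
  class(summaries) <- c("wq_summary", "data.frame")

  attrs <- data.frame(
    basin = c(rep("Bei-Shih", 12), rep("Nan-Shih", 6), rep("Sin-Dian", 4)),
    subwatershed = c(sprintf("A%03d", 1:12), sprintf("B%03d", 1:6),
                     sprintf("C%03d", 1:4)),
    avg_slope_deg = c(21.66, 22.41, 25.45, 25.85, 23.31, 23.58, 25.32, 26.71,
                      15.46, 23.34, 25.35, 21.99, 30.13, 30.22, 28.62, 24.65,
                      26.56, 28.13, 26.14, 24.26, 22.06, 19.72),
    total_area_km2 = c(42.89, 12.01, 36.87, 43.21, 1.13, 24.96, 2.15, 1.02,
                       11.97, 21.12, 26.37, 3.04, 163.99, 66.36, 83.78, 0.42,
                       2.69, 18.21, 19.66, 90.27, 13.68, 11.81),
    tea_area_km2 = c(0.789, 1.707, 0.109, 1.407, 0.145, 1.518, 0.162, 0.010,
                     0.170, 0.064, 2.573, 0.238, 0.014, 0.184, 0.005, 0.001,
                     0.010, 0.115, 0.174, 1.621, 0.411, 0.830),
    tea_pct = c(1.84, 14.21, 0.30, 3.26, 12.82, 6.08, 7.55, 1.01, 1.42, 0.30,
                9.76, 7.83, 0.01, 0.28, 0.01, 0.29, 0.38, 0.63, 0.89, 1.80,
                3.00, 7.03),
    builtup_area_km2 = c(0.53, 0.64, 0.2, 0.43, 0.03, 0.24, 0.06, 0, 0.08,
                         0.04, 0.6, 0.14, 0.23, 0.92, 0.19, 0.03, 0.08, 0.3,
                         0.27, 1.39, 2.44, 1.42),
    builtup_pct = c(1.24, 5.33, 0.54, 1.00, 2.65, 0.96, 2.79, 0.00, 0.67,
                    0.19, 2.28, 4.61, 0.14, 1.39, 0.23, 7.14, 2.97, 1.65,
                    1.37, 1.54, 17.84, 12.02),
    pop_density = c(19, 123, 8, 43, 301, 33, 34, 11, 13, 12, 41, 25, 3, 31,
                    14, 117, 99, 110, 59, 55, 249, 618))

  list(
    table1_landuse = landuse,
    table2_standards = default_standards(),
    table4_attributes = attrs,
    table5_summaries = summaries,
    table7_zone_areas = zone_exposure("A002", "tea-growing",
                                      c(71267, 374034, 810881, 450905),
                                      12012334),
    table7_source = source_characterization("tea-growing",
                                            pathogen = FALSE, major = TRUE))
}
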