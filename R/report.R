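#' Rank parameters by hazard quotient
#'
#' Orders parameters by their worst (max over stations) average-based hazard
#' quotient — the chronic screen — with the maximum-based HQ and then the
#' parameter name as tie-breaks. Range/lower-limit parameters carry no HQ and
#' are listed separately by the report writer, not ranked.
#'
#' @param hq an `hq_table` from [hq_screen()].
#' @return data frame `parameter`, `hq_avg` (max over stations), `hq_max`
#'   (max over stations), sorted descending.
#' @export
rank_pollutants <- function(hq) {
  h <- hq[!is.na(hq$hq_avg), ]
  if (nrow(h) == 0)
    stop_swrisk("no hazard quotients to rank", "swrisk_domain_error")
  agg <- do.call(rbind, lapply(split(h, h$parameter), function(g) {
    data.frame(parameter = g$parameter[1], hq_avg = max(g$hq_avg),
               hq_max = max(g$hq_max))
  }))
  agg <- agg[order(-agg$hq_avg, -agg$hq_max, agg$parameter), ]
  rownames(agg) <- NULL
  agg
}

#' Land-use percentage table
#'
#' Per-basin percentages of each land-use class, plus a grand-total column
#' recomputed from the summed areas. Percentages are rounded half-up to one
#' decimal, the convention of printed land-use tables.
#'
#' @param areas data frame with columns `basin`, `class`, `area_km2`
#'   (areas \eqn{\ge 0}; each basin total must be > 0).
#' @return data frame `basin`, `class`, `area_km2`, `percent`; the synthetic
#'   basin `"Total"` holds the summed areas and their percentages.
#' @export
#' @examples
#' landuse_percentages(data.frame(basin = "B", class = c("forest", "water"),
#'                                area_km2 = c(639.45, 58.12)))
landuse_percentages <- function(areas) {
  stopifnot(all(c("basin", "class", "area_km2") %in% names(areas)))
  if (any(areas$area_km2 < 0))
    stop_swrisk("areas must be non-negative", "swrisk_domain_error")
  totals <- lapply(split(areas$area_km2, areas$class), sum)
  grand <- data.frame(basin = "Total", class = names(totals),
                      area_km2 = unlist(totals, use.names = FALSE))
  all_rows <- rbind(areas[c("basin", "class", "area_km2")], grand)
  out <- do.call(rbind, lapply(split(all_rows, all_rows$basin), function(g) {
    tot <- sum(g$area_km2)
    if (tot <= 0) stop_swrisk("basin total area must be positive",
                              "swrisk_domain_error")
    g$percent <- round_half_up(g$area_km2 / tot * 100, 1)
    g
  }))
  rownames(out) <- NULL
  out
}

#' Assemble an integrated risk report
#'
#' Joins the quantitative screen, the qualitative assessments and the
#' land-use tabulation into one object holding the pollutant ranking
#' and the sub-watershed ranking by aggregate qualitative score.
#'
#' @param hq an `hq_table` (or `NULL`).
#' @param assessments list of `qual_risk` objects (or `NULL`).
#' @param landuse_areas data frame for [landuse_percentages()] (or `NULL`).
#' @return a `swrisk_report` list: `hq`, `pollutant_ranking`,
#'   `subwatershed_ranking`, `landuse`.
#' @export
build_report <- function(hq = NULL, assessments = NULL, landuse_areas = NULL) {
  structure(list(
    hq = hq,
    pollutant_ranking = if (!is.null(hq)) rank_pollutants(hq),
    subwatershed_ranking = if (!is.null(assessments) && length(assessments) > 0)
      qual_risk_table(assessments),
    landuse = if (!is.null(landuse_areas)) landuse_percentages(landuse_areas)
  ), class = "swrisk_report")
}

#' @export
print.swrisk_report <- function(x, ...) {
  cat("Integrated source-water risk report\n")
  if (!is.null(x$pollutant_ranking)) {
    cat("\nParameters of concern (by max-over-stations HQ on the average):\n")
    r <- x$pollutant_ranking
    r$hq_avg <- round_half_up(r$hq_avg, 2); r$hq_max <- round_half_up(r$hq_max, 2)
    print.data.frame(r, row.names = FALSE)
  }
  if (!is.null(x$subwatershed_ranking)) {
    cat("\nSub-watershed qualitative ranking:\n")
    print.data.frame(x$subwatershed_ranking, row.names = FALSE)
  }
  invisible(x)
}

#' Write report CSVs
#'
#' Emits `hq_table.csv` (screening-table layout, HQs rounded to two
#' decimals, "-" for range parameters), `ranking.csv`, `qualitative.csv`
#' (per-zone levels and products plus aggregate and band; header-only when
#' no assessments were supplied) and `landuse.csv`. Output is deterministic:
#' identical inputs give identical bytes.
#'
#' @param report a `swrisk_report`.
#' @param out_dir output directory (created if missing).
#' @param assessments optional list of `qual_risk` objects for the per-zone
#'   detail in `qualitative.csv`.
#' @return invisibly, the paths written.
#' @export
render_reports <- function(report, out_dir, assessments = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  w <- function(df, file) {
    p <- file.path(out_dir, file)
    utils::write.csv(df, p, row.names = FALSE, na = "")
    paths[[length(paths) + 1L]] <<- p
  }
  if (!is.null(report$hq)) w(format_hq_table(report$hq), "hq_table.csv")
  if (!is.null(report$pollutant_ranking)) {
    r <- report$pollutant_ranking
    r$hq_avg <- round_half_up(r$hq_avg, 2)
    r$hq_max <- round_half_up(r$hq_max, 2)
    w(r, "ranking.csv")
  }
  qual <- if (!is.null(assessments) && length(assessments) > 0) {
    do.call(rbind, lapply(assessments, function(a) {
      z <- a$zones
      data.frame(subwatershed = a$subwatershed, source = a$source$name,
                 s_level = a$s_level, zone = z$zone,
                 activity_area_m2 = z$activity_area_m2,
                 percent = round_half_up(z$percent, 1),
                 e_level = z$e_level, p_level = z$p_level, r = z$r,
                 aggregate_r = a$aggregate_r, band = as.character(a$band))
    }))
  } else {
    data.frame(subwatershed = character(), source = character(),
               s_level = integer(), zone = character(),
               activity_area_m2 = numeric(), percent = numeric(),
               e_level = integer(), p_level = integer(), r = integer(),
               aggregate_r = numeric(), band = character())
  }
  w(qual, "qualitative.csv")
  if (!is.null(report$landuse)) w(report$landuse, "landuse.csv")
  invisible(unlist(paths))
}
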