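#' Characterize a pollution source
#'
#' A source is scored on whether it can contribute human pathogens and
#' whether it is a major or minor source; the two booleans fix the source
#' level S: pathogen+major = 4, pathogen+minor = 3, non-pathogen+major = 2,
#' non-pathogen+minor = 1. For sources whose footprint is not meaningfully
#' areal (e.g. scattered recreation spots along a creek) declared proximity
#' and extent levels may be supplied; they override the computed P and E in
#' [assess_qualitative()].
#'
#' @param name free-text source name.
#' @param pathogen can the source contribute human pathogens?
#' @param major is it a major source?
#' @param p_override,e_override optional declared levels (1-4) replacing the
#'   computed proximity/extent levels in every zone.
#' @return a `source_characterization` list with the derived `s_level`.
#' @export
#' @examples
#' source_characterization("tea plantation", pathogen = FALSE, major = TRUE)$s_level  # 2
source_characterization <- function(name, pathogen, major,
                                    p_override = NULL, e_override = NULL) {
  stopifnot(is.logical(pathogen), is.logical(major))
  for (ov in c(p_override, e_override))
    if (!is.null(ov) && !(ov %in% 1:4))
      stop_swrisk("level overrides must be integers 1-4", "swrisk_domain_error")
  structure(list(name = name, pathogen = pathogen, major = major,
                 s_level = source_level(pathogen, major),
                 p_override = p_override, e_override = e_override),
            class = "source_characterization")
}

#' Source-characteristic level S
#'
#' @param pathogen,major logical vectors (recycled).
#' @return integer level(s) 1-4.
#' @export
#' @examples
#' source_level(pathogen = TRUE, major = FALSE)  # 3: minor pathogen source
source_level <- function(pathogen, major) {
  1L + 2L * as.integer(pathogen) + 1L * as.integer(major)
}

#' Proximity-to-water level P
#'
#' Maps the four buffer zones to levels 4 (0-50 m, riparian) down to
#' 1 (beyond 1000 m).
#'
#' @param zone zone label(s) as produced by [zone_of()] (character or factor).
#' @return integer level(s) 1-4.
#' @export
proximity_level <- function(zone) {
  idx <- match(as.character(zone), .zone_labels)
  if (anyNA(idx))
    stop_swrisk(paste("unknown zone label; expected one of:",
                      paste(.zone_labels, collapse = ", ")),
                "swrisk_domain_error")
  5L - idx
}

#' Spatial-extent level E
#'
#' Classifies the percentage of a sub-watershed occupied by an activity:
#' below 0.01% is level 1, 0.01-0.1% level 2, 0.1-1% level 3, and 1% or more
#' level 4 (the nominal top class is 1-10%, with larger extents clamped to 4).
#' Bins are lower-inclusive; the published bin labels overlap at their shared
#' endpoints, so a convention had to be fixed, and lower-inclusive reproduces
#' all published assignments.
#'
#' @param percent percentage(s) of the sub-watershed area, \eqn{\ge 0}.
#' @return integer level(s) 1-4.
#' @export
#' @examples
#' extent_level(c(0.6, 3.1))  # 3, 4
extent_level <- function(percent) {
  if (any(percent < 0, na.rm = TRUE))
    stop_swrisk("percent must be non-negative", "swrisk_domain_error")
  findInterval(percent, c(0, 0.01, 0.1, 1))
}

#' Per-zone risk product R = S x P x E
#'
#' @param s,p,e integer levels 1-4 (recycled).
#' @return integer product(s) in \[1, 64\].
#' @export
zone_risk <- function(s, p, e) {
  for (v in list(s, p, e))
    if (any(!(v %in% 1:4)))
      stop_swrisk("S, P and E levels must be integers 1-4", "swrisk_domain_error")
  as.integer(s) * as.integer(p) * as.integer(e)
}

#' Aggregate per-zone risk products
#'
#' Unweighted arithmetic mean of R over the zones where the activity is
#' actually present (`zone_areas > 0`). Zones without the activity carry a
#' vacuous R and are excluded by default; `include_empty_zones = TRUE`
#' restores a strict four-zone average.
#'
#' @param zone_risks integer vector of per-zone products.
#' @param zone_areas activity areas per zone (same length).
#' @param include_empty_zones average over all zones regardless of area?
#' @return the mean R, or `NA` (no-exposure) when every zone area is 0.
#' @export
#' @examples
#' aggregate_risk(c(24, 24, 16, 8), c(71267, 374034, 810881, 450905))  # 18
aggregate_risk <- function(zone_risks, zone_areas, include_empty_zones = FALSE) {
  stopifnot(length(zone_risks) == length(zone_areas))
  keep <- if (include_empty_zones) rep(TRUE, length(zone_areas)) else zone_areas > 0
  if (!any(keep)) return(NA_real_)
  mean(zone_risks[keep])
}

#' Risk band of an aggregate score
#'
#' Four bands on the product scale: low (\eqn{\le 6}), medium (\eqn{\le 9}),
#' high (\eqn{\le 16}), very high (> 16). The scale is comparative — it
#' orders issues by risk potential, it does not measure absolute risk.
#'
#' @param r aggregate risk score(s), \eqn{\ge 0}.
#' @return ordered factor with levels `low < medium < high < very_high`.
#' @export
#' @examples
#' risk_band(c(6, 8, 16, 18))
risk_band <- function(r) {
  if (any(r < 0, na.rm = TRUE))
    stop_swrisk("risk score must be non-negative", "swrisk_domain_error")
  cut(r, breaks = c(-Inf, 6, 9, 16, Inf),
      labels = c("low", "medium", "high", "very_high"), ordered_result = TRUE)
}

#' Qualitative buffer-zone risk assessment of one source in one sub-watershed
#'
#' For each buffer zone: percent occupied = activity area / sub-watershed
#' area x 100, extent level E from the percent, proximity level P from the
#' zone, and the product R = S x P x E. The per-zone products are averaged
#' (zones without the activity excluded unless `include_empty_zones`) and the
#' mean is classified into a band. A source with declared P/E overrides uses
#' those levels in every zone. If the activity is absent everywhere the
#' result is flagged `no_exposure` and banded low.
#'
#' @param exposures a `zone_exposure` table for a single sub-watershed and
#'   activity (four rows, one per zone).
#' @param source a `source_characterization`.
#' @param include_empty_zones passed to [aggregate_risk()].
#' @return a `qual_risk` object: `subwatershed`, `source`, `s_level`,
#'   `zones` (data frame: zone, activity_area_m2, percent, e_level, p_level,
#'   r), `aggregate_r`, `band`, `no_exposure`.
#' @export
#' @examples
#' tea <- source_characterization("tea-growing", pathogen = FALSE, major = TRUE)
#' ze <- zone_exposure("A002", "tea", c(71267, 374034, 810881, 450905), 12012334)
#' assess_qualitative(ze, tea)
assess_qualitative <- function(exposures, source, include_empty_zones = FALSE) {
  stopifnot(inherits(source, "source_characterization"))
  if (length(unique(exposures$subwatershed)) != 1 ||
      length(unique(exposures$activity_class)) != 1)
    stop_swrisk("exposures must cover exactly one sub-watershed and activity",
                "swrisk_domain_error")
  ord <- match(.zone_labels, as.character(exposures$zone))
  if (anyNA(ord))
    stop_swrisk("exposures must contain one row per buffer zone",
                "swrisk_domain_error")
  e <- exposures[ord, ]
  percent <- e$activity_area_m2 / e$subwatershed_area_m2 * 100
  p_level <- if (!is.null(source$p_override))
    rep(as.integer(source$p_override), 4) else proximity_level(e$zone)
  e_level <- if (!is.null(source$e_override))
    rep(as.integer(source$e_override), 4) else extent_level(percent)
  r <- zone_risk(source$s_level, p_level, e_level)
  agg <- aggregate_risk(r, e$activity_area_m2, include_empty_zones)
  no_exposure <- is.na(agg)
  structure(list(
    subwatershed = e$subwatershed[1], source = source,
    s_level = source$s_level,
    zones = data.frame(zone = .zone_labels,
                       activity_area_m2 = e$activity_area_m2,
                       percent = percent, e_level = e_level,
                       p_level = p_level, r = r),
    aggregate_r = if (no_exposure) NA_real_ else agg,
    band = if (no_exposure) risk_band(0) else risk_band(agg),
    no_exposure = no_exposure), class = "qual_risk")
}

#' @export
print.qual_risk <- function(x, ...) {
  cat(sprintf("Qualitative risk, sub-watershed %s, source '%s' (S = %d)\n",
              x$subwatershed, x$source$name, x$s_level))
  z <- x$zones
  z$percent <- sprintf("%.1f%%", round_half_up(z$percent, 1))
  print.data.frame(z, row.names = FALSE)
  if (x$no_exposure) {
    cat("No exposure: activity absent from every zone; band low\n")
  } else {
    cat(sprintf("Ave. R = %.4g -> band %s\n", x$aggregate_r, as.character(x$band)))
  }
  invisible(x)
}

#' Tabulate a batch of qualitative assessments
#'
#' @param assessments list of `qual_risk` objects.
#' @return data frame: `subwatershed`, `source`, `s_level`, `aggregate_r`,
#'   `band`, `no_exposure`, sorted by descending aggregate score.
#' @export
qual_risk_table <- function(assessments) {
  if (inherits(assessments, "qual_risk")) assessments <- list(assessments)
  out <- do.call(rbind, lapply(assessments, function(a) {
    data.frame(subwatershed = a$subwatershed, source = a$source$name,
               s_level = a$s_level, aggregate_r = a$aggregate_r,
               band = as.character(a$band), no_exposure = a$no_exposure)
  }))
  out[order(-replace(out$aggregate_r, is.na(out$aggregate_r), -Inf),
            out$subwatershed), , drop = FALSE]
}

#' Roll up multiple sources in one sub-watershed
#'
#' Interpretive summary: the unweighted mean of the aggregate scores of all
#' assessed sources in a sub-watershed (no-exposure sources excluded),
#' re-banded. Individual per-source results remain the primary output.
#'
#' @param assessments list of `qual_risk` objects sharing a sub-watershed.
#' @return list: `subwatershed`, `mean_r`, `band`, `n_sources`.
#' @export
rollup_sources <- function(assessments) {
  stopifnot(length(assessments) >= 1)
  sw <- unique(vapply(assessments, function(a) as.character(a$subwatershed), ""))
  if (length(sw) != 1)
    stop_swrisk("roll-up requires assessments of a single sub-watershed",
                "swrisk_domain_error")
  rs <- vapply(assessments, function(a) a$aggregate_r, numeric(1))
  rs <- rs[!is.na(rs)]
  if (length(rs) == 0)
    return(list(subwatershed = sw, mean_r = NA_real_, band = risk_band(0),
                n_sources = 0L))
  list(subwatershed = sw, mean_r = mean(rs), band = risk_band(mean(rs)),
       n_sources = length(rs))
}
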