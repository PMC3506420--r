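#' Hazard quotient
#'
#' The ratio of an exposure concentration to a safe threshold. A hazard
#' quotient above 1.0 means the exposure exceeds the allowable limit; the
#' value is returned unrounded, and only report renderers round it (to two
#' decimals, half-up).
#'
#' @param exposure exposure concentration(s), same units as `threshold`,
#'   non-negative.
#' @param threshold safe threshold(s), strictly positive.
#' @return `exposure / threshold`, vectorized with recycling.
#' @export
#' @examples
#' hazard_quotient(2741, 50)     # 54.82
#' hazard_quotient(0.093, 0.02)  # 4.65
hazard_quotient <- function(exposure, threshold) {
  if (any(threshold <= 0, na.rm = TRUE))
    stop_swrisk("threshold must be strictly positive", "swrisk_domain_error")
  if (any(exposure < 0, na.rm = TRUE))
    stop_swrisk("exposure must be non-negative", "swrisk_domain_error")
  exposure / threshold
}

#' Fraction of values complying with a range or lower-limit standard
#'
#' Parameters such as pH (two-sided range) and dissolved oxygen (lower limit)
#' carry no hazard quotient; compliance is instead the fraction of samples
#' inside the allowed interval.
#'
#' @param values numeric sample values.
#' @param standard a standard list as returned by [std_lookup()], of kind
#'   `range` or `lower_limit`.
#' @return fraction in \[0, 1\], or `NA` with a message attribute when
#'   `values` is empty (no-data).
#' @export
range_compliance <- function(values, standard) {
  if (!standard$kind %in% c("range", "lower_limit"))
    stop_swrisk("range_compliance applies to range or lower_limit standards",
                "swrisk_domain_error")
  values <- values[!is.na(values)]
  if (length(values) == 0) return(structure(NA_real_, no_data = TRUE))
  ok <- values >= standard$lower
  if (standard$kind == "range") ok <- ok & values <= standard$upper
  mean(ok)
}

#' Hazard-quotient screening table
#'
#' Screens every station-by-parameter summary against one standard set. For
#' parameters with an upper-limit standard it emits the average-based and
#' maximum-based hazard quotients (`hq_avg = mean/threshold`,
#' `hq_max = max/threshold`) and strict exceedance flags (`HQ > 1` on the
#' unrounded value). Range and lower-limit parameters (pH, DO) carry no HQ;
#' they get `range_within` (were min and max inside the allowed interval) and,
#' when raw `records` are supplied, the exact compliant fraction. Parameters
#' with no standard in the set are skipped with a warning.
#'
#' @param summaries a `wq_summary` from [summarize_monitoring()] (or a data
#'   frame of the same shape, e.g. a published summary table).
#' @param registry a `standard_registry`; default [default_standards()].
#' @param standard_set which set to screen against (default `"class_a"`).
#' @param records optional raw `monitoring_records`, used only to compute
#'   compliant fractions for range/lower-limit parameters.
#' @return an `hq_table` data frame: `station`, `parameter`, `n`,
#'   `n_detected`, `mean`, `maximum`, `threshold`, `kind`, `hq_avg`,
#'   `hq_max`, `exceeds_avg`, `exceeds_max`, `range_within`,
#'   `range_compliant_fraction`.
#' @export
hq_screen <- function(summaries, registry = default_standards(),
                      standard_set = "class_a", records = NULL) {
  rows <- vector("list", nrow(summaries))
  skipped <- character()
  for (i in seq_len(nrow(summaries))) {
    s <- summaries[i, ]
    std <- tryCatch(std_lookup(registry, s$parameter, standard_set),
                    swrisk_not_found = function(e) NULL)
    if (is.null(std)) {
      skipped <- c(skipped, s$parameter)
      next
    }
    row <- data.frame(station = s$station, parameter = normalize_parameter(s$parameter),
                      n = s$n, n_detected = s$n_detected,
                      mean = s$mean, maximum = s$maximum,
                      threshold = if (std$kind == "upper_limit") std$upper else NA_real_,
                      kind = std$kind,
                      hq_avg = NA_real_, hq_max = NA_real_,
                      exceeds_avg = NA, exceeds_max = NA,
                      range_within = NA, range_compliant_fraction = NA_real_)
    if (std$kind == "upper_limit") {
      row$hq_avg <- hazard_quotient(s$mean, std$upper)
      row$hq_max <- hazard_quotient(s$maximum, std$upper)
      row$exceeds_avg <- row$hq_avg > 1
      row$exceeds_max <- row$hq_max > 1
    } else {
      lo_ok <- s$minimum >= std$lower
      hi_ok <- if (std$kind == "range") s$maximum <= std$upper else TRUE
      row$range_within <- lo_ok && hi_ok
      if (!is.null(records)) {
        sel <- records$station == s$station &
          normalize_parameter(records$parameter) == normalize_parameter(s$parameter) &
          records$detected
        row$range_compliant_fraction <- range_compliance(records$value[sel], std)
      }
    }
    rows[[i]] <- row
  }
  if (length(skipped) > 0)
    warning("no '", standard_set, "' standard for: ",
            paste(unique(skipped), collapse = ", "), "; skipped", call. = FALSE)
  out <- do.call(rbind, rows)
  if (is.null(out)) stop_swrisk("no parameter could be screened", "swrisk_domain_error")
  rownames(out) <- NULL
  class(out) <- c("hq_table", "data.frame")
  attr(out, "standard_set") <- standard_set
  out
}

#' Format an HQ table the way screening reports print it
#'
#' HQs rounded half-up to two decimals; range/lower-limit rows rendered "-".
#'
#' @param x an `hq_table`.
#' @return a character data frame ready for printing or CSV export.
#' @export
format_hq_table <- function(x) {
  fmt <- function(v) ifelse(is.na(v), "-", sprintf("%.2f", round_half_up(v, 2)))
  data.frame(station = x$station, parameter = x$parameter,
             n = x$n, n_detected = x$n_detected,
             mean = x$mean, maximum = x$maximum,
             threshold = ifelse(is.na(x$threshold), "-", x$threshold),
             hq_avg = fmt(x$hq_avg), hq_max = fmt(x$hq_max))
}

#' @export
print.hq_table <- function(x, ...) {
  cat("Hazard-quotient screen against standard set '",
      attr(x, "standard_set") %||% "?", "'\n", sep = "")
  print.data.frame(format_hq_table(x), row.names = FALSE)
  ex <- x$parameter[!is.na(x$exceeds_avg) & x$exceeds_avg]
  if (length(ex) > 0)
    cat("Average exposure exceeds the standard (HQ > 1) for:",
        paste(unique(ex), collapse = ", "), "\n")
  invisible(x)
}
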