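# alias table: squashed (lower-case, alphanumeric-only) label -> canonical id.
# Suspended solids and total dissolved solids are deliberately distinct
# parameters: the Class A "solids" standard is a suspended-solids limit and
# the drinking-water one a dissolved-solids limit, and the two are never
# cross-compared.
.param_aliases <- c(
  ph                       = "pH",
  do                       = "DO",
  dissolvedoxygen          = "DO",
  bod                      = "BOD",
  biochemicaloxygendemand  = "BOD",
  ss                       = "SS",
  suspendedsolids          = "SS",
  solids                   = "SS",
  tds                      = "TDS",
  totaldissolvedsolids     = "TDS",
  ecoli                    = "coliforms",
  coliforms                = "coliforms",
  totalcoliforms           = "coliforms",
  nh3n                     = "NH3-N",
  ammonianitrogen          = "NH3-N",
  ammonia                  = "NH3-N",
  tp                       = "TP",
  totalphosphorus          = "TP",
  phosphorus               = "TP"
)

#' Normalize a water-quality parameter name
#'
#' Monitoring files and standards tables label the same parameter differently
#' ("total phosphorus" vs "TP", "ammonia nitrogen" vs "NH3-N"). Matching is
#' case-insensitive and ignores punctuation and whitespace; unknown labels are
#' passed through unchanged so that records for unlisted parameters are kept.
#'
#' Total coliform counts are normalized to the same id as *E. coli* and
#' screened against its Class A value (50 CFU/100 mL), the convention the
#' source-water screening tables use.
#'
#' @param name character vector of parameter labels.
#' @return character vector of canonical parameter ids.
#' @export
#' @examples
#' normalize_parameter(c("Total phosphorus", "NH3-N", "E. coli"))
normalize_parameter <- function(name) {
  key <- gsub("[^a-z0-9]", "", tolower(as.character(name)))
  canon <- unname(.param_aliases[key])
  out <- ifelse(is.na(canon), as.character(name), canon)
  names(out) <- NULL
  out
}

.standard_kinds <- c("upper_limit", "lower_limit", "range")

new_standard_registry <- function(df) {
  stopifnot(all(c("parameter", "standard_set", "kind", "lower", "upper", "units") %in%
                  names(df)))
  rownames(df) <- NULL
  structure(df, class = c("standard_registry", "data.frame"))
}

validate_registry <- function(df) {
  bad_kind <- !df$kind %in% .standard_kinds
  if (any(bad_kind)) {
    stop_swrisk(sprintf("unknown standard kind: %s",
                        paste(unique(df$kind[bad_kind]), collapse = ", ")),
                "swrisk_config_error")
  }
  need_upper <- df$kind %in% c("upper_limit", "range")
  need_lower <- df$kind %in% c("lower_limit", "range")
  if (any(need_upper & is.na(df$upper)) || any(!need_upper & !is.na(df$upper)))
    stop_swrisk("upper limit must be present exactly for upper_limit/range standards",
                "swrisk_config_error")
  if (any(need_lower & is.na(df$lower)) || any(!need_lower & !is.na(df$lower)))
    stop_swrisk("lower limit must be present exactly for lower_limit/range standards",
                "swrisk_config_error")
  both <- !is.na(df$lower) & !is.na(df$upper)
  if (any(both & df$lower >= df$upper))
    stop_swrisk("lower limit must be strictly below upper limit", "swrisk_config_error")
  nonpos <- ifelse(is.na(df$lower), df$upper, df$lower) <= 0
  if (any(nonpos & df$parameter != "pH"))
    stop_swrisk("standard limits must be strictly positive", "swrisk_config_error")
  key <- paste(df$parameter, df$standard_set, sep = "\r")
  if (anyDuplicated(key))
    stop_swrisk(sprintf("duplicate standard for (%s)",
                        gsub("\r", ", ", key[duplicated(key)][1])),
                "swrisk_config_error")
  df
}

#' Built-in default water-quality standard registry
#'
#' Two standard sets: `class_a`, the Taiwan EPA Class A surface-water criteria
#' applicable to public-supply source water, and `drinking`, the drinking-water
#' quality standards. Cells the regulations leave unspecified (e.g. a drinking
#' standard for TP) are simply absent and [std_lookup()] signals not-found.
#'
#' @return a `standard_registry` (data frame with columns `parameter`,
#'   `standard_set`, `kind`, `lower`, `upper`, `units`).
#' @export
#' @examples
#' reg <- default_standards()
#' std_lookup(reg, "TP", "class_a")$upper  # 0.02 mg/L
default_standards <- function() {
  df <- rbind(
    data.frame(parameter = "pH",        standard_set = "class_a",  kind = "range",
               lower = 6.5, upper = 8.5, units = "pH units"),
    data.frame(parameter = "DO",        standard_set = "class_a",  kind = "lower_limit",
               lower = 6.5, upper = NA_real_, units = "mg/L"),
    data.frame(parameter = "BOD",       standard_set = "class_a",  kind = "upper_limit",
               lower = NA_real_, upper = 1, units = "mg/L"),
    data.frame(parameter = "SS",        standard_set = "class_a",  kind = "upper_limit",
               lower = NA_real_, upper = 25, units = "mg/L"),
    data.frame(parameter = "coliforms", standard_set = "class_a",  kind = "upper_limit",
               lower = NA_real_, upper = 50, units = "CFU/100 mL"),
    data.frame(parameter = "NH3-N",     standard_set = "class_a",  kind = "upper_limit",
               lower = NA_real_, upper = 0.1, units = "mg/L"),
    data.frame(parameter = "TP",        standard_set = "class_a",  kind = "upper_limit",
               lower = NA_real_, upper = 0.02, units = "mg/L"),
    data.frame(parameter = "pH",        standard_set = "drinking", kind = "range",
               lower = 6.0, upper = 8.5, units = "pH units"),
    data.frame(parameter = "TDS",       standard_set = "drinking", kind = "upper_limit",
               lower = NA_real_, upper = 500, units = "mg/L"),
    data.frame(parameter = "coliforms", standard_set = "drinking", kind = "upper_limit",
               lower = NA_real_, upper = 6, units = "CFU/100 mL"),
    data.frame(parameter = "NH3-N",     standard_set = "drinking", kind = "upper_limit",
               lower = NA_real_, upper = 0.1, units = "mg/L")
  )
  new_standard_registry(validate_registry(df))
}

#' Load a standard registry from a YAML configuration
#'
#' The config is one document of the form `set -> parameter -> {kind, lower,
#' upper, units}`; `kind` may be omitted and is then inferred from which limits
#' are present (both -> `range`). Parameter labels are normalized via
#' [normalize_parameter()].
#'
#' @param source path to a YAML file, or an already-parsed nested list.
#' @return a `standard_registry`.
#' @seealso [write_standards()] for the inverse; [default_standards()].
#' @export
load_standards <- function(source) {
  cfg <- if (is.character(source)) yaml::read_yaml(source) else source
  if (!is.list(cfg) || is.null(names(cfg)))
    stop_swrisk("standards config must map set names to parameter tables",
                "swrisk_config_error")
  rows <- list()
  for (set in names(cfg)) {
    params <- cfg[[set]]
    if (!is.list(params) || is.null(names(params)))
      stop_swrisk(sprintf("set '%s' must map parameter names to limit entries", set),
                  "swrisk_config_error")
    for (p in names(params)) {
      e <- params[[p]]
      lower <- as.numeric(e$lower %||% NA_real_)
      upper <- as.numeric(e$upper %||% NA_real_)
      if (is.na(lower) && is.na(upper))
        stop_swrisk(sprintf("standard (%s, %s) declares no limit", p, set),
                    "swrisk_config_error")
      kind <- e$kind %||% if (!is.na(lower) && !is.na(upper)) "range"
        else if (!is.na(upper)) "upper_limit" else "lower_limit"
      rows[[length(rows) + 1L]] <- data.frame(
        parameter = normalize_parameter(p), standard_set = set, kind = kind,
        lower = lower, upper = upper, units = as.character(e$units %||% NA_character_))
    }
  }
  new_standard_registry(validate_registry(do.call(rbind, rows)))
}

#' Serialize a standard registry to YAML
#'
#' Writes the `set -> parameter -> {kind, lower, upper, units}` layout that
#' [load_standards()] reads; the round trip is lossless.
#'
#' @param registry a `standard_registry`.
#' @param path output file path; if `NULL`, the nested list is returned.
#' @export
write_standards <- function(registry, path = NULL) {
  out <- list()
  for (i in seq_len(nrow(registry))) {
    r <- registry[i, ]
    e <- list(kind = r$kind, units = r$units)
    if (!is.na(r$lower)) e$lower <- r$lower
    if (!is.na(r$upper)) e$upper <- r$upper
    out[[r$standard_set]][[r$parameter]] <- e
  }
  if (is.null(path)) return(out)
  yaml::write_yaml(out, path)
  invisible(path)
}

#' Look up one standard
#'
#' @param registry a `standard_registry`.
#' @param parameter parameter label (normalized before matching).
#' @param standard_set set id, e.g. `"class_a"` or `"drinking"`.
#' @return a list with fields `parameter`, `standard_set`, `kind`, `lower`,
#'   `upper`, `units`.
#' @details An unknown (parameter, set) pair raises a condition of class
#'   `swrisk_not_found`, distinct from the `swrisk_config_error` raised for a
#'   malformed registry, so callers can treat "no standard exists" as data.
#' @export
#' @examples
#' std_lookup(default_standards(), "DO", "class_a")$lower  # 6.5
std_lookup <- function(registry, parameter, standard_set) {
  stopifnot(inherits(registry, "standard_registry"))
  p <- normalize_parameter(parameter)
  hit <- registry$parameter == p & registry$standard_set == standard_set
  if (!any(hit)) {
    stop_swrisk(sprintf("no standard for parameter '%s' in set '%s'",
                        p, standard_set), "swrisk_not_found")
  }
  as.list(registry[which(hit)[1], ])
}

#' @export
print.standard_registry <- function(x, ...) {
  cat("Water-quality standard registry:", nrow(x), "standards in",
      length(unique(x$standard_set)), "set(s)\n")
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}
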