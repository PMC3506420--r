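#' Read a monitoring-record CSV
#'
#' Expected columns: `station`, `date`, `parameter`, `value`, and optionally
#' `detected` (0/1) and `detection_limit`. Non-detects may be encoded either
#' as `detected = 0` with the value empty (the detection limit then comes from
#' the `detection_limit` column) or as a `"<DL"` marker in the value column
#' (e.g. `"<0.013"`), from which the limit is parsed.
#'
#' @param path CSV file path.
#' @param date_format date parsing format, default ISO-8601 (`"%Y-%m-%d"`).
#' @return a `monitoring_records` data frame with columns `station`, `date`
#'   (`Date`), `parameter` (normalized), `value`, `detected` (logical),
#'   `detection_limit`. An empty file yields a zero-row frame.
#' @details A malformed date or number aborts with the offending line number
#'   (header = line 1). Parameters without a known alias are kept as-is with a
#'   warning, so unlisted analytes survive ingestion.
#' @export
read_monitoring_csv <- function(path, date_format = "%Y-%m-%d") {
  if (!file.exists(path)) stop_swrisk(paste("no such file:", path), "swrisk_io_error")
  raw <- utils::read.csv(path, colClasses = "character", strip.white = TRUE)
  empty <- data.frame(station = character(), date = as.Date(character()),
                      parameter = character(), value = numeric(),
                      detected = logical(), detection_limit = numeric())
  class(empty) <- c("monitoring_records", "data.frame")
  if (nrow(raw) == 0) return(empty)

  need <- c("station", "date", "parameter", "value")
  if (!all(need %in% names(raw)))
    stop_swrisk(paste("missing required column(s):",
                      paste(setdiff(need, names(raw)), collapse = ", ")),
                "swrisk_io_error")
  line <- seq_len(nrow(raw)) + 1L

  date <- as.Date(raw$date, format = date_format)
  if (anyNA(date))
    stop_swrisk(sprintf("malformed date '%s' at line %d",
                        raw$date[which(is.na(date))[1]], line[which(is.na(date))[1]]),
                "swrisk_io_error")

  val_str <- raw$value
  lt_marker <- grepl("^<", val_str)
  detected <- if ("detected" %in% names(raw)) {
    d <- suppressWarnings(as.numeric(raw$detected))
    ifelse(is.na(d), !(val_str == "" | lt_marker), d != 0)
  } else {
    !(val_str == "" | lt_marker)
  }
  detected[lt_marker] <- FALSE

  num_or_na <- function(s, what) {
    out <- suppressWarnings(as.numeric(s))
    bad <- !is.na(s) & s != "" & is.na(out)
    if (any(bad))
      stop_swrisk(sprintf("malformed %s '%s' at line %d",
                          what, s[which(bad)[1]], line[which(bad)[1]]),
                  "swrisk_io_error")
    out
  }
  value <- num_or_na(sub("^<", "", val_str), "value")
  dl <- if ("detection_limit" %in% names(raw))
    num_or_na(raw$detection_limit, "detection limit") else rep(NA_real_, nrow(raw))
  # "<0.013" carries its own detection limit; the value itself is unknown
  dl[lt_marker] <- value[lt_marker]
  value[lt_marker] <- NA_real_

  param <- normalize_parameter(raw$parameter)
  unknown <- unique(raw$parameter[param == raw$parameter &
                                    !param %in% .param_aliases])
  if (length(unknown) > 0)
    warning("parameter(s) without a known alias, kept verbatim: ",
            paste(unknown, collapse = ", "), call. = FALSE)
  if (any(!is.na(value) & value < 0 & param != "pH"))
    stop_swrisk("negative concentration encountered", "swrisk_io_error")

  out <- data.frame(station = raw$station, date = date, parameter = param,
                    value = value, detected = detected, detection_limit = dl)
  class(out) <- c("monitoring_records", "data.frame")
  out
}

#' Write monitoring records to CSV
#'
#' Inverse of [read_monitoring_csv()]; non-detects get an empty value cell,
#' `detected = 0` and their detection limit.
#'
#' @param records a `monitoring_records` data frame.
#' @param path output path.
#' @export
write_monitoring_csv <- function(records, path) {
  out <- data.frame(station = records$station,
                    date = format(records$date, "%Y-%m-%d"),
                    parameter = records$parameter,
                    value = ifelse(records$detected, records$value, NA_real_),
                    detected = as.integer(records$detected),
                    detection_limit = records$detection_limit)
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

.censoring_policies <- c("detected_only", "substitute_zero",
                         "substitute_half_dl", "substitute_dl")

#' Summarize monitoring records per station and parameter
#'
#' Computes the exposure summaries (n, n detected, mean, min, max) that feed
#' the hazard-quotient screen, under an explicit censoring policy for
#' non-detects:
#'
#' * `detected_only` (default): non-detects are excluded from mean/min/max.
#'   They still count in `n`. This matches summary tables whose reported
#'   ranges start at the smallest *detected* value.
#' * `substitute_zero`, `substitute_half_dl`, `substitute_dl`: each non-detect
#'   contributes 0, DL/2, or DL.
#'
#' All samples are pooled over the record span (no monthly weighting). A
#' station-parameter cell with no usable value under the policy is returned
#' with `no_data = TRUE` and `NA` statistics rather than an error.
#'
#' @param records a `monitoring_records` data frame (or anything with columns
#'   `station`, `parameter`, `value`, `detected`, `detection_limit`).
#' @param policy one of `"detected_only"`, `"substitute_zero"`,
#'   `"substitute_half_dl"`, `"substitute_dl"`.
#' @return a `wq_summary` data frame: `station`, `parameter`, `n`,
#'   `n_detected`, `mean`, `minimum`, `maximum`, `policy`, `no_data`.
#' @export
#' @examples
#' rec <- data.frame(station = "S1", parameter = "TP",
#'                   value = c(10, NA), detected = c(TRUE, FALSE),
#'                   detection_limit = c(NA, 2))
#' summarize_monitoring(rec, "substitute_half_dl")$mean  # (10 + 1)/2 = 5.5
summarize_monitoring <- function(records, policy = "detected_only") {
  policy <- match.arg(policy, .censoring_policies)
  groups <- split(seq_len(nrow(records)),
                  list(station = records$station, parameter = records$parameter),
                  drop = TRUE)
  rows <- lapply(groups, function(idx) {
    g <- records[idx, ]
    vals <- switch(policy,
      detected_only      = g$value[g$detected],
      substitute_zero    = ifelse(g$detected, g$value, 0),
      substitute_half_dl = ifelse(g$detected, g$value, g$detection_limit / 2),
      substitute_dl      = ifelse(g$detected, g$value, g$detection_limit))
    vals <- vals[!is.na(vals)]
    no_data <- length(vals) == 0
    data.frame(station = g$station[1], parameter = g$parameter[1],
               n = nrow(g), n_detected = sum(g$detected),
               mean = if (no_data) NA_real_ else mean(vals),
               minimum = if (no_data) NA_real_ else min(vals),
               maximum = if (no_data) NA_real_ else max(vals),
               policy = policy, no_data = no_data)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$station, out$parameter), ]
  rownames(out) <- NULL
  class(out) <- c("wq_summary", "data.frame")
  out
}

#' @export
print.wq_summary <- function(x, digits = 4, ...) {
  cat("Monitoring summaries (censoring policy: ", x$policy[1], ")\n", sep = "")
  y <- x
  y$mean <- signif(y$mean, digits)
  print.data.frame(y[setdiff(names(y), "policy")], row.names = FALSE)
  invisible(x)
}
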