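# Brute-force nearest-stream-cell distance: exhaustive minimum over all
# stream cells, cell-centre Euclidean. Independent oracle for the
# distance-transform path.
brute_force_distance <- function(stream, cell_size = 1) {
  idx <- which(stream, arr.ind = TRUE)
  stopifnot(nrow(idx) > 0)
  rr <- row(stream)
  cc <- col(stream)
  d2 <- matrix(Inf, nrow(stream), ncol(stream))
  for (k in seq_len(nrow(idx))) {
    d2 <- pmin(d2, (rr - idx[k, 1])^2 + (cc - idx[k, 2])^2)
  }
  sqrt(d2) * cell_size
}

# Straight-line reference for censored summaries: substitute, then plain
# arithmetic; no shared code with summarize_monitoring().
reference_summary <- function(values, detected, dl, policy) {
  v <- switch(policy,
              detected_only = values[detected],
              substitute_zero = { values[!detected] <- 0; values },
              substitute_half_dl = { values[!detected] <- dl[!detected] / 2; values },
              substitute_dl = { values[!detected] <- dl[!detected]; values })
  c(mean = mean(v), minimum = min(v), maximum = max(v))
}

write_temp_csv <- function(lines) {
  path <- withr::local_tempfile(fileext = ".csv",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

random_stream_grid <- function(n_rows, n_cols, n_stream, cell_size = 10) {
  sm <- matrix(FALSE, n_rows, n_cols)
  sm[sample(n_rows * n_cols, n_stream)] <- TRUE
  watershed_grid(matrix(1L, n_rows, n_cols), sm, cell_size = cell_size)
}
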