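#' Read and write dwell-sequence TSV files
#'
#' Dwell sequences travel between pipeline stages as plain TSV with header
#' columns `event_index`, `class`, `duration_ms` (simulation ground truth
#' additionally keeps `state` and `has_cs`). The dead time is not stored in
#' the table; pass it when reading a dead-time-regularized list.
#'
#' @param dwells a [dwell_sequence()].
#' @param path file path.
#' @return `write_dwells()` returns `path` invisibly; `read_dwells()` returns
#'   a [dwell_sequence()].
#' @export
write_dwells <- function(dwells, path) {
  stopifnot(inherits(dwells, "dwell_sequence"))
  d <- data.frame(event_index = seq_len(nrow(dwells)),
                  class = dwells$class,
                  duration_ms = sprintf("%.6f", dwells$duration_ms),
                  state = dwells$state,
                  has_cs = dwells$has_cs)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @param dead_time_ms dead time the stored record was regularized to.
#' @rdname write_dwells
#' @export
read_dwells <- function(path, dead_time_ms = 0) {
  d <- utils::read.table(path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE)
  dwell_sequence(d$class, as.numeric(d$duration_ms),
                 state = if ("state" %in% names(d)) d$state else NA_integer_,
                 has_cs = if ("has_cs" %in% names(d)) d$has_cs else NA,
                 dead_time_ms = dead_time_ms)
}

#' Read and write current-trace TSV files
#'
#' Traces are stored as two-column TSV (`time_s`, `current_pA`) with a YAML
#' sidecar (`<path>.meta.yaml`) holding the sampling rate, unitary amplitude
#' and recording metadata.
#'
#' @param trace a [trace_record()].
#' @param path file path for the TSV; the sidecar is written next to it.
#' @return `write_trace()` returns `path` invisibly; `read_trace()` a
#'   [trace_record()].
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "trace_record"))
  d <- data.frame(time_s = sprintf("%.6f", trace_times_s(trace)),
                  current_pA = sprintf("%.6f", trace$current_pA))
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- c(list(sampling_rate_hz = trace$sampling_rate_hz,
                 unitary_amplitude_pA = trace$unitary_amplitude_pA),
            trace$meta)
  yaml::write_yaml(meta, paste0(path, ".meta.yaml"))
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  d <- utils::read.table(path, sep = "\t", header = TRUE)
  meta_path <- paste0(path, ".meta.yaml")
  meta <- if (file.exists(meta_path)) yaml::read_yaml(meta_path) else list()
  fs <- meta$sampling_rate_hz
  if (is.null(fs)) fs <- 1 / stats::median(diff(d$time_s))
  amp <- meta$unitary_amplitude_pA %||% NA_real_
  trace_record(as.numeric(d$current_pA), fs, amp,
               meta = meta[setdiff(names(meta),
                                   c("sampling_rate_hz", "unitary_amplitude_pA"))])
}

#' Write descriptive statistics as a single-row TSV
#'
#' @param stats a `"burst_stats"` or `"intraburst_stats"` object (or any flat
#'   named list of scalars).
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_stats_tsv <- function(stats, path) {
  d <- as.data.frame(unclass(stats)[vapply(unclass(stats), is.numeric, TRUE)])
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a mutant-cycle corner-estimate table
#'
#' Corner estimates (one row per construct and measured quantity) are stored
#' as TSV with columns `construct`, `quantity_kind` (`rate`,
#' `equilibrium_constant` or `dwell_time`), `transition` (gating-step label),
#' `mean`, `sem`, `n`. The packaged steady-state and intraburst summary
#' tables ship in this layout under `inst/extdata/`.
#'
#' @param path file path.
#' @return A data frame with the columns above.
#' @export
read_corner_table <- function(path) {
  d <- utils::read.table(path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE)
  need <- c("construct", "quantity_kind", "transition", "mean", "sem", "n")
  if (!all(need %in% names(d))) {
    stop("corner table must have columns: ", paste(need, collapse = ", "))
  }
  d
}
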