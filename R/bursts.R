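#' Empirical burst statistics of a dwell sequence
#'
#' Segments a record into bursts and computes the descriptive gating
#' parameters directly from the events. A burst is a maximal interval
#' delimited by sojourns in the interburst closed state: closed events are
#' labelled interburst either from simulation ground truth (`has_cs`) or by
#' comparing their duration with a critical duration `t_crit_ms`; everything
#' between two interburst closures is one burst (openings plus flickery
#' closures).
#'
#' Incomplete leading/trailing bursts (not flanked by interburst closures on
#' both sides) are dropped from the burst-duration average.
#'
#' @param dwells a [dwell_sequence()].
#' @param t_crit_ms critical duration separating flickery from interburst
#'   closures (ms). If `NULL`, ground-truth `has_cs` labels are used (only
#'   available for simulated records).
#' @return List with `tau_burst_ms`, `tau_interburst_ms`, `tau_flicker_ms`,
#'   `n_flicker`, `p_open_empirical`, `n_bursts`, and standard errors
#'   `se_tau_burst_ms`, `se_tau_interburst_ms`.
#' @export
empirical_burst_stats <- function(dwells, t_crit_ms = NULL) {
  stopifnot(inherits(dwells, "dwell_sequence"))
  cls <- dwells$class
  dur <- dwells$duration_ms
  closed <- which(cls == "closed")
  if (is.null(t_crit_ms)) {
    if (all(is.na(dwells$has_cs))) {
      stop("no ground-truth state labels; supply t_crit_ms")
    }
    is_ib <- closed[dwells$has_cs[closed]]
  } else {
    is_ib <- closed[dur[closed] >= t_crit_ms]
  }
  if (length(is_ib) < 2) stop("fewer than two interburst closures in record")
  flicker <- setdiff(closed, is_ib)
  ## bursts: maximal runs between consecutive interburst closures
  burst_dur <- numeric(0)
  n_flick_in_burst <- integer(0)
  for (j in seq_len(length(is_ib) - 1L)) {
    span <- (is_ib[j] + 1L):(is_ib[j + 1L] - 1L)
    if (length(span) == 0) next
    burst_dur <- c(burst_dur, sum(dur[span]))
    n_flick_in_burst <- c(n_flick_in_burst, sum(span %in% flicker))
  }
  if (length(burst_dur) == 0) stop("no complete burst in record")
  ib_dur <- dur[is_ib]
  list(tau_burst_ms = mean(burst_dur),
       tau_interburst_ms = mean(ib_dur),
       tau_flicker_ms = if (length(flicker)) mean(dur[flicker]) else NA_real_,
       n_flicker = length(flicker) / length(burst_dur),
       p_open_empirical = sum(dur[cls == "open"]) / sum(dur),
       n_bursts = length(burst_dur),
       se_tau_burst_ms = stats::sd(burst_dur) / sqrt(length(burst_dur)),
       se_tau_interburst_ms = stats::sd(ib_dur) / sqrt(length(ib_dur)))
}
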