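#' Re-filter a trace with a Gaussian digital filter
#'
#' Applies a zero-phase discrete Gaussian filter with corner frequency `fc_hz`
#' (DC gain exactly 1). Analysis filtering before idealization typically uses
#' a much lower corner (default 100 Hz) than the recording filter; a cascade
#' of two Gaussian filters is equivalent to a single one with
#' `fc = (fc1^-2 + fc2^-2)^(-1/2)`.
#'
#' @param trace a [trace_record()].
#' @param fc_hz corner frequency (Hz), below Nyquist.
#' @return A filtered [trace_record()]; metadata gains `analysis_filter_fc_hz`.
#' @export
refilter <- function(trace, fc_hz = 100) {
  stopifnot(inherits(trace, "trace_record"))
  x <- apply_gaussian_filter(trace$current_pA, fc_hz, trace$sampling_rate_hz)
  out <- trace
  out$current_pA <- x
  out$meta$analysis_filter_fc_hz <- fc_hz
  out
}

#' Estimate closed and open current levels from a trace
#'
#' Takes the two highest-density modes of the amplitude histogram (kernel
#' density estimate); the mode nearer 0 pA is taken as the closed level.
#' Intended for traces where both levels are actually visited; supply levels
#' explicitly for very low open probability records.
#'
#' @param trace a [trace_record()].
#' @return Named numeric vector `c(closed = , open = )` in pA.
#' @export
estimate_levels <- function(trace) {
  x <- trace$current_pA
  d <- stats::density(x, n = 512)
  ## local maxima of the density
  y <- d$y
  peak <- which(diff(sign(diff(y))) == -2) + 1L
  if (length(peak) < 2) {
    ## fall back: split around the midpoint of the range
    mid <- mean(range(x))
    lv <- c(mean(x[x > mid]), mean(x[x <= mid]))
  } else {
    peak <- peak[order(y[peak], decreasing = TRUE)][1:2]
    lv <- d$x[peak]
  }
  closed <- lv[which.min(abs(lv))]
  open <- lv[which.max(abs(lv))]
  c(closed = closed, open = open)
}

#' Idealize a current trace by half-amplitude threshold crossing
#'
#' Each sample is assigned to the closed or open conductance class by
#' comparison with the 50% level between the closed and open current levels
#' (a single threshold, no hysteresis — the low-pass analysis filter is
#' relied upon to suppress threshold chatter). Runs of equal class become
#' events with duration `run length / sampling rate`. No dead time is applied
#' at this stage; see [impose_dead_time()].
#'
#' @param trace a [trace_record()] (typically after [refilter()]).
#' @param levels named numeric `c(closed = , open = )` in pA; estimated with
#'   [estimate_levels()] when missing.
#' @param threshold_fraction position of the threshold between the two levels
#'   (default 0.5, i.e. half-amplitude).
#' @return A [dwell_sequence()] with `dead_time_ms = 0`.
#' @export
idealize <- function(trace, levels = NULL, threshold_fraction = 0.5) {
  stopifnot(inherits(trace, "trace_record"),
            threshold_fraction > 0, threshold_fraction < 1)
  if (is.null(levels)) levels <- estimate_levels(trace)
  if (abs(levels[["open"]] - levels[["closed"]]) < 1e-12) {
    stop("degenerate levels: closed and open current levels must differ")
  }
  thr <- levels[["closed"]] +
    threshold_fraction * (levels[["open"]] - levels[["closed"]])
  open_side <- sign(levels[["open"]] - thr)
  is_open <- sign(trace$current_pA - thr) == open_side
  r <- rle(is_open)
  dwell_sequence(ifelse(r$values, "open", "closed"),
                 r$lengths / trace$sampling_rate_hz * 1000,
                 dead_time_ms = 0, censored_end = TRUE)
}

#' Impose a fixed dead time on a dwell sequence
#'
#' Events shorter than the dead time are treated as undetected: each is
#' removed and its duration absorbed backward into the preceding retained
#' event (forward into the first retained event when the record begins with
#' sub-dead-time events), after which adjacent events of equal class are
#' merged. Total duration is conserved exactly, every surviving event is at
#' least `dead_time_ms` long, and the operation is idempotent.
#'
#' @param dwells a [dwell_sequence()] with `dead_time_ms = 0` (or already
#'   equal to `dead_time_ms`, in which case it is returned unchanged).
#' @param dead_time_ms the imposed minimum resolvable duration (ms).
#' @return A dead-time-regularized [dwell_sequence()].
#' @export
impose_dead_time <- function(dwells, dead_time_ms) {
  stopifnot(inherits(dwells, "dwell_sequence"), dead_time_ms >= 0)
  if (dead_time_ms == 0) return(dwells)
  cur_td <- attr(dwells, "dead_time_ms")
  if (cur_td == dead_time_ms) return(dwells)
  if (cur_td != 0) {
    stop("dwells already carry a different dead time (", cur_td, " ms)")
  }
  cls <- dwells$class
  dur <- dwells$duration_ms
  keep_first <- which(dur >= dead_time_ms)[1]
  if (is.na(keep_first)) stop("no event is as long as the dead time")
  ## leading short events attach forward to the first retained event
  if (keep_first > 1) {
    dur[keep_first] <- dur[keep_first] + sum(dur[seq_len(keep_first - 1)])
    cls <- cls[keep_first:length(cls)]
    dur <- dur[keep_first:length(dur)]
  }
  out_cls <- character(length(cls))
  out_dur <- numeric(length(cls))
  n_out <- 1L
  out_cls[1] <- cls[1]; out_dur[1] <- dur[1]
  for (i in seq_along(cls)[-1]) {
    if (dur[i] < dead_time_ms) {
      ## unresolved: absorb backward into the previous retained event
      out_dur[n_out] <- out_dur[n_out] + dur[i]
    } else if (cls[i] == out_cls[n_out]) {
      ## same class after an absorbed event: merge
      out_dur[n_out] <- out_dur[n_out] + dur[i]
    } else {
      n_out <- n_out + 1L
      out_cls[n_out] <- cls[i]
      out_dur[n_out] <- dur[i]
    }
  }
  dwell_sequence(out_cls[seq_len(n_out)], out_dur[seq_len(n_out)],
                 dead_time_ms = dead_time_ms,
                 censored_end = attr(dwells, "censored_end"))
}

#' Screen a trace for superimposed (stacked) openings
#'
#' Returns `TRUE` if a non-negligible fraction of samples lies beyond 1.5x the
#' unitary amplitude, indicating that more than one channel was active; the
#' single-channel exclusion test is then not applicable.
#'
#' @param trace a [trace_record()].
#' @param unitary_amplitude_pA unitary current level (defaults to the one in
#'   the trace).
#' @param min_fraction fraction of beyond-level samples regarded as evidence
#'   of stacking (default 1e-4).
#' @return Logical.
#' @export
detect_superimposed <- function(trace, unitary_amplitude_pA = NULL,
                                min_fraction = 1e-4) {
  amp <- unitary_amplitude_pA %||% trace$unitary_amplitude_pA
  f <- mean(abs(trace$current_pA) > 1.5 * abs(amp))
  f > min_fraction
}

#' Confidence that a second active channel can be excluded
#'
#' A surrogate for the published statistical channel-count tests: given a
#' record with no superimposed openings, returns the probability that a
#' hypothetical second, independent, identical channel would have opened at
#' least once while the first channel was open. With opening rate `lambda`
#' (1/s, the reciprocal mean interburst duration) and total observed open time
#' `T` (s), that probability is `1 - exp(-lambda * T)`. Values above 0.9 mean
#' a second channel can be excluded with >90% confidence. The surrogate is
#' exact in the low-open-probability limit where the putative second channel
#' spends essentially all its time ready to open; it does not claim
#' equivalence with the original published procedure.
#'
#' @param dwells a [dwell_sequence()] with no superimposed openings.
#' @param opening_rate_s the channel's opening rate (1/s).
#' @return The exclusion confidence, a probability in (0, 1).
#' @export
single_channel_confidence <- function(dwells, opening_rate_s) {
  stopifnot(inherits(dwells, "dwell_sequence"), opening_rate_s > 0)
  open_s <- sum(dwells$duration_ms[dwells$class == "open"]) / 1000
  if (open_s <= 0) stop("record contains no open time; confidence undefined")
  1 - exp(-opening_rate_s * open_s)
}
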