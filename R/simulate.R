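## Run code with a temporarily fixed RNG state. seed = NULL means "use the
## current RNG stream" (no isolation).
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}

## Deterministic child seed, kept inside 32-bit integer range.
derive_seed <- function(seed, i) {
  if (is.null(seed)) return(NULL)
  as.integer((as.double(seed) * 1000003 + 7919 * i) %% 2147483629)
}

#' Dwell sequences
#'
#' A dwell sequence is the central exchange format between the simulation,
#' idealization and fitting stages: an ordered alternating record of
#' conductance-class sojourns. It is a data frame with columns `class`
#' (`"closed"`/`"open"`), `duration_ms`, `state` (originating state index
#' where unambiguous, `NA` for closed sojourns that visited both closed
#' states) and `has_cs` (did the sojourn visit the interburst closed state;
#' only available for simulated ground truth, `NA` otherwise), carrying
#' attributes `dead_time_ms` and `censored_end`.
#'
#' @param class character vector of `"closed"`/`"open"`, strictly alternating.
#' @param duration_ms positive dwell durations in ms.
#' @param state optional originating state index (1 = Cs, 2 = Cf, 3 = O).
#' @param has_cs optional logical: closed sojourn visited Cs.
#' @param dead_time_ms dead time already imposed on the record (0 = none).
#' @param censored_end logical: was the final dwell truncated by the end of
#'   the record?
#' @return Object of class `"dwell_sequence"` (a data frame).
#' @export
dwell_sequence <- function(class, duration_ms, state = NA_integer_,
                           has_cs = NA, dead_time_ms = 0,
                           censored_end = FALSE) {
  stopifnot(length(class) == length(duration_ms))
  if (!all(class %in% c("closed", "open"))) {
    stop("dwell classes must be 'closed' or 'open'")
  }
  if (length(class) > 1 && any(class[-1] == class[-length(class)])) {
    stop("dwell classes must strictly alternate")
  }
  if (any(duration_ms <= 0)) stop("all dwell durations must be positive")
  if (dead_time_ms > 0 && any(duration_ms < dead_time_ms - 1e-9)) {
    stop("durations below the declared dead time")
  }
  d <- data.frame(class = class, duration_ms = duration_ms,
                  state = state, has_cs = has_cs)
  structure(d, dead_time_ms = dead_time_ms, censored_end = censored_end,
            class = c("dwell_sequence", "data.frame"))
}

#' @export
print.dwell_sequence <- function(x, ...) {
  cat(sprintf("Dwell sequence: %d events, %.4g s total, dead time %.3g ms\n",
              nrow(x), sum(x$duration_ms) / 1000, attr(x, "dead_time_ms")))
  cat(sprintf("  open: %d events, mean %.3g ms; closed: %d events, mean %.3g ms\n",
              sum(x$class == "open"), mean(x$duration_ms[x$class == "open"]),
              sum(x$class == "closed"), mean(x$duration_ms[x$class == "closed"])))
  invisible(x)
}

total_duration_ms <- function(dwells) sum(dwells$duration_ms)

#' Exact stochastic simulation of a gating trajectory
#'
#' Simulates a continuous-time Markov (Gillespie) trajectory of the three-state
#' chain and aggregates it into an alternating closed/open dwell sequence.
#' State-level information is retained: unambiguous sojourns carry their state
#' index, and each closed sojourn records whether it visited the interburst
#' closed state Cs (ground truth for burst segmentation). The initial state is
#' drawn from the stationary distribution unless given, matching the
#' steady-state recording regime.
#'
#' @param model a [gating_model()].
#' @param duration_ms simulate until this total duration (the final dwell is
#'   truncated and flagged censored). Exactly one of `duration_ms`/`n_events`.
#' @param n_events simulate until this many aggregated dwells.
#' @param seed optional integer seed (reproducible trajectories).
#' @param start_state optional initial state index (1 = Cs, 2 = Cf, 3 = O).
#' @return A [dwell_sequence()] with `dead_time_ms = 0`.
#' @export
sample_trajectory <- function(model, duration_ms = NULL, n_events = NULL,
                              seed = NULL, start_state = NULL) {
  stopifnot(inherits(model, "gating_model"))
  if (is.null(duration_ms) == is.null(n_events)) {
    stop("supply exactly one of duration_ms or n_events")
  }
  with_seed(seed, {
    Q <- model$Q
    exit <- -diag(Q)
    P <- Q / exit            # jump probabilities
    diag(P) <- 0
    if (is.null(start_state)) {
      start_state <- sample.int(3, 1, prob = stationary_distribution(model))
    }
    start_state <- as.integer(start_state)
    cls <- c(1L, 1L, 2L)     # 1 = closed, 2 = open (states Cs, Cf, O)
    cap <- 4096L
    st <- integer(cap); du <- numeric(cap)
    n <- 0L; s <- start_state
    tot_ms <- 0
    target_ms <- if (is.null(duration_ms)) Inf else duration_ms
    ## aggregated-event counting target: state transitions within a class do
    ## not create new events, so track class changes
    n_agg <- 0L; last_cls <- 0L
    target_events <- if (is.null(n_events)) Inf else n_events
    censored <- FALSE
    repeat {
      if (n == cap) {
        cap <- cap * 2L
        st <- c(st, integer(cap / 2L)); du <- c(du, numeric(cap / 2L))
      }
      d_ms <- 1000 * stats::rexp(1, exit[s])
      if (tot_ms + d_ms >= target_ms) {
        d_ms <- target_ms - tot_ms
        censored <- TRUE
        if (d_ms > 0) { n <- n + 1L; st[n] <- s; du[n] <- d_ms }
        break
      }
      n <- n + 1L; st[n] <- s; du[n] <- d_ms; tot_ms <- tot_ms + d_ms
      if (cls[s] != last_cls) { n_agg <- n_agg + 1L; last_cls <- cls[s] }
      if (n_agg >= target_events + 1L) { n <- n - 1L; break }
      s <- if (sum(P[s, ] > 0) == 1L) which(P[s, ] > 0) else
        sample.int(3, 1, prob = P[s, ])
    }
    st <- st[seq_len(n)]; du <- du[seq_len(n)]
    aggregate_state_dwells(st, du, censored_end = censored)
  })
}

## Collapse a state-level trajectory into alternating class dwells.
aggregate_state_dwells <- function(states, durations_ms, censored_end = FALSE) {
  cls <- ifelse(states == 3L, "open", "closed")
  r <- rle(cls)
  idx_end <- cumsum(r$lengths)
  idx_start <- idx_end - r$lengths + 1L
  dur <- vapply(seq_along(idx_start), function(i)
    sum(durations_ms[idx_start[i]:idx_end[i]]), numeric(1))
  state <- vapply(seq_along(idx_start), function(i) {
    s <- unique(states[idx_start[i]:idx_end[i]])
    if (length(s) == 1L) s else NA_integer_
  }, integer(1))
  has_cs <- vapply(seq_along(idx_start), function(i)
    any(states[idx_start[i]:idx_end[i]] == 1L), logical(1))
  dwell_sequence(r$values, dur, state = state, has_cs = has_cs,
                 dead_time_ms = 0, censored_end = censored_end)
}

#' Current traces
#'
#' A trace record holds a uniformly sampled single-channel (or macroscopic)
#' current: the sample vector in pA, the sampling rate, the unitary current
#' amplitude, and recording metadata. Openings deflect toward
#' `unitary_amplitude_pA` (negative for inward current at negative holding
#' potentials); the closed level is 0 pA.
#'
#' @param current_pA numeric sample vector (length >= 2, finite).
#' @param sampling_rate_hz sampling rate in Hz.
#' @param unitary_amplitude_pA unitary current step in pA.
#' @param meta list of metadata (noise SD, filter corner, seed, label, ...).
#' @return Object of class `"trace_record"`.
#' @export
trace_record <- function(current_pA, sampling_rate_hz, unitary_amplitude_pA,
                         meta = list()) {
  stopifnot(sampling_rate_hz > 0, length(current_pA) >= 2,
            all(is.finite(current_pA)))
  structure(list(current_pA = current_pA,
                 sampling_rate_hz = sampling_rate_hz,
                 unitary_amplitude_pA = unitary_amplitude_pA,
                 meta = meta),
            class = "trace_record")
}

#' @export
print.trace_record <- function(x, ...) {
  cat(sprintf("Trace: %d samples at %g kHz (%.4g s), unitary amplitude %g pA\n",
              length(x$current_pA), x$sampling_rate_hz / 1000,
              length(x$current_pA) / x$sampling_rate_hz,
              x$unitary_amplitude_pA))
  invisible(x)
}

trace_times_s <- function(trace) {
  (seq_along(trace$current_pA) - 1L) / trace$sampling_rate_hz
}

## Discrete Gaussian filter kernel for corner frequency fc at sampling rate fs.
## Kernel SD in time is 0.1325/fc (the standard single-channel convention
## relating the -3 dB corner of a Gaussian filter to its impulse-response
## width); DC gain exactly 1.
gaussian_kernel <- function(fc_hz, fs_hz) {
  sigma <- 0.1325 / fc_hz * fs_hz     # in samples
  if (sigma < 0.62) {
    ## near-Nyquist corner: three-point approximation keeps variance correct
    h <- max(sigma^2 / 2, 0)
    k <- c(h, 1 - 2 * h, h)
    return(k / sum(k))
  }
  half <- ceiling(5 * sigma)
  i <- (-half):half
  k <- exp(-i^2 / (2 * sigma^2))
  k / sum(k)
}

## Apply the Gaussian filter with edge-replication padding (DC gain 1 at
## boundaries too).
apply_gaussian_filter <- function(x, fc_hz, fs_hz) {
  if (fc_hz >= fs_hz / 2) {
    stop("filter corner frequency must be below the Nyquist frequency")
  }
  k <- gaussian_kernel(fc_hz, fs_hz)
  half <- (length(k) - 1L) / 2L
  if (half == 0) return(x)
  xp <- c(rep(x[1], half), x, rep(x[length(x)], half))
  y <- stats::filter(xp, k, method = "convolution", sides = 2)
  as.numeric(y[(half + 1L):(half + length(x))])
}

#' Render a dwell sequence as a noisy filtered current trace
#'
#' Converts an ideal dwell sequence into a sampled current trace emulating a
#' patch-clamp recording: a piecewise-constant current (closed = 0 pA, open =
#' `unitary_amplitude_pA`), plus additive Gaussian baseline noise, low-pass
#' filtered with a Gaussian filter at the recording corner frequency. Defaults
#' follow common recording practice for these channels: 10 kHz sampling, 1 kHz
#' recording filter, openings as negative deflections (inward current at
#' negative membrane potential).
#'
#' @param dwells a [dwell_sequence()].
#' @param sampling_rate_hz sampling rate (Hz).
#' @param unitary_amplitude_pA open-channel current level (pA).
#' @param noise_sd_pA SD of the additive Gaussian noise before recording
#'   filtering; defaults to 15% of the unitary amplitude.
#' @param filter_fc_hz recording (anti-alias) Gaussian filter corner (Hz);
#'   `NULL` disables filtering. Must be below Nyquist.
#' @param seed optional integer seed.
#' @param label construct label stored in the metadata.
#' @return A [trace_record()].
#' @export
render_trace <- function(dwells, sampling_rate_hz = 10000,
                         unitary_amplitude_pA = -0.7,
                         noise_sd_pA = 0.15 * abs(unitary_amplitude_pA),
                         filter_fc_hz = 1000, seed = NULL, label = NULL) {
  stopifnot(inherits(dwells, "dwell_sequence"), sampling_rate_hz > 0)
  if (!is.null(filter_fc_hz) && filter_fc_hz >= sampling_rate_hz / 2) {
    stop("filter corner frequency must be below the Nyquist frequency")
  }
  with_seed(seed, {
    bounds <- round(cumsum(c(0, dwells$duration_ms)) / 1000 * sampling_rate_hz)
    n_per <- diff(bounds)
    level <- ifelse(dwells$class == "open", unitary_amplitude_pA, 0)
    x <- rep(level, n_per)
    if (length(x) < 2) stop("dwell sequence too short for this sampling rate")
    if (noise_sd_pA > 0) x <- x + stats::rnorm(length(x), 0, noise_sd_pA)
    if (!is.null(filter_fc_hz)) {
      x <- apply_gaussian_filter(x, filter_fc_hz, sampling_rate_hz)
    }
    trace_record(x, sampling_rate_hz, unitary_amplitude_pA,
                 meta = list(noise_sd_pA = noise_sd_pA,
                             recording_filter_fc_hz = filter_fc_hz,
                             seed = seed, label = label))
  })
}

#' Simulate a macroscopic ligand-removal current decay
#'
#' After sudden removal of ligand, each of `n_channels` independent channels
#' leaves the bursting state at `closing_rate_s` with no reopening, so the
#' expected ensemble current decays exponentially with time constant
#' `1/closing_rate_s`. Channels are simulated individually (binomial
#' survival), so finite ensembles show realistic step-like fluctuations.
#'
#' @param n_channels number of active channels at t = 0 (>= 1).
#' @param closing_rate_s rate of leaving the bursting state (1/s).
#' @param unitary_amplitude_pA unitary current (pA).
#' @param sampling_rate_hz sampling rate of the rendered ensemble trace.
#' @param duration_s trace duration; defaults to 6 mean lifetimes.
#' @param noise_sd_pA additive Gaussian noise SD (pA).
#' @param seed optional integer seed.
#' @return A [trace_record()]; metadata records `n_channels` and
#'   `closing_rate_s`.
#' @export
simulate_macroscopic <- function(n_channels, closing_rate_s,
                                 unitary_amplitude_pA = -0.7,
                                 sampling_rate_hz = 1000,
                                 duration_s = 6 / closing_rate_s,
                                 noise_sd_pA = 0, seed = NULL) {
  stopifnot(n_channels >= 1, closing_rate_s > 0)
  with_seed(seed, {
    close_t <- stats::rexp(n_channels, closing_rate_s)
    t <- seq(0, duration_s, by = 1 / sampling_rate_hz)
    surviving <- vapply(t, function(tt) sum(close_t > tt), numeric(1))
    x <- unitary_amplitude_pA * surviving
    if (noise_sd_pA > 0) x <- x + stats::rnorm(length(x), 0, noise_sd_pA)
    trace_record(x, sampling_rate_hz, unitary_amplitude_pA,
                 meta = list(n_channels = n_channels,
                             closing_rate_s = closing_rate_s,
                             noise_sd_pA = noise_sd_pA, seed = seed))
  })
}

#' Superimpose two independent single-channel gating trajectories
#'
#' Builds a two-active-channel test trace: two independent trajectories of the
#' same model rendered and summed. Used to validate the single-active-channel
#' screen (superimposed openings reach twice the unitary amplitude).
#'
#' @inheritParams render_trace
#' @param model a [gating_model()].
#' @param duration_ms per-channel trajectory duration.
#' @return A [trace_record()] whose metadata notes `n_channels = 2`.
#' @export
simulate_two_channel_trace <- function(model, duration_ms,
                                       sampling_rate_hz = 10000,
                                       unitary_amplitude_pA = -0.7,
                                       noise_sd_pA = 0.15 * abs(unitary_amplitude_pA),
                                       filter_fc_hz = 1000, seed = NULL) {
  with_seed(seed, {
    tr1 <- render_trace(sample_trajectory(model, duration_ms = duration_ms),
                        sampling_rate_hz, unitary_amplitude_pA,
                        noise_sd_pA = 0, filter_fc_hz = NULL)
    tr2 <- render_trace(sample_trajectory(model, duration_ms = duration_ms),
                        sampling_rate_hz, unitary_amplitude_pA,
                        noise_sd_pA = 0, filter_fc_hz = NULL)
    n <- min(length(tr1$current_pA), length(tr2$current_pA))
    x <- tr1$current_pA[seq_len(n)] + tr2$current_pA[seq_len(n)]
    if (noise_sd_pA > 0) x <- x + stats::rnorm(n, 0, noise_sd_pA)
    if (!is.null(filter_fc_hz)) {
      x <- apply_gaussian_filter(x, filter_fc_hz, sampling_rate_hz)
    }
    trace_record(x, sampling_rate_hz, unitary_amplitude_pA,
                 meta = list(n_channels = 2, noise_sd_pA = noise_sd_pA,
                             recording_filter_fc_hz = filter_fc_hz, seed = seed))
  })
}

#' Generate a suite of synthetic fixtures for a set of constructs
#'
#' For each construct in the configuration (defined either by explicit rate
#' constants or by target descriptive burst parameters, inverted through
#' [rates_from_burst_stats()]), simulates a gating trajectory, writes the
#' dwell-sequence TSV (and optionally a rendered trace TSV), and writes a
#' manifest recording per-construct seeds and file checksums. Outputs are
#' byte-identical for identical `config` and `seed`.
#'
#' @param config a list (or path to a YAML file) with an element `constructs`:
#'   a named list where each entry has either `rates` + `topology` or
#'   `burst_targets` (named list with `tau_burst_ms`, `tau_interburst_ms`,
#'   `tau_flicker_ms`, `n_flicker`) + `topology`, and optionally `n_events`
#'   (default 5000). Optional top-level `trace` (logical, default FALSE) and
#'   trace settings `sampling_rate_hz`, `noise_sd_pA`, `filter_fc_hz`,
#'   `unitary_amplitude_pA`.
#' @param dir output directory (created if needed).
#' @param seed integer master seed; per-construct seeds are derived from it.
#' @return Invisibly, the manifest list (also written to `manifest.yaml`).
#' @export
make_fixture_suite <- function(config, dir, seed) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config$constructs), length(config$constructs) >= 1)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  want_trace <- isTRUE(config$trace)
  manifest <- list(seed = seed, constructs = list())
  labels <- names(config$constructs)
  for (i in seq_along(labels)) {
    lab <- labels[i]
    cdef <- config$constructs[[lab]]
    model <- construct_model(cdef)
    n_events <- if (is.null(cdef$n_events)) 5000L else as.integer(cdef$n_events)
    cseed <- derive_seed(seed, i)
    dw <- sample_trajectory(model, n_events = n_events, seed = cseed)
    dwell_path <- file.path(dir, paste0(lab, "_dwells.tsv"))
    write_dwells(dw, dwell_path)
    entry <- list(seed = cseed, topology = model$topology,
                  rates = as.list(model$rates),
                  n_events = nrow(dw), dwells = basename(dwell_path))
    if (want_trace) {
      tr <- render_trace(
        dw,
        sampling_rate_hz = config$sampling_rate_hz %||% 10000,
        unitary_amplitude_pA = config$unitary_amplitude_pA %||% -0.7,
        noise_sd_pA = config$noise_sd_pA %||%
          (0.15 * abs(config$unitary_amplitude_pA %||% -0.7)),
        filter_fc_hz = config$filter_fc_hz %||% 1000,
        seed = derive_seed(seed, 1000 + i), label = lab)
      trace_path <- file.path(dir, paste0(lab, "_trace.tsv"))
      write_trace(tr, trace_path)
      entry$trace <- basename(trace_path)
    }
    manifest$constructs[[lab]] <- entry
  }
  files <- sort(setdiff(list.files(dir, full.names = TRUE), file.path(dir, "manifest.yaml")))
  manifest$checksums <- as.list(tools::md5sum(files))
  names(manifest$checksums) <- basename(files)
  yaml::write_yaml(manifest, file.path(dir, "manifest.yaml"))
  invisible(manifest)
}

## Build a gating model from a construct definition (rates or burst targets).
construct_model <- function(cdef) {
  topology <- cdef$topology %||% "cs-o-cf"
  if (!is.null(cdef$rates)) {
    gating_model(topology, unlist(cdef$rates))
  } else if (!is.null(cdef$burst_targets)) {
    bt <- cdef$burst_targets
    rates_from_burst_stats(topology, bt$tau_burst_ms, bt$tau_interburst_ms,
                           bt$tau_flicker_ms, bt$n_flicker)
  } else {
    stop("construct definition needs either 'rates' or 'burst_targets'")
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a
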