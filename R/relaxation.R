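#' Fit a single exponential to a macroscopic current relaxation
#'
#' Non-linear least-squares fit of `A * exp(-(t - t0)/tau) + C` to a
#' macroscopic current decay following ligand removal at `t0`. The fit window
#' starts a configurable dead period after `t0` (default 300 ms) to stay clear
#' of the finite solution-exchange transient; the offset `C` is fitted, not
#' fixed at zero, because leak currents are common in practice. Optionally the
#' trace is pre-normalized by its steady-state (pre-removal) level, which does
#' not affect the fitted time constant.
#'
#' @param trace a [trace_record()] of the ensemble current.
#' @param t0 ligand-removal time (s).
#' @param dead_period_s portion after `t0` excluded from the fit (s).
#' @param normalize divide the trace by the mean level just before `t0`.
#' @return Object of class `"relaxation_fit"`: list with `tau_ms`,
#'   `amplitude_pA`, `offset_pA`, `rms_residual_pA`, `n_points`, `flags`
#'   (character vector; `"non-decaying"` or `"tau-at-bound"` when the fit is
#'   unreliable) and `converged`.
#' @export
fit_relaxation <- function(trace, t0 = 0, dead_period_s = 0.3,
                           normalize = FALSE) {
  stopifnot(inherits(trace, "trace_record"))
  t <- trace_times_s(trace)
  y <- trace$current_pA
  if (normalize) {
    pre <- y[t < t0]
    ref <- if (length(pre) >= 5) mean(pre) else y[1]
    if (abs(ref) < 1e-12) stop("cannot normalize: zero steady-state level")
    y <- y / ref
  }
  keep <- t >= t0 + dead_period_s
  if (sum(keep) < 10) stop("fewer than 10 points in the fit window")
  tt <- t[keep] - t0
  yy <- y[keep]
  n <- length(yy)
  flags <- character(0)
  ## starting values: offset from the tail, log-linear regression for tau
  C0 <- mean(yy[tt >= stats::quantile(tt, 0.9)])
  A0 <- yy[1] - C0
  span <- max(tt) - min(tt)
  tau0 <- span / 3
  dy <- yy - C0
  pos <- if (A0 >= 0) dy > abs(A0) * 1e-3 else dy < -abs(A0) * 1e-3
  if (sum(pos) >= 10) {
    lf <- stats::lm(log(abs(dy[pos])) ~ tt[pos])
    sl <- stats::coef(lf)[2]
    if (is.finite(sl) && sl < 0) tau0 <- min(max(-1 / sl, span / 1e4), span * 10)
  }
  fit <- tryCatch(
    minpack.lm::nlsLM(yy ~ A * exp(-tt / tau) + C,
                      start = list(A = A0, tau = tau0, C = C0),
                      lower = c(-Inf, span * 1e-6, -Inf),
                      upper = c(Inf, span * 1e3, Inf),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    flags <- c(flags, "non-decaying")
    out <- list(tau_ms = NA_real_, amplitude_pA = NA_real_,
                offset_pA = NA_real_, rms_residual_pA = stats::sd(yy),
                n_points = n, flags = flags, converged = FALSE)
    class(out) <- "relaxation_fit"
    return(out)
  }
  cf <- stats::coef(fit)
  res <- stats::resid(fit)
  ## a genuine decay must have amplitude of the same sign as the current and
  ## clearly exceed the residual noise
  if (abs(cf[["A"]]) < 3 * stats::sd(res) + 1e-12) flags <- c(flags, "non-decaying")
  if (cf[["tau"]] <= span * 2e-6 || cf[["tau"]] >= span * 500) {
    flags <- c(flags, "tau-at-bound")
  }
  out <- list(tau_ms = 1000 * cf[["tau"]], amplitude_pA = cf[["A"]],
              offset_pA = cf[["C"]],
              rms_residual_pA = sqrt(mean(res^2)), n_points = n,
              flags = flags, converged = length(flags) == 0)
  class(out) <- "relaxation_fit"
  out
}

#' @export
print.relaxation_fit <- function(x, ...) {
  cat(sprintf("Single-exponential relaxation fit: tau = %.4g ms (A = %.3g, C = %.3g)\n",
              x$tau_ms, x$amplitude_pA, x$offset_pA))
  cat(sprintf("  %d points, RMS residual %.3g%s\n", x$n_points,
              x$rms_residual_pA,
              if (length(x$flags)) paste0("  [", paste(x$flags, collapse = ", "), "]")
              else ""))
  invisible(x)
}

#' Convert a relaxation time constant to a closing rate
#'
#' For a non-hydrolytic background without reopening after ligand removal,
#' the macroscopic relaxation time constant equals the mean burst duration,
#' so the closing (bursting-state exit) rate is its reciprocal.
#'
#' @param fit a `"relaxation_fit"` (or a tau in ms).
#' @return Closing rate in 1/s.
#' @export
tau_to_closing_rate <- function(fit) {
  tau_ms <- if (inherits(fit, "relaxation_fit")) fit$tau_ms else fit
  stopifnot(is.finite(tau_ms), tau_ms > 0)
  1000 / tau_ms
}
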