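## Likelihood of an alternating dwell sequence under an aggregated three-state
## model. With a single open state the HJC product of per-dwell matrices
## telescopes into scalar per-dwell terms:
##
##   open dwell t:    R_O(t - td) * exp(q_AA td)        (exit row Q_AF is
##                                                        consumed by the next
##                                                        closed term)
##   closed dwell s:  Q_AF R_F(s - td) e^{Q_FF td} Q_FA
##
## plus boundary corrections for a leading closed dwell (probability-
## normalized entry vector) and a trailing open dwell (terminal unit vector).

## Scalar per-dwell term machinery for one model and dead time. Returns
## closures evaluating the open scalar R_O(u) and the closed scalar
## Q_AF R_F(u) M_F, vectorized over excess durations u (seconds).
dwell_term_fns <- function(model, dead_time_ms) {
  b <- class_blocks(model)
  td <- dead_time_ms / 1000
  if (td == 0) {
    eF <- eigen2(b$QFF)
    wl <- as.numeric(b$QAF %*% eF$vectors)
    wr <- as.numeric(eF$inv %*% b$QFA)
    cf <- wl * wr
    lam <- eF$values
    qAA <- b$QAA[1, 1]
    list(open = function(u) exp(qAA * u),
         closed = function(u) {
           acc <- 0
           for (i in seq_along(cf)) acc <- acc + cf[i] * exp(lam[i] * u)
           acc
         },
         qAA = qAA, sumQAF = sum(b$QAF), td = 0)
  } else {
    mcO <- me_class(model, "open", dead_time_ms)
    mcF <- me_class(model, "closed", dead_time_ms)
    MF <- expm_small(b$QFF, td) %*% b$QFA
    list(open = function(u) me_scalar_eval(mcO, u, matrix(1, 1, 1),
                                           matrix(1, 1, 1)),
         closed = function(u) me_scalar_eval(mcF, u, b$QAF, MF),
         qAA = b$QAA[1, 1], sumQAF = sum(b$QAF), td = td)
  }
}

#' Log-likelihood of a dwell sequence under a gating model
#'
#' Computes the log probability density of an observed alternating
#' closed/open dwell sequence under a three-state aggregated Markov model,
#' with missed-event correction for a fixed dead time: the likelihood is that
#' of the full sequence (not of independent dwell histograms), evaluated with
#' the exact-plus-asymptotic apparent-dwell machinery described in the
#' package vignette. With `dead_time_ms = 0` it reduces to the ideal
#' aggregated-Markov sequence likelihood.
#'
#' The terminal dwell of a record is censored by the end of the recording;
#' by default it is dropped. With `include_censored = TRUE` it instead
#' contributes its survivor probability.
#'
#' @param model a [gating_model()].
#' @param dwells a [dwell_sequence()] whose `dead_time_ms` attribute matches
#'   `dead_time_ms`.
#' @param dead_time_ms the imposed dead time (ms).
#' @param include_censored include the censored terminal dwell as a survivor
#'   term instead of dropping it.
#' @return The log-likelihood (dimensionless).
#' @export
dwell_loglik <- function(model, dwells, dead_time_ms = attr(dwells, "dead_time_ms"),
                         include_censored = FALSE) {
  stopifnot(inherits(model, "gating_model"), inherits(dwells, "dwell_sequence"))
  if (abs(attr(dwells, "dead_time_ms") - dead_time_ms) > 1e-9) {
    stop("dead time mismatch: dwells carry ", attr(dwells, "dead_time_ms"),
         " ms, likelihood asked for ", dead_time_ms, " ms")
  }
  cls <- dwells$class
  dur_s <- dwells$duration_ms / 1000
  n <- length(cls)
  censored <- isTRUE(attr(dwells, "censored_end"))
  fns <- dwell_term_fns(model, dead_time_ms)
  td <- fns$td
  u <- pmax(dur_s - td, 0)

  use <- rep(TRUE, n)
  if (censored && !include_censored) use[n] <- FALSE
  if (!any(use)) stop("no usable dwells after dropping the censored terminal event")
  open_idx <- which(cls == "open" & use)
  closed_idx <- which(cls == "closed" & use)
  last_is_censored <- censored && include_censored

  ll <- 0
  if (length(open_idx)) {
    ro <- fns$open(u[open_idx])
    ll <- ll + sum(log(pmax(ro, 1e-300))) + length(open_idx) * fns$qAA * td
  }
  if (length(closed_idx)) {
    if (last_is_censored && cls[n] == "closed") {
      ## survivor term for the censored closed dwell: entry row, no exit
      ci <- setdiff(closed_idx, n)
      fc <- fns$closed(u[ci])
      ll <- ll + sum(log(pmax(fc, 1e-300)))
      b <- class_blocks(model)
      mcF <- if (td > 0) me_class(model, "closed", dead_time_ms) else NULL
      surv <- if (td > 0) {
        as.numeric(me_scalar_eval(mcF, u[n], b$QAF,
                                  expm_small(b$QFF, td) %*% matrix(1, 2, 1)))
      } else {
        as.numeric(b$QAF %*% expm_small(b$QFF, u[n]) %*% matrix(1, 2, 1))
      }
      ll <- ll + log(pmax(surv, 1e-300))
    } else {
      fc <- fns$closed(u[closed_idx])
      ll <- ll + sum(log(pmax(fc, 1e-300)))
    }
  }
  ## boundary corrections
  if (cls[1] == "closed" && use[1]) ll <- ll - log(fns$sumQAF)
  nlast <- max(which(use))
  if (cls[nlast] == "open" && !(last_is_censored && nlast == n)) {
    ll <- ll + log(fns$sumQAF)
  }
  as.numeric(ll)
}

#' Apparent dwell-time probability density
#'
#' Density of apparent (dead-time-regularized) dwell durations of one
#' conductance class, normalized over `t >= dead_time_ms`. (The per-dwell
#' factors of the sequence likelihood normalize jointly over the whole
#' alternating record, not dwell-by-dwell; the marginal density here carries
#' its own explicit normalization.) Used for overlay plots and for
#' validating the missed-event correction against simulated data.
#'
#' @param model a [gating_model()].
#' @param class `"open"` or `"closed"`.
#' @param t_ms vector of durations (ms) at which to evaluate.
#' @param dead_time_ms dead time (ms).
#' @return Density values (per ms).
#' @export
apparent_dwell_density <- function(model, class = c("open", "closed"), t_ms,
                                   dead_time_ms) {
  class <- match.arg(class)
  fns <- dwell_term_fns(model, dead_time_ms)
  u <- pmax(t_ms / 1000 - fns$td, 0)
  if (class == "open") {
    dens <- fns$open(u)
    norm <- if (fns$td == 0) 1 / (-fns$qAA) else
      me_survivor_integral(model, "open", dead_time_ms)
  } else {
    dens <- fns$closed(u)
    norm <- if (fns$td == 0) fns$sumQAF else
      me_survivor_integral(model, "closed", dead_time_ms)
  }
  dens <- dens / norm
  dens[t_ms / 1000 < fns$td] <- 0
  dens / 1000   # per ms
}

## integral over u of the scalar dwell term (grid part plus asymptotic tail),
## i.e. the normalizer of the marginal apparent dwell density
me_survivor_integral <- function(model, class, dead_time_ms) {
  b <- class_blocks(model)
  mc <- me_class(model, class, dead_time_ms)
  if (class == "open") {
    wl <- matrix(1, 1, 1); wr <- matrix(1, 1, 1)
  } else {
    wl <- b$QAF
    wr <- expm_small(b$QFF, mc$td) %*% b$QFA
  }
  g <- me_scalar_eval(mc, mc$u_grid, wl, wr)
  h <- mc$h
  m0 <- h * (sum(g) - (g[1] + g[length(g)]) / 2)
  w <- as.numeric(outer(as.numeric(wl), as.numeric(wr)))
  u_max <- mc$u_grid[length(mc$u_grid)]
  for (i in seq_along(mc$asym$s)) {
    s <- mc$asym$s[i]
    co <- sum(w * as.numeric(mc$asym$A[[i]]))
    m0 <- m0 - co * exp(s * u_max) / s
  }
  m0
}

## Deterministic EM fit of a two-component exponential mixture (used only to
## initialize the ML fit and to seed the flicker/interburst split).
em2exp <- function(x, max_iter = 300, tol = 1e-8) {
  stopifnot(length(x) >= 4)
  tau1 <- stats::quantile(x, 0.35, names = FALSE)
  tau2 <- mean(x[x >= stats::quantile(x, 0.85, names = FALSE)])
  if (tau2 <= tau1 * 1.5) tau2 <- tau1 * 10
  w1 <- 0.7
  ll_old <- -Inf
  for (i in seq_len(max_iter)) {
    d1 <- w1 / tau1 * exp(-x / tau1)
    d2 <- (1 - w1) / tau2 * exp(-x / tau2)
    tot <- d1 + d2
    r1 <- d1 / tot
    w1 <- mean(r1)
    tau1 <- sum(r1 * x) / sum(r1)
    tau2 <- sum((1 - r1) * x) / sum(1 - r1)
    ll <- sum(log(tot))
    if (abs(ll - ll_old) < tol) break
    ll_old <- ll
  }
  if (tau1 > tau2) {
    tmp <- tau1; tau1 <- tau2; tau2 <- tmp; w1 <- 1 - w1
  }
  list(tau_fast = tau1, tau_slow = tau2, w_fast = w1)
}

#' Critical duration with equal misclassified event fractions
#'
#' For a two-component exponential closed-dwell mixture (areas `area_f`,
#' `area_s`; time constants `tau_f_ms < tau_s_ms`), returns the critical
#' duration `t_crit` at which the expected number of fast (flickery) events
#' longer than `t_crit` equals the expected number of slow (interburst)
#' events shorter than it:
#' `area_f * exp(-t/tau_f) = area_s * (1 - exp(-t/tau_s))`.
#'
#' @param tau_f_ms,tau_s_ms component time constants (ms).
#' @param area_f,area_s component areas (fractions of events).
#' @return `t_crit` in ms.
#' @export
t_crit_equal_misclassification <- function(tau_f_ms, tau_s_ms, area_f, area_s) {
  stopifnot(tau_f_ms > 0, tau_s_ms > tau_f_ms, area_f > 0, area_s > 0)
  f <- function(t) area_f * exp(-t / tau_f_ms) - area_s * (1 - exp(-t / tau_s_ms))
  stats::uniroot(f, c(tau_f_ms * 1e-3, tau_s_ms * 50), tol = 1e-12)$root
}

## Closed-sojourn mixture components of a model (ideal, no dead time):
## entry-probability-weighted biexponential. Returns tau (ms) and areas,
## fast component first.
closed_dwell_mixture <- function(model) {
  b <- class_blocks(model)
  eF <- eigen2(b$QFF)
  phiF <- b$QAF / sum(b$QAF)
  wl <- as.numeric(phiF %*% eF$vectors)
  wr <- as.numeric(eF$inv %*% (-b$QFF) %*% matrix(1, 2, 1))
  coefs <- wl * wr                      # f(t) = sum coefs_i exp(lambda_i t)
  lam <- eF$values
  area <- -coefs / lam
  ord <- order(lam)                     # most negative eigenvalue = fastest
  data.frame(tau_ms = -1000 / lam[ord], area = area[ord])
}

## Method-of-moments initialization: biexponential split of closed dwells,
## empirical burst statistics at the implied t_crit, inversion to rates.
moments_init <- function(dwells, topology) {
  closed <- dwells$duration_ms[dwells$class == "closed"]
  open <- dwells$duration_ms[dwells$class == "open"]
  em <- em2exp(closed)
  tc <- tryCatch(
    t_crit_equal_misclassification(em$tau_fast, em$tau_slow,
                                   em$w_fast, 1 - em$w_fast),
    error = function(e) sqrt(em$tau_fast * em$tau_slow))
  es <- empirical_burst_stats(dwells, t_crit_ms = tc)
  tb <- es$tau_burst_ms; ti <- es$tau_interburst_ms
  tf <- if (is.na(es$tau_flicker_ms)) em$tau_fast else es$tau_flicker_ms
  nf <- max(es$n_flicker, 0.02)
  m_o <- mean(open)
  ## feasibility guard: mean open time per burst must stay positive
  nf_feas <- (tb - m_o) / (tf + m_o)
  nf <- max(min(nf, nf_feas), 0.02)
  ti <- max(ti, tf * 2)
  rates_from_burst_stats(topology, tb, ti, tf, nf)
}

#' Fit a three-state gating model to a dwell sequence by maximum likelihood
#'
#' Maximizes the missed-event-corrected sequence likelihood
#' ([dwell_loglik()]) over the four microscopic rate constants of the chosen
#' topology, parameterized on the log scale (positivity without constraints).
#' Optimization is deterministic: a method-of-moments initialization (unless
#' `init` is supplied), a Nelder-Mead stage, then a BFGS polish; standard
#' errors of the log rates come from the curvature (observed information) at
#' the optimum.
#'
#' @param dwells a [dwell_sequence()], dead-time-regularized.
#' @param topology `"cs-o-cf"` or `"cs-cf-o"`.
#' @param dead_time_ms dead time of the record (ms); defaults to the
#'   sequence's attribute.
#' @param init optional named vector of starting rate constants (1/s).
#' @param include_censored see [dwell_loglik()].
#' @param min_events refuse to fit records with fewer events (curvature
#'   standard errors are meaningless for very short records).
#' @param control list: `reltol` (default 1e-8), `maxit` (default 500).
#' @return Object of class `"dwellfit"`; see [print.dwellfit()],
#'   [summary.dwellfit()], [coef.dwellfit()], [vcov.dwellfit()],
#'   [simulate.dwellfit()].
#' @examples
#' m <- gating_model("cs-o-cf", c(k13 = 0.5, k31 = 2, k32 = 10, k23 = 100))
#' dw <- sample_trajectory(m, n_events = 2000, seed = 1)
#' fit <- dwellfit(dw, "cs-o-cf", dead_time_ms = 0)
#' coef(fit)
#' @export
dwellfit <- function(dwells, topology = c("cs-o-cf", "cs-cf-o"),
                     dead_time_ms = attr(dwells, "dead_time_ms"),
                     init = NULL, include_censored = FALSE,
                     min_events = 50, control = list()) {
  topology <- match.arg(topology)
  stopifnot(inherits(dwells, "dwell_sequence"))
  n_events <- nrow(dwells)
  if (n_events < min_events) {
    stop("only ", n_events, " events; at least ", min_events,
         " required for a meaningful fit")
  }
  reltol <- control$reltol %||% 1e-8
  maxit <- control$maxit %||% 500
  keys <- rate_keys(topology)
  mom_model <- tryCatch(moments_init(dwells, topology), error = function(e) NULL)
  init_model <- if (is.null(init)) {
    if (is.null(mom_model)) stop("method-of-moments initialization failed; ",
                                 "supply init")
    mom_model
  } else {
    gating_model(topology, init)
  }
  ## With a dead time the likelihood has spurious aliases in which ultrafast
  ## gating (state lifetimes far below the dead time) mimics the observed
  ## apparent process. Those solutions are unidentifiable at the recording
  ## bandwidth, so rates are capped at 4 / dead_time (mean per-transition
  ## waiting times of at least a quarter dead time).
  log_cap <- if (dead_time_ms > 0) log(4000 / dead_time_ms) else 23
  negll <- function(lp) {
    if (any(!is.finite(lp)) || any(lp < -23) || any(lp > log_cap)) return(1e10)
    m <- gating_model(topology, stats::setNames(exp(lp), keys))
    v <- tryCatch(-dwell_loglik(m, dwells, dead_time_ms, include_censored),
                  error = function(e) 1e10)
    if (!is.finite(v)) 1e10 else v
  }
  ## optimize from the requested start and (always) from the data-driven
  ## method-of-moments start; keep the better optimum. This makes the fit
  ## insensitive to poor user-supplied initializations.
  clip <- function(lp) pmin(pmax(lp, -22.9), log_cap - 0.1)
  starts <- list(clip(log(init_model$rates[keys])))
  if (!is.null(init) && !is.null(mom_model)) {
    starts <- c(starts, list(clip(log(mom_model$rates[keys]))))
  }
  best <- NULL
  for (par0 in starts) {
    cand <- stats::optim(par0, negll, method = "BFGS",
                         control = list(maxit = maxit, reltol = reltol))
    ## Nelder-Mead polish catches BFGS stalls on the flat low-Po ridges;
    ## iterate only while the optimum keeps moving
    for (round in 1:3) {
      on <- stats::optim(cand$par, negll, method = "Nelder-Mead",
                         control = list(maxit = maxit, reltol = reltol))
      improved <- cand$value - on$value
      if (on$value < cand$value) cand <- on
      if (improved < 1e-7) break
      ob <- stats::optim(cand$par, negll, method = "BFGS",
                         control = list(maxit = maxit, reltol = reltol))
      if (ob$value < cand$value) cand <- ob
    }
    if (is.null(best) || cand$value < best$value) best <- cand
  }
  H <- tryCatch(stats::optimHess(best$par, negll), error = function(e) NULL)
  se <- rep(NA_real_, 4)
  if (!is.null(H)) {
    V <- tryCatch(solve(H), error = function(e) NULL)
    if (!is.null(V) && all(diag(V) > 0)) se <- sqrt(diag(V))
  }
  names(se) <- keys
  rates <- stats::setNames(exp(best$par), keys)
  boundary <- any(log(rates) > log_cap - 0.05) || any(rates < 1e-5)
  converged <- (best$convergence == 0) && !boundary && all(is.finite(se))
  model <- gating_model(topology, rates)
  structure(
    list(model = model, topology = topology, rates = rates,
         se_log_rates = se,
         vcov_log = if (!is.null(H)) tryCatch(solve(H), error = function(e) NULL) else NULL,
         logLik = -best$value, n_events = n_events,
         dead_time_ms = dead_time_ms, converged = converged,
         boundary = boundary, include_censored = include_censored,
         init_rates = init_model$rates,
         optim = list(counts = best$counts, convergence = best$convergence,
                      reltol = reltol, maxit = maxit)),
    class = "dwellfit")
}

#' @describeIn dwellfit Print fitted rates, standard errors and fit status.
#' @param x,object a `"dwellfit"` object.
#' @param ... unused.
#' @export
print.dwellfit <- function(x, ...) {
  cat(sprintf("Maximum-likelihood gating fit (%s), dead time %g ms\n",
              x$topology, x$dead_time_ms))
  cat(sprintf("  %d events, log-likelihood %.2f%s%s\n", x$n_events, x$logLik,
              if (x$converged) "" else "  [NOT CONVERGED]",
              if (x$boundary) "  [BOUNDARY RATES]" else ""))
  tab <- data.frame(rate_s = signif(x$rates, 4),
                    se_log = signif(x$se_log_rates, 3))
  print(tab)
  invisible(x)
}

#' @describeIn dwellfit Fitted rates with approximate Wald intervals and the
#'   implied descriptive burst parameters.
#' @export
summary.dwellfit <- function(object, ...) {
  ci_lo <- exp(log(object$rates) - 1.96 * object$se_log_rates)
  ci_hi <- exp(log(object$rates) + 1.96 * object$se_log_rates)
  out <- list(fit = object,
              rates = data.frame(rate_s = object$rates,
                                 se_log = object$se_log_rates,
                                 ci_lo = ci_lo, ci_hi = ci_hi),
              burst = burst_stats(object$model))
  class(out) <- "summary.dwellfit"
  out
}

#' @export
print.summary.dwellfit <- function(x, ...) {
  print(x$fit)
  cat("\nImplied descriptive parameters:\n")
  print(x$burst)
  invisible(x)
}

#' @describeIn dwellfit Fitted rate constants (1/s).
#' @export
coef.dwellfit <- function(object, ...) object$rates

#' @describeIn dwellfit Log-likelihood with attributes `df` and `nobs`.
#' @export
logLik.dwellfit <- function(object, ...) {
  structure(object$logLik, df = 4L, nobs = object$n_events,
            class = "logLik")
}

#' @describeIn dwellfit Covariance of the log rate constants (curvature at
#'   the optimum).
#' @export
vcov.dwellfit <- function(object, ...) {
  V <- object$vcov_log
  if (is.null(V)) stop("no invertible curvature at the optimum")
  dimnames(V) <- list(names(object$rates), names(object$rates))
  V
}

#' @describeIn dwellfit Simulate dwell sequences from the fitted model
#'   (dead-time regularized like the data).
#' @param nsim number of sequences.
#' @param seed optional integer seed.
#' @param n_events events per simulated sequence (default: as in the data).
#' @export
simulate.dwellfit <- function(object, nsim = 1, seed = NULL,
                              n_events = object$n_events, ...) {
  out <- lapply(seq_len(nsim), function(i) {
    dw <- sample_trajectory(object$model, n_events = n_events,
                            seed = derive_seed(seed, i))
    if (object$dead_time_ms > 0) impose_dead_time(dw, object$dead_time_ms)
    else dw
  })
  if (nsim == 1) out[[1]] else out
}

#' @describeIn dwellfit Dwell-time histograms (log-binned) with the fitted
#'   apparent densities overlaid.
#' @param dwells the fitted dwell sequence (for the histograms).
#' @export
plot.dwellfit <- function(x, dwells, ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  for (cl in c("closed", "open")) {
    d <- dwells$duration_ms[dwells$class == cl]
    lx <- log10(d)
    h <- graphics::hist(lx, breaks = 30, plot = FALSE)
    grid_t <- 10^seq(min(lx), max(lx), length.out = 300)
    dens <- apparent_dwell_density(x$model, cl, grid_t, x$dead_time_ms)
    ## density per log10 duration
    dens_log <- dens * grid_t * log(10)
    graphics::plot(h, freq = FALSE, main = paste(cl, "dwells"),
                   xlab = "log10 duration (ms)")
    graphics::lines(log10(grid_t), dens_log, col = 2, lwd = 2)
  }
  invisible(x)
}

#' Label closed dwells as flickery or interburst
#'
#' Uses the fitted model's closed-dwell mixture (two exponential components)
#' to choose the critical duration that equalizes misclassified event
#' fractions between the components ([t_crit_equal_misclassification()]),
#' then labels every closed event by comparison with it. Refuses when the two
#' closed components are separated by less than 5-fold (no reliable
#' discrimination).
#'
#' @param dwells a [dwell_sequence()].
#' @param fit a `"dwellfit"` object or a [gating_model()].
#' @return Factor of length `nrow(dwells)` with levels `flicker`,
#'   `interburst` (`NA` for open events); attribute `t_crit_ms` holds the
#'   critical duration.
#' @export
classify_closed_dwells <- function(dwells, fit) {
  model <- if (inherits(fit, "dwellfit")) fit$model else fit
  stopifnot(inherits(model, "gating_model"))
  mx <- closed_dwell_mixture(model)
  sep <- mx$tau_ms[2] / mx$tau_ms[1]
  if (!is.finite(sep) || sep < 5) {
    stop("closed dwell components separated only ", signif(sep, 3),
         "-fold (< 5): flickery and interburst closures not discriminable")
  }
  tc <- t_crit_equal_misclassification(mx$tau_ms[1], mx$tau_ms[2],
                                       mx$area[1], mx$area[2])
  lab <- rep(NA_character_, nrow(dwells))
  closed <- dwells$class == "closed"
  lab[closed] <- ifelse(dwells$duration_ms[closed] >= tc,
                        "interburst", "flicker")
  structure(factor(lab, levels = c("flicker", "interburst")),
            t_crit_ms = tc)
}
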