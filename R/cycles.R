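#' Estimated kinetic or equilibrium quantities
#'
#' A corner of a thermodynamic mutant cycle: a measured rate constant,
#' equilibrium constant or mean dwell time, as mean with standard error over
#' `n` independent patches.
#'
#' @param mean positive point estimate.
#' @param sem standard error of the mean (>= 0).
#' @param n number of independent patches.
#' @param kind `"rate"` (1/s), `"equilibrium_constant"` (dimensionless) or
#'   `"dwell_time"` (ms).
#' @param label optional construct label.
#' @return Object of class `"estimated_quantity"`.
#' @export
estimated_quantity <- function(mean, sem = 0, n = 1,
                               kind = c("rate", "equilibrium_constant",
                                        "dwell_time"),
                               label = NULL) {
  kind <- match.arg(kind)
  stopifnot(is.finite(mean), mean > 0, sem >= 0, n >= 1)
  structure(list(mean = mean, sem = sem, n = n, kind = kind, label = label),
            class = "estimated_quantity")
}

#' @export
print.estimated_quantity <- function(x, ...) {
  unit <- switch(x$kind, rate = "1/s", equilibrium_constant = "",
                 dwell_time = "ms")
  cat(sprintf("%s%.4g +/- %.3g %s (%s, n = %d)\n",
              if (is.null(x$label)) "" else paste0(x$label, ": "),
              x$mean, x$sem, unit, x$kind, x$n))
  invisible(x)
}

## Mean dwell times enter log-ratio energetics as reciprocal rates;
## ln(1/tau) = -ln(tau), so the coefficient of variation (and hence the
## propagated SEM) carries over unchanged.
as_rate <- function(q) {
  if (q$kind == "rate") return(q)
  if (q$kind == "dwell_time") {
    r <- 1000 / q$mean
    return(estimated_quantity(r, r * q$sem / q$mean, q$n, "rate", q$label))
  }
  stop("cannot interpret an equilibrium constant as a rate")
}

#' Standard error of a log ratio by second-order propagation
#'
#' Treats both quantities as independent normally distributed estimates and
#' propagates their uncertainty into `ln(q1/q2)` by a second-order Taylor
#' expansion of the moments of `ln` of a normal variable: with `c = s/m`,
#' `Var[ln X] ~ c^2 + (5/2) c^4` per variable (added in quadrature), with the
#' mean shift `E[ln X] - ln m ~ -c^2/2 - (3/4) c^4` returned as attribute
#' `mean_shift` (of `ln(q1/q2)`). The `c^4` coefficients follow from the
#' fourth-order expansion of `ln(1 + cZ)` for standard normal `Z` and are
#' validated against a large Monte-Carlo oracle in the test suite. When
#' either coefficient of variation reaches 0.5 the expansion is unreliable;
#' a seeded Monte-Carlo estimate (normal draws, non-positive values
#' rejected) is used instead, with a warning.
#'
#' @param q1,q2 [estimated_quantity()] objects (independent).
#' @param n_mc Monte-Carlo draws for the fallback.
#' @param seed seed for the fallback draws.
#' @return The SEM of `ln(q1/q2)`, with attribute `mean_shift` and attribute
#'   `method` (`"second-order"` or `"monte-carlo"`).
#' @export
propagate_sem_log_ratio <- function(q1, q2, n_mc = 1e6, seed = 1) {
  stopifnot(inherits(q1, "estimated_quantity"),
            inherits(q2, "estimated_quantity"))
  cv1 <- q1$sem / q1$mean
  cv2 <- q2$sem / q2$mean
  if (cv1 >= 0.5 || cv2 >= 0.5) {
    warning("coefficient of variation >= 0.5: second-order expansion ",
            "unreliable, using Monte-Carlo propagation")
    sem <- with_seed(seed, {
      x1 <- stats::rnorm(n_mc, q1$mean, q1$sem)
      x2 <- stats::rnorm(n_mc, q2$mean, q2$sem)
      ok <- x1 > 0 & x2 > 0
      lr <- log(x1[ok] / x2[ok])
      c(stats::sd(lr), mean(lr) - log(q1$mean / q2$mean))
    })
    return(structure(sem[1], mean_shift = sem[2], method = "monte-carlo"))
  }
  v <- cv1^2 + 2.5 * cv1^4 + cv2^2 + 2.5 * cv2^4
  shift <- (-cv1^2 / 2 - 0.75 * cv1^4) - (-cv2^2 / 2 - 0.75 * cv2^4)
  structure(sqrt(v), mean_shift = shift, method = "second-order")
}

#' Mutation-induced change in a free-enthalpy barrier height
#'
#' For a transition with rate `r` over a barrier, a mutation changing the
#' rate to `r'` changes the barrier height (relative to the source ground
#' state) by `ddG = -kT ln(r'/r)`. Energies are reported as dimensionless
#' multiples of kT. Mean dwell times may be supplied; they enter as
#' reciprocal rates.
#'
#' @param rate_bg,rate_mut [estimated_quantity()] of kind `"rate"` (or
#'   `"dwell_time"`) for the background and mutant construct.
#' @return List of class `"ddg"`: `ddg_kT`, `sem_kT`, `kindof = "barrier"`.
#' @export
ddg_barrier <- function(rate_bg, rate_mut) {
  r1 <- as_rate(rate_bg); r2 <- as_rate(rate_mut)
  sem <- propagate_sem_log_ratio(r2, r1)
  structure(list(ddg_kT = -log(r2$mean / r1$mean), sem_kT = as.numeric(sem),
                 kindof = "barrier"),
            class = "ddg")
}

#' Mutation-induced change in a ground-state free-enthalpy difference
#'
#' For two ground states connected by an equilibrium constant `K`, a mutation
#' changing it to `K'` changes the free-enthalpy difference by
#' `ddG = -kT ln(K'/K)` (in kT units).
#'
#' @param keq_bg,keq_mut [estimated_quantity()] of kind
#'   `"equilibrium_constant"`.
#' @return List of class `"ddg"`: `ddg_kT`, `sem_kT`,
#'   `kindof = "equilibrium"`.
#' @export
ddg_equilibrium <- function(keq_bg, keq_mut) {
  stopifnot(keq_bg$kind == "equilibrium_constant",
            keq_mut$kind == "equilibrium_constant")
  sem <- propagate_sem_log_ratio(keq_mut, keq_bg)
  structure(list(ddg_kT = -log(keq_mut$mean / keq_bg$mean),
                 sem_kT = as.numeric(sem), kindof = "equilibrium"),
            class = "ddg")
}

#' @export
print.ddg <- function(x, ...) {
  cat(sprintf("ddG(%s) = %.3g +/- %.3g kT\n", x$kindof, x$ddg_kT, x$sem_kT))
  invisible(x)
}

#' Thermodynamic double-mutant cycle
#'
#' Four constructs — background, two single mutants and the double mutant —
#' with the same measured quantity at each corner. Non-additivity of the two
#' mutations' effects quantifies the change, between gating states, of the
#' interaction between the two mutated positions.
#'
#' @param bg,mutA,mutB,mutAB [estimated_quantity()] corners, all of the same
#'   kind (dwell times are accepted alongside rates and are converted).
#' @param transition gating-step label, e.g. `"B->T"`, `"IB->T"`, `"Cf->O"`.
#' @return Object of class `"mutant_cycle"`.
#' @export
mutant_cycle <- function(bg, mutA, mutB, mutAB, transition = "") {
  corners <- list(bg = bg, mutA = mutA, mutB = mutB, mutAB = mutAB)
  stopifnot(all(vapply(corners, inherits, TRUE, "estimated_quantity")))
  kinds <- vapply(corners, function(q) q$kind, "")
  kinds[kinds == "dwell_time"] <- "rate"
  if (length(unique(kinds)) != 1) {
    stop("all four corners must hold the same kind of quantity")
  }
  structure(list(corners = corners, transition = transition,
                 kindof = unique(kinds)),
            class = "mutant_cycle")
}

#' Interaction free energy of a double-mutant cycle
#'
#' The interaction free energy is the difference between the mutation-induced
#' free-enthalpy changes along two parallel sides of the cycle:
#' `ddG_int = ddG(mutA | background) - ddG(mutA | mutB background)`, with
#' each side computed by [ddg_barrier()] (rate corners) or
#' [ddg_equilibrium()] (equilibrium-constant corners). The reported sign is
#' oriented so that it measures the change in interaction strength in the
#' probed *ground* state: for rate-based (barrier) cycles each side enters as
#' `+kT ln(r'/r)` (source-state stabilization relative to the barrier), for
#' equilibrium cycles as `-kT ln(K'/K)`. With this single orientation, loss
#' of a state-selective stabilizing contact gives a positive `ddG_int` in
#' both kinds of cycle. Computing the difference along the two horizontal
#' sides or the two vertical sides gives identical results (algebraic cycle
#' closure).
#'
#' The SEM combines all four corners' coefficients of variation in
#' quadrature (second-order terms included); the p-value is from a two-sided
#' t statistic `ddG_int / SEM` with Welch-Satterthwaite degrees of freedom
#' over the four corner groups.
#'
#' @param cycle a [mutant_cycle()].
#' @return Object of class `"interaction_energy"`: `ddg_int_kT`, `sem_kT`,
#'   `p_value`, `df`, `transition`, `sides` (the two per-side `ddG` values).
#' @export
interaction_energy <- function(cycle) {
  stopifnot(inherits(cycle, "mutant_cycle"))
  co <- lapply(cycle$corners, function(q)
    if (q$kind == "dwell_time") as_rate(q) else q)
  if (cycle$kindof == "rate") {
    side1 <- ddg_barrier(co$bg, co$mutA)
    side2 <- ddg_barrier(co$mutB, co$mutAB)
    orient <- -1   # report +kT ln(r'/r): source ground-state stabilization
  } else {
    side1 <- ddg_equilibrium(co$bg, co$mutA)
    side2 <- ddg_equilibrium(co$mutB, co$mutAB)
    orient <- 1
  }
  ddg_int <- orient * (side1$ddg_kT - side2$ddg_kT)
  cvv <- vapply(co, function(q) {
    cv <- q$sem / q$mean
    cv^2 + 2.5 * cv^4
  }, numeric(1))
  sem <- sqrt(sum(cvv))
  ns <- vapply(co, function(q) q$n, numeric(1))
  if (sem > 0 && all(ns >= 2)) {
    df <- sum(cvv)^2 / sum(cvv^2 / (ns - 1))
    p <- 2 * stats::pt(abs(ddg_int) / sem, df, lower.tail = FALSE)
  } else {
    df <- NA_real_
    p <- NA_real_
  }
  structure(list(ddg_int_kT = ddg_int, sem_kT = sem, p_value = p, df = df,
                 transition = cycle$transition,
                 sides = c(side1 = side1$ddg_kT, side2 = side2$ddg_kT)),
            class = "interaction_energy")
}

#' @export
print.interaction_energy <- function(x, ...) {
  cat(sprintf("ddG_int(%s) = %.3g +/- %.3g kT", x$transition,
              x$ddg_int_kT, x$sem_kT))
  if (is.finite(x$p_value)) cat(sprintf("  (p = %.2g, df = %.1f)", x$p_value, x$df))
  cat("\n")
  invisible(x)
}

#' Free-enthalpy profile along a gating pathway
#'
#' Builds the ordered ground-state/barrier profile of a gating process in kT
#' units. Ground-state free enthalpies accumulate as `-kT ln(K_eq)` along the
#' given steps, with the first state as the zero reference. Barrier nodes
#' are placed between ground states but their absolute heights are not
#' determined by equilibrium measurements; they are reported with
#' `determined = FALSE` and `dG_kT = NA`, and carry the forward exit rate so
#' that *relative* barrier placements (between two exit pathways of one
#' state, or between constructs) can be computed with
#' [relative_barrier_shift()].
#'
#' @param steps data frame with columns `from`, `to`, `keq` (forward
#'   equilibrium constant of each step, e.g. `tau_burst/tau_interburst` for
#'   the interburst-to-bursting step) and optionally `rate_fwd_s` (forward
#'   exit rate over the barrier).
#' @param label optional construct label.
#' @return Object of class `"free_enthalpy_profile"`: data frame with
#'   columns `node`, `type` (`"ground"`/`"barrier"`), `dG_kT`, `determined`,
#'   `rate_fwd_s`.
#' @export
build_profile <- function(steps, label = NULL) {
  stopifnot(is.data.frame(steps), all(c("from", "to", "keq") %in% names(steps)))
  if (any(steps$keq <= 0)) stop("equilibrium constants must be positive")
  if (nrow(steps) > 1 &&
      !all(steps$from[-1] == steps$to[-nrow(steps)])) {
    stop("steps must chain: each 'from' must equal the previous 'to'")
  }
  rate <- if ("rate_fwd_s" %in% names(steps)) steps$rate_fwd_s else
    rep(NA_real_, nrow(steps))
  node <- steps$from[1]
  type <- "ground"
  dG <- 0
  det <- TRUE
  rfs <- NA_real_
  g <- 0
  for (i in seq_len(nrow(steps))) {
    node <- c(node, paste0("T(", steps$from[i], "-", steps$to[i], ")"),
              steps$to[i])
    type <- c(type, "barrier", "ground")
    g <- g - log(steps$keq[i])
    dG <- c(dG, NA_real_, g)
    det <- c(det, FALSE, TRUE)
    rfs <- c(rfs, rate[i], NA_real_)
  }
  structure(data.frame(node = node, type = type, dG_kT = dG,
                       determined = det, rate_fwd_s = rfs),
            label = label,
            class = c("free_enthalpy_profile", "data.frame"))
}

#' @export
print.free_enthalpy_profile <- function(x, ...) {
  lab <- attr(x, "label")
  cat("Free-enthalpy profile", if (!is.null(lab)) paste0(" (", lab, ")"),
      " [kT units; barrier heights not determined]:\n", sep = "")
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Relative placement of two free-enthalpy barriers
#'
#' The difference between the heights of two barriers crossed at rates `r1`
#' and `r2` — either two exit pathways from the same source state, or the
#' same barrier in two different constructs — is `-kT ln(r1/r2)`.
#'
#' @param rate1_s,rate2_s the two exit rates (1/s).
#' @return Barrier-height difference (barrier 1 minus barrier 2) in kT.
#' @export
relative_barrier_shift <- function(rate1_s, rate2_s) {
  stopifnot(rate1_s > 0, rate2_s > 0)
  -log(rate1_s / rate2_s)
}

#' Convert energies from kT units to kJ/mol
#'
#' @param x energy in kT units.
#' @param temperature_K absolute temperature (default 298.15 K, where
#'   1 kT = 2.479 kJ/mol).
#' @return Energy in kJ/mol.
#' @export
kT_to_kJ_mol <- function(x, temperature_K = 298.15) {
  x * 8.31446 * temperature_K / 1000
}

#' Decompose a bursting-state exit rate into hydrolytic and non-hydrolytic
#' closure
#'
#' In hydrolysis-competent channels the rate of leaving the (prehydrolytic)
#' bursting state is approximately the sum of the ATP-hydrolysis rate `k_h`
#' and the non-hydrolytic closing rate `k_nh`. Assuming a mutation far from
#' the catalytic site leaves `k_h` unchanged, the mutant's non-hydrolytic
#' closing rate is `rate_B_exit_mut - k_h`, and dividing by an upper bound
#' for the background's `k_nh` gives a lower-bound estimate of the
#' fold-increase in non-hydrolytic closing rate.
#'
#' @param rate_B_exit_wt background bursting-state exit rate (1/s), used only
#'   to check `k_h < rate_B_exit_wt`.
#' @param rate_B_exit_mut mutant bursting-state exit rate (1/s).
#' @param k_nh_bound upper bound on the background non-hydrolytic closing
#'   rate (1/s).
#' @param k_h ATP hydrolysis rate (1/s).
#' @param sems optional named list of SEMs (`rate_B_exit_mut`, `k_h`,
#'   `k_nh_bound`) for Monte-Carlo propagation.
#' @param n_mc,seed Monte-Carlo settings.
#' @return List of class `"hydrolytic_decomposition"`: `fold` (lower-bound
#'   fold-increase), `k_nh_mut_s`, `assumption`, and when `sems` is given,
#'   `fold_median` and `fold_ci95` from the Monte-Carlo draws.
#' @export
hydrolytic_decomposition <- function(rate_B_exit_wt, rate_B_exit_mut,
                                     k_nh_bound, k_h,
                                     sems = NULL, n_mc = 1e5, seed = 1) {
  stopifnot(rate_B_exit_wt > 0, rate_B_exit_mut > 0, k_nh_bound > 0, k_h > 0)
  if (k_h >= rate_B_exit_wt) {
    stop("hydrolysis rate cannot exceed the background exit rate")
  }
  k_nh_mut <- rate_B_exit_mut - k_h
  if (k_nh_mut <= 0) {
    stop("mutant exit rate must exceed the hydrolysis rate ",
         "(negative non-hydrolytic component)")
  }
  out <- list(fold = k_nh_mut / k_nh_bound, k_nh_mut_s = k_nh_mut,
              assumption = "mutation does not alter the catalytic rate k_h")
  if (!is.null(sems)) {
    draws <- with_seed(seed, {
      rm_ <- stats::rnorm(n_mc, rate_B_exit_mut, sems$rate_B_exit_mut %||% 0)
      kh_ <- stats::rnorm(n_mc, k_h, sems$k_h %||% 0)
      kb_ <- stats::rnorm(n_mc, k_nh_bound, sems$k_nh_bound %||% 0)
      ok <- rm_ > kh_ & kb_ > 0 & kh_ > 0
      (rm_[ok] - kh_[ok]) / kb_[ok]
    })
    out$fold_median <- stats::median(draws)
    out$fold_ci95 <- stats::quantile(draws, c(0.025, 0.975), names = FALSE)
  }
  class(out) <- "hydrolytic_decomposition"
  out
}

#' @export
print.hydrolytic_decomposition <- function(x, ...) {
  cat(sprintf("Non-hydrolytic closing rate increased >= %.3g-fold (k_nh,mut = %.3g 1/s)\n",
              x$fold, x$k_nh_mut_s))
  cat("  assumption: ", x$assumption, "\n", sep = "")
  invisible(x)
}
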