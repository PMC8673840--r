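test_that("the ideal-sequence likelihood matches closed forms and an
          expm oracle", {
  m <- gating_model("cs-o-cf", c(k13 = 0.2, k31 = 0.5, k32 = 2, k23 = 100))
  ## degenerate two-state case: one closed state effectively unreachable,
  ## single open dwell of t with total exit rate lambda
  m1 <- gating_model("cs-o-cf", c(k13 = 0.2, k31 = 0.5, k32 = 1e-12, k23 = 100))
  lam <- 0.5 + 1e-12
  dw1 <- dwell_sequence("open", 100, censored_end = FALSE)
  expect_equal(dwell_loglik(m1, dw1, 0), log(lam * exp(-lam * 0.1)),
               tolerance = 1e-9)
  ## three-event sequence against hand-assembled sub-generator exponentials
  dw <- dwell_sequence(c("open", "closed", "open"), c(100, 20, 50),
                       censored_end = FALSE)
  Q <- m$Q
  G_O <- function(t) expm_oracle(Q[3, 3, drop = FALSE], t) %*% Q[3, 1:2, drop = FALSE]
  G_F <- function(t) expm_oracle(Q[1:2, 1:2], t) %*% Q[1:2, 3, drop = FALSE]
  oracle <- log(as.numeric(G_O(0.1) %*% G_F(0.02)) *
                  as.numeric(expm_oracle(Q[3, 3, drop = FALSE], 0.05)) *
                  sum(Q[3, 1:2]))
  expect_equal(dwell_loglik(m, dw, 0), oracle, tolerance = 1e-9)
  ## dead-time mismatch is a contract error
  dwr <- impose_dead_time(dwell_sequence(c("open", "closed", "open"),
                                         c(100, 20, 50)), 4)
  expect_error(dwell_loglik(m, dwr, 0), "mismatch")
})

test_that("missed-event-corrected dwell densities predict apparent means
          seen in simulation", {
  for (nm in c("background", "R117H_E1124del")) {
    m <- target_model(nm)
    dw <- impose_dead_time(sample_trajectory(m, n_events = 60000,
                                             seed = 70 + nchar(nm)), 4)
    for (cl in c("open", "closed")) {
      pred <- apparent_dwell_mean(m, cl, 4)
      x <- dw$duration_ms[dw$class == cl]
      expect_lt(abs(mean(x) - pred), 3 * stats::sd(x) / sqrt(length(x)))
    }
  }
})

test_that("apparent densities integrate to one and agree with the dead-time-0
          ideal density", {
  m <- target_model("background")
  trapz <- function(x, y) sum(diff(x) * (y[-1] + y[-length(y)]) / 2)
  for (cl in c("open", "closed")) {
    ## fine spacing over the fast flicker component, coarser over the tail
    t_ms <- c(seq(4, 200, by = 0.02), seq(200.5, 80000, by = 0.5))
    dens <- apparent_dwell_density(m, cl, t_ms, 4)
    expect_equal(trapz(t_ms, dens), 1, tolerance = 0.005)
  }
  ## with no dead time the open density is the exponential with the open
  ## exit rate
  lam <- sum(m$rates[c("k31", "k32")])
  t_ms <- c(1, 10, 100)
  expect_equal(apparent_dwell_density(m, "open", t_ms, 0),
               lam / 1000 * exp(-lam * t_ms / 1000), tolerance = 1e-9)
})

test_that("rates are recovered from dead-time-regularized data and the fit
          is stable to initialization", {
  m <- target_model("R117H")
  dw <- impose_dead_time(sample_trajectory(m, n_events = 8000, seed = 71), 4)
  fit <- dwellfit(dw, "cs-o-cf", dead_time_ms = 4)
  expect_true(fit$converged)
  z <- (log(coef(fit)) - log(m$rates)) / fit$se_log_rates
  expect_true(all(abs(z) < 3.5))
  ## perturbed initialization (x/÷ 10): same optimum
  fit_hi <- dwellfit(dw, "cs-o-cf", dead_time_ms = 4, init = m$rates * 10)
  fit_lo <- dwellfit(dw, "cs-o-cf", dead_time_ms = 4, init = m$rates / 10)
  expect_equal(unname(coef(fit_hi)), unname(coef(fit)), tolerance = 1e-3)
  expect_equal(unname(coef(fit_lo)), unname(coef(fit)), tolerance = 1e-3)
  ## refusal below the minimum event count
  expect_error(dwellfit(dw[1:20, ], "cs-o-cf", dead_time_ms = 4,
                        min_events = 50), "at least")
})

test_that("with no dead time and a single reachable closed state the open
          exit rate is the closed-form MLE", {
  m <- gating_model("cs-o-cf", c(k13 = 1, k31 = 2, k32 = 1e-9, k23 = 100))
  dw <- sample_trajectory(m, n_events = 4000, seed = 72)
  fit <- dwellfit(dw, "cs-o-cf", dead_time_ms = 0,
                  init = c(k13 = 1, k31 = 2, k32 = 1e-5, k23 = 100))
  use <- dw[seq_len(nrow(dw) - 1L), ]   # censored terminal dwell is dropped
  o <- use$duration_ms[use$class == "open"]
  mle <- 1000 / mean(o)
  expect_equal(unname(coef(fit)[["k31"]] + coef(fit)[["k32"]]), mle,
               tolerance = 1e-3)
})

test_that("the likelihood is covariant under time rescaling", {
  m <- target_model("E1124del")
  dw <- impose_dead_time(sample_trajectory(m, n_events = 4000, seed = 73), 4)
  fit <- dwellfit(dw, "cs-o-cf", dead_time_ms = 4)
  c_scale <- 3
  dw_s <- dwell_sequence(dw$class, dw$duration_ms / c_scale,
                         dead_time_ms = 4 / c_scale,
                         censored_end = attr(dw, "censored_end"))
  fit_s <- dwellfit(dw_s, "cs-o-cf", dead_time_ms = 4 / c_scale)
  expect_equal(unname(coef(fit_s)), unname(coef(fit)) * c_scale,
               tolerance = 5e-3)
})

test_that("closed-dwell classification uses the equal-misclassification
          critical time", {
  ## forced root: the residual of the defining equation vanishes
  tc <- t_crit_equal_misclassification(10, 5000, 0.6, 0.4)
  expect_gt(tc, 10); expect_lt(tc, 5000)
  expect_lt(abs(0.6 * exp(-tc / 10) - 0.4 * (1 - exp(-tc / 5000))), 1e-9)
  ## labels against simulation ground truth at 100-fold separation
  m <- gating_model("cs-o-cf", c(k13 = 1, k31 = 10, k32 = 20, k23 = 100))
  dw <- sample_trajectory(m, n_events = 20000, seed = 74)
  lab <- classify_closed_dwells(dw, m)
  closed <- dw$class == "closed"
  truth <- ifelse(dw$has_cs[closed], "interburst", "flicker")
  expect_gt(mean(lab[closed] == truth), 0.95)
  ## all closed dwells far below t_crit: no interburst labels
  dwf <- dwell_sequence(rep(c("open", "closed"), 10), rep(c(50, 8), 10))
  labf <- classify_closed_dwells(dwf, m)
  expect_true(all(labf[dwf$class == "closed"] == "flicker"))
  ## refuse poorly separated components
  m_bad <- gating_model("cs-o-cf", c(k13 = 30, k31 = 10, k32 = 20, k23 = 100))
  expect_error(classify_closed_dwells(dw, m_bad), "separated")
})

test_that("both topologies fitted to the same record imply the same
          descriptive parameters", {
  m <- target_model("background")
  dw <- impose_dead_time(sample_trajectory(m, n_events = 8000, seed = 75), 4)
  f1 <- dwellfit(dw, "cs-o-cf", dead_time_ms = 4)
  f2 <- dwellfit(dw, "cs-cf-o", dead_time_ms = 4)
  expect_equal(f1$logLik, f2$logLik, tolerance = 1e-6)
  b1 <- burst_stats(f1$model); b2 <- burst_stats(f2$model)
  for (f in c("tau_burst_ms", "tau_interburst_ms", "tau_flicker_ms",
              "n_flicker", "p_open")) {
    expect_equal(b1[[f]], b2[[f]], tolerance = 0.02)
  }
})

test_that("dwellfit methods behave like standard model objects", {
  m <- target_model("R117H")
  dw <- impose_dead_time(sample_trajectory(m, n_events = 3000, seed = 76), 4)
  fit <- dwellfit(dw, "cs-o-cf", dead_time_ms = 4)
  expect_named(coef(fit), c("k13", "k31", "k32", "k23"))
  expect_s3_class(summary(fit), "summary.dwellfit")
  expect_equal(attr(logLik(fit), "df"), 4L)
  expect_equal(dim(vcov(fit)), c(4L, 4L))
  sim <- simulate(fit, nsim = 2, seed = 9, n_events = 200)
  expect_length(sim, 2)
  expect_s3_class(sim[[1]], "dwell_sequence")
  expect_equal(attr(sim[[1]], "dead_time_ms"), 4)
  expect_output(print(fit), "Maximum-likelihood")
})
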