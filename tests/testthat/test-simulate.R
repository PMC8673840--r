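test_that("trajectories reproduce exponential dwell laws and are reproducible", {
  m <- gating_model("cs-o-cf", c(k13 = 0.5, k31 = 2, k32 = 10, k23 = 100))
  dw <- sample_trajectory(m, n_events = 100000, seed = 21)
  ## open dwell mean = 1 / (total exit rate of O)
  o <- dw$duration_ms[dw$class == "open"]
  expect_lt(abs(mean(o) - 1000 / 12), 3 * stats::sd(o) / sqrt(length(o)))
  ## class occupancy converges to the stationary distribution
  p <- stationary_distribution(m)
  expect_equal(sum(dw$duration_ms[dw$class == "open"]) / sum(dw$duration_ms),
               unname(p[["O"]]), tolerance = 0.02)
  ## determinism under a fixed seed
  d1 <- sample_trajectory(m, n_events = 100, seed = 5)
  d2 <- sample_trajectory(m, n_events = 100, seed = 5)
  expect_identical(d1, d2)
})

test_that("a state with no exit yields a single full-length dwell", {
  ## make exits from Cs negligibly slow and start there
  m <- gating_model("cs-o-cf", c(k13 = 1e-12, k31 = 2, k32 = 10, k23 = 100))
  dw <- sample_trajectory(m, duration_ms = 5000, seed = 3, start_state = 1)
  expect_equal(nrow(dw), 1L)
  expect_equal(dw$duration_ms, 5000)
  expect_equal(dw$class, "closed")
})

test_that("mean burst duration of simulated bursts matches the closed form", {
  m <- gating_model("cs-o-cf", c(k13 = 2, k31 = 5, k32 = 20, k23 = 100))
  b <- burst_stats(m)
  dw <- sample_trajectory(m, n_events = 80000, seed = 22)
  eb <- empirical_burst_stats(dw)
  expect_gt(eb$n_bursts, 5000)
  expect_lt(abs(eb$tau_burst_ms - b$tau_burst_ms), 3 * eb$se_tau_burst_ms)
})

test_that("render_trace produces the ideal trace when noise and filter are off", {
  dw <- dwell_sequence(c("closed", "open", "closed"), c(20, 50, 30))
  tr <- render_trace(dw, 10000, -0.7, noise_sd_pA = 0, filter_fc_hz = NULL)
  expect_equal(length(tr$current_pA), 1000L)
  ## a 50 ms open dwell at 10 kHz is exactly 500 samples at the open level
  expect_equal(sum(tr$current_pA == -0.7), 500L)
  expect_equal(sort(unique(tr$current_pA)), c(-0.7, 0))
})

test_that("rendered noise has the analytic post-filter standard deviation", {
  dw <- dwell_sequence("open", 20000)
  fs <- 10000; fc <- 1000; sd_in <- 0.2
  tr <- render_trace(dw, fs, -0.7, noise_sd_pA = sd_in, filter_fc_hz = fc,
                     seed = 33)
  k <- burstkin:::gaussian_kernel(fc, fs)
  sd_pred <- sd_in * sqrt(sum(k^2))
  n <- length(tr$current_pA)
  expect_lt(abs(mean(tr$current_pA) - (-0.7)), 3 * sd_pred / sqrt(n / 10))
  ## filtered samples are correlated over ~ fs/fc samples; allow for that in
  ## the tolerance of the SD comparison
  expect_equal(stats::sd(tr$current_pA), sd_pred, tolerance = 0.05)
})

test_that("macroscopic decays have the configured time constant", {
  ## large ensemble, no noise: fitted tau within 1%
  tr <- simulate_macroscopic(20000, closing_rate_s = 0.5, noise_sd_pA = 0,
                             seed = 44)
  f <- fit_relaxation(tr, t0 = 0, dead_period_s = 0)
  expect_equal(f$tau_ms, 2000, tolerance = 0.01)
  ## survival at t = 1/rate is e^-1 (binomial error band)
  tr2 <- simulate_macroscopic(10000, closing_rate_s = 0.5, noise_sd_pA = 0,
                              seed = 45)
  t2s <- seq(0, 12, by = 1e-3)          # the trace's time base
  n_surv <- abs(tr2$current_pA[which.min(abs(t2s - 2))] /
                  tr2$unitary_amplitude_pA)
  se <- sqrt(10000 * exp(-1) * (1 - exp(-1)))
  expect_lt(abs(n_surv - 10000 * exp(-1)), 3 * se)
  ## a single channel is a single downward step
  tr1 <- simulate_macroscopic(1, closing_rate_s = 2, noise_sd_pA = 0, seed = 46)
  expect_equal(sort(unique(tr1$current_pA)), c(-0.7, 0))
  expect_equal(diff(range(which(tr1$current_pA == -0.7))) + 1L,
               sum(tr1$current_pA == -0.7))
})

test_that("fixture suites match their descriptive targets and are byte-stable", {
  cfg <- system.file("extdata", "config_d1370n_fixtures.yaml",
                     package = "burstkin")
  d1 <- file.path(tempdir(), "fx1"); d2 <- file.path(tempdir(), "fx2")
  man1 <- make_fixture_suite(cfg, d1, seed = 7)
  man2 <- make_fixture_suite(cfg, d2, seed = 7)
  expect_identical(man1$checksums, man2$checksums)
  ## background fixture: tau_burst within 10% of 2000 ms at >= 500 bursts
  ## (burst segmentation from simulation ground truth)
  dw <- read_dwells(file.path(d1, "background_dwells.tsv"))
  eb <- empirical_burst_stats(dw)
  expect_gt(eb$n_bursts, 500)
  expect_equal(eb$tau_burst_ms, 2000, tolerance = 0.1)
  ## R117H-like fixture: tau_burst within 10% of 67 ms
  dwr <- read_dwells(file.path(d1, "R117H_dwells.tsv"))
  ebr <- empirical_burst_stats(dwr)
  expect_equal(ebr$tau_burst_ms, 67, tolerance = 0.1)
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("dwell sequence invariants are enforced", {
  expect_error(dwell_sequence(c("open", "open"), c(1, 2)), "alternate")
  expect_error(dwell_sequence(c("open", "closed"), c(1, -2)), "positive")
  expect_error(dwell_sequence("shut", 1), "closed")
})
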