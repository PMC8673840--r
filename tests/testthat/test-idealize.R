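test_that("Gaussian refiltering has unit DC gain and analytic noise reduction", {
  fs <- 10000
  const <- trace_record(rep(-0.7, 2000), fs, -0.7)
  out <- refilter(const, 100)
  expect_equal(out$current_pA, const$current_pA, tolerance = 1e-12)

  set.seed(61)
  wn <- trace_record(rnorm(200000), fs, -0.7)
  f <- refilter(wn, 100)
  k <- burstkin:::gaussian_kernel(100, fs)
  expect_equal(stats::sd(f$current_pA), sqrt(sum(k^2)), tolerance = 0.03)

  ## cascade of two Gaussian filters == one at the composed corner
  fc1 <- 500; fc2 <- 300
  fc12 <- (fc1^-2 + fc2^-2)^(-1 / 2)
  x <- trace_record(c(rep(0, 500), rep(1, 500)), fs, 1)
  a <- refilter(refilter(x, fc1), fc2)
  b <- refilter(x, fc12)
  expect_equal(a$current_pA, b$current_pA, tolerance = 1e-3)

  expect_error(refilter(const, 6000), "Nyquist")
})

test_that("half-amplitude idealization handles forced cases", {
  fs <- 10000
  ## noiseless square opening of 100 ms: exactly one open event of 100 ms
  x <- c(rep(0, 1000), rep(-0.7, 1000), rep(0, 1000))
  tr <- trace_record(x, fs, -0.7)
  dw <- idealize(tr, levels = c(closed = 0, open = -0.7))
  expect_equal(dw$class, c("closed", "open", "closed"))
  expect_equal(dw$duration_ms[2], 100)
  ## all samples on the closed side: single closed event spanning the record
  tr0 <- trace_record(rep(-0.1, 5000), fs, -0.7)
  dw0 <- idealize(tr0, levels = c(closed = 0, open = -0.7))
  expect_equal(nrow(dw0), 1L)
  expect_equal(dw0$class, "closed")
  expect_equal(dw0$duration_ms, 500)
  expect_error(idealize(tr, levels = c(closed = 0, open = 0)), "degenerate")
})

test_that("level estimation finds the two amplitude modes", {
  dw <- dwell_sequence(rep(c("closed", "open"), 50),
                       rep(c(60, 40), 50))
  tr <- render_trace(dw, 10000, -0.7, noise_sd_pA = 0.07, filter_fc_hz = 1000,
                     seed = 62)
  lv <- estimate_levels(tr)
  expect_equal(unname(lv[["closed"]]), 0, tolerance = 0.05)
  expect_equal(unname(lv[["open"]]), -0.7, tolerance = 0.05)
})

test_that("simulate -> render -> refilter -> idealize -> dead time recovers the truth", {
  ## regime: dwells well above the dead time, noise at 15% of the amplitude
  set.seed(63)
  n <- 200
  dur <- 50 + rexp(n, 1 / 150)
  dw <- dwell_sequence(rep(c("open", "closed"), length.out = n), dur)
  tr <- render_trace(dw, 10000, -0.7, noise_sd_pA = 0.105,
                     filter_fc_hz = 1000, seed = 64)
  rec <- impose_dead_time(idealize(refilter(tr, 100),
                                   levels = c(closed = 0, open = -0.7)), 4)
  expect_equal(nrow(rec), n)
  expect_equal(rec$class, dw$class)
  ## interior durations within ~1 sample period per edge (noise jitter on the
  ## two smoothed edges)
  derr <- rec$duration_ms[2:(n - 1)] - dw$duration_ms[2:(n - 1)]
  expect_lt(max(abs(derr)), 0.6)
  expect_lt(stats::quantile(abs(derr), 0.95), 0.3)
})

test_that("dead-time imposition follows the stated absorption rules", {
  ## [O:10, C:2, O:5] with td = 4 -> [O:17]
  dw <- dwell_sequence(c("open", "closed", "open"), c(10, 2, 5))
  out <- impose_dead_time(dw, 4)
  expect_equal(nrow(out), 1L)
  expect_equal(out$class, "open")
  expect_equal(out$duration_ms, 17)
  ## all events at/above the dead time: unchanged
  dw2 <- dwell_sequence(c("open", "closed", "open"), c(10, 6, 5))
  out2 <- impose_dead_time(dw2, 4)
  expect_equal(out2$duration_ms, dw2$duration_ms)
  ## leading short event attaches forward
  dw3 <- dwell_sequence(c("closed", "open", "closed"), c(1, 10, 8))
  out3 <- impose_dead_time(dw3, 4)
  expect_equal(out3$class, c("open", "closed"))
  expect_equal(out3$duration_ms, c(11, 8))
  expect_error(impose_dead_time(dwell_sequence(c("open", "closed"), c(1, 2)), 4),
               "no event")
})

test_that("dead-time imposition conserves duration and is idempotent", {
  set.seed(65)
  for (i in 1:5) {
    n <- 200
    dur <- rexp(n, 1 / 8)
    dw <- dwell_sequence(rep(c("open", "closed"), length.out = n), dur)
    out <- impose_dead_time(dw, 4)
    expect_equal(sum(out$duration_ms), sum(dw$duration_ms), tolerance = 1e-12)
    expect_true(all(out$duration_ms >= 4))
    again <- impose_dead_time(out, 4)
    expect_equal(again$duration_ms, out$duration_ms)
  }
})

test_that("single-channel confidence follows 1 - exp(-lambda T) and matches
          a two-channel Monte-Carlo oracle", {
  dw <- dwell_sequence(rep(c("open", "closed"), 10), rep(c(100, 900), 10))
  T_open <- 1.0   # seconds
  lam <- 0.8
  expect_equal(single_channel_confidence(dw, lam), 1 - exp(-lam * T_open),
               tolerance = 1e-12)
  ## tiny open time: cannot exclude a second channel
  dw0 <- dwell_sequence(c("open", "closed"), c(0.01, 1000))
  expect_lt(single_channel_confidence(dw0, lam), 1e-5)
  ## two-channel Gillespie oracle: probability that an independent low-Po
  ## channel initiates a burst while the observed channel is open
  m <- target_model("R117H_E1124del")
  open_rate <- 1000 / burst_stats(m)$tau_interburst_ms
  D_ms <- 600000
  dw1 <- sample_trajectory(m, duration_ms = D_ms, seed = 661)
  ends <- cumsum(dw1$duration_ms)
  starts <- ends - dw1$duration_ms
  w_lo <- starts[dw1$class == "open"]
  w_hi <- ends[dw1$class == "open"]
  T_open <- sum(w_hi - w_lo) / 1000
  p_pred <- 1 - exp(-open_rate * T_open)
  nrep <- 300
  hit <- logical(nrep)
  for (r in seq_len(nrep)) {
    dw2 <- sample_trajectory(m, duration_ms = D_ms, seed = 700 + r)
    e2 <- cumsum(dw2$duration_ms)
    is_burst_start <- dw2$class == "open" &
      c(FALSE, dw2$has_cs[-nrow(dw2)]) %in% TRUE
    t_init <- (e2 - dw2$duration_ms)[is_burst_start]
    idx <- findInterval(t_init, w_lo)
    hit[r] <- any(idx >= 1 & t_init <= w_hi[pmax(idx, 1)])
  }
  se <- sqrt(p_pred * (1 - p_pred) / nrep)
  expect_lt(abs(mean(hit) - p_pred), 3 * se + 0.02)
})

test_that("stacked openings in a two-channel record are detected and flagged", {
  m <- gating_model("cs-o-cf", c(k13 = 2, k31 = 2, k32 = 5, k23 = 50))
  tr2 <- simulate_two_channel_trace(m, duration_ms = 20000, seed = 67)
  expect_true(detect_superimposed(tr2))
  ## a genuine single-channel record is not flagged
  tr1 <- render_trace(sample_trajectory(m, duration_ms = 20000, seed = 68),
                      seed = 69)
  expect_false(detect_superimposed(tr1))
})
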