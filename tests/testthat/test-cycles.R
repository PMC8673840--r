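test_that("barrier and ground-state ddG values reproduce published magnitudes", {
  ## ~30-fold shortening of tau_burst: |ddG| = 3.4 kT
  tb_bg <- estimated_quantity(2000, 250, 6, "dwell_time")
  tb_mut <- estimated_quantity(67, 8.8, 6, "dwell_time")
  d <- ddg_barrier(tb_bg, tb_mut)
  expect_equal(abs(d$ddg_kT), 3.40, tolerance = 0.01)
  ## 6-fold acceleration: 1.79 kT (printed ~1.8)
  r1 <- estimated_quantity(1, 0, 1, "rate")
  r6 <- estimated_quantity(6, 0, 1, "rate")
  expect_equal(abs(ddg_barrier(r1, r6)$ddg_kT), log(6), tolerance = 1e-12)
  expect_equal(abs(ddg_barrier(r1, r6)$ddg_kT), 1.8, tolerance = 0.01)
  ## identical rates: zero
  expect_equal(ddg_barrier(r1, r1)$ddg_kT, 0)
  ## equilibrium side: K 17 -> 0.20 gives 4.44 (printed ~4.5); 0.42 -> 0.042
  ## is a 10-fold drop, 2.30 kT
  k_bg <- estimated_quantity(17, 3.9, 6, "equilibrium_constant")
  k_m <- estimated_quantity(0.20, 0.031, 6, "equilibrium_constant")
  expect_equal(ddg_equilibrium(k_bg, k_m)$ddg_kT, 4.44, tolerance = 0.01)
  k_b2 <- estimated_quantity(0.42, 0.07, 6, "equilibrium_constant")
  k_m2 <- estimated_quantity(0.042, 0.006, 6, "equilibrium_constant")
  expect_equal(ddg_equilibrium(k_b2, k_m2)$ddg_kT, log(10), tolerance = 1e-12)
  expect_equal(ddg_equilibrium(k_bg, k_bg)$ddg_kT, 0)
})

test_that("second-order SEM propagation matches a 1e7-draw Monte-Carlo
          oracle within 2%", {
  q1 <- estimated_quantity(100, 16, 6, "rate")
  q2 <- estimated_quantity(80, 10, 6, "rate")
  sem <- propagate_sem_log_ratio(q1, q2)
  set.seed(91)
  n <- 1e7
  x1 <- rnorm(n, 100, 16); x2 <- rnorm(n, 80, 10)
  ok <- x1 > 0 & x2 > 0
  sem_mc <- sd(log(x1[ok] / x2[ok]))
  expect_equal(as.numeric(sem), sem_mc, tolerance = 0.02)
  ## degenerate: zero SEMs propagate to zero
  p0 <- propagate_sem_log_ratio(estimated_quantity(5, 0, 1, "rate"),
                                estimated_quantity(3, 0, 1, "rate"))
  expect_equal(as.numeric(p0), 0)
  ## symmetric inputs add in quadrature
  qa <- estimated_quantity(50, 5, 4, "rate")
  one_sided <- propagate_sem_log_ratio(qa, estimated_quantity(50, 0, 4, "rate"))
  both <- propagate_sem_log_ratio(qa, qa)
  expect_equal(as.numeric(both), sqrt(2) * as.numeric(one_sided),
               tolerance = 1e-12)
  ## CV >= 0.5 falls back to Monte-Carlo with a warning
  qw <- estimated_quantity(10, 6, 3, "rate")
  expect_warning(pw <- propagate_sem_log_ratio(qw, q2), "Monte-Carlo")
  expect_equal(attr(pw, "method"), "monte-carlo")
})

test_that("interaction energies reproduce the three published cycles", {
  ## macroscopic closing-rate cycle: fold-changes 6 and 1.47
  folds <- read_corner_table(system.file("extdata", "e1371s_closing_folds.tsv",
                                         package = "burstkin"))
  cy1 <- mutant_cycle(corner_q(folds, "background", "B->IB", "rate"),
                      corner_q(folds, "R117H", "B->IB", "rate"),
                      corner_q(folds, "E1124del", "B->IB", "rate"),
                      corner_q(folds, "R117H_E1124del", "B->IB", "rate"),
                      transition = "B->T")
  ie1 <- interaction_energy(cy1)
  expect_equal(ie1$ddg_int_kT, log(6) - log(1.47), tolerance = 1e-9)
  expect_equal(ie1$ddg_int_kT, 1.4, tolerance = 0.015)

  ## steady-state burst-duration cycle: 2000 / 67 / 100 / 58 ms
  t1 <- read_corner_table(table1_path)
  cy2 <- mutant_cycle(corner_q(t1, "background", "B->IB"),
                      corner_q(t1, "R117H", "B->IB"),
                      corner_q(t1, "E1124del", "B->IB"),
                      corner_q(t1, "R117H_E1124del", "B->IB"),
                      transition = "B->T")
  ie2 <- interaction_energy(cy2)
  expect_equal(ie2$ddg_int_kT, log(2000 / 67) - log(100 / 58), tolerance = 1e-9)
  expect_equal(ie2$ddg_int_kT, 2.85, tolerance = 0.01)
  expect_equal(ie2$sem_kT, 0.23, tolerance = 0.15)
  expect_lt(ie2$p_value, 0.05)

  ## intraburst equilibrium cycle: K 17 / 0.20 / 0.42 / 0.042
  t2 <- read_corner_table(table2_path)
  cy3 <- mutant_cycle(corner_q(t2, "background", "Cf<->O", "equilibrium_constant"),
                      corner_q(t2, "R117H", "Cf<->O", "equilibrium_constant"),
                      corner_q(t2, "E1124del", "Cf<->O", "equilibrium_constant"),
                      corner_q(t2, "R117H_E1124del", "Cf<->O", "equilibrium_constant"),
                      transition = "Cf->O")
  ie3 <- interaction_energy(cy3)
  expect_equal(ie3$ddg_int_kT, log(17 / 0.20) - log(0.42 / 0.042),
               tolerance = 1e-9)
  expect_equal(ie3$ddg_int_kT, 2.14, tolerance = 0.01)
  expect_lt(ie3$p_value, 0.05)

  ## both published barrier cycles come out positive under the sign
  ## convention (stabilizing interaction lost)
  expect_gt(ie1$ddg_int_kT, 0)
  expect_gt(ie2$ddg_int_kT, 0)
  expect_gt(ie3$ddg_int_kT, 0)
})

test_that("opening-rate cycle is indistinguishable from zero", {
  t1 <- read_corner_table(table1_path)
  cy <- mutant_cycle(corner_q(t1, "background", "IB->B"),
                     corner_q(t1, "R117H", "IB->B"),
                     corner_q(t1, "E1124del", "IB->B"),
                     corner_q(t1, "R117H_E1124del", "IB->B"),
                     transition = "IB->T")
  ie <- interaction_energy(cy)
  expect_lt(abs(ie$ddg_int_kT), 2 * ie$sem_kT)
})

test_that("cycle closure and additivity identities hold for random cycles", {
  set.seed(92)
  for (i in 1:20) {
    q <- lapply(exp(rnorm(4, 1, 1.5)), function(m)
      estimated_quantity(m, 0.1 * m, 5, "rate"))
    ie_h <- interaction_energy(mutant_cycle(q[[1]], q[[2]], q[[3]], q[[4]]))
    ## swapping which mutation is "A" computes the other pair of parallel
    ## sides; the interaction energy is identical (algebraic closure)
    ie_v <- interaction_energy(mutant_cycle(q[[1]], q[[3]], q[[2]], q[[4]]))
    expect_equal(ie_h$ddg_int_kT, ie_v$ddg_int_kT, tolerance = 1e-12)
    expect_equal(ie_h$sem_kT, ie_v$sem_kT, tolerance = 1e-12)
  }
  ## perfectly additive cycle: double-mutant effect = product of single
  ## effects, interaction energy 0
  mk <- function(m) estimated_quantity(m, 0, 1, "rate")
  ie0 <- interaction_energy(mutant_cycle(mk(2), mk(6), mk(10), mk(30)))
  expect_equal(ie0$ddg_int_kT, 0, tolerance = 1e-12)
  ## mixing corner kinds is a contract error
  expect_error(mutant_cycle(mk(1), mk(2), mk(3),
                            estimated_quantity(1, 0, 1, "equilibrium_constant")),
               "same kind")
})

test_that("free-enthalpy profiles encode ground states from equilibrium
          constants and leave barriers undetermined", {
  ## interburst <-> bursting step of the background construct
  p1 <- build_profile(data.frame(from = "IB", to = "B", keq = 2000 / 5100),
                      label = "background")
  expect_equal(abs(p1$dG_kT[p1$node == "B"]), log(5100 / 2000),
               tolerance = 1e-12)
  expect_equal(abs(p1$dG_kT[p1$node == "B"]), 0.94, tolerance = 0.01)
  expect_true(is.na(p1$dG_kT[p1$type == "barrier"]))
  expect_false(p1$determined[p1$type == "barrier"])
  ## flickery <-> open step
  p2 <- build_profile(data.frame(from = "Cf", to = "O", keq = 200 / 11))
  expect_equal(abs(p2$dG_kT[p2$node == "O"]), 2.90, tolerance = 0.01)
  ## identical constructs: all cross-construct barrier shifts vanish
  expect_equal(relative_barrier_shift(3.5, 3.5), 0)
  ## chained steps accumulate
  p3 <- build_profile(data.frame(from = c("Cs", "Cf"), to = c("Cf", "O"),
                                 keq = c(0.5, 4)))
  expect_equal(p3$dG_kT[p3$node == "O"], -log(0.5) - log(4), tolerance = 1e-12)
  expect_error(build_profile(data.frame(from = c("Cs", "O"), to = c("Cf", "X"),
                                        keq = c(1, 1))), "chain")
})

test_that("energies convert to kJ/mol by the thermal factor alone", {
  expect_equal(kT_to_kJ_mol(1), 2.479, tolerance = 1e-3)
  x <- c(-2.2, 0, 1.4)
  expect_equal(kT_to_kJ_mol(x) / 2.479, x, tolerance = 1e-3)
})

test_that("hydrolytic decomposition gives the lower-bound fold increase", {
  h <- hydrolytic_decomposition(3.5, 11, 0.5, 3)
  expect_equal(h$fold, 16)
  expect_equal(h$k_nh_mut_s, 8)
  ## mutant rate equal to k_h + bound: 1-fold (no increase)
  expect_equal(hydrolytic_decomposition(3.5, 3.5, 0.5, 3)$fold, 1)
  expect_error(hydrolytic_decomposition(3.5, 2.9, 0.5, 3), "exceed")
  ## Monte-Carlo propagation with 10% errors: median within 2% of the point
  hm <- hydrolytic_decomposition(3.5, 11, 0.5, 3,
                                 sems = list(rate_B_exit_mut = 1.1, k_h = 0.3,
                                             k_nh_bound = 0.05),
                                 n_mc = 2e5, seed = 93)
  expect_equal(hm$fold_median, hm$fold, tolerance = 0.02)
})
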