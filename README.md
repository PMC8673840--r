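# burstkin

Single-channel burst kinetics and thermodynamic double-mutant-cycle analysis
for ion channels that gate in bursts.

## The problem

Patch-clamp recordings of channels such as CFTR show *bursts* of openings:
brief (~10 ms) "flickery" closures inside a burst, long (~1 s) "interburst"
closures between bursts. Quantifying how a mutation changes gating — and
whether two mutated positions interact in a state-dependent way, as a
hydrogen bond formed in one conformation but not another would — requires
three things this package provides as one tested toolchain:

1. **Kinetic modelling.** Gating is a linear three-state aggregated Markov
   chain (one open state O, fast closed Cf, slow closed Cs; either
   connectivity Cs&harr;O&harr;Cf or Cs&harr;Cf&harr;O). Microscopic transition rate
   constants are estimated from idealized dwell-time sequences by
   maximizing the likelihood of the *full alternating sequence*, with exact
   missed-event correction for a fixed dead time t_d (events shorter than
   t_d are unresolvable at the analysis bandwidth). Closed forms map rates
   to the model-independent descriptive parameters
   &tau;_burst, &tau;_interburst, &tau;_flicker, n_flicker and P_o, and back.
2. **Synthetic data.** Exact Gillespie simulation of gating trajectories,
   rendering as noisy Gaussian-filtered current traces (10 kHz sampling,
   1 kHz recording filter by default), half-amplitude threshold
   idealization, dead-time regularization, and per-channel macroscopic
   ligand-removal decays — so every analysis stage is exercisable and
   testable without any recordings.
3. **Mutant-cycle energetics.** For a gating step measured by a rate r or
   equilibrium constant K, a mutation changes the corresponding free
   enthalpy by &Delta;&Delta;G = −kT·ln(r′/r) (barrier) or −kT·ln(K′/K)
   (ground states). For a 2×2 set of constructs (background, two single
   mutants, double mutant) the **interaction free energy**
   &Delta;&Delta;G_int — the difference of &Delta;&Delta;G along two
   parallel sides of the cycle — measures the state-dependent coupling
   between the two positions, with second-order SEM propagation, t-test
   significance, and free-enthalpy profile construction. All energies are
   dimensionless multiples of kT.

## Worked example

Build a model from descriptive targets, simulate a steady-state record,
regularize it to a 4 ms dead time, and re-estimate the rates:

```r
library(burstkin)
m <- rates_from_burst_stats("cs-o-cf", tau_burst_ms = 2000,
                            tau_interburst_ms = 5100,
                            tau_flicker_ms = 10, n_flicker = 4.8)
m
#> Linear three-state gating model: Cs <-> O <-> Cf
#> Rate constants (1/s):
#>      k13      k31      k32      k23
#>   0.1961   0.5123   2.4590 100.0000
#> Stationary P(open) = 0.2749

dw  <- sample_trajectory(m, n_events = 8000, seed = 7)
dwr <- impose_dead_time(dw, dead_time_ms = 4)
fit <- dwellfit(dwr, "cs-o-cf", dead_time_ms = 4)
fit
#> Maximum-likelihood gating fit (cs-o-cf), dead time 4 ms
#>   5796 events, log-likelihood 3862.22
#>       rate_s se_log
#> k13   0.2048 0.0380
#> k31   0.5222 0.0380
#> k32   2.4560 0.0233
#> k23 101.2000 0.0225
```

Although a third of the flickery closures are shorter than the dead time
and invisible at this bandwidth, every rate is recovered within its
standard error (`se_log` is the SE of the log rate; the generating rates
are 0.196, 0.512, 2.459, 100 s⁻¹). The fitted model's descriptive
parameters round-trip the simulation targets:

```r
burst_stats(fit$model)
#> Descriptive burst parameters:
#>   tau_burst        1.96e+03 ms
#>   tau_interburst   4.88e+03 ms
#>   tau_flicker          9.88 ms
#>   n_flicker             4.7
#>   P_open               0.28
```

A double-mutant cycle on the burst durations of the four packaged
constructs (background, R117H, E1124del, R117H/E1124del in a non-hydrolytic
background; mean dwell times enter as reciprocal rates):

```r
t1 <- read_corner_table(system.file("extdata", "table1_d1370n.tsv",
                                    package = "burstkin"))
q <- function(cn) estimated_quantity(
  t1$mean[t1$construct == cn & t1$transition == "B->IB"],
  t1$sem[t1$construct == cn & t1$transition == "B->IB"], 6, "dwell_time", cn)
interaction_energy(mutant_cycle(q("background"), q("R117H"),
                                q("E1124del"), q("R117H_E1124del"), "B->T"))
#> ddG_int(B->T) = 2.85 +/- 0.259 kT  (p = 4.9e-09, df = 16.6)
```

A positive interaction energy of ~2.8 kT on the burst-exit step, against a
null cycle on the opening step, is the signature of a stabilizing contact
present in the bursting state only.

Whole analyses (simulate &rarr; idealize &rarr; fit &rarr; cycles &rarr;
profiles, or table-only cycle recomputation) run from a single YAML
configuration via `run_pipeline()`; packaged configurations live in
`inst/extdata/`, and `inst/scripts/pipeline.R` is a thin command-line
wrapper.

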