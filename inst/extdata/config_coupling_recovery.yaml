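# Fully synthetic double-mutant-cycle experiment. The four constructs share
# opening, flicker-entry and flicker-exit rates; their bursting-state exit
# rates (k31) differ so that the mutational fold-changes embed a built-in
# state-dependent coupling of exactly 2.5 kT on the closing step: the
# ln-fold-changes in closing rate are 2.9 (mutA = 0.4 additive + 2.5 bond),
# 3.1 (mutB = 0.6 additive + 2.5 bond) and 3.5 (double = 0.4 + 0.6 + 2.5,
# the shared bond being lost only once), and no coupling on the opening step.
name: coupling-recovery
mode: synthetic
seed: 42
dead_time_ms: 4
fit_topology: cs-o-cf
n_patches: 5
n_events: 3000
constructs:
  background: {topology: cs-o-cf, rates: {k13: 0.196078, k31: 0.512295, k32: 2.459016, k23: 100.0}}
  mutA:       {topology: cs-o-cf, rates: {k13: 0.196078, k31: 9.310525, k32: 2.459016, k23: 100.0}}
  mutB:       {topology: cs-o-cf, rates: {k13: 0.196078, k31: 11.371901, k32: 2.459016, k23: 100.0}}
  mutAB:      {topology: cs-o-cf, rates: {k13: 0.196078, k31: 16.964883, k32: 2.459016, k23: 100.0}}
cycles:
  - transition: "B->T"
    quantity: closing_rate
    corners: {bg: background, mutA: mutA, mutB: mutB, mutAB: mutAB}
  - transition: "IB->T"
    quantity: opening_rate
    corners: {bg: background, mutA: mutA, mutB: mutB, mutAB: mutAB}
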