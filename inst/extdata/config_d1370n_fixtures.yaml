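# Simulation fixtures matching the descriptive gating parameters of
# table1_d1370n.tsv (see README.md for the R117H_E1124del n_flicker choice).
constructs:
  background:
    topology: cs-o-cf
    burst_targets: {tau_burst_ms: 2000, tau_interburst_ms: 5100, tau_flicker_ms: 10, n_flicker: 4.8}
    n_events: 7000
  R117H:
    topology: cs-o-cf
    burst_targets: {tau_burst_ms: 67, tau_interburst_ms: 2800, tau_flicker_ms: 33, n_flicker: 1.2}
    n_events: 5000
  E1124del:
    topology: cs-o-cf
    burst_targets: {tau_burst_ms: 100, tau_interburst_ms: 4800, tau_flicker_ms: 23, n_flicker: 2.1}
    n_events: 5000
  R117H_E1124del:
    topology: cs-o-cf
    burst_targets: {tau_burst_ms: 58, tau_interburst_ms: 3200, tau_flicker_ms: 50, n_flicker: 0.86}
    n_events: 5000
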