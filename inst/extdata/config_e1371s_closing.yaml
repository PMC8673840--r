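name: e1371s-closing-rate-cycle
mode: table
corner_table: "extdata:e1371s_closing_folds.tsv"
cycles:
  - transition: "B->T"
    quantity_kind: rate
    quantity_transition: "B->IB"
    corners: {bg: background, mutA: R117H, mutB: E1124del, mutAB: R117H_E1124del}
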