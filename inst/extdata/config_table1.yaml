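name: d1370n-steady-state-cycles
mode: table
corner_table: "extdata:table1_d1370n.tsv"
cycles:
  - transition: "B->T"
    quantity_kind: dwell_time
    quantity_transition: "B->IB"
    corners: {bg: background, mutA: R117H, mutB: E1124del, mutAB: R117H_E1124del}
  - transition: "IB->T"
    quantity_kind: dwell_time
    quantity_transition: "IB->B"
    corners: {bg: background, mutA: R117H, mutB: E1124del, mutAB: R117H_E1124del}
profiles:
  - construct: background
    steps:
      - {from: IB, to: B, keq_num: "B->IB", keq_den: "IB->B"}
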