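name: e1371s-intraburst-cycles
mode: table
corner_table: "extdata:table2_e1371s.tsv"
cycles:
  - transition: "Cf->O"
    quantity_kind: equilibrium_constant
    quantity_transition: "Cf<->O"
    corners: {bg: background, mutA: R117H, mutB: E1124del, mutAB: R117H_E1124del}
profiles:
  - construct: background
    steps:
      - {from: Cf, to: O, keq_row: "Cf<->O"}
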