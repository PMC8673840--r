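# Packaged example data

Corner-estimate tables (layout: `construct`, `quantity_kind`, `transition`,
`mean`, `sem`, `n`) with summary gating parameters for CFTR target-site
mutants (R117H, E1124del, and their combination) in two non-hydrolytic
catalytic-site backgrounds:

- `table1_d1370n.tsv` — steady-state dwell-time analysis in the D1370N
  background: mean burst durations (`B->IB`, ms), mean interburst durations
  (`IB->B`, ms) and mean flickery-closure durations (`Cf->O`, ms).
- `table2_e1371s.tsv` — intraburst ("last open channel") analysis in the
  E1371S background: mean flickery closed times (`Cf->O`, ms), mean open
  times (`O->Cf`, ms) and the intraburst closed-open equilibrium constant
  (`Cf<->O`, dimensionless).
- `e1371s_closing_folds.tsv` — relative non-hydrolytic closing rates in the
  E1371S background (macroscopic ligand-removal relaxations), expressed as
  fold-changes over the background construct. Only the ratios along the
  sides of the mutant cycle are meaningful; SEMs are not resolved for these
  fold values.

Per-construct patch counts were published only as a range; all rows use
n = 6. Pipeline configurations (`config_*.yaml`) reference these tables via
the `extdata:` prefix.

`config_coupling_recovery.yaml` defines a fully synthetic double-mutant-cycle
experiment: four constructs whose bursting-state exit rates embed a built-in
2.5 kT state-dependent coupling (and no coupling on the opening rate), used
to validate end-to-end recovery of interaction energies.

`config_d1370n_fixtures.yaml` defines simulation fixtures matching the
descriptive parameters of `table1_d1370n.tsv`. For `R117H_E1124del` the
printed rounded values imply a mean intraburst open duration below the 4 ms
dead time (mutually inconsistent with the other published intraburst
estimates for this construct); its `n_flicker` target is therefore set to
0.86 so that the mean open duration is 8 ms, keeping all three duration
targets at their printed values.
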