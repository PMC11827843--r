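# Demo screen analysis: two PCa-like cell lines, vehicle + two PARPi arms,
# small library so the full run takes seconds. Synthetic data throughout.
seed: 7
output_dir: demo_run
simulate:
  cell_lines: [LINE_A, LINE_B]
  library:
    n_target_genes: 60
    n_essential_genes: 10
    n_ntc_guides: 48
    guides_per_gene: 4
  model:
    doublings: {DMSO: 15, OLA: 15, TALA: 15}
    coverage: 300
    dispersion: 100
    efficiency_alpha: 5
    efficiency_beta: 1
    baseline_sigma: 0.5
    essential_fitness: -0.5
    sensitizers:
      n_genes: 6
      effect: -0.5
      drugs: [OLA, TALA]
contrasts:
  - {label: DMSO_vs_T0, control: T0, treated: DMSO, role: fitness}
  - {label: OLA_vs_DMSO, control: DMSO, treated: OLA, role: drug}
  - {label: TALA_vs_DMSO, control: DMSO, treated: TALA, role: drug}
resampling:
  n_rep: 20
  group_size: 4
nomination:
  fdr_max: 0.1
  require_fdr: false
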