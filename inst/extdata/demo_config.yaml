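# Demo configuration: a desk-scale end-to-end run on synthetic data.
seed: 1
atlas:
  n_transcripts: 300
  n_cell_lines: 60
  n_lineages: 10
  n_planted_specific: 30
  specific_ratio: 0.8
  dropout_prob: 0.1
drugs:
  n_drugs: 2
  n_driver_transcripts_per_drug: 3
  effect_size: 2.0
  noise_sd: 0.5
regulome:
  n_rbps: 6
  n_regulated_per_rbp: 40
  frac_bound_of_regulated: 0.9
thresholds:
  min_tpm: 0.1
  prevalence_fraction: 0.2
  fc: 1.5
  fdr: 0.05
  rho_min: 0.2
  fdr_max: 0.05
  bootstrap_B: 100
  score_threshold: 0.7
  tss_window: 500
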