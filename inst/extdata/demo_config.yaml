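# Demo pipeline configuration: small synthetic field campaign
# (six sites, five taxa, 1-20 cells per taxon per site).
seed: 1
alpha: 0.05
ci_level: 0.95
group_threshold_pct: 5
synthetic:
  cells_per_site: [1, 20]
  points_per_cell: [3, 6]
  noise_sd: 0.005
  cell_sigma: 0.25
  point_sigma: 0.10
  grid_step: 2
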