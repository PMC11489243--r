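# Example GolgiEnsemble configuration. Every key is optional; anything
# unspecified falls back to the anatomical defaults.
fibres_per_territory: 175000
contact_probability: 0.00342
dendrites_per_cell: 3
fields_per_ensemble: 3
cells_per_field: 10
gap_group_size: 6
glomeruli_per_field: 700
convergence_min: 8
convergence_max: 12
truncation_threshold: 0.001
j_grid: [0.4, 0.6, 0.8, 1.0, 1.2, 1.4, 1.6, 1.8, 2.0]
replicates: 100
n_fields: 100
n_runs: 100
seed: 1
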