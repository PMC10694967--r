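family: reciprocal_migration
deme_sizes:
- 50
- 50
- 50
- 50
- 50
- 50
- 50
- 50
- 50
- 50
migration_rate: 0.02
migration_period: 1
total_generations: 1000
seed: 1
genome:
  sequence_length_bp: 10000000.0
  mutation_rate: 5.0e-08
  map_rate: 1.0e-07
  n_chromosomes: 5
sample:
  total_sample: 100
  scheme: pooled_equal
  focal_deme: 1
events: []

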