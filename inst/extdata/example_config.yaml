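# Example hgtflow run configuration. Omitted keys take the package defaults
# (100 species at 1e4 cells/mL, 1e4 steps, m = 0.02 per day, threshold 0.99).
total_time: 60 days
mechanisms:
  - conjugation
  - transformation
  - transduction
  - vesicle
gamma_conjugation: 1.0e-8
seed: 1
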