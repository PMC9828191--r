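# Example configuration for `rrsel fit` / `rrsel cv` on the packaged
# synthetic dataset. Paths are relative to the working directory; point
# `dataset` at a copy of the file from system.file("extdata",
# "synthetic_selection_30.csv", package = "rrsel").
dataset: synthetic_selection_30.csv
roles:
  fitness: absolute_fitness
  id: individual_id
  standard: [flower_number, plant_height, inflorescence_length]
  volatiles: [linalool, beta_ocimene, alpha_pinene, limonene, eugenol,
              benzyl_acetate, methyl_benzoate, phenylacetaldehyde]
  # the packaged fixture carries Gaussian-simulated relative-scale fitness
  allow_negative_fitness: true
model:
  rank: 1
  n_chains: 2
  n_warmup: 500
  n_samples: 500
  seed: 1
cv:
  n_folds: 5
  cv_seed: 1
fit_multiple_regression: true
out: rrsel_output
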