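# Example end-to-end configuration for run_pipeline(): simulate a small
# two-centre cohort, apply the detection filter, fit the three-level
# censored model and write ICC results. See ?run_pipeline for the schema.
seed: 1
output_dir: results/example_run
simulate:
  design:
    center_sizes: [20, 20]
    repeat_fraction: 0.9
    deterministic_repeats: true
  features:
    n_features: 8
filters:
  min_detection: 0.4
model:
  levels: 3
  adjusted: false
  iterations: 2000
  chains: 4
estimands: [three_level, within_center]
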