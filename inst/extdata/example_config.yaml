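# Example run configuration: overrides are merged onto defaultRunConfig().
# Usage: cfg <- readRunConfig(system.file("extdata", "example_config.yaml", package = "icSDM"))
seed: 42
months: [6, 7, 8, 9, 10, 11]
combiner: geometric_mean
effort:
  monthly_budget: 150
  k: 2
validation:
  iterations: 100
  train_fraction: 0.8
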