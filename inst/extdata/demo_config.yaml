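# Demo pipeline configuration (synthetic planted benchmark).
# Any omitted key inherits the package default.
seed: 1
output_dir: stericsel_demo_run
benchmark:
  n_catalysts: 18
  n_substrates: 5
  n_withheld: 4
  signal_fraction: 0.95
  linear_share: 0.35
split:
  method: yequidistant
  fraction: 0.5
sisso:
  rung: 2
  sis: 50
  dim: 3
linear:
  dim: 3
chemspace:
  k: 5
  n_init: 10
  n_components: 2
  kmeans_on: parameters
tree:
  max_depth: 3
  min_leaf: 5
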