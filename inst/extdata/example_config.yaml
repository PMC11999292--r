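# Desk-scale screening configuration: trains in minutes on one CPU.
# The package defaults (default_pipeline_config()) mirror the reference
# training setup (Adam 1e-4, batch 32, 100 epochs, 80:20 split); here every
# budget is shrunk and the learning rates raised accordingly so the small
# models converge within the reduced epoch counts.
seed: 1
data:
  image_side: 64
  n_per_class: 40
  crop_side: 64
gwo:
  enabled: false
  n_wolves: 5
  max_iters: 5
  budget_epochs: 5
  variant: standard
segmenter:
  depth: 2
  base_filters: 8
  dropout_rate: 0.1
  learning_rate: 0.001
  binarize_threshold: 0.5
  epochs: 25
  patience: 10
capsnet:
  conv_filters: 8
  primary_caps_types: 2
  routing_iters: 3
  epochs: 60
  batch_size: 8
  learning_rate: 0.001
  patience: 20
eval:
  train_fraction: 0.75
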