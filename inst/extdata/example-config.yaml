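# Example run configuration for the nibgm pipeline.
# Omitted fields keep the package defaults (default_run_config()).
seed: 1
out_dir: nibgm_run
study:
  n_subjects: 4
  n_days: 4
  samples_per_day: 17
model:
  hidden_size: 25
  n_lstm_layers: 3
  mlp_width: 25
  n_mlp_layers: 3
  epochs: 50
  learning_rate: 0.01
  batch_days: 4
cv:
  mode: ablation
  k_random: 10
  k_days: 8
  days_per_fold: 2
parkes_variant: type1
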