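name: fedpap_synthetic_iid
algorithm: fedpap
dataset: synthetic_iid
config:
  algorithm: fedpap
  learning_rate: 0.001
  num_rounds: 100
  clients_per_round: 10
  num_epochs: 10
  num_iters: 20
  eval_every: 1
  batch_size: 10
  seed: 0
  mu: 0.03
  stepsize: 4.0
  scope: per_layer
  negate_scores: no
  iter_mode: product
  loss_on: test
data_spec:
  alpha: 0.0
  beta: 0.0
  n_clients: 30
  n_features: 60
  n_classes: 10
  iid: yes
  seed: 0
  train_fraction: 0.9
  size_base: 50.0
  size_meanlog: 4.0
  size_sdlog: 2.0
  cov_exponent: 1.2
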