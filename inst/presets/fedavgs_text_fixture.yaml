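name: fedavgs_text_fixture
algorithm: fedavgs
dataset: text_fixture
config:
  algorithm: fedavgs
  learning_rate: 0.001
  num_rounds: 20
  clients_per_round: 10
  num_epochs: 1
  num_iters: 10
  eval_every: 1
  batch_size: 10
  seed: 0
  mu: 0.0
  stepsize: 9.0
  scope: per_layer
  negate_scores: no
  iter_mode: product
  loss_on: test
data_spec:
  n_dialogues: 60
  sentences_per_dialogue_mean: 20.0
  vocab_size: 500
  n_classes: 2
  label_skew: 1.0
  seed: 0
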