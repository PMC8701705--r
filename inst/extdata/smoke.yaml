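# Small end-to-end run: simulate, preprocess, train a baseline LSTM for one
# epoch, prune half the channels, retrain, evaluate.
cohort:
  n_patients: 500
  prevalence: 0.109
  seed: 7
preprocess:
  bin_width: 1
  horizon: 48
model: lstm
condense: prune
prune_quantile: 0.5
pre_epochs: 1
post_epochs: 5
test_fraction: 0.15
train:
  learning_rate: 0.001
  batch_size: 8
  epochs: 6
  seed: 7
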