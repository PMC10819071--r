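# Default training configuration (mirrors crossmol_config() defaults).
model_dim: 128
n_heads: 8
n_layers: 4
rounds: 3
set2set_steps: 3
aggregate: sum
dropout: 0.1
max_len: 256
ablation: full          # full | no_graph | no_sequence
lr: 0.0001
batch_size: 64
max_epochs: 100
patience: 15
seeds: 10
split: scaffold         # scaffold | random
fractions: [0.8, 0.1, 0.1]
min_freq: 5
max_token_len: 8
max_vocab: 1024
n_bins: 5
# dataset options
smiles_column: smiles
task_type: classification
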