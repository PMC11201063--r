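# Paper-scale model configuration: the calibrated defaults reproducing the
# published parameter budgets for every ablation variant.
variant: full
stage_channels: [16, 32, 64, 128, 128]
decoder_channels: [64, 64, 32, 16]
in_channels: 3
out_channels: 1
lka:
  dw_kernel: 5
  dwd_kernel: 7
  dwd_dilation: 3
faencoder:
  hidden_ratio: 1
vam:
  expansion: 2
  state_dim: 16
  conv_kernel: 4
  dt_rank: ~
  levels: [1, 2, 3, 4]
psa:
  splits: 4
  groups: [1, 4, 8, 16]
  se_reduction: 4
attention:
  ca_reduction: 4
  sa_kernel: 7
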