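# Published training protocol.
init_lr: 0.001
power: 0.9
max_epoch: 200
batch_size: 8
weight_decay: 0.00001
augment: true
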