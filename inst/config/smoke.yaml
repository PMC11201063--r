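# Smoke-scale profile: the full architecture at reduced width, sized for
# single-CPU runs (see the methods vignette).
variant: full
stage_channels: [4, 8, 16, 32, 32]
decoder_channels: [16, 16, 8, 4]
psa:
  splits: 4
  groups: [1, 2, 4, 8]
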