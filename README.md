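# lightcf

Real-time polyp segmentation from colonoscopy frames with **LightCF-Net**,
a lightweight long-range context fusion network, implemented as a
self-contained R package. The package targets methods researchers who
want to study the architecture's components — large-kernel attention,
state-space (Mamba-style) skip connections, pyramid split attention — on
CPU, without a deep-learning framework: it ships its own reverse-mode
autodiff tape with C++ kernels, a compound BCE-Dice loss, segmentation
metrics, a seeded synthetic colonoscopy-like data generator, and a full
train/evaluate/predict pipeline with a command-line interface.

## The model

A five-stage U-shaped encoder–decoder with per-stage channels
{16, 32, 64, 128, 128} (≈1.51 M trainable parameters in the full
configuration):

* **FAEncoder** (stages 2–5): `X2 = Conv3x3(X1)`;
  `Y1 = Conv1x1(LKA(GELU(Conv1x1(X2))))`; `Y2 = Conv1x1(X2)`;
  `Yout = CA(Conv3x3(Y1 + Y2))`, where **LKA** is
  `x ⊙ Conv1x1(DWDConv7,d3(DWConv5(x)))` — a 21×21 effective receptive
  field from depth-wise pieces — and CA is a squeeze-excitation channel
  gate.
* **VAM** on every skip: flatten to a raster sequence `W ∈ R^{L×C}`
  (L = H·W), layer norm, then a gated Mamba block
  `Z1 = LN(SSM(SiLU(Conv1d(Linear(W)))))`, `Z2 = SiLU(Linear(W))`,
  `Wout = Linear(Z1 ⊙ Z2)`, where the **SSM** is the causal selective
  scan `h_t = exp(Δ_t A) ⊙ h_{t−1} + Δ_t B_t u_t`,
  `y_t = C_t·h_t + D ⊙ u_t` (N = 16, λ = 2); fused with a 1×1 branch and
  channel–spatial attention:
  `Pout = SA(CA(Conv1x1(Concat(Wout′, X2))))`.
* **PSA** at the 128-channel bottleneck: four group convolutions with
  kernels 3/5/7/9 produce 32 channels each (`F_i`); a shared SE module
  scores each branch and `att_i = softmax_i(SE(F_i))` recalibrates them
  (`T_i = att_i ⊙ F_i`) before concatenation.

Training follows the published protocol: BCE-Dice loss
`L = BCE(P,G) + 1 − (2ΣG_iP_i + σ)/(ΣG_i + ΣP_i + σ)`, Adam with weight
decay 1e-5, poly schedule `lr = 0.001·(1 − epoch/200)^0.9`, batch size 8,
flips and ±90° rotations, resize-to-320 / random-crop-256 inputs.

## Worked example

```r
library(lightcf)

# the four ablation parameter budgets (M)
for (v in c("baseline", "faencoder", "vam", "full")) {
  n <- count_parameters(build_model(model_config(variant = v), seed = 1))
  cat(sprintf("%-10s %9d params = %.2f M\n", v, n, n / 1e6))
}
#> baseline     971185 params = 0.97 M
#> faencoder   1159081 params = 1.16 M
#> vam         1213801 params = 1.21 M
#> full        1510793 params = 1.51 M

# train the smoke-scale full model on synthetic fixtures and evaluate
cfg <- model_config(variant = "full",
                    stage_channels = c(4, 8, 16, 32, 32),
                    decoder_channels = c(16, 16, 8, 4),
                    psa = psa_config(4, c(1, 2, 4, 8)))
model <- build_model(cfg, seed = 7)
data <- synth_dataset(synth_config(image_size = 128, seed = 11), 8)
res <- train(model, data,
             train_config(init_lr = 0.008, max_epoch = 100, batch_size = 4,
                          seed = 3),
             max_steps = 200)
evaluate(model, data)
#> segmentation metrics over 8 image(s):
#>   IoU 91.55%  DSC 95.50%  SE 98.12%  SP 99.13%  ACC 99.17%
```

The parameter budgets are the architecture-level headline numbers: the
baseline U-Net at these widths costs 0.97 M parameters, the fusion
attention encoder adds ≈0.19 M, the Mamba skip modules ≈0.24 M, and the
pyramid-split bottleneck ≈0.11 M. The training call overfits the eight
synthetic images in 200 optimizer steps (final training loss 0.139);
`evaluate()` prints the per-image-averaged IoU/DSC/SE/SP/ACC of the
fitted model — the Dice of 95.5% shows the whole loop (forward pass,
backpropagation, Adam, schedule) is functioning, not that this small
model generalises (the smoke training test requires DSC ≥ 90% here).

The command-line interface wraps the same functions:

```sh
inst/cli/lightcf profile --variant full
inst/cli/lightcf synth --n 16 --out data/synth --seed 1
inst/cli/lightcf train --data synthetic --out runs/demo --seed 1
inst/cli/lightcf evaluate --checkpoint runs/demo/checkpoint.rds --data data/synth
inst/cli/lightcf predict --checkpoint runs/demo/checkpoint.rds --input data/synth --out preds
```

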