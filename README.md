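# veinnet

Finger-vein verification in R: a residual convolutional network built from
pyramidal (multi-scale grouped) convolutions with scale-aware attention, a
generalized-mean (GeM) global descriptor, a joint softmax + center-loss
training objective, and the open-set biometric evaluation protocol
(genuine/impostor pairs, FAR/FRR curves, EER, Acc). A seeded generator of
synthetic vein-like images makes the whole pipeline runnable and testable
without access to restricted finger-vein datasets — the package is aimed at
biometrics researchers who want a transparent, CPU-runnable reference
implementation of this model family.

## The model

Near-infrared light is absorbed by deoxygenated hemoglobin, so finger veins
image as dark ridges on brighter tissue. Discriminative detail lives at
several spatial scales at once, which motivates three components:

* **Pyramidal convolution.** Parallel grouped convolutions with kernels
  `K = 3, 5, 7, 9` and decreasing depth, concatenated channel-wise. Under
  the idealized depth schedule `FM_i K_1^2 / K_i^2`, every level costs
  `K_1^2 · FM_i · FM_oi` parameters — the same as a standard 3×3
  convolution — so the pyramid widens the receptive field for free
  (`pyconv_param_count()`, `pyconv_flop_count()`).
* **Scale-aware attention.** Per image, two 1×1 reductions of the
  multi-scale map give `Ω ∈ R^{C×N}` and `Θ ∈ R^{N×C}` (`N = H·W`);
  `Φ = softmax(ΩΘ)` is a row-stochastic `C×C` cross-scale descriptor, and
  each scale is refined as `F_i ← gate · Σ_j Φ_ij F_j + F_i` with a gated
  skip connection (`compute_scale_descriptor()`,
  `scale_attention_refine()`).
* **GeM descriptor and joint loss.** The final map is pooled per channel as
  `f_c = (mean x^{p_c})^{1/p_c}` with learnable exponents (`p = 1` is
  average pooling, `p → ∞` max pooling); training minimizes
  `L = L_s + λ·L_c` with `L_c = ½ Σ_i ‖x_i − c_{y_i}‖²` pulling embeddings
  toward per-class centers.

Verification follows the open-set protocol: train and test classes are
disjoint; on `N_c` test classes of `N_f` samples, all
`N_g = N_c·N_f(N_f−1)/2` within-class pairs are genuine and
`N_i = C(N_c, 2)` representative cross-class pairs are impostors; EER is
the FAR/FRR crossing.

## Worked example

Generate a small synthetic dataset, train briefly, and score open-set
verification:

```r
library(veinnet)

ds  <- generate_dataset(synth_config(n_classes = 20, samples_per_class = 6,
                                     height = 64, width = 64, seed = 1))
cfg <- run_config(input_size = 64, stem_channels = 16,
                  stage_widths = c(16, 32, 64, 64),
                  classes_per_batch = 10, samples_per_class = 4,
                  lambda = 0, seed = 7)
res <- run_open_set(ds, cfg, fold_seed = 1, epochs = 40)
res$trained
#> Verification result: EER 16.67% (threshold 0.2959), Acc 90.77%
#>   150 genuine pairs, 45 impostor pairs
res$untrained
#> Verification result: EER 22.22% (threshold 0.9955), Acc 82.05%
#>   150 genuine pairs, 45 impostor pairs
```

Training on the 10 held-in classes reduces the equal error rate on the 10
never-seen classes from 22.2% (random initialization) to 16.7%, and lifts
verification accuracy from 82.1% to 90.8%: the embedding has learned
vein-topology structure that transfers to unseen fingers (the run takes
about half a minute on one CPU core). `autoplot(res$trained)` draws the
FAR/FRR curves with the EER operating point; `inspect_model(res$fit$model)`
prints the per-block idealized/realized parameter accounting. On this
desk-scale profile the center-loss weight is set to 0 — the methods
vignette explains why the center term only pays off at longer training
budgets.

A command-line front end wraps the same functions:

```sh
veinnet simulate --synth-profile test --seed 1 --out data/synth
veinnet train    --data data/synth --epochs 10 --out runs/a
veinnet evaluate --checkpoint runs/a/model.rds --data data/synth --out runs/a
```

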