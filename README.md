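# spectdenoise

Deep-learning denoising of low-dose SPECT myocardial perfusion imaging
(MPI), packaged as a fully testable simulation-to-evaluation pipeline for
medical-physics and imaging-methods researchers. It targets the question:
*how far can the injected dose be reduced if a network predicts
standard-dose projections from low-dose ones before reconstruction?*

Because clinical raw data cannot ship with a package, every stage runs on
synthetic cardiac phantoms with known ground truth; the clinical numbers
that the pipeline's reporting is checked against enter only as published
cohort summary tables.

## The method

**Low-dose simulation.** A standard-dose acquisition is a Poisson count
grid `y ~ Poisson(λ)` over 32 projection views of 64 × 64 pixels (6.4 mm).
A reduced-dose study at dose fraction *p* keeps each detected event
independently with probability *p* (binomial thinning, the in-silico
equivalent of resampling list-mode data): per bin
`y_low | y ~ Binomial(y, p)`, so `y_low ~ Poisson(p λ)` exactly — a true
low-dose acquisition, not a rescaled one. Presets: *p* = 1/2, 1/4, 1/8,
plus multinomial splitting into 8 cardiac gates.

**Denoising.** A conditional GAN maps single low-dose views to predicted
standard-dose views. The generator is a six-level U-Net
(encoder filters 64–128–256–512–512–512, 4 × 4 kernels, stride 2, to a
1 × 1 bottleneck; decoder mirrors with skip connections, dropout on the
first decoder block, sigmoid output). The discriminator scores
(low-dose, candidate) pairs with four convolutional blocks
(48–96–192–384) into an 8 × 8 patch probability map. The generator
minimises `1·BCE_adv + 100·‖G(x) − y‖²`; both networks use Adam
(lr 0.001). The network engine is implemented in-package (BLAS + C++
kernels) with finite-difference-verified backpropagation and bit-level
seed reproducibility.

**Reconstruction.** OSEM (8 iterations, 2 interleaved subsets) with a
back-projector that is the exact adjoint of the forward projector (so
one-subset MLEM has provably non-decreasing Poisson likelihood), then a
radial Butterworth low-pass `H(f) = 1/(1 + (f/0.45)^{20})` (cutoff as a
fraction of Nyquist), then rigid reorientation into short-axis / long-axis
stacks.

**Evaluation.** Paired metrics `PSNR = 20 log₁₀(Peak/RMSE)`,
`RMSE = √(Σᵢ(yᵢ−ỹᵢ)²/n)`, a global-moment SSIM with absolute constants
C₁ = 0.01, C₂ = 0.02, Pearson correlation; Bland–Altman bias and limits of
agreement `d̄ ± 1.96·SD(d)` with a paired t-test; percent-change reporting;
and a transparent 17-segment summed-score surrogate for perfusion-defect
quantification.

## Worked example

Simulate a severe-defect patient, thin to half dose, train the denoising
model briefly on four other phantoms, and compare arms:

```r
library(spectdenoise)

geom  <- acquisition_geometry()           # 32 views, 64 x 64, 6.4 mm
train <- simulate_cohort(c("healthy", "low", "intermediate", "severe"),
                         geom, total_counts = 2e5, master_seed = 101)
test  <- simulate_cohort("severe", geom, total_counts = 2e5,
                         master_seed = 999)

low_tr <- lapply(train$standard, function(s) binomial_thin(s, 0.5, seed = 1)$kept)
low_te <- binomial_thin(test$standard[[1]], 0.5, seed = 2)$kept

fit <- gan_train(paired_views(low_tr, train$standard),
                 train_config(epochs = 4, batch_size = 1, seed = 42))
pred <- denoise(fit, low_te)

ref <- proj_values(test$standard[[1]])
rbind(metrics_report(ref, proj_values(low_te), label = "half_dose"),
      metrics_report(ref, proj_values(pred),   label = "predicted"))
```

```
#> # A tibble: 2 x 5
#>   label     psnr_db  rmse  ssim pearson_rho
#>   <chr>       <dbl> <dbl> <dbl>       <dbl>
#> 1 half_dose    25.0  6.37 0.637       0.995
#> 2 predicted    33.3  3.38 0.951       0.963
```

(The run takes about six minutes on one CPU, almost all of it training.)
The predicted arm recovers the count scale and noise level of the
standard-dose reference: PSNR rises by more than 8 dB, RMSE nearly halves
and the global SSIM climbs from 0.64 to 0.95 against the unscaled
half-dose input. The half-dose arm's higher Pearson correlation is not a
contradiction — correlation is scale-invariant, so it ignores exactly the
factor-of-two count deficit that dominates the other three metrics.
Reconstruction and scoring continue the pipeline (the phantom knows its
true long axis):

```r
vol <- butterworth(osem(pred))            # 8 it x 2 subsets, order 10 / 0.45
ax  <- test$phantom[[1]]$lv_params$axis
sa  <- reorient(vol, azimuth_deg = atan2(ax[2], ax[1]) * 180 / pi,
                elevation_deg = acos(ax[3]) * 180 / pi)
segment_scores(sa)$summed_score
#> [1] 24
```

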