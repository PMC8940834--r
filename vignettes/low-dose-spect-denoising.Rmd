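---
title: "Low-dose SPECT-MPI denoising: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Low-dose SPECT-MPI denoising: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Myocardial perfusion imaging (MPI) with SPECT requires enough injected
activity to produce diagnostically usable images; reducing the dose raises
Poisson noise until perfusion defects can no longer be distinguished from
noise. One strategy is to acquire at reduced dose and restore image quality
computationally: train a network on paired (low-dose, standard-dose)
projection data and use it to predict standard-dose projections before
reconstruction. Working in projection space keeps the method independent of
the reconstruction algorithm and post-filtering.

`spectdenoise` implements this pipeline end to end as testable components:

1. **phantom** — synthetic left-ventricle activity maps and parallel-beam
   projections with Poisson counting noise;
2. **lowdose** — reduced-dose simulation by binomial thinning and cardiac
   gating by multinomial splitting;
3. **denoiser** — a conditional GAN (U-Net generator, patch discriminator)
   mapping low-dose views to predicted standard-dose views;
4. **recon** — OSEM reconstruction, Butterworth post-smoothing, cardiac
   reorientation;
5. **evalmetrics** — PSNR / RMSE / global SSIM / Pearson correlation,
   Bland–Altman agreement, percent-change reporting and a 17-segment
   summed-score surrogate;
6. **cli_io** — projection/volume containers on disk, manifests, and an
   end-to-end experiment driver with one master seed.

## The synthetic phantom and acquisition model

Clinical cardiac SPECT raw data are rarely shareable, so the package
generates its own study material. The LV myocardium is modelled as a
half-ellipsoidal shell: an ellipsoidal shell (outer semi-axes 32, 32, 48 mm;
wall 10 mm — typical adult LV dimensions at SPECT resolution) truncated at
the base plane, with uniform relative uptake. Perfusion defects are angular
/ axial sectors of the shell whose activity is multiplied by `1 - severity`;
the carved masks are stored with the phantom as ground truth. The long axis
is configurable so reorientation code meets phantoms whose true axis is
known. An optional ellipsoidal "hot liver" blob exercises the row-cropping
step that mimics manual liver exclusion.

The camera model is a 64 x 64 detector with 6.4 mm pixels acquiring 32
parallel-beam views over a 180-degree arc (right anterior oblique to left
posterior oblique), matching a dual-head 90-degree cardiac system. The
projector is rotate-and-sum with bilinear interpolation — no attenuation,
scatter or depth-dependent resolution, none of which the modelled processing
chain compensates either. Projections are line integrals (activity x mm);
counts are drawn per bin from a Poisson law after the expectation is scaled
to a chosen total.

The standard-dose count level is **2e5 expected counts per non-gated
projection set**. Clinical acquisitions state injected activity and seconds
per view rather than counts, so a count level has to be declared: 2e5 over
32 views gives peak view bins of roughly 150–200 counts, the order of
magnitude of a standard-rest acquisition binned at 64 x 64, and low-dose
arms at 1/8 of it remain clearly above the all-noise regime. This level is
a package assumption, not a reproduction of any specific scanner.

What the generator deliberately does *not* emulate: anatomical background
uptake (lungs, gut), attenuation and scatter, collimator blur, patient and
respiratory motion, and ECG variability beyond a stated gate-weight table.
Tests passing on these phantoms therefore demonstrate the *mechanics* of
the pipeline (count statistics, architecture, optimisation, metrics), not
clinical performance on real data.

## Low-dose simulation

Reduced-dose acquisitions are simulated exactly as one would resample
list-mode data: every detected event is kept with probability `p`
independently. On binned counts this is a per-bin Binomial(n, p) draw —
distribution-identical to per-event selection (an explicit event-list
adapter, `thin_events()`, demonstrates the equivalence) — and by the
Poisson thinning theorem the kept bins are again Poisson with mean
`p * lambda`, which is what makes the kept set a faithful low-dose
acquisition rather than merely a scaled one. `kept + rejected` equals the
parent exactly, bin for bin. Gating splits counts by a multinomial draw
with per-gate weights (uniform by default over 8 gates) and is independent
of thinning; a gated half-dose study is `split_gates()` followed by
`binomial_thin(0.5)` per gate.

## The conditional GAN

The generator is a U-Net on single 2D projection views (64 x 64, one
channel); the 32 views of an acquisition are 32 training samples. Six
stride-2 4 x 4 convolutional encoder blocks (filters 64, 128, 256, 512,
512, 512) take the view to a 1 x 1 bottleneck; batch normalisation is
applied in encoder blocks 2–4, LeakyReLU(0.2) in blocks 1–5 and ReLU in
block 6. Six stride-2 transposed-convolution decoder blocks (filters 512,
512, 256, 128, 64, 1) mirror the encoder with skip concatenations on
blocks 1–5, batch normalisation, dropout (rate 0.5) on block 1, ReLU after
each concatenation and a sigmoid output. There are no pooling layers. The
discriminator concatenates the low-dose view with a candidate standard-dose
view and applies four 4 x 4 conv blocks (filters 48, 96, 192, 384; strides
2, 2, 2, 1; conv + batch-norm + LeakyReLU(0.2)), then a 1 x 1 single-filter
convolution, batch normalisation and sigmoid, yielding an 8 x 8 patch
probability map.

Training alternates discriminator updates (binary cross-entropy on real
and generated pairs) with generator updates on
`1 * BCE_adversarial + 100 * L2`, the 100/1 weighting favouring the L2-norm
term; both networks use Adam at learning rate 0.001. Choices the
architecture description leaves open are fixed as defaults and exposed in
`gan_spec()` / `train_config()`:

* **Normalisation.** The sigmoid output requires inputs in (0, 1); both
  arms are divided by one global constant — the maximum standard-dose view
  count over the training set — stored with the model. Using a single
  constant for both arms preserves the low-dose/standard-dose scale ratio
  that the network must learn.
* **Output-layer bias initialisation.** The final layer's bias starts at
  the logit of the mean normalised target rather than zero. A sigmoid
  starting at 0.5 everywhere is an order of magnitude too bright for
  projection data, and recovering the global count scale is by far the
  slowest training mode; initialising the output at the data's mean (a
  standard data-statistics bias recipe) removes that mode and makes
  short CPU trainings converge to scale-calibrated predictions.
* **Batch size 8, "same" padding, transposed-convolution upsampling,
  dropout 0.5, no label smoothing.** All unstated upstream; recorded in the
  configuration. The package's own scaled-down studies train at batch 1
  (as canonical image-translation U-Nets do): with small synthetic training
  sets the number of optimiser steps, not the number of epochs, limits
  convergence, and shrinking the batch multiplies the steps per epoch at
  the same arithmetic cost (the loss histories at batch 1, 2, 4 and 8
  coincide almost exactly when aligned by optimiser step).
* **Encoder block 6 uses ReLU** (not LeakyReLU), exactly as specified for
  this architecture, although canonical image-translation U-Nets differ.
* **Discriminator batch normalisation** is applied in all four blocks
  (`disc_bn_first` flag exposes the alternative of skipping block 1, which
  the published description leaves ambiguous).
* **Independent models per dose level.** One model is trained per dose arm
  with independent initialisation.

The engine itself is implemented in-package on BLAS matrix operations
(im2col convolutions, exact-adjoint transposed convolutions, batch-norm
with running statistics, Adam in C++), with backpropagation verified
against finite differences in the test suite. Training is fully seeded and
bit-reproducible.

## Reconstruction

OSEM with 8 iterations and 2 subsets is the default, the subsets being the
interleaved even/odd view sets (the partition is not otherwise specified
anywhere; interleaving balances angular coverage). The back-projector is
the exact matrix transpose of the forward projector, so the one-subset
special case (MLEM) provably has a non-decreasing Poisson log-likelihood —
the test suite checks this monotonicity and the count-conservation property
that total reprojected counts equal total measured counts after each full
iteration. Initialisation is a uniform positive volume; voxels with zero
sensitivity are frozen at zero rather than divided by zero.

Post-smoothing uses a radially symmetric Butterworth filter,
`H(f) = 1 / (1 + (f / fc)^(2 * order))` with order 10 and cutoff 0.45. Two
conventions had to be fixed because "cutoff 0.45" alone does not determine
them: the cutoff is interpreted as a **fraction of the Nyquist frequency**
(the dominant convention in nuclear-medicine software, where voxel sizes
make cycles/cm awkward) and the **squared-magnitude form** is used, so the
gain at the cutoff is exactly 0.5. Both are arguments, not constants.
Reorientation to short-axis applies the rigid rotation aligning the stated
LV long axis with the volume z axis (trilinear interpolation); vertical and
horizontal long-axis stacks are axis permutations of the SA volume.
Automatic axis detection is out of scope — phantoms know their true axis.

## Evaluation metrics

RMSE, global SSIM and Pearson correlation follow their standard sum
formulas; SSIM is computed from *global* image moments with absolute
stabilising constants C1 = 0.01, C2 = 0.02 (no sliding window, no
dynamic-range scaling of the constants — the constants are given as
absolute values, so rescaling them would change the metric).

PSNR needs two decisions. The conventional definition is
`20 log10(Peak / RMSE)`; the formula sometimes appears in print as
`20 log10(Peak / MSE)`, which is dimensionally inconsistent (doubling both
images would change it). The package defaults to the RMSE form and exposes
the as-printed variant (`variant = "peak_over_mse"`). Second, `Peak`
defaults to the maximum of the test (low-dose or predicted) image, with
the reference maximum selectable (`peak = "reference"`). The default
matches how such metrics are usually quoted for a single arm, but it makes
comparisons *between* denoising models subtle: each model's Peak is its
own predicted maximum, so small incidental brightness differences move
PSNR independently of error. The package's own cross-arm contrasts (the
dose-ordering study) therefore fix `Peak` to the shared standard-dose
reference, under which the PSNR ordering coincides with the RMSE ordering;
within-arm comparisons keep the default. All percent-change reporting
operates on published summary tables or like-for-like computed pairs, so
neither choice silently alters a comparison.

Bland–Altman agreement reports the bias (mean difference), the limits of
agreement `bias ± 1.96 sd` of the differences, and a two-sided paired
t-test. Some agreement plots label their dashed lines as the "95%
confidence interval", which properly refers to the much narrower
`bias ± 1.96 sd / sqrt(n)` band; both are available
(`limits = "ci_of_bias"`), with limits of agreement the default since that
is what agreement analysis of paired clinical indices requires.

The 17-segment summed score is a deliberately simplified surrogate for
proprietary perfusion-quantification software: maximal-count
circumferential profiles per short-axis slice and angular bin, AHA-style
segment grouping (6 basal, 6 mid, 4 apical, apex cap), uptake as a fraction
of the maximal profile value, and the conventional 5-point scale (>= 70% of
maximum scores 0; 50–69% scores 1; 30–49% scores 2; 10–29% scores 3;
< 10% scores 4). It shares the angular convention of the phantom's defect
model so ground-truth defects land in known segments. It does not model
gender-specific normal databases, defect extent/TPD, or any vendor's
blackout maps, and its absolute scores are not comparable to clinical
summed scores; only its internal contrasts (standard vs low-dose vs
predicted on the same phantom) are meaningful.

## Numerical choices and degenerate inputs

* Seeds: every stochastic stage draws from a named substream of one master
  seed (`substream_seed()`), so stages are independently reproducible;
  identical inputs and seeds give bit-identical outputs.
* OSEM guards: forward-projection zeros contribute nothing to the update
  ratio; all-zero data annihilate the volume after one multiplicative
  update (tested); likelihood terms with `Ax = 0, y > 0` report `-Inf`.
* PSNR of identical images is reported as `Inf` with a warning rather than
  an error, since cohort summaries should flag rather than crash.
* The Butterworth filter clamps the tiny negative ringing it can introduce
  into nonnegative volumes back to zero.
* Gate splitting uses the sequential-binomial construction of a multinomial
  draw, which is exact and vectorises across bins.
* Degenerate geometry (wall thicker than the shell, empty crops, subsets
  not dividing the views, probabilities outside [0, 1]) fails fast with
  parameter errors.

## Problem sizes in the test suite and acceptance studies

The packaged studies are scaled to a single CPU. Structural and statistical
tests use a 16-cubed phantom with an 8-view arc, which exercises identical
code paths to the clinical 64-cubed / 32-view geometry. The GAN studies
train on 66 view pairs drawn from six risk-stratified phantoms (11
alternating views each, preserving anatomical diversity) at batch 1 for
roughly 130-260 optimiser steps, which with the scale-calibrated output
initialisation is past the knee of convergence for this family (half-dose
gains of about +11 dB over the unscaled low-dose baseline on held-out
phantoms), and evaluate on two held-out phantoms (64 views) never seen in
training. The dose-arm ordering study trains one model per dose at
identical settings and contrasts the arms with the common-peak PSNR
described above. These sizes are the package's declared study conditions;
they
demonstrate the mechanism at reduced scale, not clinical-scale
performance.

## Known limitations

* The phantom family is geometrically simple; a network trained on it will
  not transfer to clinical projections, and none of the packaged numbers
  are clinical claims.
* The projector ignores attenuation, scatter and resolution modelling, so
  reconstructed contrast is idealised.
* Global-moment SSIM is less discriminative than windowed SSIM for local
  artefacts; it is used because its constants and form are fully specified.
* The segment surrogate approximates ring/sector geometry on a coarse
  64-cubed grid; partial-volume effects at segment borders are untreated.
* Training at clinical scale (hundreds of patients, ~50 epochs) is
  supported by the code but not by a single-CPU time budget; the packaged
  studies are scaled-down analogues.
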