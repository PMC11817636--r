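---
title: "Multispectral lesion classification: model, phantom and protocol"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multispectral lesion classification: model, phantom and protocol}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The question this package answers

Multispectral (MS) dermatology devices illuminate a lesion sequentially at a
handful of LED bands — here eight, centred at 414, 447, 477, 524, 671, 735,
890 and 995 nm — and record one image per band, a *spectral cube*. The bands
sample the absorption spectra of skin chromophores: melanin decays
monotonically from the violet into the near infrared, hemoglobin absorbs
strongly in the blue/green with a pronounced window near 671 nm, and water
only becomes absorbing above roughly 700 nm. Because lesion etiologies
(benign nevi, melanomas, basal cell carcinomas) differ in chromophore
content, the band-wise reflectance carries diagnostic signal that a
conventional RGB camera cannot see.

The package implements the complete analysis needed to quantify that claim
with convolutional networks: simulate calibrated reflectance cubes with
controllable class structure, train the two reference architectures under a
stratified cross-validation protocol, and compare a full 8-band arm against
an RGB-like 3-band control arm (447/524/671 nm) that shares every other
detail of the pipeline.

Since the clinical MS dataset that motivates this design is not publicly
deposited, all empirical statements in this vignette are statements about
the synthetic phantom, verified by the test suite; the package reproduces
the *mechanism and ordering* of the full-cube vs RGB comparison, not the
clinical accuracy values.

## The optical phantom

`simulate_dataset()` renders raw captures from a Beer–Lambert-style
multiplicative absorption model. A lesion is an ellipse with a low-order
radial Fourier boundary perturbation (melanomas get a more irregular border,
mirroring the clinical ABCD warning signs — cosmetic, not load-bearing) and
a logistic soft edge. Per band $\lambda$, the true reflectance is

$$R(i,j,\lambda) = R_{\mathrm{skin}}(\lambda)\,
  \Big[m(i,j)\, e^{-\sum_c \kappa_c A_c(\lambda)} + (1 - m(i,j))\Big],$$

where $m$ is the soft footprint, $\kappa_c$ the lesion's chromophore
concentrations drawn from class-conditional ranges, and $A_c(\lambda)$ the
relative absorption panel shipped as a fixed, documented constant
(`build_default_chromophore_panel()`); the device study plots but does not
tabulate absorptions, so the panel encodes the qualitative shapes above.
Raw counts are then

$$S(i,j,\lambda) = \mathrm{round}\big(d + G(i,j,\lambda)\,R(i,j,\lambda)
 + \varepsilon\big)$$

clipped to the 12-bit range, with dark offset $d$, Gaussian sensor noise
$\varepsilon$, and a smooth per-capture polynomial illumination gain $G$
shared between the lesion and the neutral-gray reference frames — which is
precisely what makes flat-field correction consequential and testable. A
saturation guard rejects renders where more than 10% of pixels clip.

Three separability modes define the study conditions:

* `all_bands` — classes differ in melanin, hemoglobin and water loads
  across the whole spectrum (nevus moderate melanin, melanoma high melanin,
  BCC low melanin but more vascular and hydrated);
* `nir_only` — melanin and hemoglobin ranges are shared by all classes and
  only the water concentration differs. Because the shipped panel sets
  water absorption to exactly zero below 700 nm, the 447/524/671 nm bands
  are class-uninformative *by construction*, which turns the full-cube vs
  RGB comparison into a controlled ablation with known ground truth;
* `none` — one shared distribution, the no-signal negative control.

The study never quantifies chromophore content per etiology, so the
concentration ranges are stipulated package constants chosen once to give
an unambiguous contract: in `nir_only` mode the class means at 890 nm are
separated by well over two within-class standard deviations while the
sub-700 nm bands agree to within a fraction of one (verified by a 200-draw
Monte-Carlo test).

Defaults follow the study composition: class counts 327/112/70
(nevus/melanoma/BCC; the cohort table also reports 332 retained nevi — the
training count 327 is used as the default), 12-bit depth, and a frame of
192 × 256 (the device sensor scaled by 5 so that desk-scale runs are fast;
the native 960 × 1280 geometry is a config option).

What the phantom deliberately does **not** emulate: radiative transfer or
photon migration, specular reflection (the device crosses polarizers), hair
and motion artifacts (such captures were discarded upstream in the study),
camera PSF, or intra-lesion texture beyond the soft edge. Passing tests
therefore demonstrate that the pipeline's statistics and learning machinery
behave correctly under controlled spectral structure — not that the
networks would reach any particular accuracy on clinical images.

## Calibration

`calibrate()` applies the reflectance normalisation

$$R^{\lambda}(i,j) = k\,
  \frac{S^{\lambda}_{\mathrm{lesion}}(i,j) - S^{\lambda}_{\mathrm{dark}}(i,j)}
       {S^{\lambda}_{\mathrm{neutral}}(i,j) - S^{\lambda}_{\mathrm{dark}}(i,j)},$$

with $k$ the known reflectance of the neutral gray reference (default
0.198, a mid-gray patch). Numerical choices, each documented because the
source protocol is silent on them:

* the result is clipped to $[0,1]$ to keep the learning input bounded;
* denominator pixels at or below 1 count are treated as dead and filled
  with the local 3 × 3 median of valid neighbours; more than 5% dead pixels
  in a band rejects the capture as corrupt;
* with all three frames rounded to integer counts, the per-pixel
  reconstruction error is bounded by $(k + R)/(Gk - 1)$; the round-trip
  test asserts exactly this bound against the phantom's stored ground
  truth;
* no zero-mean/unit-variance standardisation is applied (the protocol
  states reflectance calibration replaces it);
* resizing to the network input (`resize_cube()`, default 128, smoke scale
  32 or 16) uses exact area-weighted interpolation, preserves constants,
  and happens *after* calibration — the source does not state the order,
  and calibrating at capture resolution keeps the flat-field physics at
  the sensor geometry.

`select_bands(cube, c(447, 524, 671))` extracts the RGB-like control arm.

## Dataset protocol

The class imbalance (327/112/70) is handled the way the study found
superior: random downsampling to the minimum class (70/70/70, 210 cubes)
via `balance_downsample()`. Loss weighting remains available:
`compute_class_weights()` implements the balanced scheme
$w_i = m/(C\,n_i)$ — the semantics of the utility the study names as its
source, adopted because the printed weight formula is internally
inconsistent with its own prose. A weighted training path exists behind
`use_class_weights`, but the balanced subset is the primary path.

`make_fold_plan()` first holds out a stratified 20% test set, then
partitions the remaining pool into five stratified folds. Per-class
leftovers rotate across folds by class index so every validation set's
class proportions stay within one sample of global proportions (with
70/70/70 this gives validation sets of 33–34).

Augmentation (`augmentation_policy()`) uses continuous uniform rotation
with reflect fill plus independent horizontal/vertical flips at probability
0.5, applied identically to all bands of a cube; 90°-only rotations could
not produce fifty distinct copies, so continuous angles are the coherent
reading of the stated augmentation factor of 50. Random cropping and
intensity jitter are excluded (cropping is reported to have produced poor
outcomes; intensity changes were treated with caution). Augmented copies
are streamed lazily during training and applied to training folds only —
the study could not confirm a benefit of augmenting validation data — with
a materialised `augment()` for reproducibility tests.

## Architectures

`spec_cnn2d()` is the six-layer 2D CNN: filters (8, 8, 16, 16, 32, 32),
kernel 3, same padding, ReLU, stride 1 in odd and 2 in even layers, then a
single dense softmax head and *no* pooling layers. This is the unique
natural reading under which the published total of 43,123 trainable
parameters is reproduced exactly (18,544 in convolutions plus
8192 × 3 + 3 in the head for a 128 × 128 × 8 input), so the schedule is
fixed rather than configurable. The convolution initialisation is not
stated in the source; He-uniform is used, the standard choice for ReLU
stacks.

`spec_vgg16_3d()` is the VGG-16 variant with thirteen 3D convolutions in
five blocks — (64, 64 | 128, 128 | 256, 256, 256 | 256, 256, 256 |
512, 512, 512); the fourth block keeps 256 filters rather than the
canonical 512 — each block followed by (2, 2, 2) max pooling with
ceil-mode so the 8-deep band axis survives five pools (8→4→2→1→1→1), then
flatten, two dense-ReLU layers with dropout 0.5, and a softmax head. The
hidden dense widths are not stated in the source; with the canonical
4096/4096 the closed-form total at a 128 × 128 × 8 × 1 input is
78,558,275, which does not reproduce the published 80,328,515. The widths
are therefore exposed as configuration and the discrepancy is documented
rather than resolved.

`count_parameters()` walks the layer list with the closed-form
conv/dense formulas; the test suite verifies it against the instantiated
weight-array totals for both study architectures and twenty random
architectures.

## Training engine and protocol

No R deep-learning framework with convolution support is available to this
package, so it ships a compact CPU engine: im2col gathers feeding BLAS
matrix products for 2D/3D convolution, disjoint-window 3D max pooling,
dense, dropout, and softmax cross-entropy with per-class weights, trained
with Adam. Reverse-mode gradients are hand-derived and verified against
central finite differences in the test suite (agreement to ~1e-9 on small
architectures). The loss uses log-sum-exp internally so loss and gradient
stay consistent for saturated logits; the probability-space loss
(`weighted_categorical_cross_entropy()`) floors the log at 1e-7.

`train_cross_validated()` implements both protocol variants: *continued*
training, where one model instance and its optimizer state persist across
folds and are trained further on each new fold (the study's
better-performing choice and the default), and *fresh-per-fold*
re-initialisation. Validation is monitored every epoch but never drives
selection (no early stopping). The optimizer is not named in the source
(and is reported not to matter); Adam is the default. Model selection in a
`random_grid_search()` — uniform over batch sizes 2–10 crossed with a
log-uniform learning rate in [1e-6, 1e-5] — uses final-fold validation
accuracy, a statistic the source leaves unstated. Determinism: a single
integer seed fixes initialisation, shuffling, dropout and streamed
augmentation, and two runs with the same seed produce identical traces.

The protocol ranges above are the grid-search domain; `train_config()`
itself accepts any learning rate up to 0.1, because desk-scale capacity
checks legitimately run faster than the study's schedule.

## Evaluation

`confusion_matrix()` (rows = truth, columns = prediction) feeds
`metrics_from_cm()`: per-class sensitivity, specificity, precision, F1 as
the harmonic mean of sensitivity and precision, and top-1 accuracy, with
zero-division conventions set to 0 and flagged — the published tables
contain near-degenerate rows but state no convention.
`collapse_malignant()` merges melanoma and BCC against benign nevi for the
screening-style binary view. `saliency_map()` is plain input-gradient
saliency (absolute gradient of the top-class logit, maximum over bands,
min-max normalised) — the minimal method consistent with inspecting
"attention"; on trained smoke models the mean saliency inside the
ground-truth lesion mask exceeds the outside mean.

## The experiment, and desk-scale sizes

`run_experiment()` chains the whole pipeline and trains one arm per band
mode on a *shared* fold plan and training seed, stricter than the source
protocol states, so the band subset is the only varying factor. The test
suite runs it at the smoke scale fixed in `smoke_experiment_config()`:
32 × 32 cubes, 70 captures per class, the 5-fold continued protocol with 3
epochs per fold (15 epochs in total), batch 16, Adam at 1e-3, no
augmentation. Under `nir_only` conditions the 8-band arm beats the RGB arm
by at least 0.15 test accuracy in at least 4 of 5 fixed seeds (observed
gaps 0.36–0.79), and under `none` both arms sit at chance. Capacity and
gradient checks use 16 × 16 cubes; the 3D VGG is exercised for
construction, forward pass and a 2-epoch smoke train at 16 × 16 with
narrowed dense heads, since its full-scale training run is a GPU-sized
computation by design.

## Known limitations

* The phantom's class structure is stipulated, not estimated from tissue;
  absolute accuracies on phantoms say nothing quantitative about clinical
  images.
* The engine is CPU-bound R; it is meant for desk-scale verification, not
  for reproducing 100-epoch runs on 10,500 augmented cubes.
* The published VGG parameter total is not reproduced by any stated
  configuration; see above.
* Saturation, dead pixels and illumination drift are modelled only to the
  extent needed to exercise the calibration contracts.
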