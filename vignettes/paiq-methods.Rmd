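---
title: "Quality assessment for photoacoustic images: models, choices, limits"
author: "paiq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quality assessment for photoacoustic images: models, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`paiq` assesses the quality of reconstructed 2-D photoacoustic (PA)
images along three complementary axes — full-reference similarity to a
trusted reconstruction, no-reference natural-scene statistics, and
region-based target detectability — and adds two layers on top: a
statistical framework that ranks metrics by how well they separate known
quality levels, and compact convolutional regressors that learn to
predict a full-reference score from a single image. This vignette
explains the models and their assumptions, the parameters that matter,
the numerical conventions, and what the bundled synthetic data can and
cannot show.

## Preprocessing model

Every metric operates on per-image min–max normalized intensities in
[0, 1] (data range R = 1). PA reconstructions come out of beamformers on
arbitrary linear scales, so an affine per-image normalization is the
weakest assumption that makes windowed statistics and stabilizing
constants commensurable across images; constants published for 8-bit
data (the GMSD c, FSIM T2, HaarPSI C, VIF noise variance) are rescaled
by (R/255)² so behavior on [0, 1 ] images reproduces the 0–255
conventions. A constant image normalizes to all zeros rather than
erroring, so fully degraded blank frames flow through batch runs.
Metrics are computed on the linear scale; log-compressed display
variants are out of scope.

## Full-reference metrics

The SSIM family shares one windowing convention: Gaussian-weighted local
moments in an 11×11 window with σ = 1.5, valid-region convolution (no
padding), stabilizers C1 = (0.01 R)², C2 = (0.03 R)². The multiscale
variant pools contrast–structure means over a dyadic 2×2 mean-pool
pyramid with the standard five exponents (0.0448, 0.2856, 0.3001,
0.2363, 0.1333) and evaluates the full SSIM (luminance included) at the
coarsest scale, so one scale reduces exactly to SSIM. Images too small
for the requested pyramid reduce the scale count with a warning rather
than failing — 128×128 inputs run four scales.

IW-SSIM weights the same per-scale contrast–structure maps by local
information content. Reference and distorted bands are modeled as a
Gaussian scale mixture viewed through a gain-plus-noise channel
(d = g·c + v) with sensory noise σn = 0.03 R; the weight is
log2[(1 + σc²/σn²)(1 + g²σc²/(σv² + σn²))] from 3×3 windowed moments of
the scale's Laplacian band (band minus the bilinearly upsampled next
level). Using the same mean-pool downsampler as MS-SSIM is a deliberate
choice: forcing uniform weights then reproduces MS-SSIM exactly, which
pins the weighting machinery in tests.

The sparse masked SSIM is designed for images where vessels occupy a
small fraction of the frame and background noise dominates plain SSIM.
Structure masks come from Gaussian local thresholding: a pixel is
structure iff it exceeds its Gaussian-weighted neighborhood mean by
offset × k × R (offset 0.5, k = 0.1), with neighborhood size
floor(H/16)·2+1 tied to resolution. The sign convention matters: the
threshold sits *above* the local mean, so a constant image yields an
empty mask — a threshold below the mean would mask everything, inverting
the metric's purpose. Masks of reference and test are OR-combined,
applied to both images, and the SSIM map is averaged over masked pixels
only. An empty combined mask (two structureless images) returns 1 with a
warning: blank-versus-blank is indistinguishable, and erroring would
abort ladder sweeps that legitimately contain blank frames. The
local-threshold scale k is config-exposed because the underlying method
specifies only the offset, not what it multiplies.

GMSD pools Prewitt gradient-magnitude similarity
(2·Gx·Gy + c)/(Gx² + Gy² + c), c = 170/255²·R², by the *population*
standard deviation after a 2×2 mean-pool prefilter (a variance-mode
option exists but is not the default); the multiscale variant is the
equal-weight root mean square of per-scale GMSD values on the mean-pool
pyramid. VIF is implemented exactly as the printed pixel-domain
information ratio — Σ g·log(1 + σ²/σn²) / Σ log(1 + σ²/σn²) with g the
windowed regression gain and σ² the reference's local variance over
uniform 9×9 windows, σn² = 2·(R/255)² — not the original wavelet-domain
estimator; the two agree in spirit but not numerically. UQI uses
uniform 8×8 sliding windows with ε = 1e-12 added to both denominator
factors, which keeps identical non-constant images at 1 to within ε
while leaving flat-window behavior defined. HaarPSI follows the
canonical construction (three Haar levels, two finest-level similarity
maps, coarsest-level magnitude weights, logistic squashing with
α = 4.2, squared inverse-logistic readout, 2×2 subsampling on).
FSIM combines log-Gabor phase congruency (4 scales × 4 orientations,
minimum wavelength 6, σ/f ratio 0.55, Rayleigh noise threshold with
k = 2) with Scharr gradient similarity (T1 = 0.85,
T2 = 160/255²·R²), pooled by the pointwise maximum phase congruency.

## No-reference features

The BRISQUE chain computes MSCN coefficients (I − μ)/(σ + C) with 7×7
Gaussian moments (σ = 7/6, symmetric boundary, C = R/255), four
directional pairwise products, and fits a generalized Gaussian to the
MSCN field plus an asymmetric GGD to each product field at two scales —
36 features. Fits use moment matching (the ratio-of-moments inversion,
shape clamped to [0.2, 10]) rather than maximum likelihood: it is
deterministic, fast, and accurate to well under 0.1 in shape at the
sample sizes a 128×128 image provides. The final 0–100 BRISQUE score is
deliberately not produced: it requires an SVM trained on human-labeled
natural photographs, weights we cannot reproduce or verify; users with
such a model can feed it the feature CSV.

## Detectability metrics

SNR, CNR and gCNR are computed per signal/background ROI pair and
averaged over pairs (three pairs in the standard protocol; any count ≥ 1
is accepted). Standard deviations are population rather than sample —
with the ≥ 100-pixel ROIs used in practice the difference is negligible,
and it keeps the gCNR identities exact. gCNR histograms use 100 shared
bins spanning the joint min–max of the paired ROIs (config-exposed), so
disjoint supports give exactly 1, identical pixel multisets exactly 0,
and any strictly monotone intensity remapping applied to both ROIs
leaves the score unchanged.

## Ranking framework

Within each ladder, every unordered pair of subsets is compared by a
two-sided Welch t-test at p < 0.05 — Welch rather than Student because
subset variances differ systematically across degradation levels. SC
counts significant pairs (summed across ladders); NMD averages
|Δmean|/range over significant pairs only; CS = SC × NMD. The value
range is 1 for the bounded metrics (SSIM family, UQI, VIF, HaarPSI,
FSIM — matching how the worked separability example normalizes SSIM
differences) and the pooled observed range otherwise (observed maximum
for the GMSD family, which starts at 0). No multiple-testing correction
is applied by default, matching the raw p < 0.05 protocol; a Bonferroni
switch exists. Non-finite values (PSNR on identity pairs) are excluded
with a logged count. Negating a metric changes nothing — differences are
absolute and the observed range is sign-symmetric — so lower-is-better
metrics rank on equal footing.

## Synthetic data: what it emulates

The generator produces the conditions the analysis stack assumes:
quality-ordered ladders of vessel-like and Derenzo phantoms.

- Vessel phantoms: 3–7 smooth random-walk branches of width 1–4 px with
  occasional side branching, per-branch intensity 0.6–1.0, mild
  anti-alias blur; foreground 2–25% of the frame. Derenzo phantoms: six
  angular sectors of disc triplets with per-sector decreasing radius,
  randomly rotated and jittered per seed so cohorts are distinct.
- Sparse view: Radon projection over n equispaced angles in [0, π),
  ramp-filtered backprojection, plus measurement noise of sd
  0.1/√n when seeded (averaging fewer noisy channels leaves more
  noise). The angle ladder 8–128 mirrors sparse-transducer protocols.
- Frame averaging: additive Gaussian noise of sd σ0/√n_frames (σ0 = 2,
  frames 128–2560), clipped to [0, 1] — the noise ladder of repeated
  acquisition averaging. An SNR ladder (10–50 dB) is also available.
- Domain shift: multiplicative speckle (sd 0.3) plus a 2-px Gaussian
  blur before degradation, held out as the out-of-distribution ladder.

The benchmark suite is three in-distribution ladders (vessel/sparse,
vessel/frames, Derenzo/sparse) plus the shifted ladder, ten phantoms
per level by default, every image written as 16-bit PNG with a CSV
manifest; one global seed fans out deterministically (seed + image
index), so the suite regenerates bit-identically.

What the generator does *not* emulate: wave-propagation physics
(transducer impulse response, acoustic heterogeneity, limited
bandwidth), reconstruction-algorithm differences, multi-wavelength
content, anatomical texture, or imperfect references. Passing tests on
this suite therefore demonstrate correct computation and the expected
*ordinal* response to these two degradation families — not performance
on experimental data. One consequence is worth stating plainly: with
pristine phantoms as references, PSNR is a nearly deterministic function
of the degradation level, every subset pair separates, and its mean
differences span most of its pooled observed range, so PSNR's composite
score on the synthetic suite is competitive with — and can exceed — the
structural metrics'. On experimental ladders the opposite holds, because
references are themselves reconstructions (near-duplicate pairs inflate
PSNR's observed range enormously) and datasets with very different PSNR
scales are pooled. The suite reproduces the monotone orderings, not that
cross-dataset heterogeneity; see Limitations.

## Quality regressors

PAQNet stacks four conv layers (filters 32/64/128/256, each ReLU +
2×2 max-pool) on a 1×128×128 input, then two 128-unit dense layers and a
linear head. The kernel assignment 5, 3, 3, 3 is the unique simple
reading of "5×5 or 3×3 kernels" whose parameter count lands on the
published ≈ 2.5 M (exactly 2,502,273 with one output); other
assignments are selectable. IQDCNN uses four 5×5/32-filter conv layers
with pooling after each (its source description leaves pooling
placement open; pooling after every conv is adopted — under this or any
simple variant the prose architecture's count lands near 4.28 M, not
the published 3.78 M, so the count is documented rather than asserted).
A third architecture in the source family, an EfficientNet-B0-based
regressor, is not implemented here: it is a pretrained large-scale
backbone whose value lies in transfer weights, and reproducing B0's
block zoo inside the package's compact engine is out of proportion to
what it would verify; the two fully specified custom CNNs cover the
module's testable claims.

Training follows the stated protocol: MAE loss, Adam at 1e-4, batches
of 16, early stopping on validation MAE with the best checkpoint
restored, K = 5 fold indices exposed for hyperparameter work. Labels
are internally shifted so an untrained (zero-output) network starts at
the training-label mean — with MAE + Adam the output otherwise spends
thousands of steps walking to the mean at ≈ lr per step. Multi-output
models min–max normalize each metric over the training split after
negating lower-is-better targets (GMSD family), train on the unweighted
mean of per-head MAEs, and de-normalize predictions before evaluation.
The engine itself is single-precision im2col + GEMM with deterministic
seeded shuffling and dropout, so fixed seeds reproduce runs on a fixed
BLAS. Grad-CAM weights the post-ReLU activations of the last conv layer
by the spatial mean of the selected output's gradient, ReLU-rectifies
the weighted sum, upsamples bilinearly, and min–max normalizes.

Problem sizes in the shipped tests were chosen to exercise the claims
at desk scale: the regression check trains PAQNet on 5,000 synthetic
images (500 phantoms × 5 sparse-view + 5 frame-averaging levels) for
three epochs and evaluates on held-out in-distribution and
domain-shifted ladders of 40 images each; the benchmark suite uses
eight phantoms per level. The paper-scale analogue (hundreds of
thousands of images, hours of GPU training) is out of scope.

## Numerical conventions and degenerate inputs

- ROI geometry is 0-based, row-major, half-open, origin top-left.
- Valid-region convolution for all windowed moments; symmetric
  reflection only where a same-size field is required (MSCN, local
  thresholds, Prewitt gradients).
- Variances from windowed moments are clamped at 0 before use.
- PSNR of identical images is +Inf by definition and excluded (with a
  logged count) from significance testing.
- An all-constant reference makes the VIF ratio undefined: error.
- Welch tests on two essentially constant samples: p = 1 when the means
  coincide, 0 otherwise.
- Constant metric vectors make Spearman-vs-rank undefined: 0 with a
  warning.
- gCNR of two constant equal ROIs is 0 (identical distributions).
- UQI windows that are constant in both images score 0 under the ε
  convention, so the identity score on images with large flat regions
  (vessel-on-black phantoms) sits below 1; the unit identity holds for
  images that are non-constant in every window.

## Known limitations

- The composite-score ordering of metrics on synthetic ladders does not
  transfer to experimental data where references are imperfect; in
  particular PSNR over-performs here (see above). Conclusions about
  *which* metric to use should come from running the framework on real
  ladders.
- The pixel-domain VIF is a simplified estimator; it preserves the
  information-ratio interpretation but not the wavelet-domain values.
- FSIM's phase congruency involves many filter-bank conventions; the
  implementation follows the canonical parameterization, but third-party
  FSIM scores can differ at the 1e-2 level.
- BRISQUE features without the trained scorer cannot produce the 0–100
  scale; they are features, not scores.
- The conv-net engine is CPU-only and single-threaded apart from BLAS;
  it is sized for 128×128 inputs and the two shipped architectures, not
  for general deep learning.
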