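---
title: "Eye-state classification with binarized shifted-orientation HOG features"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Eye-state classification with binarized shifted-orientation HOG features}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(drowsyhog)
```

## The problem

Instantaneous (per-frame) driver drowsiness detection labels each video
frame by the driver's eye state: closed eyes are treated as the drowsy
state, open eyes as alert. The pipeline in this package is

1. **Preprocessing** — Gaussian smoothing, contrast-limited adaptive
   histogram equalization (CLAHE) for light compensation, optional
   downscaling;
2. **Region of interest** — face detection (a pluggable backend),
   an anthropometric eye-band prior, and extraction of a canonical
   64×32 eye-pair patch;
3. **Features** — either a conventional block-normalized HOG vector, or
   the package's primary descriptor: *binarized shifted-orientation
   HOG* (BOSH, also called advHOG), binary comparisons between
   cyclically shifted cell histograms;
4. **Classification** — a from-scratch Naïve Bayes classifier:
   Bernoulli with m-estimate smoothing for the binary descriptor,
   Gaussian class-conditionals for the real-valued baseline;
5. **Evaluation** — per-scenario precision/recall/F1/accuracy reports
   over five illumination/occlusion scenarios.

## The descriptor

For a gray patch $I$, per-pixel derivatives $L_x, L_y$ come from the
centered mask $[-1, 0, 1]$ (default) or first-order Gaussian-derivative
kernels at scale $\sigma$. Gradient magnitude and unsigned orientation
are

$$\rho = \sqrt{L_x^2 + L_y^2}, \qquad
  \gamma = \arctan(L_y / L_x) \bmod \pi \in [0, \pi).$$

Each pixel votes its magnitude $\rho$ into an $m$-bin orientation
histogram over its 8×8-pixel cell. To avoid aliasing at bin boundaries
the vote is split between the two nearest bin centers (bin width
$\pi/m$, centers at $(k + 0.5)\,\pi/m$, circular wrap modulo $m$): an
orientation at a bin center gives that bin the whole vote, one at a
boundary splits it evenly. Writing $b$ for the bin containing $\gamma$
and $\alpha = b + 0.5 - \gamma m/\pi$ for the signed offset from its
center, the pixel contributes $(1-|\alpha|)\rho$ to bin $b$ and
$|\alpha|\rho$ to the neighbor on $\gamma$'s side. We deliberately split
the *magnitude*, not the orientation value itself: the vote quantity
accumulated in a histogram must be gradient mass for the histogram to
be magnitude-weighted, and the tests assert the equivalence of this
sign-safe form with the bin-offset weight formula.

Cells are grouped into 2×2-cell blocks with a one-cell stride, so each
interior cell is covered by four blocks. Within each block, for every
pair of cells $(c_1, c_2)$ and every cyclic shift
$\varepsilon \in \{0, \dots, m-1\}$,

$$b_{c_1 c_2}(k, \varepsilon) =
  \begin{cases} 1 & \text{if } v_{c_1}(k) \ge
     v_{c_2}((k + \varepsilon) \bmod m) \\ 0 & \text{otherwise.}
  \end{cases}$$

All six unordered cell pairs of a block are compared in a fixed raster
order (TL–TR, TL–BL, TL–BR, TR–BL, TR–BR, BL–BR; the comparison is
asymmetric, so the order is part of the format), each contributing
$m \times m$ bits, shift-major. A 64×32 patch with 8×8 cells and
$m = 8$ yields $21 \text{ blocks} \times 6 \text{ pairs} \times 64 =
8064$ bits.

Because every bit compares two vote masses, multiplying the image by
any $a > 0$ or adding any constant leaves every bit unchanged — the
descriptor is exactly invariant to affine illumination changes, which
is why no block normalization is applied before binarization (it would
be redundant; the baseline HOG path keeps the usual L2 block
normalization with a $10^{-6}$ guard).

**Design choices that were genuinely open.** Which cell pairs to
compare is not forced by the construction; we compare all six pairs
*within* each overlapping block, which keeps the descriptor local,
bounds its length, and parallels how HOG normalizes within blocks. An
alternative (comparing grid-adjacent cells across blocks) is noted in
the configuration surface (`bosh.pair_scope`) but not implemented.
Bit order (block-major, pair-major, shift-major; packed 8 bits per
byte, first bit most significant) is fixed and recorded in the
container header, because an 8064-bit layout silently misaligned
between training and prediction would be undebuggable — model files
therefore store the descriptor geometry and prediction refuses
mismatched layouts.

## The classifier

The Naïve Bayes classifier assumes conditional independence of
features given the class and picks
$\omega^* = \arg\max_j \hat P(\omega_j) \prod_i \hat P(x_i \mid \omega_j)$
(MAP; the ML rule replaces the priors with a uniform one). Priors are
class frequencies. For binary features the conditionals use the
m-estimate

$$\hat P(x_i = 1 \mid \omega_j) = \frac{n_c + m_w \alpha}{n + m_w},
  \qquad \alpha = 1/t,$$

with $t = 2$ values per feature and weight $m_w \ge 1$ (default
$m_w = 2$, which makes the estimate add-one smoothing). Smoothing keeps
every parameter strictly inside $(0, 1)$, so log-likelihoods are finite
for every input. For continuous features the class-conditionals are
Gaussian with per-class, per-feature sample mean and *population*
variance (denominator $n$), floored at $10^{-9}$ to keep constant
features well-defined.

Numerical choices: all probability computation is in log space (the
product form underflows at thousands of features); posteriors are
normalized with log-sum-exp; argmax ties break to the lowest class
index (classes are kept sorted, so predictions are deterministic).

## The synthetic generator

The generator renders what the descriptor measures rather than
photorealistic faces: open eyes contribute strong sclera/iris gradient
texture (bright ellipse, dark disc), closed eyes a smooth shaded lid
over a skin gradient. An eyelid chord at *aperture* $\in [0,1]$
controls how much eye is visible (closed samples use apertures in
$[0, 0.15]$, open in $[0.15 + 0.35 s,\, 1]$ for separability $s$; at
the default $s = 1$ open apertures are at least 0.5 and the classes do
not overlap in aperture). Five scenario presets emulate the standard
recording conditions of driver-monitoring benchmarks: bare face,
glasses (a semi-transparent dark band over the upper eye margin,
opacity 0.45), sunglasses (opacity 0.65 over the whole eye band),
and night variants (global illumination gain 0.35, emulating low-gain
IR capture). Additive Gaussian pixel noise (default sd 0.02 on a
[0, 1] scale) is applied last. Per-sample seeds derive from the master
seed by `bitwXor(seed, sample_index)`, so datasets are reproducible
sample-by-sample and the generator is a pure function of its
parameters.

What passing tests on this generator do and do not show: they show the
descriptor separates gradient-texture classes under occlusion and
illumination change and that the full train/predict/evaluate loop is
correct and deterministic; they do not show performance on real faces,
where head pose, blur, blinks in transition, and detector error
dominate. The generator also makes no attempt at temporal blink
dynamics — the method is per-frame by design.

## Study conditions used by the tests and the acceptance script

The end-to-end study trains on 250 patches per class and evaluates on
100 per class (uniform scenario mix, separability 1, noise sd 0.02),
a size at which descriptor extraction and both classifier fits complete
in seconds while per-scenario cells still hold 40 test samples each.
Robustness is probed by repeating the study at noise sd 0.08 and 0.15
and checking that accuracy does not increase with noise. The
`scripts/acceptance.R` script reruns exactly this study from a
command-line seed and writes every computed quantity (per-scenario and
average accuracies and F1 scores for both feature paths) as JSON.

```{r study, eval = FALSE}
train <- generate_dataset(250, seed = 42)
test  <- generate_dataset(100, seed = 42 + 4200)
ytr <- vapply(train, `[[`, "", "label")
model <- fit_bernoulli_nb(
  drowsyhog:::samples_descriptors(train, "bosh"), ytr)
pred <- predict_map(model, drowsyhog:::samples_descriptors(test, "bosh"))
mean(pred$label == vapply(test, `[[`, "", "label"))
```

## Preprocessing parameters

* Gaussian blur: 3×3 kernel, $\sigma = 0.5$ — light noise suppression
  that retains edge structure; reflect borders everywhere, so constant
  images are exact fixed points and total intensity is conserved.
* CLAHE: clip limit 2.0 (multiples of the mean bin count), 8×8 tiles,
  256 bins. The implementation is the textbook tile-mapping scheme:
  per-tile histograms are clipped and the excess redistributed
  iteratively, tile CDFs become mappings, and each pixel bilinearly
  interpolates the four neighboring tile mappings. With 256 bins a
  constant image moves by at most about one gray level. Each color
  channel is equalized independently; single-channel (night/IR) input
  is equalized as-is.
* Grayscale: BT.601 luma weights (0.299, 0.587, 0.114). Night footage
  is effectively single-channel, so the choice matters only for
  daytime frames.
* Downscaling: exact area averaging; default off (factor 1).

## ROI conventions and limitations

Boxes are 0-based and half-open. Face detection is a contract, not a
trained model: the annotation backend replays stored boxes and a
brightness-blob backend handles the synthetic frames; a trained
cascade would plug in through the same `detect(image)` interface.
The eye band is a fixed anthropometric prior (15–85% of face width,
25–55% of face height), which is affine in the face box and therefore
translation- and scale-equivariant; it replaces statistical shape
models that would require landmark-annotated training data. Patch
resampling uses area averaging when shrinking and bilinear
interpolation when growing; the canonical 64×32 size makes the 8-pixel
cell grid tile exactly.

Known limitations: no multi-face tracking (largest box wins), no
temporal smoothing by default (an option exists in the CLI design but
per-frame decisions are the default), PNG is the supported image
format, and the brightness-blob detector is only meant for the
generator's frames.
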