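---
title: "Multifractal descriptors of retinal OCT texture: models, estimators, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multifractal descriptors of retinal OCT texture}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(octmf)
```

## The problem and the model

Early diabetic retinopathy (DR) disturbs the fine texture of retinal
tissue before clinically obvious lesions appear. On cross-sectional OCT
scans these disturbances show up as spatial heterogeneity: intensity
structure that is not uniformly complex but varies in "roughness" from
place to place. A single fractal dimension summarizes global complexity
only; multifractal analysis characterizes the whole distribution of local
scaling behaviors and is therefore the natural tool for this kind of
diffuse, scale-spanning alteration.

The analysis treats the binarized image as a measure: each foreground
("white") pixel carries equal mass. Covering the image with boxes of side
$\varepsilon$ and writing $p_i(\varepsilon)$ for the mass fraction in box
$i$, the generalized (Rényi) dimensions are

$$D_q = \frac{1}{q-1}\,\lim_{\varepsilon\to 0}
  \frac{\log \sum_i p_i^q(\varepsilon)}{\log \varepsilon},
  \qquad
  D_1 = \lim_{\varepsilon\to 0}
  \frac{\sum_i p_i \log p_i}{\log \varepsilon},$$

with the box-counting, information and correlation dimensions $D_0, D_1,
D_2$ as the familiar special cases. The mass exponents
$\tau(q) = (q-1)D_q$ yield the singularity spectrum by Legendre
transform:

$$\alpha(q) = \frac{d\tau}{dq}, \qquad
  f(\alpha) = q\,\alpha(q) - \tau(q).$$

Nine descriptors are extracted per image: $D_0$ (`Db`), $D_1$ (`Di`),
$D_2$ (`Dc`), the spectrum landmarks $\alpha_{\min}$, $\alpha_{\max}$,
$\alpha_{center}$, $f(\alpha)_{\max}$, the spectrum width
$\Delta\alpha = \alpha_{\max} - \alpha_{\min}$, and the symmetric shift
$\alpha_{center} - (\alpha_{\min}+\alpha_{\max})/2$. Width is the key
heterogeneity index: wider spectra mean a richer mix of local scaling
behaviors, the signature of degraded tissue.

## Preprocessing

Images are conditioned before analysis, in this order:

1. **Gaussian blur**, $\sigma = 2$ px. The discrete kernel is the 2D
   Gaussian evaluated on the integer grid, truncated at radius
   $\lceil 4\sigma \rceil$ and renormalized to unit sum (truncated mass
   below $10^{-4}$). Borders use symmetric reflection: zero padding would
   darken the frame and leak spurious structure into the box counts.
2. **CLAHE** with block size 127 px, 256 histogram bins, and clip limit 3
   in the max-slope convention of the standard tile-interpolated
   algorithm (the `EBImage` implementation of Zuiderveld's method). The
   block size is converted to a tile grid of roughly block-sized tiles,
   at least two per axis; the image is reflected out to a tile-divisible
   size and cropped back, so arbitrary image sizes are accepted.
3. **Thresholding**. The flowchart convention is blur, then CLAHE, then
   threshold, then binarize. The threshold method defaults to Otsu
   (maximum between-class variance over the 8-bit histogram): it is
   parameter-free and reproducible. A `fixed` override exists. A constant
   image, for which Otsu is undefined, yields an all-background mask and
   a warning rather than an error. Foreground is *strictly above* the
   threshold.

Images are not resized. Batch processing walks a directory in sorted
filename order and writes `<stem>_processed.png` files, skipping and
counting non-image or unreadable files.

## Estimation choices

**Scale schedule.** Box sizes are powers of two from 4 px up to half the
shorter image side. Both cut-offs matter: boxes coarser than side/2 are
almost all occupied, which saturates $N(\varepsilon)$ and biases slopes
toward the embedding dimension (on the level-5 Sierpiński carpet a
schedule of literal halvings of the odd side, 121/60/30/15/7, returns
$D_0 = 1.67$ against the closed form 1.8928, while the dyadic schedule
returns 1.883); single-pixel boxes saturate the opposite way. At least
four scales are required for the log–log fits.

**Moment grid.** $q$ runs over $[-5, 5]$ in steps of 0.25, symmetric so
that both tails of the spectrum are probed, and always containing
$q = 0, 1, 2$. Negative-order moments are computed over non-empty boxes
only.

**Fitting and regularization.** Raw exponents $\hat\tau(q)$ come from
ordinary least squares of $\log Z(q,\varepsilon)$ on
$\log \varepsilon$ (the entropy sum replaces $\log Z$ at $q = 1$), with
per-$q$ coefficients of determination kept as scaling diagnostics. On
perfectly scaling measures this is the whole story. Real binarized
images, however, scale imperfectly, and the raw per-$q$ slopes need not
be monotone in $q$ even though true generalized dimensions always are;
the Legendre transform of a non-concave $\hat\tau$ then produces
spectra whose maximum drifts away from $D_0$. Two exact constraints
rescue the estimate: $\tau(1) = 0$ holds identically (probabilities sum
to one at every scale), and the true $\tau$ is concave. The estimator
therefore projects the finite-difference Hölder curve
$\hat\alpha(q) = d\hat\tau/dq$ onto non-increasing curves
(pool-adjacent-violators) and rebuilds $\tau$ by trapezoidal
integration anchored at $\tau(1) = 0$. The rebuilt $\tau$ is concave by
construction, so three identities hold *exactly*: $D_q$ (a chord slope
of $\tau$ from the anchor) is non-increasing in $q$; the spectrum peak
sits at $q = 0$; and $f(\alpha(0)) = D_0$. On well-scaling measures the
projection is the identity and only an $O(\Delta q^2)$ discretization
remains — the level-8 cascade below moves from its exact closed form by
about $10^{-3}$. Raw values stay available as `D_raw`.

**Landmark conventions.** The peak descriptors are evaluated at
$q = 0$: $f(\alpha)_{\max} = D_0$, and (in the default `argmax_f` mode)
$\alpha_{center} = \alpha(0)$. This matches the convention of the
established plugin-style tools, whose output tables list identical
`Db` and `f(alpha)max` columns. A `midpoint` mode defining
$\alpha_{center} = (\alpha_{\min}+\alpha_{\max})/2$ is provided because
some published feature tables evidently use it (their printed centers
equal the midpoint exactly); under that mode the symmetric shift is zero
by definition, so the default remains `argmax_f`.

Note one mathematical caveat: the bound $D_q \le 2$ for 2D images holds
for $q \ge 0$. For $q < 0$ the generalized dimensions of a non-uniform
measure legitimately exceed the embedding dimension (the level-8
cascade with $p = 0.9$ has $D_{-5} = 5.5$ exactly), so no such bound is
enforced there.

## The synthetic module: what it emulates, and what it does not

Every stage is validated against constructions with known answers:

* **Filled square** — $D_q = 2$ for all $q$, spectrum width 0.
* **Sierpiński carpet** — $D_0 = \log 8/\log 3$; foreground count
  exactly $8^{\text{level}}$.
* **2D binomial cascade** — each refinement splits a cell 2×2 with
  weights $(p, 1-p)$ applied independently along rows and columns, so
  each axis contributes a 1D binomial cascade and
  $D_q = 2\log_2(p^q + (1-p)^q)/(1-q)$, twice the 1D closed form, with
  $\alpha(q)$ available in closed form as well. Randomizing the split
  orientation changes the geometry, not the spectrum.

**Retinal phantoms.** A phantom is a layered band structure (alternating
bright and dark strata with mild sinusoidal warp over a dark
vitreous/choroid background), a multiplicative-cascade texture, dark
elliptical lesion blobs for the DR class, and multiplicative speckle.
Three choices were made deliberately, after measuring what survives the
conditioning pipeline:

* *The texture enters through its rank transform*, and layer contrast is
  kept mild, so the binarization threshold cuts through the texture's
  level sets instead of between layers. A monotone intensity transform
  leaves level sets — and hence the post-threshold geometry — unchanged,
  while keeping intensities well conditioned for CLAHE.
* *Class heterogeneity controls the cascade's depth, not its weight.*
  For any two-valued weight cascade the log-mass is a monotone function
  of the number of heavy-weight draws along a pixel's dyadic path, so a
  histogram-based threshold produces nearly the same mask whatever the
  weight $p$ is (empirically, 89% pixel agreement between $p = 0.57$
  and $p = 0.80$ masks built on the same random pattern): amplitude
  heterogeneity is invisible to a thresholded analysis. What a mask
  does see is the *finest scale at which cascade structure lives*. The
  heterogeneity parameter $h \in [0,1]$ therefore sets the cascade
  depth (about $2 + 6h$ dyadic levels, weight fixed at 0.75): shallow
  cascades (Normal default, $h = 0.2$) give smooth blob-like masks with
  narrow spectra; deep cascades (DR default, $h = 0.65$) give rough,
  scale-spanning masks with wide spectra. With 30 phantoms per class the
  DR mean width exceeds the Normal mean width by roughly 0.2 with
  within-class SDs near 0.05–0.1.
* *Speckle is multiplicative* (coefficient of variation `noise_sd`/128,
  default 10/128), as in OCT physics. Additive noise on the dark
  background creates isolated supra-threshold pixels after CLAHE —
  random dust whose anomalous negative-$q$ scaling drowns every other
  signal in the spectrum tails.

Phantoms are *not* photorealistic OCT: no point-spread physics, no
depth-dependent attenuation, no anatomy. Passing tests on phantoms show
that the pipeline measures what it claims to measure and separates
classes whose textural heterogeneity genuinely differs; they do not show
clinical performance on real scans.

**Feature-table sampler.** For tests that need labeled descriptor tables
without images, `sample_feature_table()` draws per-class Gaussians whose
merged moments reproduce the package's reference population (global
means and SDs representative of a large two-class OCT screening cohort,
e.g. mean width 1.0941, SD 0.2150). Class means sit symmetrically about
the global mean with separations between 0.6 and 1.4 global SDs on the
descriptors that discriminate (width, $\alpha_{\max}$,
$\alpha_{center}$, shift, $D_1$, $D_2$), zero on the class-stable ones
($D_0$, $f(\alpha)_{\max}$), and class SDs shrunk so the merge is
moment-exact. Row-level consistency is kept exactly where the field's
tools keep it — `f_alpha_max` equals `Db`, and `alpha_max` is derived as
`alpha_min + spectrum_width` — but `alpha_center` and `symmetric_shift`
are drawn from their own moments rather than derived: the reference
population's mean center coincides with the support midpoint while its
mean shift is distinctly negative, which no row-wise consistent
definition can reproduce simultaneously, so the sampler follows the
population tables as printed.

## Evaluation design

Classification uses stratified $k$-fold cross-validation ($k = 5$, i.e.
80/20 train/test in every fold), with fold assignment by seeded
round-robin within class, so per-fold class counts deviate from perfect
proportion by at most one. Z-score normalization is fitted on each
fold's training split only and applied unchanged to its test split; a
zero-variance feature passes through with a warning. The positive class
is DR throughout.

Eight classifiers run with fixed hyperparameters: L2 logistic regression
(C = 1), random forest (100 trees, depth 10), decision tree (depth 5,
entropy), polynomial-kernel SVM (degree 3, C = 1), and three
gradient-boosted tree presets (100 rounds, learning rate 0.1, depths 3,
4, 5) backed by one boosted-tree implementation, plus a multilayer
perceptron with hidden layers (128, 64), ReLU activations, a sigmoid
output, and full-batch Adam (learning rate $10^{-3}$, at most 1000
iterations, random state 42); training stops early only when the loss
has stabilized to within $10^{-6}$ for ten consecutive iterations, and
hitting the cap raises a warning, not an error. The perceptron is
implemented in the package because no two-hidden-layer Adam-trained MLP
exists in the supporting R stack; its forward pass is the standard
$a^{(h)} = \mathrm{ReLU}(W^{(h)} a^{(h-1)} + b^{(h)})$ with
$y = \sigma(W^{(out)} a^{(L)} + b^{(out)})$ and threshold 0.5.

Per fold, the confusion counts give accuracy, precision, recall
(sensitivity), specificity and F1; a zero-denominator metric is reported
as `NA` with a warning, never silently as 0. Across folds the package
reports per-metric means, a 95% Student-$t$ confidence interval for
accuracy ($k-1$ degrees of freedom — the standard choice for CV folds),
and a one-sided one-sample $t$-test of fold accuracies against the 0.5
chance level; with zero variance across folds the CI collapses to the
mean and the p-value degenerates to 0 or 1.

## Problem sizes and limitations

The shipped tests and the acceptance script run at desk scale, chosen so
the whole suite completes in minutes on one CPU: 256-px phantoms, 200
images in the end-to-end study, level-8 cascades, level-5 carpet. The
estimators are size-stable well beyond that (the cascade closed forms
are recovered essentially exactly because dyadic boxes align with
cascade cells; the carpet, whose side is a power of three, is the honest
misalignment test).

Known limitations: negative-$q$ estimates on thin or noisy masks are
intrinsically fragile (poor $R^2$ flags them); the Legendre route
recovers only the concave hull of the spectrum; the phantom generator
models texture heterogeneity, not disease; and nothing here validates
clinical performance on real OCT data — the package's claim is
methodological correctness, demonstrated against closed forms.
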