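# octmf — multifractal box-counting analysis of retinal OCT images

`octmf` is an R package for texture-based screening of retinal optical
coherence tomography (OCT) scans. Early diabetic retinopathy (DR)
changes the fine structure of retinal tissue in ways that a single
summary statistic misses; this package quantifies those changes with a
nine-descriptor multifractal signature and classifies images from it
under stratified cross-validation. It is aimed at researchers in
quantitative ophthalmic imaging and at anyone who needs a validated,
self-contained 2D box-counting multifractal estimator.

## The method

A binarized image is treated as a measure: each foreground pixel carries
equal mass. For boxes of side ε with per-box mass fractions pᵢ(ε), the
generalized dimensions are

    D_q = 1/(q−1) · lim log Σᵢ pᵢ^q(ε) / log ε        (q ≠ 1)
    D_1 =           lim Σᵢ pᵢ log pᵢ / log ε

estimated by least squares over a dyadic scale schedule. The mass
exponents τ(q) = (q−1) D_q give the singularity spectrum by Legendre
transform, α(q) = dτ/dq and f(α) = qα − τ(q). Nine descriptors are
extracted per image: D₀ (`Db`), D₁ (`Di`), D₂ (`Dc`), `alpha_min`,
`alpha_max`, `alpha_center`, `f_alpha_max`, `spectrum_width`
(Δα = α_max − α_min) and `symmetric_shift`. Wider, more asymmetric
spectra indicate more heterogeneous — degraded — tissue.

Around the estimator the package provides the full workflow: image
conditioning (Gaussian blur σ = 2, CLAHE with block 127 / 256 bins /
clip 3, Otsu binarization), batch processing with `_processed.png`
naming, feature-table I/O with a canonical CSV header, and stratified
5-fold evaluation of eight classifiers (logistic regression, random
forest, decision tree, polynomial SVM, three gradient-boosted-tree
presets, and a (128, 64) ReLU multilayer perceptron trained with Adam)
with accuracy, precision, recall, specificity, F1, a 95% CI and a
p-value against chance. A synthetic module supplies ground truth:
canonical fractals with closed-form spectra and two-class OCT-like
retinal phantoms. See the methods vignette
(`vignettes/methods.Rmd`) for the estimator's design decisions.

## Worked example

Analyze a measure whose spectrum is known in closed form — a level-8 2D
binomial cascade with weight p = 0.7, for which
D_q = 2·log₂(p^q + (1−p)^q)/(1−q):

```r
library(octmf)
cas <- make_binomial_cascade(8, 0.7, seed = 1)
ft  <- extract_features(cas, use_mass = TRUE, id = "cascade_p0.7")
print(ft)
#> Multifractal descriptors (cascade_p0.7)
#>              Db              Di              Dc       alpha_min       alpha_max
#>          2.0013          1.7641          1.5743          1.0679          3.4352
#>    alpha_center     f_alpha_max  spectrum_width symmetric_shift
#>          2.2515          2.0013          2.3673          0.0000
cascade_dq(0.7, 0:2)              # exact: 2.0000 1.7626 1.5718
cascade_spectrum_width(0.7)       # exact width on q in [-5, 5]: 2.3751
```

The estimates sit within about 10⁻³–10⁻² of the closed forms. `Db`
equals `f_alpha_max` and `spectrum_width` equals
`alpha_max − alpha_min` exactly, by construction.

A miniature end-to-end study — phantoms, preprocessing, descriptor
extraction, cross-validated MLP classification:

```r
res <- run_demo(n_per_class = 15, seed = 42, models = "mlp")
print(res$report)
#> Evaluation report: 30 rows, 5-fold stratified CV (seed 42)
#>   mlp    acc 1.0000  prec 1.0000  rec 1.0000  spec 1.0000  F1 1.0000  CI [1.0000, 1.0000]
```

DR phantoms carry deeper cascade texture than Normal phantoms, so their
binarized masks have wider singularity spectra (means ≈ 0.94 vs 0.75 at
the defaults), which the classifier separates cleanly. A thin CLI over
the same functions is included at `inst/scripts/octmf-cli.R`
(`generate`, `preprocess`, `analyze`, `evaluate`, `run` subcommands).

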