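# Synthetic inputs with analytically known multifractal structure: canonical
# fractal sets, 2D multiplicative cascades, layered OCT-like retinal phantoms,
# and class-conditional Gaussian feature tables. These are the ground-truth
# oracles against which the estimation pipeline is validated.

#' Filled rectangle (plane-filling monofractal)
#'
#' Every pixel is foreground, so the exact generalized dimension is
#' \eqn{D_q = 2} for all \eqn{q}.
#'
#' @param side image side in pixels (>= 8).
#' @return 0/1 integer matrix of dimension `side x side`, all ones.
#' @export
make_filled_rect <- function(side) {
  if (!is.numeric(side) || length(side) != 1 || side < 8 || side != round(side))
    stop("`side` must be an integer >= 8", call. = FALSE)
  matrix(1L, side, side)
}

#' Sierpinski carpet
#'
#' Deterministic self-similar set with similarity dimension
#' \eqn{\log 8 / \log 3 \approx 1.8928}. The image side is `3^level` and the
#' foreground count is exactly `8^level`.
#'
#' @param level recursion depth, 1..7.
#' @return 0/1 integer matrix of side `3^level`.
#' @export
make_sierpinski_carpet <- function(level) {
  if (!is.numeric(level) || length(level) != 1 || level < 1 || level > 7 ||
      level != round(level))
    stop("`level` must be an integer in 1..7", call. = FALSE)
  m <- matrix(1L, 1, 1)
  for (i in seq_len(level)) {
    s <- nrow(m)
    M <- matrix(0L, 3 * s, 3 * s)
    for (a in 0:2) for (b in 0:2) {
      if (a == 1 && b == 1) next
      M[a * s + seq_len(s), b * s + seq_len(s)] <- m
    }
    m <- M
  }
  m
}

#' Two-dimensional binomial multiplicative cascade
#'
#' Starting from unit mass on a single cell, each refinement step splits every
#' cell into a 2 x 2 block, distributing mass with weights `(p, 1-p)` along
#' rows and, independently, `(p, 1-p)` along columns (a product of two 1D
#' binomial cascades). The resulting measure has the closed-form spectrum of
#' [cascade_dq()] / [cascade_alpha()]: each axis contributes
#' \eqn{\log_2(p^q + (1-p)^q)/(1-q)} so the 2D dimensions are twice the 1D
#' values. With `seed = NULL` the heavier weight always goes to the first
#' half (fully deterministic); with a seed the orientation of each split is
#' randomized, which changes the geometry but not the spectrum.
#'
#' @param level dyadic depth, 1..11; image side is `2^level`.
#' @param p heavy weight, strictly in (0.5, 1); `p -> 0.5` degenerates to the
#'   uniform (monofractal) measure.
#' @param seed integer to randomize split orientations, or `NULL` for the
#'   deterministic construction.
#' @return non-negative numeric matrix of side `2^level` with total mass 1.
#' @export
make_binomial_cascade <- function(level, p, seed = NULL) {
  if (!is.numeric(level) || length(level) != 1 || level < 1 || level > 11 ||
      level != round(level))
    stop("`level` must be an integer in 1..11", call. = FALSE)
  if (!is.numeric(p) || length(p) != 1 || p <= 0.5 || p >= 1)
    stop("`p` must lie strictly in (0.5, 1)", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  m <- matrix(1, 1, 1)
  for (l in seq_len(level)) {
    s <- nrow(m)
    if (is.null(seed)) {
      A <- matrix(p, s, s)
      B <- matrix(p, s, s)
    } else {
      A <- matrix(sample(c(p, 1 - p), s * s, replace = TRUE), s, s)
      B <- matrix(sample(c(p, 1 - p), s * s, replace = TRUE), s, s)
    }
    od <- seq(1, 2 * s, by = 2)
    ev <- od + 1
    M <- matrix(0, 2 * s, 2 * s)
    M[od, od] <- m * A * B
    M[ev, od] <- m * (1 - A) * B
    M[od, ev] <- m * A * (1 - B)
    M[ev, ev] <- m * (1 - A) * (1 - B)
    m <- M
  }
  m
}

#' Closed-form generalized dimensions of the 2D binomial cascade
#'
#' For the product construction of [make_binomial_cascade()], each axis is a
#' 1D binomial cascade with \eqn{\tau_1(q) = -\log_2(p^q + (1-p)^q)}, so
#' \eqn{D_q = 2 \log_2(p^q + (1-p)^q)/(1-q)}; at \eqn{q = 1} this is twice
#' the binary entropy of `p`.
#'
#' @param p heavy weight in (0.5, 1).
#' @param q vector of moment orders.
#' @return numeric vector of exact dimensions `D_q`.
#' @export
cascade_dq <- function(p, q) {
  vapply(q, function(qi) {
    if (abs(qi - 1) < 1e-12) {
      2 * (-(p * log2(p) + (1 - p) * log2(1 - p)))
    } else {
      2 * log2(p^qi + (1 - p)^qi) / (1 - qi)
    }
  }, numeric(1))
}

#' Closed-form Holder exponent curve of the 2D binomial cascade
#'
#' \eqn{\alpha(q) = d\tau/dq} with \eqn{\tau(q) = (q-1) D_q}; for the product
#' cascade this is twice the 1D value
#' \eqn{-(p^q \ln p + (1-p)^q \ln(1-p)) / ((p^q + (1-p)^q)\ln 2)}.
#'
#' @inheritParams cascade_dq
#' @return numeric vector of exact `alpha(q)` values.
#' @export
cascade_alpha <- function(p, q) {
  vapply(q, function(qi) {
    w <- p^qi + (1 - p)^qi
    2 * (-(p^qi * log(p) + (1 - p)^qi * log(1 - p)) / (w * log(2)))
  }, numeric(1))
}

#' Closed-form spectrum width of the 2D binomial cascade over a q-range
#'
#' @inheritParams cascade_dq
#' @param q_min,q_max extremes of the moment-order grid.
#' @return `alpha(q_min) - alpha(q_max)`, the exact width reachable on that
#'   grid (the full support width is the limit `q -> +/- Inf`).
#' @export
cascade_spectrum_width <- function(p, q_min = -5, q_max = 5) {
  cascade_alpha(p, q_min) - cascade_alpha(p, q_max)
}

#' Specification of a synthetic retinal phantom
#'
#' Class defaults encode the qualitative contrast seen in early diabetic
#' retinopathy: DR tissue carries a more heterogeneous texture (wider
#' singularity spectrum, higher `alpha_max`) and focal lesions, while normal
#' tissue is closer to a homogeneous layered structure.
#'
#' @param class_label `"DR"` or `"Normal"`.
#' @param image_side phantom side in pixels (>= 128).
#' @param n_layers number of horizontal retinal bands.
#' @param cascade_heterogeneity in [0, 1]; controls how deep (toward fine
#'   scales) the multiplicative-cascade texture is iterated, and thereby the
#'   singularity-spectrum width of the binarized image: 0 leaves only
#'   coarse-scale structure, 1 iterates the cascade to pixel scale.
#'   Defaults: DR 0.65, Normal 0.20.
#' @param lesion_count number of focal lesion blobs (default: DR 8, Normal 0).
#' @param noise_sd speckle strength in gray levels at mid intensity
#'   (multiplicative, coefficient of variation `noise_sd / 128`).
#' @param seed integer RNG seed.
#' @return a `phantom_spec` list.
#' @export
phantom_spec <- function(class_label = c("DR", "Normal"), image_side = 256,
                         n_layers = 7, cascade_heterogeneity = NULL,
                         lesion_count = NULL, noise_sd = 10, seed = 42) {
  class_label <- match.arg(class_label)
  if (image_side < 128) stop("`image_side` must be >= 128", call. = FALSE)
  if (is.null(cascade_heterogeneity))
    cascade_heterogeneity <- if (class_label == "DR") 0.65 else 0.20
  if (is.null(lesion_count))
    lesion_count <- if (class_label == "DR") 8L else 0L
  if (cascade_heterogeneity < 0 || cascade_heterogeneity > 1)
    stop("`cascade_heterogeneity` must lie in [0, 1]", call. = FALSE)
  if (lesion_count < 0) stop("`lesion_count` must be >= 0", call. = FALSE)
  structure(list(class_label = class_label, image_side = image_side,
                 n_layers = n_layers,
                 cascade_heterogeneity = cascade_heterogeneity,
                 lesion_count = lesion_count, noise_sd = noise_sd,
                 seed = seed),
            class = "phantom_spec")
}

#' Generate a layered OCT-like retinal phantom
#'
#' Builds a horizontal layered band structure (bright and dark retinal
#' strata with mild curvature over a dark vitreous/choroid background),
#' modulates it with a multiplicative-cascade texture, adds focal lesion
#' blobs for the DR class, and overlays multiplicative speckle. Two design
#' choices matter for what survives the conditioning pipeline (blur, CLAHE,
#' Otsu): the cascade enters through its rank transform, so the binarization
#' threshold cuts through the texture's level sets rather than between
#' layers; and `cascade_heterogeneity` sets the depth of the cascade — the
#' finest scale at which its structure lives — because a threshold mask is
#' insensitive to pure amplitude rescaling of the texture but very sensitive
#' to how far down in scale its clustering extends. Deep cascades (DR) give
#' rough, scale-spanning masks with wide singularity spectra; shallow
#' cascades (Normal) give smooth blob-like masks with narrow spectra.
#'
#' @param spec a [phantom_spec()].
#' @return grayscale matrix in [0, 255] of side `spec$image_side`.
#' @export
make_retina_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  set.seed(spec$seed)
  n <- spec$image_side
  x <- seq_len(n)

  # layered background: alternating bright/dark bands with sinusoidal warp;
  # band contrast is mild so the texture spans the binarization threshold
  band <- matrix(0, n, n)
  bounds <- round(seq(0.12, 0.88, length.out = spec$n_layers + 1) * n)
  warp <- 0.02 * n * sin(2 * pi * x / n + runif(1, 0, 2 * pi))
  bright <- rep(c(TRUE, FALSE), length.out = spec$n_layers)
  levels <- ifelse(bright, runif(spec$n_layers, 150, 170),
                   runif(spec$n_layers, 105, 125))
  for (j in x) {
    for (l in seq_len(spec$n_layers)) {
      y0 <- max(1, bounds[l] + round(warp[j]))
      y1 <- min(n, bounds[l + 1] + round(warp[j]))
      if (y0 <= y1) band[y0:y1, j] <- levels[l]
    }
  }
  band[band == 0] <- 25  # vitreous / choroid background

  # depth-limited cascade texture, rank-transformed
  lev <- ceiling(log2(n))
  depth <- max(1L, min(lev, round(2 + 6 * spec$cascade_heterogeneity)))
  cas <- make_binomial_cascade(depth, p = 0.75, seed = spec$seed + 1L)
  if (depth < lev) {
    blow <- 2^(lev - depth)
    cas <- cas %x% matrix(1 / blow^2, blow, blow)
  }
  cas <- cas[1:n, 1:n]
  u <- matrix(rank(cas, ties.method = "average") / (n * n), n, n)
  img <- band * (0.55 + 0.9 * u)

  # focal lesions: dark elliptical blobs inside the retinal band
  if (spec$lesion_count > 0) {
    for (k in seq_len(spec$lesion_count)) {
      cy <- runif(1, 0.2 * n, 0.8 * n)
      cx <- runif(1, 0.1 * n, 0.9 * n)
      ry <- runif(1, 0.015 * n, 0.04 * n)
      rx <- runif(1, 0.02 * n, 0.06 * n)
      dy <- outer((x - cy) / ry, rep(1, n))
      dx <- outer(rep(1, n), (x - cx) / rx)
      img[dy^2 + dx^2 <= 1] <- img[dy^2 + dx^2 <= 1] * 0.25
    }
  }

  # multiplicative speckle (dark regions stay dark)
  img <- img * (1 + rnorm(n * n, 0, spec$noise_sd / 128))
  img[img < 0] <- 0
  img[img > 255] <- 255
  img
}

# Reference population moments of the nine descriptors (global mean and SD
# over a large two-class OCT screening cohort); order matches the canonical
# feature-table header.
.octmf_global_mean <- c(Db = 1.9990, Di = 1.9419, Dc = 1.8925,
                        alpha_min = 1.7404, alpha_max = 2.8345,
                        alpha_center = 2.2874, f_alpha_max = 1.9990,
                        spectrum_width = 1.0941, symmetric_shift = -0.2312)
.octmf_global_sd <- c(Db = 0.0022, Di = 0.0233, Dc = 0.0402,
                      alpha_min = 0.0528, alpha_max = 0.2417,
                      alpha_center = 0.1380, f_alpha_max = 0.0022,
                      spectrum_width = 0.2150, symmetric_shift = 0.1540)
# class separation, in units of the global SD, applied as +d/2 to DR and
# -d/2 to Normal (sign encodes the direction of the DR shift)
.octmf_class_sep <- c(Db = 0, Di = 0.6, Dc = 0.6, alpha_min = 0.1,
                      alpha_max = 1.2, alpha_center = 1.2, f_alpha_max = 0,
                      spectrum_width = 1.4, symmetric_shift = -1.2)

#' Default class-conditional feature distribution
#'
#' Per-descriptor Gaussian moments for the DR and Normal classes. Class means
#' sit symmetrically about the global population mean and the class SDs are
#' shrunk so that merging the two classes with equal weight reproduces the
#' global mean and SD of each descriptor. The direction of each class shift
#' follows the clinical picture: wider spectra, higher `alpha_max` /
#' `alpha_center`, slightly higher `Di` / `Dc` and a more negative symmetric
#' shift in DR, with `Db` and `f_alpha_max` essentially class-invariant.
#'
#' @return a `feature_distribution` list with `mean` and `sd` matrices
#'   (rows `DR`, `Normal`; columns the nine descriptors).
#' @export
default_feature_distribution <- function() {
  d <- .octmf_class_sep * .octmf_global_sd
  mean <- rbind(DR = .octmf_global_mean + d / 2,
                Normal = .octmf_global_mean - d / 2)
  sdc <- .octmf_global_sd * sqrt(pmax(1 - .octmf_class_sep^2 / 4, 0.25))
  sd <- rbind(DR = sdc, Normal = sdc)
  colnames(mean) <- colnames(sd) <- .octmf_feature_names
  structure(list(mean = mean, sd = sd), class = "feature_distribution")
}

#' Sample a balanced two-class feature table
#'
#' Draws Gaussian descriptors per class. Internal consistency of the
#' descriptor set is preserved where it is exact in the field's tooling:
#' `f_alpha_max` is set equal to `Db` and `alpha_max` is derived as
#' `alpha_min + spectrum_width` (the primitives sampled are `alpha_min` and
#' `spectrum_width`), so the width identity holds row by row.
#'
#' @param dist a `feature_distribution` (default
#'   [default_feature_distribution()]).
#' @param n_per_class rows per class (>= 2).
#' @param seed integer RNG seed.
#' @return data.frame with columns `ID`, the nine descriptors, and `class`,
#'   `2 * n_per_class` rows, classes exactly balanced.
#' @export
sample_feature_table <- function(dist = default_feature_distribution(),
                                 n_per_class, seed = 42) {
  stopifnot(inherits(dist, "feature_distribution"))
  if (n_per_class < 2) stop("`n_per_class` must be >= 2", call. = FALSE)
  if (any(dist$sd < 0)) stop("feature SDs must be >= 0", call. = FALSE)
  set.seed(seed)
  one_class <- function(cl) {
    m <- dist$mean[cl, ]; s <- dist$sd[cl, ]
    draw <- function(f) rnorm(n_per_class, m[[f]], s[[f]])
    Db <- draw("Db")
    amin <- draw("alpha_min")
    width <- draw("spectrum_width")
    data.frame(Db = Db, Di = draw("Di"), Dc = draw("Dc"),
               alpha_min = amin, alpha_max = amin + width,
               alpha_center = draw("alpha_center"),
               f_alpha_max = Db, spectrum_width = width,
               symmetric_shift = draw("symmetric_shift"),
               class = cl)
  }
  tab <- rbind(one_class("DR"), one_class("Normal"))
  tab <- cbind(ID = seq_len(nrow(tab)), tab)
  rownames(tab) <- NULL
  tab
}
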