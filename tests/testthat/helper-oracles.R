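# Independent oracles used across the suite.

# Brute-force partition sums: explicit double loop over the box grid,
# independent of the vectorized implementation.
brute_force_Z <- function(img, epsilon, q_grid) {
  nr <- nrow(img); nc <- ncol(img)
  total <- sum(img)
  masses <- c()
  for (i0 in seq(1, nr, by = epsilon)) {
    for (j0 in seq(1, nc, by = epsilon)) {
      box <- img[i0:min(i0 + epsilon - 1, nr), j0:min(j0 + epsilon - 1, nc),
                 drop = FALSE]
      m <- sum(box)
      if (m > 0) masses <- c(masses, m)
    }
  }
  p <- masses / total
  vapply(q_grid, function(q) {
    if (abs(q - 1) < 1e-12) sum(p * log(p)) else sum(p^q)
  }, numeric(1))
}

# Exhaustive Otsu threshold: search all 8-bit cut points, maximize
# between-class variance of the histogram.
between_class_variance <- function(img, t) {
  v <- as.vector(img)
  lo <- v[v <= t]; hi <- v[v > t]
  if (!length(lo) || !length(hi)) return(-Inf)
  w0 <- length(lo) / length(v)
  w0 * (1 - w0) * (mean(lo) - mean(hi))^2
}
otsu_exhaustive <- function(img) {
  cand <- vapply(0:254, function(t) between_class_variance(img, t),
                 numeric(1))
  (0:254)[which.max(cand)]
}

# small deterministic two-class Gaussian table built without the package's
# sampler, for evaluation tests
toy_table <- function(n_per_class, sep = 3, seed = 1) {
  set.seed(seed)
  mk <- function(cl, shift) {
    width <- rnorm(n_per_class, 1 + shift, 0.15)
    amin <- rnorm(n_per_class, 1.74, 0.05)
    Db <- rnorm(n_per_class, 1.999, 0.002)
    data.frame(Db = Db, Di = rnorm(n_per_class, 1.94, 0.02),
               Dc = rnorm(n_per_class, 1.89, 0.04),
               alpha_min = amin, alpha_max = amin + width,
               alpha_center = rnorm(n_per_class, 2.29 + shift / 2, 0.1),
               f_alpha_max = Db, spectrum_width = width,
               symmetric_shift = rnorm(n_per_class, -0.23 - shift / 4, 0.1),
               class = cl)
  }
  tab <- rbind(mk("DR", sep * 0.1), mk("Normal", 0))
  cbind(ID = seq_len(nrow(tab)), tab)
}
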