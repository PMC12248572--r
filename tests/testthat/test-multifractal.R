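test_that("box probabilities partition mass correctly, including partial
           border boxes", {
  one <- matrix(0L, 16, 16)
  one[5, 11] <- 1L
  for (eps in c(1, 3, 8)) {
    bm <- box_probabilities(one, eps)
    expect_equal(bm$n_boxes, 1)
    expect_equal(bm$probabilities, 1)
  }
  full4 <- matrix(1L, 4, 4)
  bm <- box_probabilities(full4, 2)
  expect_equal(bm$n_boxes, 4)
  expect_equal(bm$probabilities, rep(0.25, 4))
  # 6x6 all-foreground with eps = 4: boxes hold 16, 8, 8, 4 pixels
  bm6 <- box_probabilities(matrix(1L, 6, 6), 4)
  expect_equal(sort(bm6$probabilities), sort(c(16, 8, 8, 4) / 36))
  expect_equal(sum(bm6$probabilities), 1)
  expect_error(box_probabilities(matrix(0L, 8, 8), 2), "empty measure")
  expect_error(box_probabilities(full4, 0), "epsilon")
})

test_that("partition sums have their closed forms on uniform and single-box
           measures", {
  q_grid <- default_qgrid()
  img <- matrix(1L, 64, 64)
  pf <- build_partition(img, scales = c(32, 16, 8, 4), q_grid = q_grid)
  for (s in seq_along(pf$scales)) {
    N <- (64 / pf$scales[s])^2
    expect_equal(pf$n_boxes[s], N)
    for (k in seq_along(q_grid)) {
      q <- q_grid[k]
      expected <- if (q == 1) N * (1 / N) * log(1 / N) else N^(1 - q)
      expect_equal(pf$Z[k, s], expected, tolerance = 1e-9)
    }
  }
  expect_equal(unname(pf$Z[q_grid == 0, ]), pf$n_boxes)
  one <- matrix(0L, 64, 64); one[10, 10] <- 1L
  pf1 <- build_partition(one, scales = c(32, 16, 8, 4), q_grid = c(0, 1, 2, 5))
  expect_equal(unname(pf1$Z[c(1, 3, 4), ]), matrix(1, 3, 4))
  expect_equal(unname(pf1$Z[2, ]), rep(0, 4))  # entropy of a point mass
})

test_that("partition sums equal a brute-force double loop on small images", {
  set.seed(8)
  q_grid <- c(-5, -2, -0.5, 0, 1, 2, 3.5, 5)
  for (case in 1:8) {
    nr <- sample(17:64, 1)
    nc <- sample(17:64, 1)
    img <- if (case %% 2) {
      matrix(rbinom(nr * nc, 1, 0.4), nr, nc)
    } else {
      matrix(runif(nr * nc), nr, nc)  # mass-map path
    }
    if (sum(img) == 0) img[1, 1] <- 1
    scales <- c(13, 8, 5, 3)
    pf <- build_partition(img, scales = scales, q_grid = q_grid)
    for (s in seq_along(scales)) {
      expect_equal(unname(pf$Z[, s]), brute_force_Z(img, scales[s], q_grid),
                   tolerance = 1e-12)
    }
  }
})

test_that("generalized dimensions recover closed forms", {
  # plane-filling uniform measure
  gd <- fit_generalized_dimensions(build_partition(make_filled_rect(256)))
  expect_true(all(abs(gd$D - 2) < 0.05))
  expect_true(all(gd$r2 > 0.999))
  # Sierpinski carpet
  gdc <- fit_generalized_dimensions(build_partition(make_sierpinski_carpet(5)))
  expect_lt(abs(gdc$Db - log(8) / log(3)), 0.05)
  # deterministic and randomized 2D binomial cascades
  for (sd_ in list(NULL, 13)) {
    gdk <- fit_generalized_dimensions(
      build_partition(make_binomial_cascade(8, 0.7, seed = sd_)))
    expect_lt(abs(gdk$Db - cascade_dq(0.7, 0)), 0.05)
    expect_lt(abs(gdk$Di - cascade_dq(0.7, 1)), 0.05)
    expect_lt(abs(gdk$Dc - cascade_dq(0.7, 2)), 0.05)
    expect_true(gdk$Db >= gdk$Di && gdk$Di >= gdk$Dc)
  }
  expect_error(
    fit_generalized_dimensions(
      structure(list(scales = c(8, 4), q_grid = 0:2,
                     Z = matrix(1, 3, 2)), class = "partition_function")),
    "insufficient scales")
})

test_that("cascade weight is recoverable by inverting the fitted D1", {
  # D1(p) = 2 * binary entropy is monotone on (0.5, 1): invert numerically
  for (p_true in c(0.65, 0.75)) {
    gd <- fit_generalized_dimensions(
      build_partition(make_binomial_cascade(8, p_true, seed = 21)))
    p_hat <- uniroot(function(p) cascade_dq(p, 1) - gd$Di,
                     c(0.5001, 0.9999))$root
    expect_lt(abs(p_hat - p_true), 0.03)
  }
})

test_that("halving the scale count perturbs carpet D0 only slightly", {
  carp <- make_sierpinski_carpet(5)
  full <- default_scales(ncol(carp))
  gd_full <- fit_generalized_dimensions(build_partition(carp, scales = full))
  half <- full[seq(1, length(full), by = 2)]
  if (length(half) < 4) half <- full[1:4]
  gd_half <- fit_generalized_dimensions(build_partition(carp, scales = half))
  expect_lt(abs(gd_full$Db - gd_half$Db), 0.03)
})

test_that("singularity spectrum collapses for monofractals and matches the
           cascade closed form", {
  sp <- singularity_spectrum(build_partition(make_filled_rect(256)))
  expect_lt(sp$landmarks[["spectrum_width"]], 0.1)
  expect_equal(sp$landmarks[["alpha_center"]], 2, tolerance = 0.05)

  gd <- fit_generalized_dimensions(
    build_partition(make_binomial_cascade(8, 0.7)))
  sp7 <- singularity_spectrum(gd)
  expect_lt(abs(sp7$landmarks[["spectrum_width"]] -
                cascade_spectrum_width(0.7, -5, 5)), 0.1)
  # f(alpha(0)) = D0 identity, exact
  expect_equal(sp7$landmarks[["f_alpha_max"]], gd$Db, tolerance = 1e-12)
  expect_true(all(diff(sp7$alpha) <= 1e-6))
})

test_that("a perfectly symmetric spectrum has zero symmetric shift", {
  q <- default_qgrid()
  gd <- structure(list(q_grid = q, D = 2 - 0.05 * q^2 / (1 + q^2 / 50)),
                  class = "generalized_dimensions")
  sp <- singularity_spectrum(gd, alpha_center_mode = "midpoint")
  expect_equal(sp$landmarks[["symmetric_shift"]], 0, tolerance = 1e-12)
})

test_that("feature extraction produces nine finite descriptors and fails
           loudly on empty masks", {
  ft <- extract_features(make_sierpinski_carpet(5), id = "carpet5")
  expect_s3_class(ft, "multifractal_features")
  expect_length(unclass(ft)[1:9], 9)
  expect_true(all(is.finite(unclass(ft)[1:9])))
  expect_equal(ft[["Db"]], ft[["f_alpha_max"]], tolerance = 1e-12)
  expect_equal(ft[["spectrum_width"]],
               ft[["alpha_max"]] - ft[["alpha_min"]], tolerance = 1e-12)
  expect_error(extract_features(matrix(0, 128, 128), id = "img7"), "img7")
})

test_that("descriptor monotonicity holds over random cascade parameters", {
  set.seed(31)
  for (i in 1:5) {
    p <- runif(1, 0.55, 0.9)
    gd <- fit_generalized_dimensions(
      build_partition(make_binomial_cascade(7, p, seed = i)))
    expect_true(all(diff(gd$D) <= 1e-6))
    # the embedding bound applies at q >= 0 (negative-order dimensions of a
    # non-uniform measure legitimately exceed it)
    pos <- gd$q_grid >= 0
    expect_true(all(gd$D[pos] >= 0 & gd$D[pos] <= 2 + 0.1))
  }
})
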