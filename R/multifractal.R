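# Box-counting multifractal estimation. A measure is built from the
# foreground pixels of a binary mask (each white pixel carries equal mass) or
# directly from a non-negative mass map; moment sums over a dyadic scale
# schedule give the generalized dimensions D(q) by log-log regression, and
# the Legendre transform of tau(q) = (q - 1) D(q) gives the singularity
# spectrum f(alpha) and its landmark descriptors.

#' Default dyadic scale schedule
#'
#' Powers of two from `min_box` up to half the shorter image side. Coarser
#' boxes than side/2 are excluded because almost every such box is occupied,
#' which saturates the counts and biases the fitted slopes toward the
#' embedding dimension.
#'
#' @param side shorter image side in pixels.
#' @param min_box smallest box size in pixels (default 4; single-pixel boxes
#'   saturate the opposite way).
#' @return decreasing integer vector of box sizes (at least 4 scales).
#' @export
default_scales <- function(side, min_box = 4) {
  kmax <- floor(log2(side / 2))
  kmin <- ceiling(log2(min_box))
  if (kmax - kmin + 1 < 4)
    stop("image too small for a 4-scale dyadic schedule (side >= 64 needed)",
         call. = FALSE)
  rev(2^(kmin:kmax))
}

#' Default moment-order grid
#'
#' Symmetric grid including q = 0, 1, 2 so that the box-counting,
#' information and correlation dimensions are always available.
#'
#' @param q_min,q_max grid extremes.
#' @param q_step grid step.
#' @return numeric vector of moment orders.
#' @export
default_qgrid <- function(q_min = -5, q_max = 5, q_step = 0.25) {
  q <- seq(q_min, q_max, by = q_step)
  if (!all(c(0, 1, 2) %in% q))
    stop("q grid must contain 0, 1 and 2", call. = FALSE)
  q
}

# per-box mass totals for one box size; grid anchored at the top-left pixel,
# partial boxes at the right/bottom edges included
.box_masses <- function(img, epsilon) {
  bi <- (seq_len(nrow(img)) - 1L) %/% epsilon
  bj <- (seq_len(ncol(img)) - 1L) %/% epsilon
  idx <- outer(bi, (max(bi) + 1L) * bj, "+")
  as.vector(rowsum(as.vector(img), as.vector(idx)))
}

#' Box occupation probabilities at one scale
#'
#' Partitions the image into `epsilon x epsilon` boxes anchored at the
#' top-left corner (partial boxes at the right and bottom edges are kept)
#' and returns the normalized mass per non-empty box, i.e. the probabilities
#' \eqn{p_i(\epsilon)} entering the moment sums.
#'
#' @param img binary 0/1 mask (each foreground pixel carries equal mass) or
#'   non-negative mass map.
#' @param epsilon box side in pixels (>= 1).
#' @return object of class `box_measure`: list with `epsilon`,
#'   `probabilities` (all > 0, summing to 1) and `n_boxes`.
#' @export
box_probabilities <- function(img, epsilon) {
  if (!is.matrix(img) || any(img < 0))
    stop("`img` must be a non-negative matrix", call. = FALSE)
  if (epsilon < 1 || epsilon != round(epsilon))
    stop("`epsilon` must be a positive integer", call. = FALSE)
  total <- sum(img)
  if (total <= 0)
    stop("empty measure: image has no foreground mass", call. = FALSE)
  mass <- .box_masses(img, epsilon)
  p <- mass[mass > 0] / total
  structure(list(epsilon = epsilon, probabilities = p, n_boxes = length(p)),
            class = "box_measure")
}

#' Moment partition sums over a scale schedule
#'
#' Fills the table \eqn{Z(q, \epsilon) = \sum_i p_i^q(\epsilon)} for
#' \eqn{q \neq 1}; the q = 1 slot holds the entropy sum
#' \eqn{\sum_i p_i \log p_i} used for the information dimension. Only
#' non-empty boxes contribute, which keeps negative-order moments finite.
#'
#' @param img binary mask or mass map (see [box_probabilities()]).
#' @param scales decreasing vector of box sizes; default
#'   [default_scales()] for the image.
#' @param q_grid moment orders, must contain 0, 1, 2; default
#'   [default_qgrid()].
#' @return object of class `partition_function`: `scales`, `q_grid`,
#'   matrix `Z` (rows = q, columns = scales) and `n_boxes` per scale.
#' @export
build_partition <- function(img, scales = NULL, q_grid = NULL) {
  if (is.null(scales)) scales <- default_scales(min(dim(img)))
  if (is.null(q_grid)) q_grid <- default_qgrid()
  scales <- as.numeric(scales)
  if (length(scales) < 4) stop("at least 4 scales required", call. = FALSE)
  if (any(diff(scales) >= 0))
    stop("`scales` must be strictly decreasing", call. = FALSE)
  if (!all(c(0, 1, 2) %in% q_grid))
    stop("q grid must contain 0, 1 and 2", call. = FALSE)
  Z <- matrix(NA_real_, length(q_grid), length(scales),
              dimnames = list(q = q_grid, epsilon = scales))
  n_boxes <- integer(length(scales))
  for (s in seq_along(scales)) {
    bm <- box_probabilities(img, scales[s])
    p <- bm$probabilities
    n_boxes[s] <- bm$n_boxes
    lp <- log(p)
    for (k in seq_along(q_grid)) {
      q <- q_grid[k]
      Z[k, s] <- if (abs(q - 1) < 1e-12) sum(p * lp) else sum(exp(q * lp))
    }
  }
  structure(list(scales = scales, q_grid = q_grid, Z = Z, n_boxes = n_boxes),
            class = "partition_function")
}

#' Generalized dimensions from a partition function
#'
#' For \eqn{q \neq 1}, the raw mass exponent \eqn{\hat\tau(q)} is the
#' ordinary-least-squares slope of \eqn{\log Z(q, \epsilon)} against
#' \eqn{\log \epsilon} (so \eqn{\hat D_q = \hat\tau(q)/(q-1)}); for q = 1
#' the slope of the entropy sum \eqn{\sum_i p_i \log p_i} gives
#' \eqn{\hat D_1} directly, and \eqn{\tau(1) = 0} holds exactly because the
#' box probabilities sum to one. The coefficient of determination of each
#' fit is recorded as a scaling diagnostic.
#'
#' On images that do not scale perfectly, the raw per-q slopes need not be
#' monotone in q even though the true dimensions always are. The estimator
#' therefore regularizes: the Holder curve
#' \eqn{\hat\alpha(q) = d\hat\tau/dq} (central finite differences,
#' one-sided at the grid ends) is projected onto non-increasing curves by
#' the pool-adjacent-violators algorithm, and \eqn{\tau} is rebuilt by
#' trapezoidal integration of the projected curve anchored at the exact
#' point \eqn{\tau(1) = 0}. The rebuilt \eqn{\tau} is concave with
#' \eqn{\tau(1) = 0}, which makes \eqn{D_q = \tau(q)/(q-1)} (a chord slope
#' from that anchor) non-increasing in q by construction and restores the
#' Legendre identities exactly; on well-scaling measures the projection is
#' the identity and only the O(step^2) discretization of the
#' differentiate-reintegrate round trip remains. The unregularized values
#' are kept in `D_raw`.
#'
#' @param pf a `partition_function` from [build_partition()].
#' @return object of class `generalized_dimensions`: `q_grid`, `D`, `r2`,
#'   `tau`, `alpha`, `D_raw`, and the special values `Db`, `Di`, `Dc`
#'   (\eqn{D_0, D_1, D_2}: box-counting, information and correlation
#'   dimensions).
#' @export
fit_generalized_dimensions <- function(pf) {
  stopifnot(inherits(pf, "partition_function"))
  if (length(pf$scales) < 4)
    stop("insufficient scales: need >= 4 for the log-log fit", call. = FALSE)
  x <- log(pf$scales)
  xc <- x - mean(x)
  sxx <- sum(xc^2)
  qg <- pf$q_grid
  n <- length(qg)
  D_raw <- r2 <- tau_raw <- numeric(n)
  for (k in seq_len(n)) {
    q <- qg[k]
    y <- if (abs(q - 1) < 1e-12) pf$Z[k, ] else log(pf$Z[k, ])
    slope <- sum(xc * (y - mean(y))) / sxx
    fitted <- mean(y) + slope * xc
    sst <- sum((y - mean(y))^2)
    r2[k] <- if (sst > 0) 1 - sum((y - fitted)^2) / sst else 1
    if (abs(q - 1) < 1e-12) {
      D_raw[k] <- slope
      tau_raw[k] <- 0           # sum(p) = 1 at every scale, exactly
    } else {
      D_raw[k] <- slope / (q - 1)
      tau_raw[k] <- slope
    }
  }
  # Holder curve of the raw exponents, projected onto monotone curves
  alpha_hat <- numeric(n)
  alpha_hat[1] <- (tau_raw[2] - tau_raw[1]) / (qg[2] - qg[1])
  alpha_hat[n] <- (tau_raw[n] - tau_raw[n - 1]) / (qg[n] - qg[n - 1])
  if (n > 2) {
    i <- 2:(n - 1)
    alpha_hat[i] <- (tau_raw[i + 1] - tau_raw[i - 1]) / (qg[i + 1] - qg[i - 1])
  }
  alpha <- -stats::isoreg(qg, -alpha_hat)$yf
  # rebuild tau by trapezoidal integration, anchored at tau(1) = 0
  dq <- diff(qg)
  increments <- dq * (alpha[-n] + alpha[-1]) / 2
  cum <- c(0, cumsum(increments))
  i1 <- which(abs(qg - 1) < 1e-12)
  tau <- cum - cum[i1]
  D <- ifelse(abs(qg - 1) < 1e-12, alpha, tau / (qg - 1))
  names(D) <- names(D_raw) <- names(r2) <- names(tau) <- names(alpha) <- qg
  structure(list(q_grid = qg, D = D, r2 = r2, tau = tau, alpha = alpha,
                 D_raw = D_raw,
                 Db = unname(D[qg == 0]),
                 Di = unname(D[qg == 1]),
                 Dc = unname(D[qg == 2])),
            class = "generalized_dimensions")
}

#' Singularity spectrum by Legendre transform
#'
#' Builds the mass exponents \eqn{\tau(q) = (q - 1) D_q}, differentiates by
#' central finite differences on the q grid (one-sided at the ends) to get
#' the Holder exponents \eqn{\alpha(q) = d\tau/dq}, and evaluates
#' \eqn{f(\alpha) = q \alpha(q) - \tau(q)}. Landmarks: `alpha_min`,
#' `alpha_max` (extremes of \eqn{\alpha} over the grid), `f_alpha_max` (the
#' spectrum peak, equal to \eqn{D_0} at q = 0 by construction),
#' `alpha_center` (the \eqn{\alpha} at the peak, or the support midpoint
#' with `alpha_center_mode = "midpoint"`), `spectrum_width`
#' (\eqn{\alpha_{max} - \alpha_{min}}) and `symmetric_shift`
#' (\eqn{\alpha_{center} - (\alpha_{min} + \alpha_{max})/2}).
#'
#' Non-monotone \eqn{\alpha(q)} beyond a 1e-6 tolerance — possible on poorly
#' scaling measures — is flagged in `diagnostics$alpha_monotone` but the
#' landmarks are still returned.
#'
#' @param gd a `generalized_dimensions` object (or a `partition_function`,
#'   which is fitted first).
#' @param alpha_center_mode `"argmax_f"` (the stated definition) or
#'   `"midpoint"`.
#' @return object of class `singularity_spectrum`: `q_grid`, `alpha`, `f`,
#'   `tau`, `landmarks` (named vector) and `diagnostics`.
#' @export
singularity_spectrum <- function(gd, alpha_center_mode = c("argmax_f",
                                                           "midpoint")) {
  alpha_center_mode <- match.arg(alpha_center_mode)
  if (inherits(gd, "partition_function")) gd <- fit_generalized_dimensions(gd)
  stopifnot(inherits(gd, "generalized_dimensions"))
  q <- gd$q_grid
  n <- length(q)
  if (!is.null(gd$tau) && !is.null(gd$alpha)) {
    tau <- gd$tau
    alpha <- gd$alpha
  } else {
    # hand-built D_q curve: differentiate tau = (q - 1) D_q directly
    tau <- (q - 1) * gd$D
    alpha <- numeric(n)
    alpha[1] <- (tau[2] - tau[1]) / (q[2] - q[1])
    alpha[n] <- (tau[n] - tau[n - 1]) / (q[n] - q[n - 1])
    if (n > 2) {
      i <- 2:(n - 1)
      alpha[i] <- (tau[i + 1] - tau[i - 1]) / (q[i + 1] - q[i - 1])
    }
  }
  f <- q * alpha - tau
  # the Legendre spectrum of a concave tau peaks at q = 0, where
  # f(alpha(0)) = D_0; taking the peak there keeps that identity exact
  i_peak <- which(abs(q) < 1e-12)
  if (!length(i_peak)) i_peak <- which.max(f)
  i_peak <- i_peak[1]
  a_min <- min(alpha)
  a_max <- max(alpha)
  a_center <- if (alpha_center_mode == "argmax_f") unname(alpha[i_peak]) else
    (a_min + a_max) / 2
  landmarks <- c(alpha_min = a_min, alpha_max = a_max,
                 alpha_center = a_center, f_alpha_max = unname(f[i_peak]),
                 spectrum_width = a_max - a_min,
                 symmetric_shift = a_center - (a_min + a_max) / 2)
  diagnostics <- list(alpha_monotone = all(diff(alpha) <= 1e-6),
                      alpha_center_mode = alpha_center_mode)
  structure(list(q_grid = q, alpha = alpha, f = f, tau = tau,
                 landmarks = landmarks, diagnostics = diagnostics),
            class = "singularity_spectrum")
}

#' Spectrum width from its landmark bounds
#'
#' The width descriptor is defined as \eqn{\Delta\alpha =
#' \alpha_{max} - \alpha_{min}}; this helper recomputes it from published
#' landmark values (e.g. when re-deriving widths from a reported feature
#' table).
#'
#' @param alpha_min,alpha_max spectrum support bounds.
#' @return `alpha_max - alpha_min`.
#' @export
spectrum_width <- function(alpha_min, alpha_max) alpha_max - alpha_min

#' Extract the nine multifractal descriptors from an image
#'
#' Runs the full estimation chain: binarize (grayscale inputs only, using
#' the thresholding settings of `config`), box counting over the scale
#' schedule, generalized-dimension fits and the Legendre spectrum. The
#' result is the nine-descriptor vector used for classification: `Db`,
#' `Di`, `Dc`, `alpha_min`, `alpha_max`, `alpha_center`, `f_alpha_max`,
#' `spectrum_width`, `symmetric_shift`.
#'
#' @param img binary 0/1 mask, or grayscale matrix in [0, 255].
#' @param config a [preprocess_config()]; only its thresholding settings are
#'   used here (blur/CLAHE belong to [preprocess_image()]).
#' @param scales,q_grid see [build_partition()].
#' @param alpha_center_mode see [singularity_spectrum()].
#' @param use_mass if `TRUE`, analyze a grayscale image directly as a mass
#'   map (summed intensity per box) instead of binarizing; the standard
#'   white-pixel path is `FALSE`.
#' @param id optional image identifier used in error messages.
#' @return object of class `multifractal_features`: named numeric vector of
#'   the nine descriptors, with the `generalized_dimensions` and
#'   `singularity_spectrum` attached as attributes.
#' @export
extract_features <- function(img, config = preprocess_config(),
                             scales = NULL, q_grid = NULL,
                             alpha_center_mode = "argmax_f",
                             use_mass = FALSE, id = NULL) {
  is_binary <- all(img %in% c(0, 1))
  mat <- if (is_binary || use_mass) img else
    binarize(img, method = config$threshold_method,
             fixed_threshold = config$fixed_threshold)
  if (sum(mat) <= 0)
    stop("feature extraction failed",
         if (!is.null(id)) paste0(" for image ", id),
         ": degenerate (empty) mask", call. = FALSE)
  pf <- build_partition(mat, scales = scales, q_grid = q_grid)
  gd <- fit_generalized_dimensions(pf)
  sp <- singularity_spectrum(gd, alpha_center_mode = alpha_center_mode)
  lm <- sp$landmarks
  feats <- c(Db = gd$Db, Di = gd$Di, Dc = gd$Dc,
             alpha_min = unname(lm["alpha_min"]),
             alpha_max = unname(lm["alpha_max"]),
             alpha_center = unname(lm["alpha_center"]),
             f_alpha_max = unname(lm["f_alpha_max"]),
             spectrum_width = unname(lm["spectrum_width"]),
             symmetric_shift = unname(lm["symmetric_shift"]))
  structure(feats, class = "multifractal_features",
            dimensions = gd, spectrum = sp, id = id)
}

#' @export
print.multifractal_features <- function(x, ...) {
  cat("Multifractal descriptors", if (!is.null(attr(x, "id")))
    paste0("(", attr(x, "id"), ")"), "\n")
  print(round(unclass(x)[seq_len(9)], 4))
  invisible(x)
}

#' @export
as.data.frame.multifractal_features <- function(x, ...) {
  as.data.frame(as.list(unclass(x)[seq_len(9)]))
}
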