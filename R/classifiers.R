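# Classifier panel. Eight models with fixed, pre-optimized hyperparameters;
# the multilayer perceptron — the study's headline model — is implemented
# here directly (two ReLU hidden layers of 128 and 64 units, sigmoid output,
# full-batch Adam, iteration-capped), while the standard learners are backed
# by their established R implementations.

#' Classifier specification with fixed hyperparameters
#'
#' Defaults per model: logistic regression (L2, C = 1); random forest (100
#' trees, depth 10); decision tree (depth 5, entropy criterion); polynomial
#' SVM (degree 3, C = 1, probability estimates); gradient-boosted trees in
#' three presets — depth 3, depth 4 ("xgboost-style") and depth 5
#' ("lightgbm-style"), all 100 rounds at learning rate 0.1; MLP with hidden
#' layers (128, 64), ReLU activation, Adam solver, at most 1000 iterations
#' and random state 42.
#'
#' @param name one of `"logistic_regression"`, `"random_forest"`,
#'   `"decision_tree"`, `"svm_poly"`, `"gradient_boosting"`,
#'   `"xgboost_style_gbt"`, `"lightgbm_style_gbt"`, `"mlp"`.
#' @param ... named hyperparameter overrides.
#' @return a `classifier_spec` list with `name` and `hyper`.
#' @export
classifier_spec <- function(name, ...) {
  name <- match.arg(name, .octmf_model_names)
  hyper <- switch(name,
    logistic_regression = list(penalty = "L2", C = 1.0),
    random_forest = list(n_estimators = 100, max_depth = 10, seed = 42),
    decision_tree = list(max_depth = 5, criterion = "entropy"),
    svm_poly = list(kernel = "poly", degree = 3, C = 1.0, probability = TRUE),
    gradient_boosting = list(n_estimators = 100, learning_rate = 0.1,
                             max_depth = 3, seed = 42),
    xgboost_style_gbt = list(n_estimators = 100, learning_rate = 0.1,
                             max_depth = 4, seed = 42),
    lightgbm_style_gbt = list(n_estimators = 100, learning_rate = 0.1,
                              max_depth = 5, seed = 42),
    mlp = list(hidden = c(128, 64), activation = "relu", solver = "adam",
               max_iter = 1000, random_state = 42))
  override <- list(...)
  hyper[names(override)] <- override
  structure(list(name = name, hyper = hyper), class = "classifier_spec")
}

#' All eight default classifier specifications
#' @return named list of [classifier_spec()] objects.
#' @export
default_classifiers <- function() {
  specs <- lapply(.octmf_model_names, classifier_spec)
  names(specs) <- .octmf_model_names
  specs
}

# rectifier and logistic activations of the perceptron forward pass
relu <- function(x) {
  x[x < 0] <- 0
  x
}
sigmoid <- function(x) 1 / (1 + exp(-x))

# Two-hidden-layer perceptron trained by full-batch Adam on the logistic
# loss. X: n x p matrix; y: 0/1 vector. Deterministic given random_state.
.mlp_fit <- function(X, y, hidden = c(128, 64), max_iter = 1000,
                     random_state = 42, learning_rate = 1e-3, tol = 1e-6) {
  set.seed(random_state)
  sizes <- c(ncol(X), hidden, 1L)
  L <- length(sizes) - 1L
  W <- b <- mW <- vW <- mb <- vb <- vector("list", L)
  for (l in seq_len(L)) {
    # Glorot-uniform initialization
    lim <- sqrt(6 / (sizes[l] + sizes[l + 1]))
    W[[l]] <- matrix(runif(sizes[l] * sizes[l + 1], -lim, lim),
                     sizes[l], sizes[l + 1])
    b[[l]] <- rep(0, sizes[l + 1])
    mW[[l]] <- vW[[l]] <- matrix(0, sizes[l], sizes[l + 1])
    mb[[l]] <- vb[[l]] <- rep(0, sizes[l + 1])
  }
  n <- nrow(X)
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  prev_loss <- Inf
  stall <- 0L
  for (it in seq_len(max_iter)) {
    # forward
    A <- vector("list", L + 1L)
    A[[1]] <- X
    for (l in seq_len(L - 1L))
      A[[l + 1]] <- relu(sweep(A[[l]] %*% W[[l]], 2, b[[l]], "+"))
    z_out <- drop(A[[L]] %*% W[[L]]) + b[[L]]
    p <- sigmoid(z_out)
    loss <- -mean(y * log(pmax(p, 1e-12)) +
                  (1 - y) * log(pmax(1 - p, 1e-12)))
    # backward
    delta <- matrix((p - y) / n, n, 1)
    gW <- gb <- vector("list", L)
    for (l in seq(L, 1)) {
      gW[[l]] <- crossprod(A[[l]], delta)
      gb[[l]] <- colSums(delta)
      if (l > 1) {
        delta <- (delta %*% t(W[[l]])) * (A[[l]] > 0)
      }
    }
    # Adam update with bias correction
    c1 <- 1 - beta1^it; c2 <- 1 - beta2^it
    for (l in seq_len(L)) {
      mW[[l]] <- beta1 * mW[[l]] + (1 - beta1) * gW[[l]]
      vW[[l]] <- beta2 * vW[[l]] + (1 - beta2) * gW[[l]]^2
      W[[l]] <- W[[l]] - learning_rate * (mW[[l]] / c1) /
        (sqrt(vW[[l]] / c2) + eps)
      mb[[l]] <- beta1 * mb[[l]] + (1 - beta1) * gb[[l]]
      vb[[l]] <- beta2 * vb[[l]] + (1 - beta2) * gb[[l]]^2
      b[[l]] <- b[[l]] - learning_rate * (mb[[l]] / c1) /
        (sqrt(vb[[l]] / c2) + eps)
    }
    if (abs(prev_loss - loss) < tol) stall <- stall + 1L else stall <- 0L
    if (stall >= 10L) break
    prev_loss <- loss
  }
  if (it == max_iter)
    warning("mlp: iteration cap reached before loss stabilized", call. = FALSE)
  list(W = W, b = b, iterations = it, loss = loss)
}

.mlp_predict_prob <- function(fit, X) {
  L <- length(fit$W)
  A <- X
  for (l in seq_len(L - 1L))
    A <- relu(sweep(A %*% fit$W[[l]], 2, fit$b[[l]], "+"))
  sigmoid(drop(A %*% fit$W[[L]]) + fit$b[[L]])
}

#' Train a classifier on a feature table
#'
#' Features are the nine multifractal descriptors; labels are `DR`
#' (positive class) vs `Normal`. The table is expected to be normalized
#' already (see [normalize_features()]); no scaling happens here.
#'
#' @param spec a [classifier_spec()].
#' @param train feature table data.frame.
#' @return a `trained_classifier` with a [predict][predict.trained_classifier]
#'   method returning `"DR"`/`"Normal"` labels (decision threshold 0.5 on
#'   the positive-class probability where applicable).
#' @export
train_classifier <- function(spec, train) {
  stopifnot(inherits(spec, "classifier_spec"))
  X <- as.matrix(train[, .octmf_feature_names])
  y <- as.integer(train$class == "DR")
  h <- spec$hyper
  fit <- switch(spec$name,
    logistic_regression = {
      cf <- suppressWarnings(
        stats::glm.fit(cbind(1, X), y,
                       family = stats::binomial())$coefficients)
      cf[is.na(cf)] <- 0  # aliased (exactly collinear) features drop out
      cf
    },
    random_forest = {
      set.seed(h$seed)
      # depth cap expressed as a leaf cap; a tree on n cases cannot have
      # more than n leaves, so clamp to keep randomForest quiet
      randomForest::randomForest(X, factor(y, levels = 0:1),
                                 ntree = h$n_estimators,
                                 maxnodes = min(2^h$max_depth, nrow(X)))
    },
    decision_tree = {
      df <- data.frame(X, y = factor(y, levels = 0:1))
      rpart::rpart(y ~ ., df, method = "class",
                   parms = list(split = "information"),
                   control = rpart::rpart.control(maxdepth = h$max_depth,
                                                  cp = 0, minsplit = 5))
    },
    svm_poly = e1071::svm(X, factor(y, levels = 0:1), kernel = "polynomial",
                          degree = h$degree, cost = h$C,
                          probability = h$probability),
    gradient_boosting = ,
    xgboost_style_gbt = ,
    lightgbm_style_gbt = {
      set.seed(h$seed)
      xgboost::xgb.train(
        params = list(learning_rate = h$learning_rate,
                      max_depth = h$max_depth,
                      objective = "binary:logistic", nthread = 1),
        data = xgboost::xgb.DMatrix(X, label = y, nthread = 1),
        nrounds = h$n_estimators)
    },
    mlp = .mlp_fit(X, y, hidden = h$hidden, max_iter = h$max_iter,
                   random_state = h$random_state))
  structure(list(spec = spec, fit = fit), class = "trained_classifier")
}

#' Predict class labels (or probabilities) for a feature table
#'
#' @param object a `trained_classifier`.
#' @param newdata feature table data.frame.
#' @param type `"class"` for `"DR"`/`"Normal"` labels or `"prob"` for the
#'   positive-class (DR) probability where the model provides one.
#' @param ... unused.
#' @return character vector of labels or numeric vector of probabilities.
#' @export
predict.trained_classifier <- function(object, newdata, type = c("class",
                                                                 "prob"),
                                       ...) {
  type <- match.arg(type)
  X <- as.matrix(newdata[, .octmf_feature_names])
  name <- object$spec$name
  prob <- switch(name,
    logistic_regression = sigmoid(drop(cbind(1, X) %*% object$fit)),
    random_forest = stats::predict(object$fit, X, type = "prob")[, "1"],
    decision_tree = stats::predict(object$fit, data.frame(X),
                                   type = "prob")[, "1"],
    svm_poly = {
      pr <- stats::predict(object$fit, X, probability = TRUE)
      attr(pr, "probabilities")[, "1"]
    },
    gradient_boosting = ,
    xgboost_style_gbt = ,
    lightgbm_style_gbt = stats::predict(object$fit,
                                        xgboost::xgb.DMatrix(X, nthread = 1)),
    mlp = .mlp_predict_prob(object$fit, X))
  if (type == "prob") return(unname(prob))
  ifelse(prob > 0.5, "DR", "Normal")
}
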