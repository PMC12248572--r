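# Stratified k-fold evaluation with a clinical metric suite. Normalization
# statistics are always fitted on the training split of each fold and
# applied unchanged to its test split, so no information leaks across the
# partition. The positive class is DR throughout.

#' Z-score normalization fitted on the training split only
#'
#' Centers and scales the nine descriptor columns using the training mean
#' and standard deviation, then applies the same transform to the test
#' split. Zero-variance features are passed through unchanged with a
#' warning.
#'
#' @param train,test feature table data.frames.
#' @return list with transformed `train`, `test`, and `scaler` (per-feature
#'   `center` and `scale`).
#' @export
normalize_features <- function(train, test) {
  center <- vapply(train[, .octmf_feature_names], mean, numeric(1))
  scale <- vapply(train[, .octmf_feature_names], stats::sd, numeric(1))
  degenerate <- !is.finite(scale) | scale == 0
  if (any(degenerate)) {
    warning("zero-variance feature(s) passed through unscaled: ",
            paste(.octmf_feature_names[degenerate], collapse = ", "),
            call. = FALSE)
    center[degenerate] <- 0
    scale[degenerate] <- 1
  }
  apply_tf <- function(tab) {
    for (j in seq_along(.octmf_feature_names)) {
      f <- .octmf_feature_names[j]
      tab[[f]] <- (tab[[f]] - center[j]) / scale[j]
    }
    tab
  }
  list(train = apply_tf(train), test = apply_tf(test),
       scaler = list(center = center, scale = scale))
}

#' Stratified k-fold partition of a feature table
#'
#' Rows of each class are shuffled (seeded) and dealt round-robin to k test
#' folds, so per-fold class counts deviate from perfect proportion by at
#' most one. Folds are disjoint and cover every row.
#'
#' @param tab feature table data.frame.
#' @param k number of folds.
#' @param seed RNG seed (default 42).
#' @return list of k elements, each `list(train_ids, test_ids)` of `ID`
#'   values.
#' @export
stratified_kfold <- function(tab, k = 5, seed = 42) {
  validate_feature_table(tab)
  counts <- table(tab$class)
  if (any(counts < k))
    stop("every class needs at least k rows for k-fold stratification",
         call. = FALSE)
  set.seed(seed)
  fold_of <- integer(nrow(tab))
  for (cl in names(counts)) {
    idx <- sample(which(tab$class == cl))
    fold_of[idx] <- rep_len(seq_len(k), length(idx))
  }
  lapply(seq_len(k), function(f)
    list(train_ids = tab$ID[fold_of != f], test_ids = tab$ID[fold_of == f]))
}

#' Confusion counts of a trained classifier on a test split
#'
#' @param model a `trained_classifier`.
#' @param test feature table data.frame (normalized like the training data).
#' @return named integer vector `c(TP, TN, FP, FN)` with DR as the positive
#'   class.
#' @export
evaluate_fold <- function(model, test) {
  pred <- predict(model, test)
  truth <- test$class
  c(TP = sum(pred == "DR" & truth == "DR"),
    TN = sum(pred == "Normal" & truth == "Normal"),
    FP = sum(pred == "DR" & truth == "Normal"),
    FN = sum(pred == "Normal" & truth == "DR"))
}

#' Clinical metric suite from confusion counts
#'
#' Accuracy, precision, recall (sensitivity), specificity and F1. A metric
#' whose denominator is zero is reported as `NA` (undefined), with a
#' warning, rather than coerced to 0.
#'
#' @param counts named vector with `TP`, `TN`, `FP`, `FN`.
#' @return named numeric vector of the five metrics.
#' @export
compute_metrics <- function(counts) {
  TP <- counts[["TP"]]; TN <- counts[["TN"]]
  FP <- counts[["FP"]]; FN <- counts[["FN"]]
  if (any(c(TP, TN, FP, FN) < 0)) stop("negative confusion counts",
                                       call. = FALSE)
  safe_div <- function(num, den, what) {
    if (den == 0) {
      warning(what, " undefined: zero denominator", call. = FALSE)
      return(NA_real_)
    }
    num / den
  }
  accuracy <- safe_div(TP + TN, TP + TN + FP + FN, "accuracy")
  precision <- safe_div(TP, TP + FP, "precision")
  recall <- safe_div(TP, TP + FN, "recall")
  specificity <- safe_div(TN, TN + FP, "specificity")
  f1 <- if (is.na(precision) || is.na(recall) || precision + recall == 0)
    NA_real_ else 2 * precision * recall / (precision + recall)
  c(accuracy = accuracy, precision = precision, recall = recall,
    specificity = specificity, f1 = f1)
}

#' Aggregate per-fold metrics into an evaluation summary
#'
#' Per-metric arithmetic means, a 95% Student-t confidence interval for the
#' accuracy across folds (k - 1 degrees of freedom), and a one-sided
#' one-sample t-test of the fold accuracies against the 0.5 chance level.
#' With zero variance across folds the CI collapses to the mean and the
#' p-value degenerates to 0 (mean above chance) or 1.
#'
#' @param fold_metrics matrix or data.frame, one row per fold, columns the
#'   five metrics.
#' @return list with `mean` (named vector), `ci_accuracy` (`lower`,
#'   `upper`), and `p_value_vs_chance`.
#' @export
aggregate_folds <- function(fold_metrics) {
  m <- as.matrix(fold_metrics)
  if (nrow(m) < 2) stop("need >= 2 folds to aggregate", call. = FALSE)
  means <- colMeans(m)
  acc <- m[, "accuracy"]
  k <- length(acc)
  s <- stats::sd(acc)
  if (s > 0) {
    half <- stats::qt(0.975, k - 1) * s / sqrt(k)
    tt <- stats::t.test(acc, mu = 0.5, alternative = "greater")
    p <- tt$p.value
  } else {
    half <- 0
    p <- if (mean(acc) > 0.5) 0 else 1
  }
  list(mean = means,
       ci_accuracy = c(lower = mean(acc) - half, upper = mean(acc) + half),
       p_value_vs_chance = p)
}

#' Run the full cross-validated classification experiment
#'
#' For every requested classifier: stratified k-fold split (identical folds
#' across models), per-fold z-score normalization fitted on the training
#' split, training with the fixed hyperparameters, confusion counts and the
#' metric suite on the test split, then aggregation with CI and
#' significance versus chance.
#'
#' @param features feature table data.frame or path to a canonical CSV.
#' @param models `"all"`, a character vector of model names, or a list of
#'   [classifier_spec()] objects.
#' @param k number of folds (default 5, i.e. 80/20 train/test per fold).
#' @param seed RNG seed controlling fold assignment and stochastic model
#'   initialization (default 42).
#' @param out_dir optional directory; when given, writes `report.json`,
#'   `table_folds.csv` (per-fold metrics), `table_summary.csv` (aggregate
#'   metrics with CI) and `confusion.json`.
#' @return object of class `evaluation_report`: per-model list with
#'   `folds` (per-fold metrics data.frame), `confusion` (per-fold counts),
#'   `aggregate`, `ci_accuracy`, `p_value_vs_chance`.
#' @export
run_experiment <- function(features, models = "all", k = 5, seed = 42,
                           out_dir = NULL) {
  tab <- if (is.character(features)) read_feature_table(features) else
    validate_feature_table(features)
  specs <- if (inherits(models, "classifier_spec")) {
    stats::setNames(list(models), models$name)
  } else if (is.list(models)) {
    stats::setNames(models, vapply(models, `[[`, "", "name"))
  } else if (identical(models, "all")) {
    default_classifiers()
  } else {
    stats::setNames(lapply(models, classifier_spec), models)
  }
  folds <- stratified_kfold(tab, k = k, seed = seed)
  report <- list()
  for (nm in names(specs)) {
    fold_metrics <- NULL
    confusion <- NULL
    for (f in seq_along(folds)) {
      tr <- tab[tab$ID %in% folds[[f]]$train_ids, ]
      te <- tab[tab$ID %in% folds[[f]]$test_ids, ]
      nz <- normalize_features(tr, te)
      model <- train_classifier(specs[[nm]], nz$train)
      counts <- evaluate_fold(model, nz$test)
      fold_metrics <- rbind(fold_metrics, compute_metrics(counts))
      confusion <- rbind(confusion, counts)
    }
    agg <- aggregate_folds(fold_metrics)
    report[[nm]] <- list(
      folds = data.frame(fold = seq_along(folds), fold_metrics),
      confusion = data.frame(fold = seq_along(folds), confusion),
      aggregate = agg$mean,
      ci_accuracy = agg$ci_accuracy,
      p_value_vs_chance = agg$p_value_vs_chance)
  }
  res <- structure(report, class = "evaluation_report",
                   k = k, seed = seed, n = nrow(tab))
  if (!is.null(out_dir)) write_evaluation_report(res, out_dir)
  res
}

#' Write an evaluation report to disk
#'
#' @param report an `evaluation_report`.
#' @param out_dir output directory (created if missing).
#' @return `out_dir`, invisibly.
#' @export
write_evaluation_report <- function(report, out_dir) {
  stopifnot(inherits(report, "evaluation_report"))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  jsonlite::write_json(
    lapply(report, function(r) list(
      folds = r$folds, aggregate = as.list(r$aggregate),
      ci_accuracy = as.list(r$ci_accuracy),
      p_value_vs_chance = r$p_value_vs_chance)),
    file.path(out_dir, "report.json"), auto_unbox = TRUE, digits = NA,
    dataframe = "rows")
  fold_rows <- do.call(rbind, lapply(names(report), function(nm)
    cbind(model = nm, report[[nm]]$folds)))
  utils::write.csv(fold_rows, file.path(out_dir, "table_folds.csv"),
                   row.names = FALSE)
  summary_rows <- do.call(rbind, lapply(names(report), function(nm) {
    r <- report[[nm]]
    data.frame(model = nm, t(r$aggregate),
               ci_lower = r$ci_accuracy[["lower"]],
               ci_upper = r$ci_accuracy[["upper"]],
               p_value_vs_chance = r$p_value_vs_chance)
  }))
  utils::write.csv(summary_rows, file.path(out_dir, "table_summary.csv"),
                   row.names = FALSE)
  jsonlite::write_json(lapply(report, `[[`, "confusion"),
                       file.path(out_dir, "confusion.json"),
                       dataframe = "rows", digits = NA)
  invisible(out_dir)
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("Evaluation report: %d rows, %d-fold stratified CV (seed %d)\n",
              attr(x, "n"), attr(x, "k"), attr(x, "seed")))
  for (nm in names(x)) {
    a <- x[[nm]]$aggregate
    cat(sprintf("  %-20s acc %.4f  prec %.4f  rec %.4f  spec %.4f  F1 %.4f  CI [%.4f, %.4f]\n",
                nm, a[["accuracy"]], a[["precision"]], a[["recall"]],
                a[["specificity"]], a[["f1"]],
                x[[nm]]$ci_accuracy[["lower"]], x[[nm]]$ci_accuracy[["upper"]]))
  }
  invisible(x)
}
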