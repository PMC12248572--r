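test_that("z-score normalization is fitted on the training split only", {
  tr <- toy_table(20, seed = 5)
  te <- toy_table(10, seed = 6)
  te$ID <- te$ID + 100
  nz <- normalize_features(tr, te)
  expect_equal(mean(nz$train$spectrum_width), 0, tolerance = 1e-12)
  expect_equal(sd(nz$train$spectrum_width), 1, tolerance = 1e-12)
  # test transformed with train statistics, never its own
  expect_equal(nz$test$spectrum_width,
               (te$spectrum_width - nz$scaler$center[["spectrum_width"]]) /
                 nz$scaler$scale[["spectrum_width"]])
  expect_false(abs(mean(nz$test$spectrum_width)) < 1e-10)
  # worked example: mean 10, sd 2, value 12 -> 1
  tr2 <- tr
  tr2$Db <- rep(c(8, 12), 20)  # mean 10, sd ~2.03
  tr2$Db <- (tr2$Db - 10) / sd(tr2$Db) * 2 + 10
  te2 <- te
  te2$Db <- 12
  nz2 <- normalize_features(tr2, te2)
  expect_equal(unique(nz2$test$Db), 1, tolerance = 1e-12)
})

test_that("constant features pass through unchanged with a warning", {
  tr <- toy_table(10, seed = 7)
  tr$Dc <- 1.5
  te <- toy_table(4, seed = 8)
  te$ID <- te$ID + 50
  expect_warning(nz <- normalize_features(tr, te), "zero-variance")
  expect_equal(nz$train$Dc, rep(1.5, 20))
})

test_that("stratified folds partition the table with balanced classes", {
  tab <- toy_table(100, seed = 9)
  folds <- stratified_kfold(tab, k = 5, seed = 42)
  test_ids <- unlist(lapply(folds, `[[`, "test_ids"))
  expect_setequal(test_ids, tab$ID)
  expect_equal(anyDuplicated(test_ids), 0L)
  for (f in folds) {
    cls <- tab$class[tab$ID %in% f$test_ids]
    expect_equal(sum(cls == "DR"), 20)
    expect_equal(sum(cls == "Normal"), 20)
    expect_setequal(c(f$train_ids, f$test_ids), tab$ID)
  }
  expect_identical(folds, stratified_kfold(tab, k = 5, seed = 42))
  small <- toy_table(3, seed = 10)
  expect_error(stratified_kfold(small, k = 5), "at least k")
})

test_that("uneven class sizes stratify to within one row of proportion", {
  tab <- toy_table(26, seed = 11)
  tab <- tab[-c(1, 2, 3), ]  # 23 DR, 26 Normal
  folds <- stratified_kfold(tab, k = 5, seed = 1)
  for (f in folds) {
    cls <- tab$class[tab$ID %in% f$test_ids]
    expect_lte(abs(sum(cls == "DR") - 23 / 5), 1)
    expect_lte(abs(sum(cls == "Normal") - 26 / 5), 1)
  }
})

test_that("metric suite matches hand-computed confusion tables", {
  m <- compute_metrics(c(TP = 90, TN = 80, FP = 20, FN = 10))
  expect_equal(m[["recall"]], 0.90)
  expect_equal(m[["specificity"]], 0.80)
  expect_equal(m[["accuracy"]], 0.85)
  expect_equal(m[["precision"]], 90 / 110)
  expect_equal(m[["f1"]], 2 * (90 / 110) * 0.9 / ((90 / 110) + 0.9))
  perfect <- compute_metrics(c(TP = 20, TN = 20, FP = 0, FN = 0))
  expect_true(all(perfect == 1))
  expect_warning(und <- compute_metrics(c(TP = 0, TN = 50, FP = 0, FN = 50)),
                 "precision undefined")
  expect_true(is.na(und[["precision"]]))
  expect_equal(und[["accuracy"]], 0.5)
})

test_that("F1 equals the harmonic-mean identity on random confusion counts", {
  set.seed(12)
  for (i in 1:20) {
    counts <- c(TP = rpois(1, 30) + 1, TN = rpois(1, 30) + 1,
                FP = rpois(1, 10) + 1, FN = rpois(1, 10) + 1)
    m <- compute_metrics(counts)
    expect_true(all(m[!is.na(m)] >= 0 & m[!is.na(m)] <= 1))
    expect_equal(m[["f1"]],
                 2 / (1 / m[["precision"]] + 1 / m[["recall"]]),
                 tolerance = 1e-12)
  }
})

test_that("confusion counts are consistent with predictions and fold size", {
  tab <- toy_table(30, sep = 5, seed = 13)
  folds <- stratified_kfold(tab, k = 5, seed = 42)
  tr <- tab[tab$ID %in% folds[[1]]$train_ids, ]
  te <- tab[tab$ID %in% folds[[1]]$test_ids, ]
  nz <- normalize_features(tr, te)
  model <- train_classifier(classifier_spec("decision_tree"), nz$train)
  counts <- evaluate_fold(model, nz$test)
  expect_equal(sum(counts), nrow(te))
  expect_true(all(counts >= 0))
})

test_that("aggregation reproduces means, degenerate CIs, and a null p-value
           at chance level", {
  five <- matrix(rep(c(accuracy = 0.9, precision = 0.9, recall = 0.9,
                       specificity = 0.9, f1 = 0.9), each = 5), 5, 5,
                 dimnames = list(NULL, c("accuracy", "precision", "recall",
                                         "specificity", "f1")))
  agg <- aggregate_folds(five)
  expect_equal(unname(agg$mean["accuracy"]), 0.9)
  expect_equal(unname(diff(agg$ci_accuracy)), 0)
  accs <- c(0.8950, 0.9142, 0.8842, 0.8983, 0.8942)
  m2 <- five
  m2[, "accuracy"] <- accs
  agg2 <- aggregate_folds(m2)
  expect_equal(unname(agg2$mean["accuracy"]), mean(accs), tolerance = 1e-12)
  expect_lte(agg2$ci_accuracy[["lower"]], mean(accs))
  expect_gte(agg2$ci_accuracy[["upper"]], mean(accs))
  expect_lt(agg2$p_value_vs_chance, 0.05)
  chance <- five
  chance[, "accuracy"] <- 0.5
  expect_gt(aggregate_folds(chance)$p_value_vs_chance, 0.05)
})

test_that("MLP internals honor the ReLU and sigmoid contracts and separate
           a separable set", {
  expect_equal(octmf:::relu(c(-3, 0, 3)), c(0, 0, 3))
  expect_equal(octmf:::sigmoid(0), 0.5)
  tab <- toy_table(25, sep = 8, seed = 14)
  nz <- normalize_features(tab, tab)
  for (nm in c("mlp", "svm_poly")) {
    model <- train_classifier(classifier_spec(nm), nz$train)
    expect_equal(unname(predict(model, nz$train)), tab$class)
  }
  # deterministic retraining given the fixed random state
  m1 <- train_classifier(classifier_spec("mlp"), nz$train)
  m2 <- train_classifier(classifier_spec("mlp"), nz$train)
  expect_identical(predict(m1, nz$test, type = "prob"),
                   predict(m2, nz$test, type = "prob"))
})

test_that("experiment on a zero-separation table stays at chance for every
           model", {
  dist <- default_feature_distribution()
  dist$mean["DR", ] <- dist$mean["Normal", ]
  tab <- sample_feature_table(dist, n_per_class = 100, seed = 15)
  # the MLP legitimately warns that its iteration cap was reached: there is
  # nothing to learn here, so the loss never stabilizes
  rep <- suppressWarnings(run_experiment(tab, models = "all", k = 5,
                                         seed = 42))
  expect_length(rep, 8)
  for (nm in names(rep)) {
    acc <- rep[[nm]]$aggregate[["accuracy"]]
    expect_gte(acc, 0.4)
    expect_lte(acc, 0.6)
  }
})

test_that("experiment on a separated table is accurate, deterministic, and
           bookkeeps folds", {
  tab <- sample_feature_table(n_per_class = 60, seed = 16)
  r1 <- run_experiment(tab, models = c("logistic_regression", "mlp"),
                       k = 5, seed = 42)
  r2 <- run_experiment(tab, models = c("logistic_regression", "mlp"),
                       k = 5, seed = 42)
  expect_identical(r1, r2)
  # the default class separation is ~1.4 SD on the strongest descriptor,
  # i.e. Bayes-level accuracy a little under 0.9: well above chance
  expect_gt(r1$mlp$aggregate[["accuracy"]], 0.8)
  expect_lt(r1$mlp$p_value_vs_chance, 0.05)
  expect_equal(nrow(r1$mlp$folds), 5)
  expect_equal(sum(as.matrix(r1$mlp$confusion[, c("TP", "TN", "FP", "FN")])),
               120)
  # leakage guard: normalization inside the experiment never sees test rows
  expect_equal(r1$mlp$aggregate[["accuracy"]],
               mean(r1$mlp$folds$accuracy), tolerance = 1e-12)
})

test_that("report files are written in the documented formats", {
  outd <- withr::local_tempdir()
  tab <- sample_feature_table(n_per_class = 20, seed = 17)
  run_experiment(tab, models = "decision_tree", k = 5, seed = 42,
                 out_dir = outd)
  expect_true(all(file.exists(file.path(outd,
    c("report.json", "table_folds.csv", "table_summary.csv",
      "confusion.json")))))
  js <- jsonlite::read_json(file.path(outd, "report.json"))
  expect_named(js, "decision_tree")
  folds_csv <- read.csv(file.path(outd, "table_folds.csv"))
  expect_equal(nrow(folds_csv), 5)
})
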