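test_that("split plans are subject-disjoint, sized and deterministic", {
  ids <- paste0("S", 1:10)
  plan <- make_split_plan(ids, n_folds = 25, test_fraction = 0.1, seed = 4)
  for (fold in plan$folds) {
    expect_length(fold$test, 1)
    expect_length(fold$train, 9)
    expect_length(intersect(fold$train, fold$test), 0)
    expect_setequal(c(fold$train, fold$test), ids)
  }
  # 94 subjects at 10% -> 9 test subjects (round half up of 9.4)
  plan94 <- make_split_plan(paste0("P", 1:94), n_folds = 5, seed = 1)
  expect_true(all(vapply(plan94$folds, function(f) length(f$test),
                         integer(1)) == 9L))
  # round half up: 15 subjects at 10% -> 1.5 -> 2
  plan15 <- make_split_plan(paste0("Q", 1:15), n_folds = 3, seed = 1)
  expect_length(plan15$folds[[1]]$test, 2)

  expect_identical(make_split_plan(ids, 10, 0.2, seed = 99)$folds,
                   make_split_plan(ids, 10, 0.2, seed = 99)$folds)
  expect_error(make_split_plan("S1"), "at least 2")
  expect_error(make_split_plan(ids, test_fraction = 0), "test_fraction")
  expect_error(make_split_plan(c("a", "b"), test_fraction = 0.99),
               "empty training")
})

test_that("classifier defaults carry the fixed hyperparameter set", {
  hp <- xgb_hyperparameters()
  expect_equal(hp$max_depth, 3)
  expect_equal(hp$n_estimators, 700)
  expect_equal(hp$learning_rate, 0.1)
  expect_equal(hp$subsample, 0.6)
  expect_equal(hp$colsample_bytree, 1.0)
  expect_equal(hp$gamma, 5)
  expect_equal(hp$min_child_weight, 1)
  over <- xgb_hyperparameters(n_estimators = 50, gamma = 0)
  expect_equal(over$n_estimators, 50)
  expect_equal(over$gamma, 0)
})

test_that("classifier separates separable data and is deterministic", {
  set.seed(10)
  x <- cbind(f1 = c(rnorm(10, 3), rnorm(10, -3)), f2 = rnorm(20))
  labels <- rep(c("AD", "HC"), each = 10)
  hp <- xgb_hyperparameters(n_estimators = 60, gamma = 0, subsample = 1,
                            random_seed = 1)
  clf <- train_classifier(x, labels, hp)
  pred <- ifelse(predict(clf, x) >= 0.5, "AD", "HC")
  expect_equal(pred, labels) # training accuracy 1.0
  clf2 <- train_classifier(x, labels, hp)
  expect_identical(predict(clf, x), predict(clf2, x))

  imp <- feature_importance(clf)
  expect_named(imp, c("f1", "f2"))
  expect_true(all(imp >= 0))
  expect_gt(imp[["f1"]], imp[["f2"]])

  expect_error(train_classifier(x, rep("AD", 20), hp), "single-class")
})

test_that("permuted labels give chance-level held-out AUC", {
  set.seed(22)
  n <- 50
  x <- matrix(rnorm(n * 5), n, dimnames = list(NULL, paste0("f", 1:5)))
  labels <- sample(rep(c("AD", "HC"), 25)) # labels independent of x
  hp <- xgb_hyperparameters(n_estimators = 40, random_seed = 3)
  aucs <- vapply(1:20, function(i) {
    test <- sample(n, 10)
    while (length(unique(labels[test])) < 2 ||
           length(unique(labels[-test])) < 2) {
      test <- sample(n, 10)
    }
    clf <- train_classifier(x[-test, ], labels[-test], hp)
    roc_auc(predict(clf, x[test, , drop = FALSE]), labels[test])
  }, numeric(1))
  expect_gt(mean(aucs), 0.2)
  expect_lt(mean(aucs), 0.8)
})

test_that("metrics reproduce the confusion-count formulas", {
  m <- compute_metrics(tp = 42, fp = 8, tn = 40, fn = 10)
  expect_equal(m$precision, 0.84)
  expect_equal(round(m$recall, 4), 0.8077)
  expect_equal(round(m$specificity, 4), 0.8333)
  expect_equal(round(m$f1, 4), 0.8235)
  expect_equal(m$accuracy, 0.82)

  # f1 is the harmonic mean identity and invariant to scaling tp/fp/fn
  m2 <- compute_metrics(tp = 84, fp = 16, tn = 7, fn = 20)
  expect_equal(m2$f1, m$f1)
  expect_equal(m2$f1, 2 * m2$precision * m2$recall /
                 (m2$precision + m2$recall))

  # swapping the positive class swaps recall and specificity
  sw <- compute_metrics(tp = 40, fp = 10, tn = 42, fn = 8)
  expect_equal(sw$recall, m$specificity)
  expect_equal(sw$specificity, m$recall)

  # zero denominators are undefined, not 0 or NaN crashes
  z <- compute_metrics(tp = 0, fp = 0, tn = 5, fn = 5)
  expect_true(is.na(z$precision))
  expect_true(is.na(z$f1))
  expect_equal(z$specificity, 1)
})

test_that("rank-based AUC handles separation, ties and degenerate input", {
  expect_equal(roc_auc(c(0.8, 0.9, 0.1, 0.2), c("AD", "AD", "HC", "HC")), 1)
  expect_equal(roc_auc(c(0.5, 0.5, 0.5, 0.5), c("AD", "AD", "HC", "HC")),
               0.5)
  expect_equal(roc_auc(c(0.1, 0.9), c("AD", "HC")), 0)
  expect_true(is.na(roc_auc(c(0.1, 0.9), c("AD", "AD"))))
})

test_that("rank-based AUC matches the all-pairs oracle", {
  set.seed(77)
  for (i in 1:200) {
    n <- sample(4:30, 1)
    labels <- sample(c("AD", "HC"), n, replace = TRUE)
    if (length(unique(labels)) < 2) labels[1:2] <- c("AD", "HC")
    scores <- round(runif(n), sample(c(1, 2, 5), 1)) # rounding forces ties
    expect_equal(roc_auc(scores, labels), oracle_auc(scores, labels))
  }
})

test_that("run_validation aggregates folds and importances correctly", {
  set.seed(9)
  cohort <- generate_cohort(synthetic_cohort_config(
    n_subjects_per_group = 8, visits_per_subject = 2,
    effect_size = reference_effect_size(), seed = 9))
  fm <- build_feature_matrix(cohort$corpus)
  plan <- make_split_plan(unique(fm$subject_id), n_folds = 6,
                          test_fraction = 0.2, seed = 9)
  hp <- xgb_hyperparameters(n_estimators = 60, random_seed = 9)
  report <- suppressMessages(run_validation(fm, plan, hp))

  expect_length(report$folds, 6)
  for (f in report$folds) {
    expect_equal(f$tp + f$fp + f$tn + f$fn, f$n_test)
  }
  # aggregate means equal arithmetic means of the defined fold values
  expect_equal(
    report$aggregate$mean[report$aggregate$metric == "f1"],
    mean(report$fold_metrics[, "f1"], na.rm = TRUE)
  )
  # absent features carry importance 0 before averaging
  expect_equal(
    report$importance$mean_importance,
    unname(colMeans(report$importance_by_fold))
  )
  expect_equal(report$nonzero_importance_count,
               sum(colSums(report$importance_by_fold > 0) > 0))

  # determinism: same inputs, same plan, same report
  report2 <- suppressMessages(run_validation(fm, plan, hp))
  expect_equal(report$fold_metrics, report2$fold_metrics)
  expect_equal(report$importance, report2$importance)

  # serialization writes valid JSON plus the importance table
  json_path <- withr::local_tempfile(fileext = ".json")
  imp_path <- withr::local_tempfile(fileext = ".tsv")
  write_validation_report(report, json_path, imp_path)
  payload <- jsonlite::read_json(json_path)
  expect_equal(length(payload$folds), 6)
  expect_equal(payload$hyperparameters$n_estimators, 60)
  imp <- utils::read.table(imp_path, sep = "\t", header = TRUE)
  expect_equal(nrow(imp), 906)
})

test_that("run_validation refuses leaky or mismatched plans", {
  set.seed(13)
  cohort <- generate_cohort(synthetic_cohort_config(
    n_subjects_per_group = 3, visits_per_subject = 1, seed = 13))
  fm <- build_feature_matrix(cohort$corpus)
  plan <- make_split_plan(unique(fm$subject_id), n_folds = 2,
                          test_fraction = 0.2, seed = 13)
  leaky <- plan
  leaky$folds[[1]]$train <- unique(fm$subject_id) # test subject also in train
  expect_error(suppressMessages(run_validation(fm, leaky)), "leakage")

  foreign <- make_split_plan(c("Z1", "Z2", "Z3"), n_folds = 2,
                             test_fraction = 0.4, seed = 1)
  expect_error(run_validation(fm, foreign), "absent")
})

test_that("top_k_features sorts, breaks ties deterministically and truncates", {
  report <- list(importance = data.frame(
    feature = c("a", "b", "c", "d"),
    mean_importance = c(3, 5, 1, 0),
    sd_importance = 0
  ))
  expect_equal(top_k_features(report, 2)$feature, c("b", "a"))
  tie <- list(importance = data.frame(
    feature = c("b", "a"), mean_importance = c(2, 2), sd_importance = 0))
  expect_equal(top_k_features(tie, 1)$feature, "a")
  expect_equal(nrow(top_k_features(report, 0)), 0)
  expect_message(all3 <- top_k_features(report, 10), "3 features")
  expect_equal(nrow(all3), 3)
})
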