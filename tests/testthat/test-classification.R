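test_that("splits are disjoint, exhaustive, seeded and near the 5:1 ratio", {
  feats <- noise_features(n = 600)
  parts <- split_dataset(feats, split_spec(seed = 3))
  expect_equal(nrow(parts$train) + nrow(parts$test), 600)
  expect_length(intersect(parts$train$tile_id, parts$test$tile_id), 0)
  expect_true(abs(nrow(parts$test) - 100) <= 2)
  again <- split_dataset(feats, split_spec(seed = 3))
  expect_identical(parts$test$tile_id, again$test$tile_id)
})

test_that("group-aware splits never let a group span both sides", {
  feats <- noise_features(n = 96)
  parts <- split_dataset(feats, split_spec(seed = 5, group_aware = TRUE))
  expect_length(intersect(unique(parts$train$group_id),
                          unique(parts$test$group_id)), 0)
  expect_equal(nrow(parts$train) + nrow(parts$test), 96)
})

test_that("a split leaving one class empty is rejected", {
  feats <- noise_features(n = 48)
  feats$label <- as.integer(feats$group_id == "g00")  # one positive group
  expect_error(split_dataset(feats, split_spec(seed = 2, group_aware = TRUE)),
               "absent")
})

test_that("the linear SVM separates well-separated clusters perfectly", {
  feats <- separable_features()
  parts <- split_dataset(feats, split_spec(seed = 1))
  ev <- evaluate(train_linear_svm(parts$train), parts$test)
  expect_equal(ev$accuracy, 100)
  single <- dplyr::filter(parts$train, .data$label == 0)
  expect_error(train_linear_svm(single), "both classes")
})

test_that("classifiers stay at chance on signal-free features", {
  feats <- noise_features(n = 240, seed = 31)
  parts <- split_dataset(feats, split_spec(seed = 7))
  for (model in list(train_linear_svm(parts$train),
                     train_mlp(parts$train, hidden = 16, epochs = 30, seed = 3))) {
    ev <- evaluate(model, parts$test)
    k <- round(ev$accuracy / 100 * ev$n_test)
    p <- stats::binom.test(k, ev$n_test, 0.5)$p.value
    expect_gt(p, 0.01)
  }
})

test_that("the MLP fits separable data and is seed-deterministic", {
  feats <- separable_features(n = 80)
  parts <- split_dataset(feats, split_spec(seed = 2))
  m1 <- train_mlp(parts$train, hidden = 32, dropout_rate = 0, epochs = 60,
                  seed = 11)
  train_pred <- predict(m1, parts$train)
  expect_equal(mean(train_pred == parts$train$label), 1)
  m2 <- train_mlp(parts$train, hidden = 32, dropout_rate = 0, epochs = 60,
                  seed = 11)
  expect_identical(m1$W1, m2$W1)
  expect_identical(m1$W2, m2$W2)
  expect_equal(evaluate(m1, parts$test)$accuracy,
               evaluate(m2, parts$test)$accuracy)
})

test_that("evaluation reports hand-countable accuracy and chance rate", {
  feats <- separable_features(n = 60, gap = 1.5, seed = 21)
  parts <- split_dataset(feats, split_spec(seed = 4))
  model <- train_linear_svm(parts$train)
  ev <- evaluate(model, parts$test)
  pred <- predict(model, parts$test)
  confusion <- table(factor(pred, 0:1), factor(parts$test$label, 0:1))
  expect_equal(ev$accuracy, 100 * sum(diag(confusion)) / sum(confusion))
  expect_equal(ev$chance_rate,
               100 * max(table(parts$test$label)) / nrow(parts$test))
  # permutation invariance in sample order
  perm <- withr::with_seed(5, sample(nrow(parts$test)))
  expect_equal(evaluate(model, parts$test[perm, ])$accuracy, ev$accuracy)
  expect_error(evaluate(model, parts$test[0, ]), "empty")
})

test_that("a majority-vote dummy model scores exactly the chance rate", {
  registerS3method("predict", "majority_model",
                   function(object, newdata, ...) {
                     rep(object$lab, nrow(newdata))
                   },
                   envir = asNamespace("stats"))
  feats <- noise_features(n = 60)
  test <- feats[1:30, ]
  maj <- as.integer(names(which.max(table(test$label))))
  dummy <- structure(list(lab = maj, n_train = 30, classifier = "dummy",
                          config = list()), class = "majority_model")
  ev <- evaluate(dummy, test)
  expect_equal(ev$accuracy, ev$chance_rate)
})

test_that("error reduction reproduces its closed form and sign convention", {
  expect_equal(error_reduction(85.48, 93.32), 53.9944, tolerance = 1e-4)
  expect_equal(round(error_reduction(85.48, 93.32)), 54)
  expect_equal(error_reduction(70, 70), 0)
  expect_equal(error_reduction(50, 100), 100)
  expect_error(error_reduction(100, 90), "below 100")
  expect_error(error_reduction(50, 120), "0, 100")
  # improving vs worsening flips the sign
  expect_gt(error_reduction(80, 90), 0)
  expect_lt(error_reduction(90, 80), 0)
})

test_that("MLP accuracy is competitive with the SVM on pipeline features", {
  sp <- small_pipeline()
  svm <- benchmark_features(sp$features, "svm", split_spec(seed = 1),
                            repeats = 5)
  mlp <- benchmark_features(sp$features, "mlp", split_spec(seed = 1),
                            repeats = 5, hidden = 32, epochs = 60)
  expect_gte(mean(mlp$accuracy), mean(svm$accuracy) - 2)
})

test_that("tidy and glance methods return well-formed tibbles", {
  sp <- small_pipeline()
  parts <- split_dataset(sp$features, split_spec(seed = 6))
  ev <- evaluate(train_linear_svm(parts$train), parts$test)
  g <- glance(ev)
  expect_s3_class(g, "tbl_df")
  expect_named(g, c("classifier", "accuracy", "chance_rate", "n_train",
                    "n_test"))
  expect_s3_class(tidy(ev), "tbl_df")
  expect_s3_class(glance(sp$fit), "tbl_df")
  expect_s3_class(tidy(sp$fit$log), "tbl_df")
})
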