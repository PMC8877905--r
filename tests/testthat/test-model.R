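# Classifier training, metrics and prediction.

test_that("evaluation metrics match an independent count-based oracle", {
  # frozen confusion counts: TP 40, FP 15, FN 10, TN 35
  label <- c(rep(1, 40), rep(0, 15), rep(1, 10), rep(0, 35))
  predicted <- c(rep(1, 40), rep(1, 15), rep(0, 10), rep(0, 35))
  m <- eval_metrics(label, predicted)
  expect_equal(m$confusion, c(TP = 40L, FP = 15L, FN = 10L, TN = 35L))
  expect_equal(m$accuracy, 0.75)
  expect_equal(m$recall_positive, 0.8)
  expect_equal(m$precision_positive, 8 / 11)
  expect_equal(m$f1, 2 * (8 / 11) * 0.8 / ((8 / 11) + 0.8))

  # metric identities on random confusion tables vs direct counting
  set.seed(42)
  for (i in 1:25) {
    lab <- rbinom(60, 1, 0.5)
    prd <- rbinom(60, 1, 0.5)
    mm <- eval_metrics(lab, prd)
    tp <- sum(lab & prd); fp <- sum(!lab & prd)
    fn <- sum(lab & !prd); tn <- sum(!lab & !prd)
    expect_equal(mm$accuracy, (tp + tn) / 60)
    if (mm$precision_positive + mm$recall_positive > 0) {
      expect_equal(mm$f1, 2 * mm$precision_positive * mm$recall_positive /
                     (mm$precision_positive + mm$recall_positive))
    } else {
      expect_equal(mm$f1, 0)
    }
  }
})

test_that("degenerate all-negative predictor yields zero recall and F1", {
  m <- eval_metrics(rep(c(0, 1), 25), rep(0, 50))
  expect_equal(m$accuracy, 0.5)
  expect_equal(m$recall_positive, 0)
  expect_equal(m$f1, 0)
})

test_that("perfect predictions give all metrics 1", {
  lab <- rep(c(0, 1), 20)
  m <- eval_metrics(lab, lab)
  expect_equal(unlist(m[c("accuracy", "recall_positive",
                          "precision_positive", "f1")]),
               c(accuracy = 1, recall_positive = 1,
                 precision_positive = 1, f1 = 1))
})

test_that("the MLP separates a linearly separable toy problem", {
  set.seed(5)
  n <- 10
  x <- rbind(cbind(rnorm(n, -3), rnorm(n, -3)),
             cbind(rnorm(n, 3), rnorm(n, 3)))
  colnames(x) <- c("u", "v")
  y <- rep(c(0, 1), each = n)
  fit <- mlp_fit(x, y, learning_rate = 0.01, max_epochs = 500,
                 patience = 500, seed = 1)
  expect_equal(as.integer(predict(fit, x) >= 0.5), y)
})

test_that("training is deterministic given data, config and seed", {
  lib <- small_library()
  pr <- prepare_library(lib)
  probe <- pr$split$test[1:20, ]
  for (alg in c("ann", "random_forest", "gradient_boosting")) {
    cfg <- model_config(alg, seed = 3)
    m1 <- train_classifier(pr$split$train, pr$dmat, cfg)
    m2 <- train_classifier(pr$split$train, pr$dmat, cfg)
    expect_equal(predict_pairs(m1, probe, pr$dmat)$probability,
                 predict_pairs(m2, probe, pr$dmat)$probability,
                 info = alg)
  }
})

test_that("predictions respect the decision threshold and schema checks", {
  lib <- small_library()
  pr <- prepare_library(lib)
  m <- train_classifier(pr$split$train, pr$dmat, model_config("ann", seed = 1))
  pred <- predict_pairs(m, pr$split$test, pr$dmat)
  expect_true(all(pred$probability >= 0 & pred$probability <= 1))
  expect_equal(pred$predicted, as.integer(pred$probability >= 0.5))

  strict <- model_config("ann", seed = 1, decision_threshold = 0.9)
  m2 <- train_classifier(pr$split$train, pr$dmat, strict)
  pred2 <- predict_pairs(m2, pr$split$test, pr$dmat)
  expect_true(all(pred2$predicted[pred2$probability < 0.9] == 0L))

  expect_error(predict_pairs(m, pr$split$test,
                             pr$dmat[, -1, drop = FALSE]), "schema")
  expect_error(train_classifier(pr$split$train[pr$split$train$label == 1, ],
                                pr$dmat, model_config("ann")), "single class")
})

test_that("compare_models tabulates all configs on one split, sorted by F1", {
  lib <- small_library()
  pr <- prepare_library(lib)
  configs <- list(model_config("ann", seed = 2),
                  model_config("random_forest", seed = 2),
                  model_config("gradient_boosting", seed = 2))
  tab <- compare_models(lib$pairs, pr$dmat, configs, seed = 2)
  expect_equal(names(tab), c("algorithm", "accuracy", "recall_positive",
                             "precision_positive", "f1"))
  expect_equal(nrow(tab), 3L)
  expect_true(all(diff(tab$f1) <= 0))
  expect_true(all(tab$accuracy > 0.5))  # all beat the majority class
  expect_error(compare_models(lib$pairs, pr$dmat, configs[1]), "at least 2")
})
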