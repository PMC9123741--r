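make_features <- function(n, p, seed = 1L, informative = 2L, flip = 0) {
  # first `informative` features determine the label through their sum
  xtclass:::with_seed(seed, {
    X <- matrix(rnorm(n * p), n, p,
                dimnames = list(sprintf("s%03d", seq_len(n)),
                                sprintf("f%02d", seq_len(p))))
    y <- as.integer(rowSums(X[, seq_len(informative), drop = FALSE]) > 0)
    if (flip > 0) {
      i <- sample(n, flip)
      y[i] <- 1L - y[i]
    }
    list(X = X, y = y)
  })
}

test_that("stratified split keeps class ratios within one sample", {
  d <- make_features(10L, 3L, seed = 2L)
  d$y <- rep(c(0L, 1L), each = 5L)
  sp <- split_dataset(d$X, d$y, split_config(0.7, seed = 4L))
  expect_true(sum(sp$train$y == 1L) %in% c(3L, 4L))
  expect_true(sum(sp$train$y == 0L) %in% c(3L, 4L))
  expect_length(intersect(rownames(sp$train$X), rownames(sp$test$X)), 0L)

  sp2 <- split_dataset(d$X, d$y, split_config(0.7, seed = 4L))
  expect_identical(sp, sp2)

  big <- make_features(396L, 2L, seed = 3L)
  big$y <- c(rep(1L, 25L), rep(0L, 371L))
  sp3 <- split_dataset(big$X, big$y, split_config(0.7, seed = 1L))
  expect_true(sum(sp3$train$y == 1L) %in% c(17L, 18L))

  expect_error(split_dataset(big$X, c(1L, rep(0L, 395L)),
                             split_config(0.7)), "fewer than 2")
})

test_that("metrics match brute-force oracles on the hand example", {
  sc <- c(0.9, 0.8, 0.7, 0.4, 0.3, 0.2)
  lb <- c(1L, 1L, 0L, 1L, 0L, 0L)
  expect_equal(roc_auc(sc, lb), auc_oracle(sc, lb))
  expect_equal(average_precision(sc, lb), ap_oracle(sc, lb))

  m <- metrics_report(sc, lb, threshold = 0.5)
  expect_equal(unname(m$confusion), c(2L, 1L, 2L, 1L))  # TP FP TN FN
  expect_equal(m$precision, 2 / 3)
  expect_equal(m$recall, 2 / 3)
  expect_equal(m$mcc, (2 * 2 - 1 * 1) / sqrt(3 * 3 * 3 * 3))

  # random small inputs incl. ties
  set.seed(23)
  for (rep in 1:20) {
    n <- sample(6:20, 1L)
    scores <- round(runif(n), 2L)
    labels <- rbinom(n, 1L, 0.4)
    if (length(unique(labels)) < 2L) next
    expect_equal(roc_auc(scores, labels), auc_oracle(scores, labels),
                 tolerance = 1e-12)
    expect_equal(average_precision(scores, labels),
                 ap_oracle(scores, labels), tolerance = 1e-12)
  }
})

test_that("metric edge cases are flagged, not fabricated", {
  m <- metrics_report(c(0.9, 0.8, 0.7), c(1L, 1L, 1L), 0.5)
  expect_true(is.na(m$roc_auc))
  m2 <- metrics_report(c(0.1, 0.2, 0.1, 0.3), c(1L, 0L, 0L, 1L), 0.5)
  expect_false(m2$precision_defined)
  expect_equal(m2$precision, 0)
  expect_equal(m2$recall, 0)
  mp <- metrics_report(c(0.99, 0.97, 0.01), c(1L, 0L, 0L), 0.98)
  expect_equal(unname(mp$confusion[["TP"]]), 1L)
  expect_equal(unname(mp$confusion[["FP"]]), 0L)
})

test_that("RFECV handles trivial schedules and recovers informative features", {
  d <- make_features(60L, 1L, seed = 5L, informative = 1L)
  sel1 <- rfecv(d$X, d$y, folds = 3L, seed = 1L)
  expect_equal(sel1$selected, "f01")

  d2 <- make_features(60L, 6L, seed = 6L)
  sel2 <- rfecv(d2$X, d2$y, step = 100L, folds = 3L, seed = 1L)
  expect_equal(length(sel2$sizes), 2L)  # one elimination round only

  # features 1-2 fully determine the label: retained in >= 4/5 seeded runs
  hits <- 0L
  for (s in 1:5) {
    d3 <- make_features(80L, 10L, seed = s)
    sel3 <- rfecv(d3$X, d3$y, step = 2L, folds = 4L, min_features = 2L,
                  seed = s)
    hits <- hits + as.integer(all(c("f01", "f02") %in% sel3$selected))
  }
  expect_gte(hits, 4L)
})

test_that("fitting, evaluation and prediction compose deterministically", {
  d <- make_features(80L, 6L, seed = 9L, flip = 4L)
  sp <- split_dataset(d$X, d$y, split_config(seed = 2L))
  model <- fit_model(sp$train$X, sp$train$y, seed = 3L)
  expect_s3_class(model, "xt_model")
  expect_equal(sum(model$importance$gain_fraction), 1, tolerance = 1e-9)

  model2 <- fit_model(sp$train$X, sp$train$y, seed = 3L)
  expect_identical(predict(model, sp$test$X)$probability,
                   predict(model2, sp$test$X)$probability)

  m <- evaluate_model(model, sp$test$X, sp$test$y)
  expect_s3_class(m, "xt_metrics")
  expect_true(m$roc_auc > 0.6)

  # perfectly separable toy data fits the training set exactly
  toy <- make_features(40L, 2L, seed = 4L, informative = 1L)
  tm <- fit_model(toy$X, toy$y, seed = 1L)
  pr <- predict(tm, toy$X)
  expect_equal(as.integer(pr$probability >= 0.5), toy$y)

  # shuffling candidate rows permutes the output identically
  perm <- sample(nrow(sp$test$X))
  p1 <- predict(model, sp$test$X)
  p2 <- predict(model, sp$test$X[perm, ])
  expect_equal(p2$probability[order(p2$id)], p1$probability[order(p1$id)])

  expect_error(predict(model, sp$test$X[, 1:2]), "lacks feature")
})

test_that("threshold recalibration obeys the >= semantics and monotonicity", {
  d <- make_features(100L, 4L, seed = 12L, flip = 6L)
  sp <- split_dataset(d$X, d$y, split_config(seed = 7L))
  model <- fit_model(sp$train$X, sp$train$y, seed = 1L)

  m98 <- calibrate_threshold(model, sp$test$X, sp$test$y, value = 0.98)
  expect_equal(m98$threshold, 0.98)
  expect_named(m98$comparison, c("model1", "model2"))
  # probability exactly at the threshold is classified positive
  fake <- model
  fake$threshold <- 0.98
  probs <- c(a = 0.99, b = 0.979, c = 0.98)
  cls <- as.integer(probs >= fake$threshold)
  expect_equal(cls, c(1L, 0L, 1L))

  # raising the threshold never increases the predicted-positive count
  prob <- model$learner$predict_prob(model$model,
                                     sp$test$X[, model$features, drop = FALSE])
  counts <- vapply(sort(unique(prob)), function(t) sum(prob >= t), integer(1))
  expect_true(all(diff(counts) <= 0))

  pf <- calibrate_threshold(model, sp$test$X, sp$test$y,
                            mode = "precision_floor", value = 0.8)
  mrep <- metrics_report(prob, sp$test$y, pf$threshold)
  expect_gte(mrep$precision, 0.8)
  expect_error(calibrate_threshold(model, sp$test$X, sp$test$y,
                                   mode = "precision_floor", value = 1.0001),
               "unattainable|value")
})

test_that("near-miss flags mark probabilities just under the threshold", {
  d <- make_features(60L, 3L, seed = 15L)
  model <- fit_model(d$X, d$y, seed = 1L)
  model$threshold <- 0.98
  pr <- predict(model, d$X)
  in_band <- pr$probability >= 0.93 & pr$probability < 0.98
  expect_equal(pr$near_miss, in_band)
  expect_equal(pr$class, as.integer(pr$probability >= 0.98))
})

test_that("model serialisation round-trips predictions bitwise", {
  d <- make_features(60L, 5L, seed = 20L, flip = 3L)
  model <- fit_model(d$X, d$y, seed = 2L)
  model$threshold <- 0.98
  f <- tempfile(fileext = ".json")
  write_model(model, f)
  back <- read_model(f)
  expect_identical(predict(back, d$X)$probability,
                   predict(model, d$X)$probability)
  expect_equal(back$threshold, 0.98)
  expect_equal(back$metadata$seed, model$metadata$seed)

  # a file with the threshold removed is rejected
  obj <- jsonlite::read_json(f)
  obj$threshold <- NULL
  jsonlite::write_json(obj, f, auto_unbox = TRUE)
  expect_error(read_model(f), "threshold")
  file.remove(f)
})
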