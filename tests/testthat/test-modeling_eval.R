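test_that("stratified folds preserve class proportions exactly when divisible", {
  y <- c(rep(1, 60), rep(0, 40))
  folds <- stratified_folds(y, k = 10, seed = 3)
  expect_length(folds, 10)
  for (f in folds) {
    expect_equal(sum(y[f$test] == 1), 6)
    expect_equal(sum(y[f$test] == 0), 4)
    expect_setequal(c(f$train, f$test), seq_along(y))
  }
  tests <- unlist(lapply(folds, `[[`, "test"))
  expect_equal(sort(tests), seq_along(y))     # partition, pairwise disjoint
})

test_that("stratified folds handle non-divisible sizes within one sample", {
  set.seed(8)
  y <- sample(c(rep("positive", 51), rep("negative", 50)))
  folds <- stratified_folds(y, k = 10, seed = 5)
  sizes <- vapply(folds, function(f) length(f$test), numeric(1))
  expect_setequal(unique(sizes), c(11, 10))
  expect_equal(sum(sizes), 101)
  expect_equal(sort(unlist(lapply(folds, `[[`, "test"))), 1:101)
  for (f in folds) {
    expect_lte(abs(sum(y[f$test] == "positive") - 5.1), 1)
  }
  expect_error(stratified_folds(rep(1, 10), k = 10), "fewer|class")
  # determinism
  expect_identical(stratified_folds(y, k = 10, seed = 5), folds)
})

test_that("confusion-count metrics follow the standard definitions", {
  m <- classification_metrics(tp = 3, fp = 1, fn = 1, tn = 5)
  expect_equal(unname(m["precision"]), 0.75)
  expect_equal(unname(m["recall"]), 0.75)
  expect_equal(unname(m["f1"]), 0.75)
  expect_equal(unname(m["accuracy"]), 0.8)
  z <- classification_metrics(0, 0, 5, 5)
  expect_equal(unname(z["precision"]), 0)
  expect_equal(unname(z["f1"]), 0)
})

test_that("ROC/AUC: perfect ranking gives 1, random scores give ~0.5, pROC agrees", {
  y <- c(rep(0, 5), rep(1, 5))
  r <- roc_curve(c(1:5 / 10, 6:10 / 10), y)
  expect_equal(r$auc, 1)

  set.seed(19)
  y2 <- rep(c(0, 1), 1000)
  s2 <- runif(2000)
  expect_lt(abs(roc_curve(s2, y2)$auc - 0.5), 0.05)

  skip_if_not_installed("pROC")
  for (rep in 1:5) {
    yy <- rbinom(60, 1, 0.5)
    if (length(unique(yy)) < 2) next
    ss <- rnorm(60) + yy
    ref <- suppressMessages(pROC::auc(pROC::roc(yy, ss, direction = "<",
                                                quiet = TRUE)))
    expect_equal(roc_curve(ss, yy)$auc, as.numeric(ref), tolerance = 1e-12)
  }
})

test_that("the ELM fits separable Gaussian blobs nearly perfectly", {
  set.seed(31)
  n <- 100
  x <- rbind(matrix(rnorm(n * 5, 0), n),
             matrix(rnorm(n * 5, 6), n))
  colnames(x) <- paste0("f", 1:5)
  y <- rep(c(0, 1), each = n)
  scl <- lncdisc:::fit_scaler(x)
  xs <- lncdisc:::apply_scaler(x, scl)
  elm <- train_elm(xs, y, n_hidden = 22, seed = 12)
  pred <- predict(elm, xs, type = "class")
  m <- classification_metrics(sum(pred == 1 & y == 1),
                              sum(pred == 1 & y == 0),
                              sum(pred == 0 & y == 1),
                              sum(pred == 0 & y == 0))
  expect_gte(unname(m["f1"]), 0.99)
  expect_length(coef(elm), 22)

  expect_error(train_elm(xs, rep(1, 2 * n)), "one class")
  expect_error(train_elm(xs, y, n_hidden = 0), "positive integer")
  expect_error(train_elm(matrix(1, 10, 3), rep(c(0, 1), 5)), "degenerate")
  # deterministic given seed
  expect_identical(train_elm(xs, y, seed = 5)$beta,
                   train_elm(xs, y, seed = 5)$beta)
})

test_that("model specs carry the tuned defaults and fit/predict round-trips", {
  sv <- model_spec("svm")
  expect_equal(sv$hyperparameters, list(C = 0.1, gamma = 0.001,
                                        kernel = "linear"))
  rf <- model_spec("rf")
  expect_equal(rf$hyperparameters$n_estimators, 130)
  expect_equal(rf$hyperparameters$max_depth, 9)
  el <- model_spec("elm")
  expect_equal(el$hyperparameters$n_hidden, 22)
  expect_equal(el$hyperparameters$activation, "sigmoid")
  expect_error(model_spec("svm", bogus = 2), "unknown")

  set.seed(47)
  x <- rbind(matrix(rnorm(200, 0), 40), matrix(rnorm(200, 3), 40))
  colnames(x) <- paste0("f", 1:5)
  y <- rep(c(0, 1), each = 40)
  for (kind in c("svm", "rf", "elm")) {
    model <- fit_model(model_spec(kind, seed = 2), x, y)
    pred <- predict(model, x)
    expect_gte(mean(pred$class == y), 0.95)
    expect_length(pred$score, nrow(x))
  }
})

test_that("grid search returns the exhaustively-best point, first on ties", {
  set.seed(53)
  x <- rbind(matrix(rnorm(150, 0), 30), matrix(rnorm(150, 2), 30))
  colnames(x) <- paste0("f", 1:5)
  y <- rep(c(0, 1), each = 30)
  folds <- stratified_folds(y, k = 5, seed = 1)

  single <- list(model_spec("svm", C = 1))
  gs1 <- grid_search(single, x, y, folds)
  expect_identical(gs1$best, single[[1]])

  dup <- list(model_spec("svm", C = 1), model_spec("svm", C = 1))
  gs2 <- grid_search(dup, x, y, folds)
  expect_identical(gs2$best, dup[[1]])
  expect_equal(gs2$scores[1], gs2$scores[2])

  grid <- list(model_spec("svm", C = 0.01), model_spec("svm", C = 0.1),
               model_spec("svm", C = 1))
  gs <- grid_search(grid, x, y, folds)
  brute <- vapply(grid, function(sp)
    evaluate_cv(sp, x, y, folds = folds)$aggregate["mean", "f1"],
    numeric(1))
  expect_equal(gs$scores, brute)
  expect_identical(gs$best, grid[[which.max(brute)]])
  expect_error(grid_search(list(), x, y, folds), "empty")
})

test_that("cross-validation scales on the training split only", {
  set.seed(59)
  x <- matrix(rnorm(600, mean = 5, sd = 2), 120, 5,
              dimnames = list(NULL, paste0("f", 1:5)))
  y <- rep(c(0, 1), each = 60)
  x[y == 1, 1] <- x[y == 1, 1] + 3
  folds <- stratified_folds(y, k = 5, seed = 2)
  # fit on train only: the scaler derived from the training rows leaves the
  # test rows with nonzero mean / non-unit sd in general
  scl <- lncdisc:::fit_scaler(x[folds[[1]]$train, ])
  xt <- lncdisc:::apply_scaler(x[folds[[1]]$test, ], scl)
  expect_gt(max(abs(colMeans(xt))), 1e-3)
  expect_gt(max(abs(apply(xt, 2, sd) - 1)), 1e-3)
  # and the full path runs with scaling enabled
  rep <- evaluate_cv(model_spec("svm"), x, y, folds = folds)
  expect_equal(nrow(rep$per_fold), 5)
  expect_true(all(rep$per_fold$f1 >= 0 & rep$per_fold$f1 <= 1))
})

test_that("per-fold feature selection never sees test rows", {
  set.seed(61)
  x <- cbind(sig = rep(c(0, 1), each = 50) + rnorm(100, 0, 0.4),
             matrix(rnorm(100 * 6), 100,
                    dimnames = list(NULL, paste0("n", 1:6))))
  y <- rep(c(0, 1), each = 50)
  folds <- stratified_folds(y, k = 5, seed = 9)
  rep <- evaluate_cv(model_spec("rf"), x, y, folds = folds,
                     selection = "per_fold")
  for (f in seq_along(folds)) {
    expect_equal(rep$selections[[f]]$n_obs, length(folds[[f]]$train))
  }
  expect_true(all(rep$per_fold$n_selected <= ncol(x)))

  # paper-mode: one selection on all rows, shared by every fold
  rep2 <- evaluate_cv(model_spec("rf"), x, y, folds = folds,
                      selection = "once")
  expect_equal(unique(vapply(rep2$selections, `[[`, numeric(1), "n_obs")),
               nrow(x))
})

test_that("fold metrics are invariant to permuting sample order", {
  set.seed(73)
  x <- rbind(matrix(rnorm(200, 0), 40), matrix(rnorm(200, 1.5), 40))
  colnames(x) <- paste0("f", 1:5)
  y <- rep(c(0, 1), each = 40)
  folds <- stratified_folds(y, k = 4, seed = 1)
  base <- evaluate_cv(model_spec("svm"), x, y, folds = folds)
  perm_folds <- lapply(folds, function(f)
    list(train = sample(f$train), test = sample(f$test)))
  perm <- evaluate_cv(model_spec("svm"), x, y, folds = perm_folds)
  expect_equal(base$per_fold$f1, perm$per_fold$f1, tolerance = 1e-9)
})

test_that("single-class test folds record missing AUC with a warning", {
  y <- rep(c(0, 1), each = 20)
  x <- matrix(rnorm(160), 40, 4, dimnames = list(NULL, paste0("f", 1:4)))
  x[, 1] <- x[, 1] + y
  folds <- list(list(train = 1:30, test = 31:40))  # test all positive
  expect_warning(rep <- evaluate_cv(model_spec("svm"), x, y, folds = folds),
                 "single-class")
  expect_true(is.na(rep$per_fold$auc[1]))
})
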