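#' Model specification
#'
#' Captures a classifier kind with its hyperparameters. Defaults are the
#' grid-search optima reported for this task: SVM with a linear kernel,
#' `C = 0.1`, `gamma = 0.001`; random forest with 130 trees, depth cap 9,
#' entropy-style impurity (the backend splits on Gini; the name is recorded
#' for provenance); ELM with 22 sigmoid hidden units. Features are z-scored
#' for SVM and ELM and left raw for the forest unless `scale` is forced.
#'
#' @param kind `"svm"`, `"rf"`, or `"elm"`.
#' @param ... hyperparameter overrides: for svm `C`, `gamma`, `kernel`; for
#'   rf `n_estimators`, `max_depth`, `criterion`; for elm `n_hidden`,
#'   `activation`.
#' @param scale logical or `NULL` (default: TRUE for svm/elm, FALSE for rf).
#' @param seed RNG seed for the stochastic parts (forest, ELM weights).
#' @return list of class `model_spec`.
#' @export
model_spec <- function(kind = c("svm", "rf", "elm"), ..., scale = NULL,
                       seed = 1) {
  kind <- match.arg(kind)
  defaults <- switch(kind,
    svm = list(C = 0.1, gamma = 0.001, kernel = "linear"),
    rf  = list(n_estimators = 130, max_depth = 9, criterion = "entropy"),
    elm = list(n_hidden = 22, activation = "sigmoid"))
  hp <- modifyList(defaults, list(...))
  extra <- setdiff(names(hp), names(defaults))
  if (length(extra)) stopf("unknown %s hyperparameter(s): %s", kind,
                           paste(extra, collapse = ", "))
  if (is.null(scale)) scale <- kind %in% c("svm", "elm")
  structure(list(kind = kind, hyperparameters = hp, scale = scale,
                 seed = seed), class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  hp <- paste(sprintf("%s=%s", names(x$hyperparameters),
                      vapply(x$hyperparameters, format, "")), collapse = ", ")
  cat(sprintf("<model_spec %s> %s%s, seed %d\n", x$kind, hp,
              if (x$scale) ", z-scored inputs" else "", x$seed))
  invisible(x)
}

# z-score parameters fit on training data only; constant columns get sd 1
fit_scaler <- function(x) {
  mu <- colMeans(x)
  s <- apply(x, 2, sd)
  s[!is.finite(s) | s < 1e-12] <- 1
  list(center = mu, scale = s)
}

apply_scaler <- function(x, scaler) {
  scale(x, center = scaler$center, scale = scaler$scale)[, , drop = FALSE]
}

#' Fit a classifier from a model specification
#'
#' @param spec a [model_spec()].
#' @param x numeric feature matrix (training rows).
#' @param y labels: factor with levels `negative`/`positive`, or 0/1 where
#'   1 is the positive (disease-related) class.
#' @return list of class `lnc_model` with a [predict.lnc_model()] method.
#' @export
fit_model <- function(spec, x, y) {
  stopifnot(inherits(spec, "model_spec"))
  x <- as.matrix(x)
  y01 <- as_binary_labels(y)
  if (length(unique(y01)) < 2) stopf("training labels contain one class")
  scaler <- NULL
  if (spec$scale) {
    scaler <- fit_scaler(x)
    x <- apply_scaler(x, scaler)
  }
  hp <- spec$hyperparameters
  fit <- switch(spec$kind,
    svm = {
      set.seed(spec$seed)
      e1071::svm(x = x, y = factor(y01, levels = c(0, 1)),
                 kernel = hp$kernel, cost = hp$C, gamma = hp$gamma,
                 scale = FALSE, probability = FALSE)
    },
    rf = {
      set.seed(spec$seed)
      randomForest::randomForest(
        x = x, y = factor(y01, levels = c(0, 1)),
        ntree = hp$n_estimators,
        maxnodes = min(2^hp$max_depth, nrow(x)))
    },
    elm = train_elm(x, y01, n_hidden = hp$n_hidden,
                    activation = hp$activation, seed = spec$seed))
  structure(list(spec = spec, fit = fit, scaler = scaler,
                 features = colnames(x)), class = "lnc_model")
}

#' Predict from a fitted classifier
#'
#' @param object an `lnc_model`.
#' @param newdata numeric matrix with the training columns.
#' @param ... unused.
#' @return list with `score` (continuous, larger = more disease-like) and
#'   `class` (0/1 integer vector).
#' @export
predict.lnc_model <- function(object, newdata, ...) {
  x <- as.matrix(newdata)[, object$features, drop = FALSE]
  if (!is.null(object$scaler)) x <- apply_scaler(x, object$scaler)
  score <- switch(object$spec$kind,
    svm = {
      dv <- attr(predict(object$fit, x, decision.values = TRUE),
                 "decision.values")
      # orient so larger = positive class regardless of e1071's level order
      if (grepl("^0/1", colnames(dv)[1])) -dv[, 1] else dv[, 1]
    },
    rf = predict(object$fit, x, type = "prob")[, "1"],
    elm = as.numeric(predict(object$fit, x, type = "score")))
  cls <- switch(object$spec$kind,
    svm = as.integer(score > 0),
    rf = as.integer(score >= 0.5),
    elm = as.integer(score >= 0.5))
  list(score = unname(score), class = cls)
}

#' @export
print.lnc_model <- function(x, ...) {
  cat(sprintf("<lnc_model> %s on %d feature(s)\n", x$spec$kind,
              length(x$features)))
  invisible(x)
}

as_binary_labels <- function(y) {
  if (is.factor(y) || is.character(y)) {
    v <- as.character(y)
    if (all(v %in% c("positive", "negative")))
      return(as.integer(v == "positive"))
    if (all(v %in% c("0", "1"))) return(as.integer(v == "1"))
    stopf("labels must be positive/negative or 0/1")
  }
  if (all(y %in% c(0, 1))) return(as.integer(y))
  stopf("labels must be positive/negative or 0/1")
}

#' Train an extreme learning machine
#'
#' Single-hidden-layer network with fixed random input weights: `W` and
#' biases `b` are drawn uniformly from `[-1, 1]` under `seed`, hidden
#' activations are `H = act(XW + b)`, and only the output weights are fit,
#' by the ridge-regularized least-squares solve
#' `beta = (H'H + 1e-6 I)^{-1} H' y`. Classification threshold is 0.5 on
#' the continuous output.
#'
#' @param x numeric matrix (callers should z-score; [fit_model()] does).
#' @param y binary labels (0/1 or positive/negative).
#' @param n_hidden hidden-layer width (default 22).
#' @param activation `"sigmoid"` (default), `"tanh"`, or `"relu"`.
#' @param seed RNG seed for the input weights.
#' @return list of class `elm` with `predict` and `coef` methods.
#' @export
train_elm <- function(x, y, n_hidden = 22, activation = "sigmoid", seed = 1) {
  if (!is_count(n_hidden) || n_hidden < 1)
    stopf("n_hidden must be a positive integer")
  x <- as.matrix(x)
  y01 <- as_binary_labels(y)
  if (length(unique(y01)) < 2) stopf("training labels contain one class")
  if (all(apply(x, 2, function(col) max(col) - min(col)) < 1e-12))
    stopf("degenerate feature matrix: every column is constant")
  act <- switch(match.arg(activation, c("sigmoid", "tanh", "relu")),
                sigmoid = function(z) 1 / (1 + exp(-z)),
                tanh = tanh,
                relu = function(z) pmax(z, 0))
  set.seed(seed)
  W <- matrix(runif(ncol(x) * n_hidden, -1, 1), ncol = n_hidden)
  b <- runif(n_hidden, -1, 1)
  H <- act(sweep(x %*% W, 2, b, `+`))
  ridge <- 1e-6
  beta <- solve(crossprod(H) + diag(ridge, n_hidden), crossprod(H, y01))
  structure(list(W = W, b = b, beta = beta, activation = act,
                 activation_name = activation, n_hidden = n_hidden,
                 seed = seed, features = colnames(x)),
            class = "elm")
}

#' Predict from an extreme learning machine
#'
#' @param object an `elm`.
#' @param newdata numeric matrix.
#' @param type `"score"` for the continuous output, `"class"` for 0/1 at
#'   threshold 0.5.
#' @param ... unused.
#' @export
predict.elm <- function(object, newdata, type = c("score", "class"), ...) {
  type <- match.arg(type)
  x <- as.matrix(newdata)
  H <- object$activation(sweep(x %*% object$W, 2, object$b, `+`))
  s <- as.numeric(H %*% object$beta)
  if (type == "score") s else as.integer(s >= 0.5)
}

#' @export
print.elm <- function(x, ...) {
  cat(sprintf("<elm> %d input(s) -> %d %s hidden unit(s) -> 1 output\n",
              nrow(x$W), x$n_hidden, x$activation_name))
  invisible(x)
}

#' @export
coef.elm <- function(object, ...) as.numeric(object$beta)
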