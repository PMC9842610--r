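#' Stratified k-fold assignment
#'
#' Partitions sample indices into `k` folds preserving class proportions:
#' within each class, shuffled members are dealt round-robin to folds, so
#' per-fold class counts differ by at most 1 from exact proportionality.
#' Deterministic given `seed`.
#'
#' @param labels class labels (any type with >= k members per class).
#' @param k number of folds (default 10).
#' @param seed shuffle seed.
#' @return list of `k` elements, each `list(train = idx, test = idx)`;
#'   the test sets partition `seq_along(labels)`.
#' @export
stratified_folds <- function(labels, k = 10, seed = 1) {
  stopifnot(is_count(k), k >= 2)
  labels <- as.character(labels)
  tab <- table(labels)
  if (length(tab) < 2)
    stopf("stratification needs >= 2 classes; got only '%s'", names(tab))
  if (any(tab < k))
    stopf("class '%s' has %d member(s), fewer than k = %d",
          names(tab)[which.min(tab)], min(tab), k)
  set.seed(seed)
  fold_of <- integer(length(labels))
  for (cl in names(tab)) {
    idx <- sample(which(labels == cl))
    fold_of[idx] <- rep_len(seq_len(k), length(idx))
  }
  lapply(seq_len(k), function(f)
    list(train = which(fold_of != f), test = which(fold_of == f)))
}

#' Binary classification metrics from a confusion count
#'
#' @param tp,fp,fn,tn confusion-matrix counts (positive class = disease).
#' @return named vector: `accuracy`, `precision` = TP/(TP+FP), `recall` =
#'   TP/(TP+FN), `f1` (harmonic mean). Undefined ratios (zero denominator)
#'   are reported as 0.
#' @examples
#' classification_metrics(tp = 3, fp = 1, fn = 1, tn = 5)
#' @export
classification_metrics <- function(tp, fp, fn, tn) {
  prec <- if (tp + fp > 0) tp / (tp + fp) else 0
  rec <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
  c(accuracy = (tp + tn) / (tp + fp + fn + tn),
    precision = prec, recall = rec, f1 = f1)
}

#' ROC curve by score-threshold sweep, with trapezoidal AUC
#'
#' @param scores continuous classifier scores, larger = more positive.
#' @param labels binary labels (0/1 or negative/positive).
#' @return list of class `roc_curve`: `fpr`, `tpr` (threshold sweep from
#'   strictest to most permissive), `auc`. `auc` is `NA` when only one
#'   class is present.
#' @export
roc_curve <- function(scores, labels) {
  y <- as_binary_labels(labels)
  P <- sum(y == 1); N <- sum(y == 0)
  if (P == 0 || N == 0)
    return(structure(list(fpr = NA_real_, tpr = NA_real_, auc = NA_real_),
                     class = "roc_curve"))
  o <- order(scores, decreasing = TRUE)
  ys <- y[o]; ss <- scores[o]
  tp <- cumsum(ys == 1); fp <- cumsum(ys == 0)
  # collapse tied scores to one operating point
  last_of_tie <- c(ss[-1] != ss[-length(ss)], TRUE)
  tpr <- c(0, tp[last_of_tie] / P)
  fpr <- c(0, fp[last_of_tie] / N)
  auc <- sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
  structure(list(fpr = fpr, tpr = tpr, auc = auc), class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("<roc_curve> %d point(s), AUC = %.3f\n", length(x$fpr), x$auc))
  invisible(x)
}

#' Cross-validated evaluation of a classifier
#'
#' Runs the full per-fold protocol: (optional) feature selection and
#' z-scoring are fit on the training split only and applied to the test
#' split, the model is fit on the training rows, and held-out confusion
#' counts, ROC curve and AUC are recorded per fold. Folds whose test split
#' contains one class get `auc = NA` with a warning.
#'
#' Feature selection placement follows the leakage-free default: with
#' `selection = "per_fold"` a fresh importance selection is fit inside each
#' training fold. `selection = "once"` replicates the common — but leaky —
#' shortcut of selecting once on the complete data before cross-validation
#' (kept available for comparison, i.e. "paper mode"); `"none"` uses all
#' columns.
#'
#' @param spec a [model_spec()].
#' @param x numeric feature matrix or `feature_matrix`.
#' @param y labels (omit when `x` is a labelled `feature_matrix`).
#' @param folds fold list from [stratified_folds()], or `NULL` to build
#'   `k` folds from `seed`.
#' @param k folds when `folds` is `NULL` (default 10).
#' @param selection `"none"`, `"per_fold"`, or `"once"`.
#' @param selection_args list of arguments for [select_features()].
#' @param seed master seed: folds, per-fold selections and model fits are
#'   derived from it.
#' @return A `cv_report`: `per_fold` data frame (accuracy, precision,
#'   recall, f1, auc, n_test, n_selected), `roc` (list of per-fold
#'   `roc_curve`s), `aggregate` (mean/min/max per metric), `selections`
#'   (per-fold `selection_result`s, recording the rows each selection was
#'   fit on), `folds`, `spec`, `selection`, `seed`.
#' @export
evaluate_cv <- function(spec, x, y = NULL, folds = NULL, k = 10,
                        selection = c("none", "per_fold", "once"),
                        selection_args = list(), seed = 1) {
  selection <- match.arg(selection)
  if (inherits(x, "feature_matrix")) {
    if (is.null(y)) y <- x$labels
    x <- x$x
  }
  x <- as.matrix(x)
  y01 <- as_binary_labels(y)
  if (is.null(folds)) folds <- stratified_folds(y01, k = k, seed = seed)

  sel_once <- NULL
  if (selection == "once") {
    sel_once <- do.call(select_features,
                        c(list(x, labels = y01,
                               seed = derive_seed(seed, 777L)),
                          selection_args))
  }

  metrics <- vector("list", length(folds))
  rocs <- vector("list", length(folds))
  sels <- vector("list", length(folds))
  for (f in seq_along(folds)) {
    tr <- folds[[f]]$train; te <- folds[[f]]$test
    sel <- switch(selection,
      none = NULL,
      once = sel_once,
      per_fold = do.call(select_features,
                         c(list(x[tr, , drop = FALSE], labels = y01[tr],
                                seed = derive_seed(seed, f)),
                           selection_args)))
    xtr <- x[tr, , drop = FALSE]; xte <- x[te, , drop = FALSE]
    if (!is.null(sel) && length(sel$kept) > 0) {
      xtr <- xtr[, sel$kept, drop = FALSE]
      xte <- xte[, sel$kept, drop = FALSE]
    }
    fold_spec <- spec
    fold_spec$seed <- derive_seed(spec$seed, f)
    model <- fit_model(fold_spec, xtr, y01[tr])
    pred <- predict(model, xte)
    tp <- sum(pred$class == 1 & y01[te] == 1)
    fp <- sum(pred$class == 1 & y01[te] == 0)
    fn <- sum(pred$class == 0 & y01[te] == 1)
    tn <- sum(pred$class == 0 & y01[te] == 0)
    m <- classification_metrics(tp, fp, fn, tn)
    roc <- roc_curve(pred$score, y01[te])
    if (is.na(roc$auc))
      warnf("fold %d: single-class test split; AUC undefined", f)
    metrics[[f]] <- data.frame(fold = f, t(m), auc = roc$auc,
                               n_test = length(te),
                               n_selected = if (is.null(sel)) ncol(x)
                                            else length(sel$kept))
    rocs[[f]] <- roc
    sels[[f]] <- sel
  }
  per_fold <- do.call(rbind, metrics)
  agg <- sapply(c("accuracy", "precision", "recall", "f1", "auc"),
                function(m) {
                  v <- per_fold[[m]]
                  c(mean = mean(v, na.rm = TRUE),
                    min = suppressWarnings(min(v, na.rm = TRUE)),
                    max = suppressWarnings(max(v, na.rm = TRUE)))
                })
  structure(list(per_fold = per_fold, roc = rocs, aggregate = agg,
                 selections = sels, folds = folds,
                 spec = spec, selection = selection, seed = seed),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  a <- x$aggregate
  cat(sprintf("<cv_report> %s, %d folds%s\n", x$spec$kind,
              nrow(x$per_fold),
              if (x$selection != "none")
                sprintf(", selection = %s", x$selection) else ""))
  for (m in colnames(a))
    cat(sprintf("  %-9s mean %.3f  (min %.3f, max %.3f)\n",
                m, a["mean", m], a["min", m], a["max", m]))
  invisible(x)
}

#' @export
summary.cv_report <- function(object, ...) {
  print(object)
  invisible(object$aggregate)
}

#' Plot per-fold ROC curves of a cross-validation report
#'
#' @param x a `cv_report`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.cv_report <- function(x, ...) {
  graphics::plot(c(0, 1), c(0, 1), type = "l", lty = 3, col = "grey50",
                 xlab = "False positive rate", ylab = "True positive rate",
                 main = sprintf("%s: per-fold ROC (mean AUC %.2f)",
                                x$spec$kind, x$aggregate["mean", "auc"]),
                 ...)
  for (r in x$roc)
    if (!is.na(r$auc)) graphics::lines(r$fpr, r$tpr, col = "#00000055")
  invisible(x)
}

#' Grid search over model specifications
#'
#' Evaluates every grid point by cross-validated mean F1 and returns the
#' best; ties are broken by grid order (first wins).
#'
#' @param grid list of [model_spec()] objects, or a data frame / named list
#'   of hyperparameter vectors together with `kind` to expand.
#' @param x,y,folds as in [evaluate_cv()].
#' @param kind model kind when `grid` is a parameter list.
#' @param seed master seed forwarded to the evaluations.
#' @return list with `best` (the winning `model_spec`), `scores` (mean F1
#'   per grid point), `grid`.
#' @export
grid_search <- function(grid, x, y = NULL, folds = NULL, kind = NULL,
                        seed = 1) {
  if (!length(grid)) stopf("empty grid")
  if (!inherits(grid[[1]], "model_spec")) {
    if (is.null(kind)) stopf("kind required when grid is a parameter list")
    combos <- expand.grid(grid, stringsAsFactors = FALSE)
    grid <- lapply(seq_len(nrow(combos)), function(i)
      do.call(model_spec, c(list(kind = kind), as.list(combos[i, , drop = FALSE]))))
  }
  scores <- vapply(grid, function(spec) {
    rep <- evaluate_cv(spec, x, y, folds = folds, seed = seed)
    rep$aggregate["mean", "f1"]
  }, numeric(1))
  best <- which.max(scores)   # first maximum wins
  list(best = grid[[best]], scores = scores, grid = grid)
}
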