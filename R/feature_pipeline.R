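FEATURE_GROUPS_SEQ <- c(kmer2 = 16, kmer3 = 64, psednc = 26,
                        conservation = 1, gc = 1, ppi = 1, mutation = 1)
FEATURE_GROUPS_STRUCT <- c(mfe = 1, pairs = 6, unpaired = 3)

#' Assemble the full design matrix
#'
#' Concatenates the sequence-feature block and (optionally) the
#' structure-feature block into the canonical 120-column design matrix:
#' 2-mers (16), 3-mers (64), pseudo dinucleotide composition (26),
#' conservation (1), GC (1), interactions (1), mutations (1), MFE (1),
#' base-pair types (6), unpaired-loop classes (3). With structure features
#' absent the matrix has 110 columns and the group metadata reflects that.
#'
#' @param seq_features matrix from [featurize_sequences()].
#' @param struct_features optional matrix from [featurize_structures()].
#' @param labels optional character/factor vector of per-transcript labels
#'   (named by transcript id, or in row order).
#' @return A `feature_matrix`: list with `x` (numeric matrix), `labels`
#'   (factor with levels negative/positive or `NULL`), `groups` (named
#'   integer vector of column-group sizes), `surrogate_mfe` flag.
#' @export
assemble_features <- function(seq_features, struct_features = NULL,
                              labels = NULL) {
  x <- as.matrix(seq_features)
  groups <- FEATURE_GROUPS_SEQ
  surrogate <- FALSE
  if (!is.null(struct_features)) {
    s <- as.matrix(struct_features)
    extra_seq <- setdiff(rownames(x), rownames(s))
    extra_struct <- setdiff(rownames(s), rownames(x))
    if (length(extra_seq) || length(extra_struct))
      stopf("row-id mismatch between feature blocks%s%s",
            if (length(extra_seq))
              sprintf("; only in sequence block: %s",
                      paste(extra_seq, collapse = ", ")) else "",
            if (length(extra_struct))
              sprintf("; only in structure block: %s",
                      paste(extra_struct, collapse = ", ")) else "")
    s <- s[rownames(x), , drop = FALSE]
    surrogate <- isTRUE(attr(struct_features, "surrogate_mfe"))
    x <- cbind(x, s)
    groups <- c(groups, FEATURE_GROUPS_STRUCT)
  }
  if (any(!is.finite(x)))
    stopf("non-finite values in assembled feature matrix")
  if (!is.null(labels)) {
    if (!is.null(names(labels))) {
      miss <- setdiff(rownames(x), names(labels))
      if (length(miss)) stopf("labels missing for: %s",
                              paste(miss, collapse = ", "))
      labels <- labels[rownames(x)]
    } else if (length(labels) != nrow(x)) {
      stopf("labels length %d != %d rows", length(labels), nrow(x))
    }
    labels <- factor(as.character(labels), levels = c("negative", "positive"))
    if (anyNA(labels)) stopf("labels must be 'positive' or 'negative'")
  }
  structure(list(x = x, labels = labels, groups = groups,
                 surrogate_mfe = surrogate), class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d transcripts x %d features\n",
              nrow(x$x), ncol(x$x)))
  cat("  groups:", paste(sprintf("%s=%d", names(x$groups), x$groups),
                         collapse = ", "), "\n")
  if (!is.null(x$labels)) {
    t <- table(x$labels)
    cat(sprintf("  labels: %d positive, %d negative\n",
                t[["positive"]], t[["negative"]]))
  }
  if (isTRUE(x$surrogate_mfe))
    cat("  note: mfe column is a surrogate fold score, not RNAfold energy\n")
  invisible(x)
}

#' Importance-based feature selection
#'
#' Fits a random forest of the given shape on the labelled matrix and keeps
#' the features whose (normalized) importance meets the threshold — the
#' mean importance by default, mirroring the common select-from-model rule.
#' The backend forest splits on Gini impurity; the `criterion` argument is
#' recorded for provenance but does not change the split rule (see the
#' methods vignette). `max_depth` is enforced as a `maxnodes = 2^max_depth`
#' cap.
#'
#' @param fm a `feature_matrix` with labels of both classes, or a plain
#'   numeric matrix (then `labels` is required).
#' @param labels labels when `fm` is a plain matrix.
#' @param n_estimators number of trees (default 50).
#' @param max_depth tree depth cap (default 11).
#' @param criterion recorded impurity name (default `"entropy"`).
#' @param threshold `"mean"` (default) or a numeric importance cutoff.
#' @param seed RNG seed; selection is deterministic given it.
#' @return A `selection_result`: `importances` (normalized, sum 1),
#'   `threshold` (numeric value used), `keep` (logical mask), `kept`
#'   (column names), `seed`, and the forest parameters.
#' @export
select_features <- function(fm, labels = NULL, n_estimators = 50,
                            max_depth = 11, criterion = "entropy",
                            threshold = "mean", seed = 1) {
  if (inherits(fm, "feature_matrix")) {
    x <- fm$x
    labels <- fm$labels
  } else {
    x <- as.matrix(fm)
    if (is.null(labels)) stopf("labels required")
    labels <- factor(as.character(labels))
  }
  labels <- droplevels(factor(labels))
  if (nlevels(labels) < 2) stopf("need >= 2 classes for feature selection")
  constant <- apply(x, 2, function(col) max(col) - min(col) == 0)
  imp <- setNames(numeric(ncol(x)), colnames(x))
  if (all(constant)) {
    warnf("all columns constant; nothing selectable")
  } else {
    set.seed(seed)
    rf <- randomForest::randomForest(
      x = x[, !constant, drop = FALSE], y = labels,
      ntree = n_estimators,
      maxnodes = min(2^max_depth, nrow(x)),
      importance = FALSE)
    imp[!constant] <- rf$importance[, "MeanDecreaseGini"]
  }
  total <- sum(imp)
  if (total > 0) imp <- imp / total
  thr <- if (identical(threshold, "mean")) mean(imp) else as.numeric(threshold)
  # kept = importance >= threshold; a forest with no signal keeps nothing
  keep <- if (total > 0) imp >= thr else imp > 0
  if (!any(keep)) warnf("no feature reaches the importance threshold")
  structure(list(importances = imp, threshold = thr, keep = keep,
                 kept = names(imp)[keep], seed = seed, n_obs = nrow(x),
                 params = list(n_estimators = n_estimators,
                               max_depth = max_depth,
                               criterion = criterion)),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("<selection_result> kept %d / %d features (threshold %.4g)\n",
              sum(x$keep), length(x$keep), x$threshold))
  top <- sort(x$importances[x$keep], decreasing = TRUE)
  show <- head(top, 8)
  for (n in names(show)) cat(sprintf("  %-14s %.4f\n", n, show[[n]]))
  if (length(top) > 8) cat(sprintf("  ... and %d more\n", length(top) - 8))
  invisible(x)
}

#' Apply a selection result to a feature matrix
#'
#' @param fm a `feature_matrix` or numeric matrix.
#' @param selection a `selection_result`.
#' @return the matrix restricted to kept columns.
#' @export
apply_selection <- function(fm, selection) {
  x <- if (inherits(fm, "feature_matrix")) fm$x else as.matrix(fm)
  x[, selection$kept, drop = FALSE]
}
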