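## Supervised reconstructability of the phenotype labels: stratified
## 70/15/15 split, stratified 5-fold CV with a gradient-boosted multiclass
## classifier, and a single held-out evaluation with per-class OvR ROC
## curves. The labels arrive frozen — the factor model and clustering are
## fitted once on the full cohort and never refit per fold, so the metrics
## quantify internal reconstructability, not external validation.

#' Stratified three-way split
#'
#' Splits the cohort into train/validation/test with per-class allocation by
#' largest-remainder rounding, reconciled so that the total part sizes equal
#' the largest-remainder rounding of `fractions * N` exactly. Each class's
#' allocation to each part stays within one participant of its proportional
#' quota.
#'
#' @param labels Class label vector (>= 2 classes, every class >= 3
#'   members).
#' @param fractions Length-3 vector of train/validation/test fractions
#'   (sum 1).
#' @param seed Integer seed for the within-class assignment (default 42).
#' @return Object of class `"split_plan"`: integer index vectors `train`,
#'   `validation`, `test`, plus `sizes`.
#' @export
split_cohort <- function(labels, fractions = c(0.70, 0.15, 0.15), seed = 42L) {
  labels <- as.vector(labels)
  n <- length(labels)
  if (abs(sum(fractions) - 1) > 1e-8 || length(fractions) != 3L)
    stop("'fractions' must be three numbers summing to 1", call. = FALSE)
  classes <- sort(unique(labels))
  if (length(classes) < 2L) stop("need at least 2 classes", call. = FALSE)
  cnt <- table(factor(labels, levels = classes))
  if (any(cnt < 3L))
    stop(sprintf("class(es) too small to appear in all parts: %s",
                 paste(names(cnt)[cnt < 3L], collapse = ", ")), call. = FALSE)

  largest_remainder <- function(total, fr) {
    q <- total * fr
    fl <- floor(q)
    rem <- total - sum(fl)
    if (rem > 0) {
      ord <- order(q - fl, decreasing = TRUE)
      fl[ord[seq_len(rem)]] <- fl[ord[seq_len(rem)]] + 1L
    }
    as.integer(fl)
  }
  target <- largest_remainder(n, fractions)

  ## per-class largest-remainder allocation
  alloc <- t(vapply(as.integer(cnt), largest_remainder,
                    integer(3), fr = fractions))
  quota <- outer(as.integer(cnt), fractions)
  ## reconcile part totals to the global target by moving single units
  ## between parts within a class, choosing the move that stays closest to
  ## the class quotas (deterministic tie-break by class order)
  for (guard in seq_len(10L * n)) {
    diffs <- colSums(alloc) - target
    if (all(diffs == 0L)) break
    over <- which.max(diffs)
    under <- which.min(diffs)
    cand <- which(alloc[, over] > 0L)
    score <- (quota[cand, under] - alloc[cand, under]) -
      (quota[cand, over] - alloc[cand, over])
    pick <- cand[order(-score, cand)][1L]
    alloc[pick, over] <- alloc[pick, over] - 1L
    alloc[pick, under] <- alloc[pick, under] + 1L
  }
  if (!all(colSums(alloc) == target))
    stop("internal error: split reconciliation failed", call. = FALSE)
  if (any(alloc == 0L & matrix(cnt >= 3L, nrow(alloc), 3L)))
    stop("a class received no members in one part; adjust fractions",
         call. = FALSE)

  parts <- list(train = integer(0), validation = integer(0),
                test = integer(0))
  with_seed(seed, {
    for (ci in seq_along(classes)) {
      idx <- which(labels == classes[ci])
      idx <- idx[sample.int(length(idx))]
      a <- alloc[ci, ]
      parts$train <- c(parts$train, idx[seq_len(a[1])])
      parts$validation <- c(parts$validation,
                            idx[a[1] + seq_len(a[2])])
      parts$test <- c(parts$test, idx[a[1] + a[2] + seq_len(a[3])])
    }
  })
  parts <- lapply(parts, sort)
  structure(c(parts, list(sizes = stats::setNames(target,
                                                  c("train", "validation", "test")),
                          fractions = fractions, seed = seed)),
            class = "split_plan")
}

#' @export
print.split_plan <- function(x, ...) {
  cat(sprintf("Stratified split: train %d / validation %d / test %d (seed %d)\n",
              x$sizes[1], x$sizes[2], x$sizes[3], x$seed))
  invisible(x)
}

## stratified k-fold assignment (returns fold id per row)
stratified_folds <- function(labels, n_folds, seed) {
  fold <- integer(length(labels))
  with_seed(seed, {
    for (cl in unique(labels)) {
      idx <- which(labels == cl)
      idx <- idx[sample.int(length(idx))]
      fold[idx] <- rep_len(seq_len(n_folds), length(idx))
    }
  })
  fold
}

## ---- metrics --------------------------------------------------------------

#' Macro-averaged F1 score
#'
#' Unweighted mean of per-class F1; a class with no true or predicted
#' members contributes F1 = 0.
#'
#' @param truth,pred Label vectors.
#' @param classes Class set (default: observed in `truth`).
#' @return Macro F1 in `[0, 1]`.
#' @export
macro_f1 <- function(truth, pred, classes = sort(unique(truth))) {
  f1 <- vapply(classes, function(cl) {
    tp <- sum(truth == cl & pred == cl)
    fp <- sum(truth != cl & pred == cl)
    fn <- sum(truth == cl & pred != cl)
    if (2 * tp + fp + fn == 0) return(0)
    2 * tp / (2 * tp + fp + fn)
  }, numeric(1))
  mean(f1)
}

#' ROC curve points
#'
#' False- and true-positive rates at every distinct score threshold
#' (descending), anchored at (0, 0) and (1, 1). Both coordinates are
#' monotone non-decreasing.
#'
#' @param scores Numeric classifier scores (higher = more positive).
#' @param truth 0/1 vector of true class membership.
#' @return Data frame with columns `fpr`, `tpr`, `threshold`.
#' @export
roc_curve <- function(scores, truth) {
  if (!any(truth == 1) || !any(truth == 0))
    stop("ROC undefined: need both classes present", call. = FALSE)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- truth[ord]
  cum_tp <- cumsum(y == 1)
  cum_fp <- cumsum(y == 0)
  last <- which(diff(s) != 0)         # last index of each distinct score
  keep <- c(last, length(s))
  data.frame(fpr = c(0, cum_fp[keep] / sum(truth == 0)),
             tpr = c(0, cum_tp[keep] / sum(truth == 1)),
             threshold = c(Inf, s[keep]))
}

#' Area under the ROC curve (trapezoidal rule)
#' @param scores,truth As in [roc_curve()].
#' @return AUC in `[0, 1]`.
#' @export
auc_trapezoid <- function(scores, truth) {
  rc <- roc_curve(scores, truth)
  sum(diff(rc$fpr) * (utils::head(rc$tpr, -1) + utils::tail(rc$tpr, -1)) / 2)
}

#' Area under the ROC curve (Mann-Whitney rank statistic)
#'
#' Probability that a positive outranks a negative, ties counted half; the
#' rank formulation equals the trapezoidal integral exactly.
#'
#' @param scores,truth As in [roc_curve()].
#' @return AUC in `[0, 1]`.
#' @export
auc_rank <- function(scores, truth) {
  n1 <- sum(truth == 1); n0 <- sum(truth == 0)
  if (n1 == 0 || n0 == 0) stop("AUC undefined: need both classes", call. = FALSE)
  r <- rank(scores)
  (sum(r[truth == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

## one-vs-rest AUC averaged unweighted over classes
ovr_auc <- function(prob, truth, classes = colnames(prob)) {
  mean(vapply(classes, function(cl)
    auc_rank(prob[, cl], as.numeric(truth == cl)), numeric(1)))
}

## ---- classifier backend ---------------------------------------------------

#' Gradient-boosted tree backend (xgboost)
#'
#' The default classifier behind the reconstructability check: multiclass
#' softprob objective, 500 trees, depth 6, learning rate 0.1, single
#' thread. Any list with the same `fit`/`predict_proba` contract can be
#' substituted.
#'
#' @param nrounds,max_depth,eta Boosting hyperparameters.
#' @param early_stopping_rounds Used only when a validation set is passed to
#'   `fit`.
#' @return List with functions `fit(x, y, xval, yval)` and
#'   `predict_proba(model, x)`; `y` must be integer codes `0..G-1`.
#' @export
xgb_backend <- function(nrounds = 500L, max_depth = 6L, eta = 0.1,
                        early_stopping_rounds = 25L) {
  list(
    fit = function(x, y, xval = NULL, yval = NULL) {
      nclass <- length(unique(y))
      params <- list(objective = "multi:softprob", num_class = nclass,
                     max_depth = max_depth, eta = eta, nthread = 1L,
                     eval_metric = "mlogloss")
      dtrain <- xgboost::xgb.DMatrix(as.matrix(x), label = y)
      if (is.null(xval)) {
        xgboost::xgb.train(params, dtrain, nrounds = nrounds, verbose = 0)
      } else {
        dval <- xgboost::xgb.DMatrix(as.matrix(xval), label = yval)
        xgboost::xgb.train(params, dtrain, nrounds = nrounds,
                           evals = list(val = dval),
                           early_stopping_rounds = early_stopping_rounds,
                           verbose = 0)
      }
    },
    predict_proba = function(model, x) {
      p <- predict(model, xgboost::xgb.DMatrix(as.matrix(x)))
      if (is.matrix(p)) p else matrix(p, nrow = nrow(as.matrix(x)),
                                      byrow = TRUE)
    })
}

## ---- cross-validation and holdout -----------------------------------------

#' Stratified cross-validation of label reconstructability
#'
#' Stratified `n_folds`-fold CV on the training portion: in each fold the
#' classifier is fitted on the other folds and evaluated on the held fold;
#' macro-F1 and one-vs-rest ROC-AUC (per-class AUC averaged unweighted) are
#' reported as mean and SD across folds.
#'
#' @param x Feature matrix (missing values allowed; the default backend
#'   handles them natively).
#' @param y Class labels.
#' @param n_folds Number of folds (default 5).
#' @param seed Fold-assignment seed.
#' @param backend Classifier backend (default [xgb_backend()]).
#' @return List: `macro_f1_mean`, `macro_f1_sd`, `auc_mean`, `auc_sd`,
#'   `per_fold` data frame.
#' @export
crossval_classifier <- function(x, y, n_folds = 5L, seed = 42L,
                                backend = xgb_backend()) {
  x <- as.matrix(x)
  y <- as.vector(y)
  classes <- sort(unique(y))
  fold <- stratified_folds(y, n_folds, seed)
  if (any(vapply(seq_len(n_folds), function(f)
    length(unique(y[fold == f])) < length(classes), logical(1))))
    stop("every class must be present in every fold; reduce n_folds",
         call. = FALSE)
  per_fold <- do.call(rbind, lapply(seq_len(n_folds), function(f) {
    tr <- fold != f; te <- !tr
    if (length(unique(y[tr])) < 2L)
      stop("single-class training fold", call. = FALSE)
    ycode <- as.integer(factor(y, levels = classes)) - 1L
    model <- backend$fit(x[tr, , drop = FALSE], ycode[tr])
    prob <- backend$predict_proba(model, x[te, , drop = FALSE])
    colnames(prob) <- as.character(classes)
    pred <- classes[max.col(prob, ties.method = "first")]
    data.frame(fold = f,
               macro_f1 = macro_f1(y[te], pred, classes),
               ovr_auc = ovr_auc(prob, y[te], as.character(classes)))
  }))
  list(macro_f1_mean = mean(per_fold$macro_f1),
       macro_f1_sd = stats::sd(per_fold$macro_f1),
       auc_mean = mean(per_fold$ovr_auc),
       auc_sd = stats::sd(per_fold$ovr_auc),
       per_fold = per_fold)
}

#' Single held-out evaluation with per-class ROC curves
#'
#' Refits the classifier on the full training part (early stopping on the
#' validation part when the backend supports it) and evaluates exactly once
#' on the test part: accuracy, macro-F1, OvR ROC-AUC, per-class F1 and AUC,
#' confusion matrix, and per-class ROC curve points.
#'
#' @param x Feature matrix for the whole cohort.
#' @param y Label vector for the whole cohort.
#' @param split A `"split_plan"` from [split_cohort()].
#' @param backend Classifier backend (default [xgb_backend()]).
#' @return Object of class `"validation_report"`.
#' @export
evaluate_holdout <- function(x, y, split, backend = xgb_backend()) {
  stopifnot(inherits(split, "split_plan"))
  x <- as.matrix(x); y <- as.vector(y)
  classes <- sort(unique(y))
  if (length(setdiff(classes, unique(y[split$test]))))
    stop("class absent from the test set: AUC undefined", call. = FALSE)
  ycode <- as.integer(factor(y, levels = classes)) - 1L
  model <- backend$fit(x[split$train, , drop = FALSE], ycode[split$train],
                       x[split$validation, , drop = FALSE],
                       ycode[split$validation])
  prob <- backend$predict_proba(model, x[split$test, , drop = FALSE])
  colnames(prob) <- as.character(classes)
  ytest <- y[split$test]
  pred <- classes[max.col(prob, ties.method = "first")]
  per_class <- do.call(rbind, lapply(classes, function(cl) {
    truth01 <- as.numeric(ytest == cl)
    data.frame(class = cl,
               f1 = macro_f1(ytest, pred, classes = cl),
               auc = auc_rank(prob[, as.character(cl)], truth01),
               n_test = sum(truth01))
  }))
  roc <- lapply(stats::setNames(as.character(classes), classes), function(cl)
    roc_curve(prob[, cl], as.numeric(ytest == cl)))
  confusion <- table(truth = factor(ytest, levels = classes),
                     predicted = factor(pred, levels = classes))
  structure(list(
    accuracy = mean(ytest == pred),
    macro_f1 = macro_f1(ytest, pred, classes),
    ovr_auc = ovr_auc(prob, ytest, as.character(classes)),
    per_class = per_class, confusion = confusion, roc = roc,
    model = model, prob = prob),
    class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat("Held-out reconstructability (internal consistency check, not external validation)\n")
  cat(sprintf("accuracy %.3f | macro-F1 %.3f | OvR ROC-AUC %.3f\n",
              x$accuracy, x$macro_f1, x$ovr_auc))
  print(x$confusion)
  invisible(x)
}

#' @export
plot.validation_report <- function(x, ...) {
  graphics::plot(c(0, 1), c(0, 1), type = "l", lty = 2, col = "grey50",
                 xlab = "False positive rate", ylab = "True positive rate",
                 main = "One-vs-rest ROC (held-out test)", ...)
  cols <- grDevices::hcl.colors(length(x$roc), "Dark 3")
  for (i in seq_along(x$roc))
    graphics::lines(x$roc[[i]]$fpr, x$roc[[i]]$tpr, col = cols[i], lwd = 2)
  graphics::legend("bottomright", bty = "n", lwd = 2, col = cols,
                   legend = sprintf("%s (AUC %.3f)", names(x$roc),
                                    x$per_class$auc))
  invisible(x)
}
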