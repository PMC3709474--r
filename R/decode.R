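#' Leave-one-run-out fold plan
#'
#' One fold per run: the classifier is trained on all other runs and tested
#' on the held-out run, so every trial is tested exactly once.
#'
#' @param runs integer vector of run ids (per trial, or the unique ids).
#' @return list of folds, each a list with `train` and `test` run ids.
#' @export
fold_plan <- function(runs) {
  ids <- sort(unique(runs))
  if (length(ids) < 2) stop("leave-one-run-out needs at least 2 runs")
  lapply(ids, function(r) list(train = setdiff(ids, r), test = r))
}

# Fit a linear SVM (libsvm via e1071) and return weights oriented so that a
# positive decision value predicts levels(y)[1]. libsvm assigns +1 to the
# class of the first training sample, so the raw sign can flip with trial
# order; re-orienting makes weights comparable across folds and subjects.
.fit_wb <- function(x, y, cost) {
  m <- e1071::svm(x, y, type = "C-classification", kernel = "linear",
                  cost = cost, scale = FALSE)
  w <- drop(crossprod(m$coefs, m$SV))
  b <- -m$rho
  pos <- m$levels[m$labels[1]]
  if (pos != levels(y)[1]) { w <- -w; b <- -b }
  list(w = w, b = b)
}

#' Fit a linear maximum-margin classifier on trial patterns
#'
#' Trains LibSVM's linear support vector machine (C-classification, fixed
#' regularization constant `cost`, no internal rescaling) on a two-class
#' trials-by-voxels matrix. The decision rule is
#' `sign(w . pattern + b)`: positive predicts the first factor level.
#' The per-voxel weights `w` are the subject-level sensitivity values.
#'
#' @param x trials x voxels numeric matrix.
#' @param y factor (or vector) with exactly two distinct labels.
#' @param cost regularization constant C (default 1).
#' @return an object of class `mvpa_svm` with elements `weights`, `bias`,
#'   `levels` and `cost`.
#' @examples
#' x <- matrix(c(-1, 1), 2, 1)
#' f <- fit_linear_classifier(x, c("A", "B"))
#' predict(f, x)  # both training points recovered
#' @export
fit_linear_classifier <- function(x, y, cost = 1) {
  x <- as.matrix(x)
  y <- droplevels(as.factor(y))
  if (nlevels(y) < 2) stop("training set contains a single class")
  if (nlevels(y) > 2) stop("binary classifier: found more than two labels")
  if (cost <= 0) stop("cost must be > 0")
  fit <- .fit_wb(x, y, cost)
  structure(list(weights = fit$w, bias = fit$b, levels = levels(y),
                 cost = cost, n_train = nrow(x)),
            class = "mvpa_svm")
}

#' @export
predict.mvpa_svm <- function(object, newdata, type = c("class", "decision"), ...) {
  type <- match.arg(type)
  dv <- drop(as.matrix(newdata) %*% object$weights + object$bias)
  if (type == "decision") return(dv)
  factor(ifelse(dv > 0, object$levels[1], object$levels[2]),
         levels = object$levels)
}

#' @export
coef.mvpa_svm <- function(object, ...) {
  c(bias = object$bias, object$weights)
}

#' @export
print.mvpa_svm <- function(x, ...) {
  cat(sprintf("linear SVM: %s vs %s, %d voxels, C = %g\n",
              x$levels[1], x$levels[2], length(x$weights), x$cost))
  invisible(x)
}

# condition must be present in every run (each fold needs both classes)
.check_runs <- function(condition, run, labels) {
  tab <- table(factor(run), factor(condition, levels = labels))
  bad <- rownames(tab)[apply(tab == 0, 1, any)]
  if (length(bad))
    stop(sprintf("condition(s) missing from run(s): %s", paste(bad, collapse = ", ")))
}

# Lean two-way CV core shared with the permutation machinery.
# y_train/y_test allow label permutation scopes that differ between the two
# sides of the fold boundary. Returns the vector of fold accuracies.
.cv_two_acc <- function(x, y_train, run, cost, y_test = y_train) {
  folds <- sort(unique(run))
  vapply(folds, function(r) {
    tr <- run != r
    fit <- .fit_wb(x[tr, , drop = FALSE], droplevels(y_train[tr]), cost)
    dv <- x[!tr, , drop = FALSE] %*% fit$w + fit$b
    pred <- ifelse(dv > 0, levels(y_train)[1], levels(y_train)[2])
    mean(pred == as.character(y_test[!tr]))
  }, numeric(1))
}

#' Two-way decoding with leave-one-run-out cross-validation
#'
#' Restricts the trial set to a pair of conditions, then for every fold
#' trains a linear SVM on the other runs and classifies the held-out run's
#' trials. Accuracy is the fraction of correct guesses among test trials;
#' the overall accuracy is the unweighted mean over folds.
#'
#' @param tp a `trial_patterns` object.
#' @param pair character vector of two condition labels.
#' @param cost SVM regularization constant.
#' @return an object of class `mvpa_decoding` with per-fold accuracies,
#'   mean accuracy, a guesses-by-targets confusion matrix, and the
#'   fold-averaged weight vector (the subject sensitivity values).
#' @export
crossvalidate_two_way <- function(tp, pair, cost = 1) {
  stopifnot(inherits(tp, "trial_patterns"), length(pair) == 2)
  sub <- subset_patterns(tp, pair)
  if (nrow(sub$x) == 0) stop("no trials for the requested pair")
  .check_runs(sub$condition, sub$run, pair)
  folds <- fold_plan(sub$run)
  conf <- matrix(0L, 2, 2, dimnames = list(guess = pair, target = pair))
  acc <- numeric(length(folds)); W <- NULL; B <- numeric(length(folds))
  for (i in seq_along(folds)) {
    tr <- sub$run %in% folds[[i]]$train
    fit <- .fit_wb(sub$x[tr, , drop = FALSE], droplevels(sub$condition[tr]), cost)
    dv <- sub$x[!tr, , drop = FALSE] %*% fit$w + fit$b
    pred <- ifelse(dv > 0, pair[1], pair[2])
    truth <- as.character(sub$condition[!tr])
    acc[i] <- mean(pred == truth)
    for (j in seq_along(pred)) conf[pred[j], truth[j]] <- conf[pred[j], truth[j]] + 1L
    if (is.null(W)) W <- matrix(0, length(folds), length(fit$w))
    W[i, ] <- fit$w; B[i] <- fit$b
  }
  structure(list(task = paste(pair, collapse = " vs "), pair = pair,
                 fold_accuracy = stats::setNames(acc, paste0("run", vapply(folds, `[[`, 0, "test"))),
                 accuracy = mean(acc), confusion = conf,
                 weights = colMeans(W), fold_weights = W, bias = mean(B),
                 n_trials = nrow(sub$x), cost = cost, roi = tp$roi, k = tp$k),
            class = "mvpa_decoding")
}

#' Tally pairwise votes into a multiclass prediction
#'
#' Given, for each test trial, the predictions of all pairwise binary
#' classifiers, counts how often each label was predicted and returns the
#' modal label. Ties are broken either uniformly at random among the tied
#' labels (using the current RNG stream; seed upstream for
#' reproducibility) or deterministically by the lowest label index.
#'
#' @param votes character matrix, trials x contests, of predicted labels.
#' @param labels character vector of all candidate labels, in index order.
#' @param tie_break `"random"` or `"lowest"`.
#' @return factor of winning labels, one per trial.
#' @export
tally_votes <- function(votes, labels, tie_break = c("random", "lowest")) {
  tie_break <- match.arg(tie_break)
  votes <- as.matrix(votes)
  win <- character(nrow(votes))
  for (i in seq_len(nrow(votes))) {
    cnt <- tabulate(factor(votes[i, ], levels = labels), nbins = length(labels))
    top <- which(cnt == max(cnt))
    win[i] <- if (length(top) == 1) labels[top]
              else if (tie_break == "lowest") labels[top[1]]
              else labels[top[sample.int(length(top), 1)]]
  }
  factor(win, levels = labels)
}

# Lean multiclass CV core (pairwise voting); returns list(acc, conf).
.cv_multi <- function(x, y_train, run, cost, tie_break, y_test = y_train,
                      want_conf = TRUE) {
  labels <- levels(y_train)
  pairs <- utils::combn(labels, 2)
  folds <- sort(unique(run))
  conf <- if (want_conf)
    matrix(0L, length(labels), length(labels),
           dimnames = list(guess = labels, target = labels))
  acc <- numeric(length(folds))
  for (fi in seq_along(folds)) {
    te <- run == folds[fi]
    xte <- x[te, , drop = FALSE]
    votes <- matrix("", nrow(xte), ncol(pairs))
    for (p in seq_len(ncol(pairs))) {
      pr <- pairs[, p]
      trp <- !te & (y_train %in% pr)
      ytr <- factor(as.character(y_train[trp]), levels = pr)
      fit <- .fit_wb(x[trp, , drop = FALSE], ytr, cost)
      dv <- xte %*% fit$w + fit$b
      votes[, p] <- ifelse(dv > 0, pr[1], pr[2])
    }
    pred <- tally_votes(votes, labels, tie_break)
    truth <- as.character(y_test[te])
    acc[fi] <- mean(as.character(pred) == truth)
    if (want_conf)
      for (j in seq_along(pred))
        conf[as.character(pred[j]), truth[j]] <- conf[as.character(pred[j]), truth[j]] + 1L
  }
  list(acc = acc, conf = conf)
}

#' Multiclass decoding by pairwise voting
#'
#' Four-way (in general, k-way) classification built from all pairwise
#' binary SVMs: in each leave-one-run-out fold, every pair classifier
#' trained on the training runs predicts every held-out trial, and the
#' label predicted most often wins. The result carries the
#' guesses-by-targets confusion matrix accumulated over folds.
#'
#' @param tp a `trial_patterns` object (all its condition levels are used).
#' @param cost SVM regularization constant.
#' @param tie_break vote tie handling, `"random"` (seed the RNG upstream)
#'   or `"lowest"` (deterministic).
#' @return an `mvpa_decoding` object; `accuracy` is the unweighted mean of
#'   fold accuracies.
#' @export
crossvalidate_four_way <- function(tp, cost = 1,
                                   tie_break = c("random", "lowest")) {
  stopifnot(inherits(tp, "trial_patterns"))
  tie_break <- match.arg(tie_break)
  labels <- levels(tp$condition)
  if (length(labels) < 2) stop("need at least two conditions")
  .check_runs(tp$condition, tp$run, labels)
  res <- .cv_multi(tp$x, tp$condition, tp$run, cost, tie_break)
  structure(list(task = sprintf("%d-way", length(labels)), pair = NULL,
                 fold_accuracy = stats::setNames(res$acc, paste0("run", sort(unique(tp$run)))),
                 accuracy = mean(res$acc), confusion = res$conf,
                 n_trials = nrow(tp$x), cost = cost, roi = tp$roi, k = tp$k,
                 tie_break = tie_break),
            class = "mvpa_decoding")
}

#' @export
print.mvpa_decoding <- function(x, ...) {
  cat(sprintf("MVPA decoding [%s], ROI '%s', volume k=%d\n", x$task, x$roi, x$k))
  cat(sprintf("  mean accuracy over %d folds: %.3f (chance %.3f)\n",
              length(x$fold_accuracy), x$accuracy, 1 / nrow(x$confusion)))
  invisible(x)
}

#' @export
summary.mvpa_decoding <- function(object, ...) {
  cat(sprintf("MVPA decoding [%s], ROI '%s', %d trials, C = %g\n",
              object$task, object$roi, object$n_trials, object$cost))
  cat("fold accuracies:\n"); print(round(object$fold_accuracy, 3))
  cat(sprintf("mean accuracy: %.3f\n", object$accuracy))
  cat("confusion (guesses x targets):\n"); print(object$confusion)
  invisible(object)
}

#' @export
plot.mvpa_decoding <- function(x, ...) {
  cm <- x$confusion
  graphics::image(seq_len(ncol(cm)), seq_len(nrow(cm)),
                  t(cm[rev(seq_len(nrow(cm))), , drop = FALSE]),
                  axes = FALSE, xlab = "target", ylab = "guess",
                  main = sprintf("%s (acc %.2f)", x$task, x$accuracy), ...)
  graphics::axis(1, seq_len(ncol(cm)), colnames(cm))
  graphics::axis(2, seq_len(nrow(cm)), rev(rownames(cm)))
  graphics::box()
  invisible(x)
}

#' Decoding accuracy as a function of the extracted volume
#'
#' Repeats the identical two-way decoding pipeline using the volume
#' acquired before/at stimulus onset (`k = 0`) and at successive
#' post-stimulus volumes, tracing the time course of decodable
#' information: accuracy should sit at chance before the stimulus and peak
#' at the volume containing the hemodynamic response peak.
#'
#' @param ds a preprocessed `functional_dataset`.
#' @param events an `event_table`.
#' @param roi binary mask.
#' @param pair two condition labels.
#' @param k_range volume offsets to test (subset of 0..6).
#' @param cost SVM regularization constant.
#' @param ... passed to [extract_patterns()].
#' @return data.frame with columns `k` and `accuracy`; the full
#'   `mvpa_decoding` objects are attached as attribute `results`.
#' @export
timecourse_decoding <- function(ds, events, roi, pair, k_range = 0:6,
                                cost = 1, ...) {
  stopifnot(all(k_range %in% 0:6))
  res <- lapply(k_range, function(k) {
    tp <- extract_patterns(ds, events, roi, k = k, ...)
    crossvalidate_two_way(tp, pair, cost = cost)
  })
  out <- data.frame(k = k_range,
                    accuracy = vapply(res, `[[`, numeric(1), "accuracy"))
  attr(out, "results") <- res
  out
}
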