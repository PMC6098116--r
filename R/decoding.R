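# Linear-SVM trial classification: conjunction, naive-voting and self
# decoders with leave-one-subject-out / leave-one-run-out cross-validation.

#' Train a soft-margin linear SVM
#'
#' Linear kernel, hinge loss, L2 regularization, constant `C` (default 1),
#' no feature scaling beyond the z-scores produced upstream. The fitted
#' hyperplane is extracted into an explicit weight vector and bias so that
#' decision values are reproducible without the solver.
#'
#' @param X trials-by-features matrix.
#' @param y labels in {+1, -1} (+1 = attend-left).
#' @param C soft-margin cost.
#' @param tol solver tolerance.
#' @return a `linear_classifier` with elements `w`, `b`, `n_train`.
#' @export
train_svm <- function(X, y, C = 1, tol = 1e-6) {
  X <- as.matrix(X)
  y <- as.integer(y)
  if (length(unique(y)) < 2) stop("training labels contain a single class")
  stopifnot(all(y %in% c(-1L, 1L)), nrow(X) == length(y))
  fit <- e1071::svm(x = X, y = factor(y, levels = c(-1, 1)), scale = FALSE,
                    kernel = "linear", cost = C, tolerance = tol)
  w <- crossprod(fit$SV, fit$coefs)[, 1]
  b <- -fit$rho
  # libSVM's decision sign follows the first training label; normalize so
  # that positive decision values mean class +1
  dec <- X %*% w + b
  pred <- predict(fit, X)
  if (mean(dec[pred == "1"]) < mean(dec[pred == "-1"])) {
    w <- -w
    b <- -b
  }
  structure(list(w = w, b = b, n_train = nrow(X)), class = "linear_classifier")
}

#' @export
predict.linear_classifier <- function(object, newdata, ...) {
  dec <- as.numeric(as.matrix(newdata) %*% object$w + object$b)
  structure(sign(dec), decision = dec)
}

decoding_result <- function(scheme, subject, truth, pred, decision = NULL,
                            extra = NULL) {
  acc <- mean(pred == truth) * 100
  structure(c(list(scheme = scheme, subject = subject, accuracy = acc,
                   trials = data.frame(true = truth, predicted = pred,
                                       decision = if (is.null(decision)) NA_real_
                                                  else decision)),
              extra),
            class = "decoding_result")
}

#' @export
print.decoding_result <- function(x, ...) {
  cat(sprintf("%s decoding | subject %s | accuracy %.1f%% (%d trials)\n",
              x$scheme, as.character(x$subject), x$accuracy, nrow(x$trials)))
  invisible(x)
}

check_cohort_patterns <- function(patterns) {
  stopifnot(length(patterns) >= 2)
  for (p in patterns) {
    if (length(unique(p$labels)) < 2)
      stop("subject ", p$subject, " lacks one of the two classes")
  }
  nv <- vapply(patterns, function(p) ncol(p$X), integer(1))
  if (length(unique(nv)) != 1) stop("subjects have differing feature counts")
  invisible(TRUE)
}

#' Conjunction transfer decoder (pooled reference training)
#'
#' Trains one linear SVM on the pooled trials of all reference subjects (the
#' target excluded) as if they came from one individual in the common space,
#' and tests on every trial of the target subject.
#'
#' @param patterns list of `trial_patterns` in common coordinates with
#'   aligned feature columns, one per subject.
#' @param target index of the target subject within `patterns`.
#' @param C,tol SVM parameters, see [train_svm()].
#' @return a `decoding_result` (`accuracy` in percent; ties at decision value
#'   0 count as errors).
#' @export
conjunction_decode <- function(patterns, target, C = 1, tol = 1e-6) {
  check_cohort_patterns(patterns)
  refs <- setdiff(seq_along(patterns), target)
  Xtr <- do.call(rbind, lapply(patterns[refs], `[[`, "X"))
  ytr <- unlist(lapply(patterns[refs], `[[`, "labels"))
  clf <- train_svm(Xtr, ytr, C = C, tol = tol)
  pred <- predict(clf, patterns[[target]]$X)
  decoding_result("conjunction", patterns[[target]]$subject,
                  patterns[[target]]$labels, as.integer(pred),
                  attr(pred, "decision"))
}

#' Naive-voting transfer decoder (per-subject classifiers, majority vote)
#'
#' One linear SVM per reference subject; each votes on every target trial and
#' the majority wins. An exact tie is scored as a miss regardless of the true
#' label.
#'
#' @inheritParams conjunction_decode
#' @return a `decoding_result`; per-trial vote sums are in `$votes`.
#' @export
voting_decode <- function(patterns, target, C = 1, tol = 1e-6) {
  check_cohort_patterns(patterns)
  refs <- setdiff(seq_along(patterns), target)
  votes <- matrix(0L, nrow(patterns[[target]]$X), length(refs))
  for (i in seq_along(refs)) {
    clf <- train_svm(patterns[[refs[i]]]$X, patterns[[refs[i]]]$labels,
                     C = C, tol = tol)
    votes[, i] <- as.integer(sign(predict(clf, patterns[[target]]$X)))
  }
  tally <- rowSums(votes)
  pred <- sign(tally)  # 0 on ties -> never equals a +/-1 label -> miss
  decoding_result("voting", patterns[[target]]$subject,
                  patterns[[target]]$labels, as.integer(pred),
                  extra = list(votes = tally))
}

#' Self decoder (leave-one-run-out within one subject)
#'
#' Per fold, trains on all runs but one and tests on the held-out run;
#' accuracy is the average over folds. Folds whose training set lacks a
#' class are skipped with a warning.
#'
#' @param patterns a `trial_patterns` for one subject (with `runs` ids).
#' @param C,tol SVM parameters.
#' @return a `decoding_result` with per-fold accuracies in `$folds`.
#' @export
self_decode <- function(patterns, C = 1, tol = 1e-6) {
  runs <- unique(patterns$runs)
  if (length(runs) < 2) stop("self-decoding needs at least 2 runs")
  fold_acc <- numeric(0)
  truth <- pred <- integer(0)
  for (r in runs) {
    tr <- patterns$runs != r
    if (length(unique(patterns$labels[tr])) < 2) {
      warning("fold for run ", r, " has single-class training data; skipped")
      next
    }
    clf <- train_svm(patterns$X[tr, , drop = FALSE], patterns$labels[tr],
                     C = C, tol = tol)
    p <- as.integer(sign(predict(clf, patterns$X[!tr, , drop = FALSE])))
    fold_acc <- c(fold_acc, mean(p == patterns$labels[!tr]) * 100)
    truth <- c(truth, patterns$labels[!tr])
    pred <- c(pred, p)
  }
  if (length(fold_acc) == 0) stop("no usable folds")
  out <- decoding_result("self", patterns$subject, truth, pred)
  out$accuracy <- mean(fold_acc)
  out$folds <- fold_acc
  out
}

#' Leave-one-subject-out transfer decoding over a cohort
#'
#' Runs [conjunction_decode()] or [voting_decode()] with every subject as the
#' target in turn, optionally preceded by supervised voxel selection
#' ([select_voxels()]) computed on the reference subjects of each fold only.
#'
#' @param patterns list of `trial_patterns` in common coordinates.
#' @param scheme `"conjunction"` or `"voting"`.
#' @param fraction voxel fraction for within-fold selection (1 = no selection).
#' @param C,tol SVM parameters.
#' @return data frame with one row per target subject (`subject`,
#'   `accuracy`); the `decoding_result`s are in `attr(, "results")`.
#' @export
transfer_decode <- function(patterns, scheme = c("conjunction", "voting"),
                            fraction = 1, C = 1, tol = 1e-6) {
  scheme <- match.arg(scheme)
  fun <- if (scheme == "conjunction") conjunction_decode else voting_decode
  results <- list()
  for (tgt in seq_along(patterns)) {
    pats <- patterns
    if (fraction < 1) {
      sel <- select_voxels(pats[setdiff(seq_along(pats), tgt)], fraction)
      pats <- lapply(pats, function(p) {
        p$X <- p$X[, sel, drop = FALSE]
        p
      })
    }
    results[[tgt]] <- fun(pats, tgt, C = C, tol = tol)
  }
  out <- data.frame(
    subject = vapply(patterns, function(p) as.character(p$subject), character(1)),
    accuracy = vapply(results, `[[`, numeric(1), "accuracy"))
  attr(out, "results") <- results
  out
}
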