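#' Enumerate the tkNN hyperparameter grid
#'
#' The fixed 60-configuration grid: k = 1..10 (outer), distance in {L1, L2}
#' (middle), weight in {equal, inverse, squared_inverse} (inner), so config 1
#' is (k = 1, L1, equal) and config 60 is (k = 10, L2, squared_inverse).
#'
#' @return A 60-row data.frame with columns `k`, `distance`, `weight`.
#' @export
enumerate_configs <- function() {
  grid <- expand.grid(weight = c("equal", "inverse", "squared_inverse"),
                      distance = c("L1", "L2"),
                      k = 1:10,
                      stringsAsFactors = FALSE)
  data.frame(k = grid$k, distance = grid$distance, weight = grid$weight,
             stringsAsFactors = FALSE)
}

# elementwise mode of the first q columns of an integer label matrix (columns
# already in descending-accuracy order); ties break toward the label of the
# most accurate contributing column, then the smallest level
vote_mode <- function(P, q, nlev) {
  Pq <- P[, seq_len(q), drop = FALSE]
  counts <- vapply(seq_len(nlev), function(l) rowSums(Pq == l),
                   numeric(nrow(Pq)))
  if (is.null(dim(counts))) counts <- matrix(counts, nrow = 1L)
  top <- max.col(counts, ties.method = "first")
  mx <- counts[cbind(seq_len(nrow(Pq)), top)]
  ties <- which(rowSums(counts == mx) > 1L)
  for (i in ties) {
    tied <- which(counts[i, ] == mx[i])
    hit <- Pq[i, ][match(TRUE, Pq[i, ] %in% tied)]
    top[i] <- if (is.na(hit)) min(tied) else hit
  }
  as.integer(top)
}

#' tkNN: ensemble k-nearest-neighbor with iterative majority voting
#'
#' Fits the full t-algorithm over kNN on a labeled feature matrix:
#' \enumerate{
#'   \item 60 cross-validated prediction vectors, one per grid configuration
#'     ([enumerate_configs()]), all on one shared stratified fold split;
#'   \item the 60 outcomes are sorted by descending accuracy (stable; earlier
#'     config first) and, for each q = 3..60, the elementwise mode of the
#'     top-q vectors yields 58 iterative-majority-voting (IMV) outcomes;
#'   \item a greedy pass keeps the single most accurate of the pooled 118
#'     outcomes (ties: classifier-wise before voted, then lower index).
#' }
#'
#' The greedy winner is chosen on the same labels the ensemble was scored on,
#' exactly as the protocol prescribes; the reported `final_accuracy` is
#' therefore an optimistically biased model-selection quantity, not an
#' unbiased generalization estimate. Judge generalization on held-out data
#' via [predict.tknn()].
#'
#' @param x numeric feature matrix (samples x features), typically the
#'   INCA-selected columns.
#' @param y class labels (factor, >= 2 classes).
#' @param folds integer fold assignment; default a fresh stratified split.
#' @param nfolds,seed fold construction when `folds` is `NULL`.
#' @param standardize z-score features within training folds (default `TRUE`).
#' @return An object of class `"tknn"` with components `configs`,
#'   `classifier_outcomes` (n x 60 factor matrix), `classifier_accuracy`
#'   (length 60), `sort_order`, `voted_outcomes` (n x 58), `voted_accuracy`,
#'   `final_labels`, `final_accuracy`, `source` (winner provenance),
#'   `confusion`, `folds`, `levels`, `call`.
#' @examples
#' set.seed(1)
#' x <- rbind(matrix(rnorm(60, 0), 30), matrix(rnorm(60, 4), 30))
#' fit <- tknn(x, rep(c("a", "b"), each = 30), seed = 2)
#' fit$final_accuracy
#' @export
tknn <- function(x, y, folds = NULL, nfolds = 10L, seed = 1L,
                 standardize = TRUE) {
  cl <- match.call()
  x <- as.matrix(x)
  y <- factor(y)
  n <- nrow(x)
  if (length(y) != n) stop("'y' length must match rows of 'x'")
  if (nlevels(y) < 2L) stop("tkNN needs at least 2 classes")
  if (is.null(folds)) folds <- make_folds(y, nfolds, seed)
  configs <- enumerate_configs()
  m <- nrow(configs)

  preds <- matrix(NA_integer_, n, m)
  cacc <- numeric(m)
  for (r in seq_len(m)) {
    cv <- cv_predict(x, y, folds, k = configs$k[r],
                     distance = configs$distance[r],
                     weight = configs$weight[r], standardize = standardize)
    preds[, r] <- as.integer(cv$labels)
    cacc[r] <- cv$accuracy
  }

  ix <- order(-cacc, seq_len(m))        # stable descending-accuracy sort
  qs <- 3:m
  voted <- matrix(NA_integer_, n, length(qs))
  vacc <- numeric(length(qs))
  yi <- as.integer(y)
  sorted <- preds[, ix, drop = FALSE]
  for (h in seq_along(qs)) {
    voted[, h] <- vote_mode(sorted, qs[h], nlevels(y))
    vacc[h] <- mean(voted[, h] == yi)
  }

  pooled <- c(cacc, vacc)               # classifier-first pooling order
  win <- which.max(pooled)              # first max = documented tie rule
  if (win <= m) {
    final <- preds[, win]
    source <- list(type = "classifier", index = win,
                   config = configs[win, ])
  } else {
    h <- win - m
    final <- voted[, h]
    source <- list(type = "voted", q = qs[h],
                   top_configs = ix[seq_len(qs[h])])
  }
  final <- factor(levels(y)[final], levels = levels(y))

  structure(list(configs = configs,
                 classifier_outcomes = preds,
                 classifier_accuracy = cacc,
                 sort_order = ix,
                 voted_outcomes = voted,
                 voted_accuracy = vacc,
                 final_labels = final,
                 final_accuracy = pooled[win],
                 source = source,
                 confusion = confusion_matrix(y, final),
                 folds = folds,
                 levels = levels(y),
                 standardize = standardize,
                 x = x, y = y,
                 call = cl),
            class = "tknn")
}

#' @export
print.tknn <- function(x, ...) {
  cat("tkNN ensemble (60 configurations + 58 voted outcomes)\n")
  cat("call: "); print(x$call)
  src <- if (x$source$type == "classifier")
    sprintf("configuration %d (k=%d, %s, %s)", x$source$index,
            x$source$config$k, x$source$config$distance,
            x$source$config$weight)
  else sprintf("majority vote of the top %d configurations", x$source$q)
  cat(sprintf("winner: %s\nCV accuracy: %.4f\n", src, x$final_accuracy))
  invisible(x)
}

#' Summarize a tkNN fit
#'
#' @param object a [tknn()] fit.
#' @param ... unused.
#' @return A list of class `"summary.tknn"` with the accuracy spread of the
#'   118 pooled outcomes, the winner, and per-class metrics of the final
#'   label vector.
#' @export
summary.tknn <- function(object, ...) {
  pooled <- c(object$classifier_accuracy, object$voted_accuracy)
  structure(list(fit = object,
                 n_outcomes = length(pooled),
                 accuracy_range = range(pooled),
                 best_classifier = max(object$classifier_accuracy),
                 best_voted = max(object$voted_accuracy),
                 metrics = classification_metrics(object$confusion)),
            class = "summary.tknn")
}

#' @export
print.summary.tknn <- function(x, ...) {
  print(x$fit)
  cat(sprintf("pooled outcomes: %d; accuracy range %.4f..%.4f\n",
              x$n_outcomes, x$accuracy_range[1L], x$accuracy_range[2L]))
  cat(sprintf("best classifier-wise %.4f, best voted %.4f\n",
              x$best_classifier, x$best_voted))
  print(x$metrics)
  invisible(x)
}

#' Predict new samples from a tkNN fit
#'
#' Refits the winning outcome on the full training data: a single kNN for a
#' classifier-wise winner, or the elementwise mode over the winning top-q
#' configurations for a voted winner (same tie rules as in training).
#'
#' @param object a [tknn()] fit.
#' @param newdata numeric matrix with the same feature columns as training.
#' @param ... unused.
#' @return Factor of predicted labels.
#' @export
predict.tknn <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  xtr <- object$x
  if (ncol(newdata) != ncol(xtr)) stop("'newdata' feature mismatch")
  if (object$standardize) {
    mu <- colMeans(xtr)
    sd <- apply(xtr, 2L, stats::sd)
    sd[sd == 0 | !is.finite(sd)] <- 1
    xtr <- scale(xtr, mu, sd)
    newdata <- scale(newdata, mu, sd)
  }
  cfg_pred <- function(r) {
    as.integer(knn_predict(xtr, object$y, newdata,
                           k = object$configs$k[r],
                           distance = object$configs$distance[r],
                           weight = object$configs$weight[r]))
  }
  if (object$source$type == "classifier") {
    out <- cfg_pred(object$source$index)
  } else {
    P <- vapply(object$source$top_configs, cfg_pred,
                integer(nrow(newdata)))
    if (is.null(dim(P))) P <- matrix(P, nrow = 1L)
    out <- vote_mode(P, ncol(P), length(object$levels))
  }
  factor(object$levels[out], levels = object$levels)
}

#' Iterative majority voting over accuracy-sorted outcomes
#'
#' Standalone IMV: sorts label vectors by descending accuracy (stable) and,
#' for each q = 3..m, returns the elementwise mode of the top-q vectors.
#'
#' @param outcomes n x m matrix of predicted labels (integer codes or a
#'   factor-level matrix); m >= 3.
#' @param accuracy length-m accuracy vector used for sorting.
#' @param nlev number of label levels (default `max(outcomes)`).
#' @return A list: `voted` (n x (m-2) integer matrix, column h is q = h+2)
#'   and `sort_order`.
#' @export
imv <- function(outcomes, accuracy, nlev = max(outcomes)) {
  outcomes <- as.matrix(outcomes)
  m <- ncol(outcomes)
  if (m < 3L) stop("IMV needs at least 3 outcomes")
  if (length(accuracy) != m) stop("'accuracy' length must equal the outcomes")
  ix <- order(-accuracy, seq_len(m))
  sorted <- outcomes[, ix, drop = FALSE]
  qs <- 3:m
  voted <- vapply(qs, function(q) vote_mode(sorted, q, nlev),
                  integer(nrow(outcomes)))
  if (is.null(dim(voted))) voted <- matrix(voted, nrow = 1L)
  list(voted = voted, sort_order = ix)
}
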