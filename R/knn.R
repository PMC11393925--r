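#' Stratified fold assignment
#'
#' Assigns each sample to one of `k` cross-validation folds, preserving class
#' proportions: within each class, indices are shuffled and dealt round-robin.
#' Deterministic given `seed`; the same assignment is shared by the INCA loss
#' and every tkNN configuration so all outcomes are comparable.
#'
#' @param y class labels (coerced to factor).
#' @param k number of folds (default 10).
#' @param seed integer seed for the within-class shuffle.
#' @return Integer vector of fold ids in `1..k`, one per sample.
#' @export
make_folds <- function(y, k = 10L, seed = 1L) {
  y <- factor(y)
  n <- length(y)
  if (k < 2L || k > n) stop("'k' must be in 2..n")
  folds <- integer(n)
  rs <- local_rng(seed)
  on.exit(rs())
  for (cl in levels(y)) {
    idx <- which(y == cl)
    idx <- idx[sample.int(length(idx))]
    folds[idx] <- rep_len(seq_len(k), length(idx))
  }
  folds
}

# run code under a temporary RNG state; returns the restore function
local_rng <- function(seed) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  function() {
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  }
}

# test x train distance matrix under L1 (Manhattan) or L2 (Euclidean)
pair_dist <- function(test, train, distance) {
  if (distance == "L2") {
    d2 <- outer(rowSums(test^2), rowSums(train^2), `+`) -
      2 * tcrossprod(test, train)
    sqrt(pmax(d2, 0))
  } else {
    t(apply(test, 1L, function(v) colSums(abs(t(train) - v))))
  }
}

#' Weighted k-nearest-neighbor prediction
#'
#' Predicts test labels from a training set under one hyperparameter
#' configuration: `k` neighbors, `L1` or `L2` distance, and a neighbor
#' weighting of `"equal"` (unweighted vote), `"inverse"` (1/d) or
#' `"squared_inverse"` (1/d^2). Under the inverse weightings an exact match
#' (distance 0) carries infinite weight: the prediction is then the majority
#' label among the zero-distance neighbors. Vote ties break toward the label
#' of the nearest neighbor holding a tied label, then the smallest factor
#' level.
#'
#' @param train numeric matrix of training samples (rows).
#' @param y training labels (factor).
#' @param test numeric matrix of test samples.
#' @param k number of neighbors.
#' @param distance `"L1"` or `"L2"`.
#' @param weight `"equal"`, `"inverse"` or `"squared_inverse"`.
#' @return Factor of predicted labels with the levels of `y`.
#' @export
knn_predict <- function(train, y, test, k = 1L,
                        distance = c("L2", "L1"),
                        weight = c("equal", "inverse", "squared_inverse")) {
  distance <- match.arg(distance)
  weight <- match.arg(weight)
  y <- factor(y)
  train <- as.matrix(train); test <- as.matrix(test)
  if (ncol(train) != ncol(test)) stop("train/test feature mismatch")
  k <- min(as.integer(k), nrow(train))
  D <- pair_dist(test, train, distance)
  lev <- levels(y)
  yi <- as.integer(y)
  out <- integer(nrow(test))
  for (i in seq_len(nrow(test))) {
    d <- D[i, ]
    ord <- order(d, seq_along(d))
    nn <- ord[seq_len(k)]
    if (weight != "equal" && d[nn[1L]] == 0) {
      zero <- which(d == 0)
      tab <- tabulate(yi[zero], nbins = length(lev))
    } else {
      w <- switch(weight,
                  equal = rep(1, k),
                  inverse = 1 / d[nn],
                  squared_inverse = 1 / d[nn]^2)
      tab <- vapply(seq_along(lev), function(l) sum(w[yi[nn] == l]), 0)
    }
    best <- which(tab == max(tab))
    if (length(best) > 1L) {
      # nearest neighbor whose label is among the tied labels decides
      hit <- yi[ord][match(TRUE, yi[ord] %in% best)]
      best <- if (is.na(hit)) min(best) else hit
    }
    out[i] <- best
  }
  factor(lev[out], levels = lev)
}

#' Cross-validated kNN predictions
#'
#' Predicts every sample from a kNN fitted on the other folds, under one
#' configuration, and reports the pooled out-of-fold label vector and its
#' accuracy. Features are z-scored with training-fold statistics before
#' distances are computed (constant features get unit scale).
#'
#' @param x numeric feature matrix (samples x features).
#' @param y class labels.
#' @param folds integer fold assignment from [make_folds()]; every fold must
#'   contain every class.
#' @param k,distance,weight kNN configuration, as in [knn_predict()].
#' @param standardize z-score features within training folds (default `TRUE`).
#' @return A list: `labels` (factor, one out-of-fold prediction per sample)
#'   and `accuracy` (fraction correct).
#' @export
cv_predict <- function(x, y, folds, k = 1L, distance = "L2",
                       weight = "equal", standardize = TRUE) {
  x <- as.matrix(x)
  y <- factor(y)
  if (length(folds) != nrow(x)) stop("'folds' length must match rows of 'x'")
  for (f in unique(folds)) {
    if (nlevels(droplevels(y[folds != f])) < nlevels(y))
      stop("fold ", f, " removes all samples of a class from training")
  }
  pred <- factor(rep(NA_character_, nrow(x)), levels = levels(y))
  for (f in sort(unique(folds))) {
    tr <- folds != f
    xtr <- x[tr, , drop = FALSE]
    xte <- x[!tr, , drop = FALSE]
    if (standardize) {
      mu <- colMeans(xtr)
      sd <- apply(xtr, 2L, stats::sd)
      sd[sd == 0 | !is.finite(sd)] <- 1
      xtr <- scale(xtr, mu, sd)
      xte <- scale(xte, mu, sd)
    }
    pred[!tr] <- knn_predict(xtr, y[tr], xte, k = k,
                             distance = distance, weight = weight)
  }
  list(labels = pred, accuracy = mean(pred == y))
}
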