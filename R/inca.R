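#' Iterative NCA feature selection
#'
#' Ranks all features by descending [nca_weights()] relevance, then evaluates
#' every prefix size `k` in `size_range` by the stratified 10-fold
#' cross-validated accuracy of a loss kNN (default 1-NN, Euclidean, equal
#' weights) on the top-`k` features, and keeps the accuracy-maximizing
#' prefix. Accuracy ties go to the smallest size (parsimony). Rank ties go to
#' the lower feature index (stable).
#'
#' @param x feature matrix (samples x features) or a `"feature_matrix"`.
#' @param y class labels; taken from the feature matrix when `x` is one.
#' @param size_range integer vector `c(lo, hi)` of prefix sizes to try;
#'   default `c(10, p)` clipped to the feature count (for the 196-feature
#'   ChannelPat matrix this is the 10..196 sweep, 187 candidate subsets).
#' @param folds fold assignment to reuse; default a fresh [make_folds()]
#'   under `seed`.
#' @param nfolds,seed fold construction when `folds` is `NULL`.
#' @param loss_k,loss_distance,loss_weight the loss kNN configuration.
#' @param ... passed to [nca_weights()].
#' @return An object of class `"inca_selection"`: `ranked_indices` (all
#'   features, best first), `chosen_indices` (the winning prefix, in rank
#'   order), `chosen_size`, `per_size_accuracy` (named numeric over the
#'   range), `weights`, `folds`.
#' @export
inca_select <- function(x, y = NULL, size_range = NULL, folds = NULL,
                        nfolds = 10L, seed = 1L, loss_k = 1L,
                        loss_distance = "L2", loss_weight = "equal", ...) {
  if (inherits(x, "feature_matrix")) {
    if (is.null(y)) y <- x$labels
    x <- x$x
  }
  x <- as.matrix(x)
  y <- factor(y)
  p <- ncol(x)
  if (is.null(size_range)) size_range <- c(min(10L, p), p)
  size_range <- as.integer(size_range)
  lo <- min(size_range); hi <- max(size_range)
  if (lo < 1L || hi > p)
    stop("'size_range' must lie within [1, ", p, "]")
  if (is.null(folds)) folds <- make_folds(y, nfolds, seed)

  w <- nca_weights(x, y, ...)
  ranked <- order(-w, seq_len(p))
  sizes <- lo:hi
  acc <- vapply(sizes, function(k) {
    cv_predict(x[, ranked[seq_len(k)], drop = FALSE], y, folds,
               k = loss_k, distance = loss_distance,
               weight = loss_weight)$accuracy
  }, 0)
  names(acc) <- sizes
  chosen_size <- sizes[which.max(acc)]  # first max = smallest size
  structure(list(ranked_indices = ranked,
                 chosen_indices = ranked[seq_len(chosen_size)],
                 chosen_size = chosen_size,
                 per_size_accuracy = acc,
                 weights = as.numeric(w),
                 folds = folds),
            class = "inca_selection")
}

#' @export
print.inca_selection <- function(x, ...) {
  rng <- range(as.integer(names(x$per_size_accuracy)))
  cat(sprintf("INCA selection: %d features chosen from sizes %d..%d (%d evaluated)\n",
              x$chosen_size, rng[1L], rng[2L], length(x$per_size_accuracy)))
  cat(sprintf("best CV accuracy: %.4f\n", max(x$per_size_accuracy)))
  cat("top features:", paste(utils::head(x$chosen_indices, 10L),
                             collapse = ", "),
      if (x$chosen_size > 10L) "..." else "", "\n")
  invisible(x)
}
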