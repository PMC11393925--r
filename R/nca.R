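#' Neighborhood component analysis feature weights
#'
#' Learns one nonnegative relevance weight per feature by maximizing the
#' regularized softmax leave-one-out nearest-neighbor objective. With
#' per-feature scale parameters `w`, the weighted distance between samples
#' `i` and `j` is `d_ij = sum_r w_r^2 |x_ir - x_jr|`; sample `i` picks
#' neighbor `j` with probability `p_ij = exp(-d_ij) / sum_{l != i} exp(-d_il)`
#' and the objective is the expected leave-one-out accuracy
#' `F(w) = (1/n) sum_i sum_{j in class(i)} p_ij - lambda * sum_r w_r^2`.
#' `F` is maximized by L-BFGS with the analytic gradient, from a flat start
#' `w = 1`. The reported weight of feature `r` is `w_r^2`, so higher means
#' more class-informative and irrelevant features are driven toward zero.
#'
#' Features are z-scored internally before fitting (raw transition counts are
#' heavy-tailed); the weights refer to the standardized features.
#'
#' @param x numeric feature matrix (samples x features) or a
#'   `"feature_matrix"` from [build_feature_matrix()].
#' @param y class labels (>= 2 classes, >= 2 samples each); taken from the
#'   feature matrix when `x` is one.
#' @param lambda L2 regularization strength; default `1/n`.
#' @param standardize z-score features first (default `TRUE`).
#' @param maxit L-BFGS iteration cap.
#' @return Numeric vector of nonnegative per-feature weights, with the final
#'   objective value in attribute `"objective"`.
#' @export
nca_weights <- function(x, y = NULL, lambda = NULL, standardize = TRUE,
                        maxit = 60L) {
  if (inherits(x, "feature_matrix")) {
    if (is.null(y)) y <- x$labels
    x <- x$x
  }
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  y <- factor(y)
  n <- nrow(x); p <- ncol(x)
  if (nlevels(y) < 2L) stop("NCA needs at least 2 classes")
  if (any(table(y) < 2L)) stop("NCA needs at least 2 samples per class")
  if (length(y) != n) stop("'y' length must match rows of 'x'")
  if (is.null(lambda)) lambda <- 1 / n
  if (standardize) {
    sd <- apply(x, 2L, stats::sd)
    constant <- sd == 0 | !is.finite(sd)
    if (all(constant)) {
      warning("all features are constant; NCA weights are degenerate")
      return(structure(rep(0, p), objective = NA_real_))
    }
    sd[constant] <- 1
    x <- scale(x, colMeans(x), sd)
  }
  same <- outer(y, y, `==`)
  diag(same) <- FALSE

  # pairwise per-feature |x_ir - x_jr| stacked as an n*n x p matrix
  ii <- rep(seq_len(n), times = n)
  jj <- rep(seq_len(n), each = n)
  absdiff <- abs(x[ii, , drop = FALSE] - x[jj, , drop = FALSE])

  softmax_rows <- function(negd) {
    m <- apply(negd, 1L, max)
    e <- exp(negd - m)
    diag(e) <- 0
    e / rowSums(e)
  }
  objective <- function(w) {
    d <- matrix(absdiff %*% (w^2), n, n)
    P <- softmax_rows(-d)
    mean(rowSums(P * same)) - lambda * sum(w^2)
  }
  gradient <- function(w) {
    d <- matrix(absdiff %*% (w^2), n, n)
    P <- softmax_rows(-d)
    pin <- rowSums(P * same)
    # coefficient on |x_ir - x_jr|: p_i * p_ij - [j in class(i)] p_ij
    Cf <- P * pin - P * same
    g <- crossprod(absdiff, as.vector(Cf))  # row i + (j-1)n of absdiff is (i, j)
    (2 * w / n) * as.vector(g) - 2 * lambda * w
  }
  fit <- stats::optim(rep(1, p), fn = objective, gr = gradient,
                      method = "L-BFGS-B",
                      control = list(fnscale = -1, maxit = maxit))
  w2 <- fit$par^2
  if (stats::sd(w2) == 0 && p > 1L)
    warning("NCA weights are all equal; selection order is degenerate")
  structure(w2, objective = fit$value)
}
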