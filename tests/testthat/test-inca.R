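make_signal_matrix <- function(n = 60, p = 10, seed = 1, sd_signal = 0.2) {
  set.seed(seed)
  y <- factor(rep(c("a", "b"), each = n / 2))
  x <- matrix(rnorm(n * p), n, p)
  x[, 1] <- as.integer(y) + rnorm(n, 0, sd_signal)
  list(x = x, y = y)
}

test_that("the label-carrying feature gets the top NCA weight", {
  d <- make_signal_matrix(seed = 21)
  w <- nca_weights(d$x, d$y)
  expect_true(all(is.finite(w)) && all(w >= 0))
  expect_equal(which.max(w), 1L)
  # cross-check informativeness ranking with a leave-one-out 1-NN oracle
  loo <- vapply(seq_len(ncol(d$x)), function(j) loo_1nn_single(d$x[, j], d$y), 0)
  expect_equal(which.max(loo), 1L)
})

test_that("duplicated features get equal weights; permutation permutes weights", {
  d <- make_signal_matrix(n = 40, p = 5, seed = 3)
  x <- cbind(d$x, d$x[, 1])  # feature 6 duplicates feature 1
  w <- nca_weights(x, d$y)
  expect_equal(w[1], w[6], tolerance = 1e-4)

  perm <- c(3, 1, 5, 2, 4)
  w0 <- nca_weights(d$x, d$y)
  wp <- nca_weights(d$x[, perm], d$y)
  expect_equal(as.numeric(wp), as.numeric(w0)[perm], tolerance = 1e-5)
})

test_that("NCA rejects degenerate inputs", {
  d <- make_signal_matrix(n = 20, p = 4)
  expect_error(nca_weights(d$x, rep("a", 20)), "2 classes")
  expect_warning(nca_weights(matrix(1, 20, 4), d$y), "constant")
})

test_that("INCA evaluates the whole size range and returns the best prefix", {
  d <- make_signal_matrix(n = 40, p = 12, seed = 5)
  sel <- inca_select(d$x, d$y, size_range = c(2, 9), seed = 1)
  expect_identical(as.integer(names(sel$per_size_accuracy)), 2:9)
  expect_identical(sel$chosen_indices,
                   sel$ranked_indices[seq_len(sel$chosen_size)])
  expect_equal(max(sel$per_size_accuracy),
               sel$per_size_accuracy[[as.character(sel$chosen_size)]])
  # chosen accuracy dominates every evaluated size by construction
  expect_true(all(sel$per_size_accuracy <=
                    sel$per_size_accuracy[[as.character(sel$chosen_size)]]))
  expect_error(inca_select(d$x, d$y, size_range = c(2, 13)), "within")
})

test_that("a single-size range returns exactly the top-k ranked features", {
  d <- make_signal_matrix(n = 40, p = 8, seed = 6)
  sel <- inca_select(d$x, d$y, size_range = c(3, 3), seed = 2)
  expect_equal(sel$chosen_size, 3L)
  expect_identical(sel$chosen_indices, sel$ranked_indices[1:3])
})

test_that("selection is deterministic given the fold seed", {
  d <- make_signal_matrix(n = 40, p = 8, seed = 7)
  s1 <- inca_select(d$x, d$y, size_range = c(2, 6), seed = 4)
  s2 <- inca_select(d$x, d$y, size_range = c(2, 6), seed = 4)
  expect_identical(s1$chosen_indices, s2$chosen_indices)
  expect_identical(s1$per_size_accuracy, s2$per_size_accuracy)
})

test_that("planted informative pair is recovered, checked against exhaustion", {
  d <- xor_signal_matrix(seed = 31, n = 40, p = 6)
  # exhaustive oracle over all 1- and 2-feature subsets: {1,2} is the unique
  # best pair and beats every singleton
  pairs <- utils::combn(6, 2)
  pair_acc <- apply(pairs, 2, function(cl) loo_1nn_subset(d$x, d$y, cl))
  single_acc <- vapply(1:6, function(j) loo_1nn_subset(d$x, d$y, j), 0)
  best <- pairs[, which.max(pair_acc)]
  expect_identical(sort(best), c(1L, 2L))
  expect_gt(max(pair_acc), max(single_acc))

  sel <- inca_select(d$x, d$y, size_range = c(1, 6), seed = 1)
  expect_true(all(c(1L, 2L) %in% sel$chosen_indices))
})
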