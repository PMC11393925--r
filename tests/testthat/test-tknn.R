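sep_data <- function(n_per = 20, seed = 1) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(n_per * 2, 0, 0.3), n_per),
             matrix(rnorm(n_per * 2, 5, 0.3), n_per))
  list(x = x, y = factor(rep(c("a", "b"), each = n_per)))
}

test_that("the configuration grid is the fixed 60-element enumeration", {
  cfg <- enumerate_configs()
  expect_equal(nrow(cfg), 60L)
  expect_equal(nrow(unique(cfg)), 60L)
  expect_equal(cfg$k[1], 1)
  expect_equal(cfg$distance[1], "L1")
  expect_equal(cfg$weight[1], "equal")
  expect_equal(sort(unique(cfg$k)), 1:10)
  expect_setequal(unique(cfg$distance), c("L1", "L2"))
  expect_setequal(unique(cfg$weight), c("equal", "inverse", "squared_inverse"))
})

test_that("kNN predictions match hand-computed neighbors on a toy set", {
  # 6 points on a line; L1 == L2 in 1D up to monotonicity
  train <- matrix(c(0, 1, 2, 10, 11, 12), ncol = 1)
  y <- factor(c("a", "a", "a", "b", "b", "b"))
  test <- matrix(c(1.4, 9.0), ncol = 1)
  # k=3, L1, equal: neighbors of 1.4 are {1,2,0} -> a; of 9.0 are {10,11,12}? no: {10,11,8?}
  # distances from 9.0: 9,8,7,1,2,3 -> neighbors {10,11,12} -> b
  got <- knn_predict(train, y, test, k = 3, distance = "L1", weight = "equal")
  expect_identical(as.character(got), c("a", "b"))

  # 2D hand-checked case, k=3 L1: point (2,2); train pts and L1 distances:
  # (0,0)->4 a, (1,2)->1 a, (3,3)->2 b, (5,5)->6 b, (2,4)->2 b, (0,3)->3 a
  tr2 <- rbind(c(0, 0), c(1, 2), c(3, 3), c(5, 5), c(2, 4), c(0, 3))
  y2 <- factor(c("a", "a", "b", "b", "b", "a"))
  got2 <- knn_predict(tr2, y2, matrix(c(2, 2), 1), k = 3,
                      distance = "L1", weight = "equal")
  expect_identical(as.character(got2), "b")  # neighbors (1,2),(3,3),(2,4): a,b,b
})

test_that("zero-distance duplicates dominate under inverse weighting", {
  train <- matrix(c(0, 0, 1, 2), ncol = 1)
  y <- factor(c("a", "a", "b", "b"))
  test <- matrix(0, 1)
  for (w in c("inverse", "squared_inverse")) {
    expect_identical(as.character(
      knn_predict(train, y, test, k = 3, distance = "L2", weight = w)), "a")
  }
  # k=1 equal: duplicate's label wins by nearest distance
  expect_identical(as.character(
    knn_predict(train, y, test, k = 1, weight = "equal")), "a")
})

test_that("1-NN L2 equal agrees with an established implementation", {
  skip_if_not_installed("class")
  set.seed(12)
  train <- matrix(rnorm(60), 30, 2)
  y <- factor(rep(c("a", "b"), 15))
  test <- matrix(rnorm(20), 10, 2)
  ours <- knn_predict(train, y, test, k = 1, distance = "L2", weight = "equal")
  ref <- class::knn(train, test, y, k = 1)
  expect_identical(as.character(ours), as.character(ref))
})

test_that("cross-validated predictions are out-of-fold and reject bad folds", {
  d <- sep_data(20, seed = 2)
  folds <- make_folds(d$y, 10, seed = 1)
  cv <- cv_predict(d$x, d$y, folds, k = 1)
  expect_equal(cv$accuracy, 1.0)            # well-separated clusters
  expect_length(cv$labels, 40L)
  bad <- ifelse(d$y == "a", 1L, 2L)          # fold 1 holds every 'a'
  expect_error(cv_predict(d$x, d$y, bad, k = 1), "removes all samples")
})

test_that("stratified folds balance classes and are seed-deterministic", {
  y <- factor(rep(c("a", "b"), c(30, 50)))
  f1 <- make_folds(y, 10, seed = 3)
  f2 <- make_folds(y, 10, seed = 3)
  expect_identical(f1, f2)
  expect_false(identical(f1, make_folds(y, 10, seed = 4)))
  per_fold <- table(f1, y)
  expect_true(all(per_fold[, "a"] == 3))
  expect_true(all(per_fold[, "b"] == 5))
})

test_that("IMV votes elementwise with the documented tie rule", {
  # top-3 vectors (already equal accuracy -> stable order kept)
  outcomes <- cbind(c(1, 1, 2), c(1, 2, 2), c(2, 1, 2))
  res <- imv(outcomes, accuracy = c(0.9, 0.8, 0.7), nlev = 2)
  expect_equal(ncol(res$voted), 1L)
  expect_equal(res$voted[, 1], c(1, 1, 2))

  # unanimity: every voted outcome equals the common vector
  m <- matrix(1, 5, 60)
  m[3, ] <- 2
  res2 <- imv(m, accuracy = runif(60), nlev = 2)
  expect_equal(ncol(res2$voted), 58L)
  expect_true(all(res2$voted == m[, 1]))

  # even-q tie: most accurate contributing outcome decides
  tie <- cbind(c(1, 2), c(2, 1), c(1, 2), c(2, 1))
  res3 <- imv(tie, accuracy = c(0.6, 0.9, 0.5, 0.4), nlev = 2)
  # sorted order: col2, col1, col3, col4; q=4 splits 2-2, col2 wins
  expect_equal(res3$voted[, 2], c(2, 1))

  expect_error(imv(outcomes[, 1:2], accuracy = c(0.5, 0.6)), "at least 3")
})

test_that("tknn pools 118 outcomes and the greedy winner dominates", {
  d <- sep_data(15, seed = 5)
  fit <- tknn(d$x, d$y, nfolds = 5, seed = 1)
  expect_s3_class(fit, "tknn")
  expect_equal(ncol(fit$classifier_outcomes), 60L)
  expect_equal(ncol(fit$voted_outcomes), 58L)
  pooled <- c(fit$classifier_accuracy, fit$voted_accuracy)
  expect_length(pooled, 118L)
  expect_equal(fit$final_accuracy, max(pooled))
  expect_true(all(fit$final_accuracy >= fit$classifier_accuracy))
  expect_equal(fit$final_accuracy, 1.0)  # separable clusters
  expect_output(print(fit), "winner")
  expect_output(print(summary(fit)), "pooled outcomes: 118")
})

test_that("q=60 vote depends only on the multiset of outcomes", {
  set.seed(20)
  outcomes <- matrix(sample(1:2, 25 * 60, TRUE), 25, 60)
  acc <- runif(60)
  perm <- sample(60)
  v1 <- imv(outcomes, acc, nlev = 2)$voted[, 58]
  v2 <- imv(outcomes[, perm], acc[perm], nlev = 2)$voted[, 58]
  expect_identical(v1, v2)
})

test_that("predict.tknn labels held-out separable data correctly", {
  d <- sep_data(15, seed = 6)
  fit <- tknn(d$x, d$y, nfolds = 5, seed = 1)
  new <- sep_data(10, seed = 99)
  expect_identical(as.character(predict(fit, new$x)), as.character(new$y))
  expect_error(predict(fit, new$x[, 1, drop = FALSE]), "mismatch")
})

test_that("tkNN final accuracy at permuted labels stays within binomial noise", {
  set.seed(77)
  n <- 100
  x <- matrix(rnorm(n * 15), n, 15)   # pure noise features
  y <- factor(rep(c("a", "b"), each = n / 2))
  fit <- tknn(x, sample(y), nfolds = 10, seed = 3)
  # majority rate 0.5; allow the greedy max-of-118 its selection slack of
  # ~3 binomial standard errors
  expect_lt(fit$final_accuracy, 0.5 + 3 * sqrt(0.25 / n))
})
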