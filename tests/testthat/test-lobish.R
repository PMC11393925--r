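test_that("feature ids decode to lobe-symbol pairs via the pair-code inverse", {
  lut <- lobe_lut()
  expect_identical(unname(feature_to_symbols(1, lut)[1, ]), c("F", "F"))
  # id 62 -> channels (5, 6) -> T7, P7 -> T P
  expect_identical(unname(feature_to_symbols(62, lut)[1, ]), c("T", "P"))
  expect_identical(unname(feature_to_symbols(196, lut)[1, ]), c("F", "F"))
  expect_error(feature_to_symbols(0, lut), "1\\.\\.196")
})

test_that("pair_code and feature_to_symbols round-trip over all 196 bins", {
  lut <- lobe_lut()
  for (a in 1:14) {
    for (b in 1:14) {
      id <- pair_code(a, b, 14) + 1L
      expect_identical(unname(feature_to_symbols(id, lut)[1, ]),
                       unname(c(lut[a], lut[b])))
    }
  }
})

test_that("sentences concatenate two symbols per feature in id order", {
  lut <- lobe_lut()
  expect_identical(as.character(lobish_sentence(1, lut)), "FF")
  expect_identical(as.character(lobish_sentence(c(62, 1), lut)), "TPFF")
  s <- lobish_sentence(sample(1:196, 144), lut)
  expect_equal(nchar(unclass(s)), 288L)
  expect_warning(empty <- lobish_sentence(integer(0), lut), "empty")
  expect_identical(as.character(empty), "")
})

test_that("sentence histogram equals the LUT image of the decoded channels", {
  lut <- lobe_lut()
  set.seed(13)
  for (rep in 1:5) {
    ids <- sample(1:196, 8)
    ab <- pair_decode(ids, 14)
    expected <- table(factor(unclass(lut)[c(t(ab))],
                             levels = c("F", "T", "P", "O")))
    got <- lobe_histogram(lobish_sentence(ids, lut))
    expect_identical(unname(got), as.integer(expected))
  }
})

test_that("basic symbol-count and transition cases", {
  expect_identical(lobe_histogram("FFFF"),
                   c(F = 4L, T = 0L, P = 0L, O = 0L))
  expect_identical(lobe_histogram("FTPO"),
                   c(F = 1L, T = 1L, P = 1L, O = 1L))
  tc <- transition_counts("FT")
  expect_equal(tc["F", "T"], 1L)
  expect_equal(sum(tc), 1L)
  expect_error(lobe_histogram("FXPO"), "alphabet")
  expect_error(transition_counts("F"), "at least 2")
})

test_that("transition counts always sum to length - 1", {
  set.seed(14)
  for (rep in 1:10) {
    s <- paste(sample(c("F", "T", "P", "O"), sample(2:50, 1), TRUE),
               collapse = "")
    expect_equal(sum(transition_counts(s)), nchar(s) - 1L)
  }
})

test_that("entropy has the right bounds, degenerate and uniform cases", {
  expect_equal(shannon_entropy(c(1, 1, 1, 1)), 2)
  expect_equal(shannon_entropy(c(5, 0, 0, 0)), 0)
  expect_equal(shannon_entropy(rep(3, 16)), 4)
  set.seed(15)
  for (rep in 1:10) {
    h <- shannon_entropy(rmultinom(1, 100, runif(4)))
    expect_gte(h, 0); expect_lte(h, 2)
    ht <- shannon_entropy(rmultinom(1, 200, runif(16)))
    expect_lte(ht, 4)
  }
  expect_error(shannon_entropy(c(0, 0)), "undefined")
  expect_error(shannon_entropy(c(-1, 2)), "nonnegative")
})

test_that("transition matrices are row-stochastic with zero rows flagged", {
  counts <- matrix(0L, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  counts[1, 3] <- 5L
  tm <- transition_matrix(counts)
  expect_equal(tm[1, ], c(A = 0, B = 0, C = 1, D = 0))
  expect_identical(as.integer(attr(tm, "zero_rows")), 2:4)

  set.seed(16)
  rnd <- matrix(rpois(16, 3), 4)
  tm2 <- transition_matrix(rnd)
  nz <- rowSums(rnd) > 0
  expect_equal(unname(rowSums(tm2)[nz]), rep(1, sum(nz)), tolerance = 1e-9)
})

test_that("the 288-symbol reference sentence reproduces all its statistics", {
  sen <- reference_sentence()
  expect_equal(nchar(sen), 288L)
  rep <- lobish_report(sen)

  expect_identical(rep$symbol_counts, c(F = 158L, T = 44L, P = 45L, O = 41L))

  tc <- rep$transition_counts
  expected <- c(FF = 86, TT = 3, PP = 6, OO = 5, FT = 25, FP = 24, FO = 23,
                TP = 9, TO = 6, PO = 7, TF = 26, PF = 24, OF = 22, PT = 8,
                OT = 7, OP = 6)
  for (nm in names(expected)) {
    expect_equal(tc[substr(nm, 1, 1), substr(nm, 2, 2)],
                 unname(expected[nm]), label = nm)
  }
  expect_equal(sum(tc), 287L)

  expect_equal(rep$symbol_entropy_bits, 1.7081, tolerance = 1e-3)
  expect_equal(rep$transition_entropy_bits, 3.3986, tolerance = 1e-3)

  # remaining in F is the most likely move out of F
  expect_equal(which.max(rep$transition_matrix["F", ]), c(F = 1L))
})

test_that("the gloss table annotates all 16 ordered transitions", {
  g <- lobish_gloss()
  expect_equal(nrow(g), 16L)
  expect_setequal(g$transition,
                  as.vector(outer(c("F", "T", "P", "O"),
                                  c("F", "T", "P", "O"), paste0)))
  rep <- lobish_report(c(1, 62))
  expect_identical(rep$gloss, g)
})
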