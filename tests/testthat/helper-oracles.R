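# Independent brute-force oracles, kept deliberately naive.

# all permutations of 1..n (n small)
all_perms <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (p in all_perms(n - 1L)) {
    for (pos in seq_len(n)) {
      out[[length(out) + 1L]] <- append(p, n, after = pos - 1L)
    }
  }
  out
}

# rank transform by enumeration: per column, among all permutations whose
# value sequence is non-increasing, take the lexicographically smallest
# (equal values -> lower channel index first)
oracle_transform <- function(m) {
  C <- nrow(m)
  perms <- all_perms(C)
  out <- integer(0)
  for (j in seq_len(ncol(m))) {
    v <- m[, j]
    ok <- Filter(function(p) all(diff(v[p]) <= 0), perms)
    key <- vapply(ok, function(p) paste(sprintf("%03d", p), collapse = ""), "")
    out <- c(out, ok[[which.min(key)]])
  }
  out
}

# transition histogram by scanning every ordered pair explicitly
oracle_features <- function(ranks, C) {
  counts <- matrix(0L, C, C)
  for (t in seq_len(length(ranks) - 1L)) {
    a <- ranks[t]; b <- ranks[t + 1L]
    counts[a, b] <- counts[a, b] + 1L
  }
  # flatten so that bin = C*(a-1) + b
  as.integer(t(counts))
}

# planted-signal matrix: features 1 and 2 jointly (and only jointly) carry
# the class signal in an XOR layout; the rest is standard Gaussian noise
xor_signal_matrix <- function(seed, n = 40, p = 12, sd_noise = 0.3) {
  set.seed(seed)
  y <- factor(rep(c("a", "b"), each = n / 2))
  x <- matrix(rnorm(n * p), n, p)
  half_a <- sample(rep(c(0, 1), length.out = n / 2))
  half_b <- sample(rep(c(0, 1), length.out = n / 2))
  x[y == "a", 1] <- 3 * half_a + rnorm(n / 2, 0, sd_noise)
  x[y == "a", 2] <- 3 * half_a + rnorm(n / 2, 0, sd_noise)
  x[y == "b", 1] <- 3 * half_b + rnorm(n / 2, 0, sd_noise)
  x[y == "b", 2] <- 3 * (1 - half_b) + rnorm(n / 2, 0, sd_noise)
  list(x = x, y = y)
}

# exhaustive subset oracle: LOO 1-NN (Euclidean) accuracy of a feature subset
loo_1nn_subset <- function(x, y, cols) {
  xs <- scale(x[, cols, drop = FALSE])
  n <- nrow(xs)
  correct <- 0L
  for (i in seq_len(n)) {
    d <- colSums((t(xs[-i, , drop = FALSE]) - xs[i, ])^2)
    if (y[-i][which.min(d)] == y[i]) correct <- correct + 1L
  }
  correct / n
}

# leave-one-out 1-NN accuracy of a single feature column (selection oracle)
loo_1nn_single <- function(v, y) {
  n <- length(v)
  correct <- 0L
  for (i in seq_len(n)) {
    d <- abs(v[-i] - v[i])
    nn <- which.min(d)
    if (y[-i][nn] == y[i]) correct <- correct + 1L
  }
  correct / n
}

# minimal EDF writer, independent of the package reader: fixed-width ASCII
# header fields + little-endian int16 records
write_edf_fixture <- function(path, data, labels, n_records = 1L,
                              physmin = -100, physmax = 100,
                              digmin = -32768, digmax = 32767) {
  ns <- nrow(data)
  spr <- ncol(data) / n_records
  stopifnot(spr == round(spr))
  pad <- function(x, w) formatC(as.character(x), width = w, flag = "-")
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(pad("0", 8), pad("patient", 80), pad("recording", 80),
                pad("01.01.24", 8), pad("00.00.00", 8),
                pad(256 * (1 + ns), 8), pad("", 44), pad(n_records, 8),
                pad(1, 8), pad(ns, 4))
  sig <- paste0(paste(pad(labels, 16), collapse = ""),
                paste(rep(pad("", 80), ns), collapse = ""),
                paste(rep(pad("uV", 8), ns), collapse = ""),
                paste(rep(pad(physmin, 8), ns), collapse = ""),
                paste(rep(pad(physmax, 8), ns), collapse = ""),
                paste(rep(pad(digmin, 8), ns), collapse = ""),
                paste(rep(pad(digmax, 8), ns), collapse = ""),
                paste(rep(pad("", 80), ns), collapse = ""),
                paste(rep(pad(spr, 8), ns), collapse = ""),
                paste(rep(pad("", 32), ns), collapse = ""))
  writeChar(paste0(hdr, sig), con, eos = NULL)
  # physical -> digital, rounded; records interleave channels
  dig <- round((data - physmin) / (physmax - physmin) *
                 (digmax - digmin) + digmin)
  for (r in seq_len(n_records)) {
    cols <- ((r - 1L) * spr + 1L):(r * spr)
    for (s in seq_len(ns)) {
      writeBin(as.integer(dig[s, cols]), con, size = 2L, endian = "little")
    }
  }
  invisible(path)
}

reference_sentence <- function() {
  readLines(system.file("extdata", "lobish_sentence_288.txt",
                        package = "channelpat"))
}
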