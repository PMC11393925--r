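#' Channel-rank transformation
#'
#' At every time point the C channel amplitudes are sorted in descending
#' order and the channel *indices* in that order are emitted, so a C x N
#' segment becomes a flat integer sequence of length C*N whose aligned
#' C-blocks are each a permutation of 1..C. The transform is invariant to any
#' strictly increasing rescaling of the amplitudes: only the per-timepoint
#' ordering of channels survives, which is what the downstream transition
#' features consume.
#'
#' Ties are broken stably: among equal amplitudes the lower channel index
#' comes first, so a constant column yields `1, 2, ..., C`.
#'
#' @param segment an [eeg_segment()] or a plain numeric channels x samples
#'   matrix with at least 2 rows.
#' @return Integer vector of length `C * N` of class `"rank_sequence"` with
#'   attribute `n_channels`.
#' @examples
#' seg <- eeg_segment(matrix(c(1, 2, 3, 0), 2, 2))  # columns (1,2) and (3,0)
#' channel_transform(seg)                            # 2 1 1 2
#' @export
channel_transform <- function(segment) {
  if (inherits(segment, "eeg_segment")) {
    m <- unclass(segment)
    attr(m, "segment_id") <- NULL
  } else {
    m <- as.matrix(segment)
  }
  if (!is.numeric(m) || nrow(m) < 2L)
    stop("'segment' must be a numeric matrix with at least 2 channels")
  if (any(!is.finite(m))) stop("segment contains non-finite values")
  C <- nrow(m)
  idx <- apply(m, 2L, function(v) order(-v, seq_len(C)))
  rank_sequence(as.integer(idx), C)
}

#' Rank-sequence constructor
#'
#' Validates and tags a flat channel-index sequence produced by
#' [channel_transform()]: length a multiple of `n_channels`, every aligned
#' block a permutation of `1..n_channels`.
#'
#' @param values integer vector of channel indices.
#' @param n_channels the channel count C.
#' @param check validate the block-permutation invariant (default `TRUE`).
#' @return `values` as an integer vector of class `"rank_sequence"`.
#' @export
rank_sequence <- function(values, n_channels, check = TRUE) {
  values <- as.integer(values)
  C <- as.integer(n_channels)
  if (C < 2L) stop("'n_channels' must be >= 2")
  if (length(values) %% C != 0L)
    stop("rank sequence length must be a multiple of n_channels")
  if (check) {
    blocks <- matrix(values, nrow = C)
    ok <- apply(blocks, 2L, function(b) identical(sort(b), seq_len(C)))
    if (!all(ok))
      stop("block ", which(!ok)[1L], " is not a permutation of 1..", C)
  }
  structure(values, n_channels = C, class = "rank_sequence")
}

#' @export
print.rank_sequence <- function(x, ...) {
  C <- attr(x, "n_channels")
  cat(sprintf("rank sequence: %d values (%d channels x %d time points)\n",
              length(x), C, length(x) %/% C))
  utils::str(as.integer(x))
  invisible(x)
}
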