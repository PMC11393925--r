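#' Base-C code of an ordered channel pair
#'
#' The transition from channel `a` to channel `b` is coded as the two-digit
#' base-C number `C*(a-1) + (b-1)`, giving codes `0 .. C^2-1`; histogram bins
#' are reported 1-based, `bin = code + 1`, so bin arithmetic lines up with the
#' 1-based feature ids used by the lobe-symbol decoder.
#'
#' @param a,b channel indices in `1..C` (vectorized, recycled).
#' @param n_channels the channel count C (and the base).
#' @return Integer code(s) in `0 .. C^2 - 1`.
#' @examples
#' pair_code(2, 1, 14)    # 14  (bin 15)
#' pair_code(14, 14, 14)  # 195 (bin 196)
#' @export
pair_code <- function(a, b, n_channels) {
  C <- as.integer(n_channels)
  a <- as.integer(a); b <- as.integer(b)
  if (any(a < 1L | a > C) || any(b < 1L | b > C))
    stop("channel indices must lie in 1..", C)
  C * (a - 1L) + (b - 1L)
}

#' Decode a 1-based feature bin back to its channel pair
#'
#' Exact inverse of [pair_code()] on bins: bin `id` maps to the ordered pair
#' `a = (id-1) %/% C + 1`, `b = (id-1) %% C + 1`.
#'
#' @param id feature bin index in `1..C^2` (vectorized).
#' @param n_channels the channel count C.
#' @return Integer matrix with columns `from` and `to`.
#' @export
pair_decode <- function(id, n_channels) {
  C <- as.integer(n_channels)
  id <- as.integer(id)
  if (any(id < 1L | id > C * C))
    stop("feature ids must lie in 1..", C * C)
  cbind(from = (id - 1L) %/% C + 1L, to = (id - 1L) %% C + 1L)
}

#' ChannelPat transition-histogram features
#'
#' Slides an overlapping window of length 2 along the flat rank sequence —
#' including across time-point boundaries — codes each ordered pair with
#' [pair_code()], and tabulates the codes into a `C^2`-bin histogram of raw
#' counts. For a C x N segment the counts always sum to `C*N - 1`. Counts are
#' left unnormalized; scaling is the selector/classifier's concern.
#'
#' @param ranks a `"rank_sequence"` from [channel_transform()], or an integer
#'   vector of channel indices (then `n_channels` is required).
#' @param n_channels channel count; taken from the rank sequence when absent.
#' @return Integer vector of length `C^2`, named `p<a>_<b>`.
#' @examples
#' r <- rank_sequence(c(2, 1, 1, 2), 2)
#' extract_features(r)   # pairs (2,1), (1,1), (1,2)
#' @export
extract_features <- function(ranks, n_channels = attr(ranks, "n_channels")) {
  if (is.null(n_channels)) stop("'n_channels' is required for plain vectors")
  C <- as.integer(n_channels)
  v <- as.integer(ranks)
  if (length(v) < 2L) stop("need at least 2 rank values to form a pair")
  if (any(v < 1L | v > C)) stop("rank values must lie in 1..", C)
  bins <- pair_code(v[-length(v)], v[-1L], C) + 1L
  counts <- tabulate(bins, nbins = C * C)
  names(counts) <- paste0("p", rep(seq_len(C), each = C), "_",
                          rep(seq_len(C), C))
  counts
}

#' Build the segments x features matrix
#'
#' Runs [channel_transform()] and [extract_features()] over a collection of
#' segments and stacks the histograms row-wise. All segments must share the
#' same channel count.
#'
#' @param x a list of [eeg_segment()] objects, or a manifest data.frame as
#'   returned by [read_manifest()] (columns `path`, `label`), in which case
#'   segments are read from disk.
#' @param labels class labels, one per segment; taken from the manifest when
#'   `x` is one. Optional (`NULL`) for unlabeled feature extraction.
#' @return A list of class `"feature_matrix"`: `x` (integer matrix, one row
#'   per segment, `C^2` columns), `labels` (factor or `NULL`), `n_channels`.
#' @export
build_feature_matrix <- function(x, labels = NULL) {
  if (is.data.frame(x)) {
    if (is.null(labels)) labels <- x$label
    x <- lapply(x$path, read_segment)
  }
  if (!is.list(x) || length(x) == 0L)
    stop("'x' must be a nonempty list of segments or a manifest data.frame")
  Cs <- vapply(x, nrow, 0L)
  if (length(unique(Cs)) != 1L)
    stop("segments have mixed channel counts: ",
         paste(unique(Cs), collapse = ", "))
  C <- Cs[1L]
  rows <- t(vapply(x, function(s) extract_features(channel_transform(s)),
                   integer(C * C)))
  ids <- vapply(x, function(s) attr(s, "segment_id") %||% "segment", "")
  rownames(rows) <- make.unique(ids)
  if (!is.null(labels)) {
    labels <- factor(labels)
    if (length(labels) != nrow(rows))
      stop("'labels' length must equal the number of segments")
  }
  structure(list(x = rows, labels = labels, n_channels = C),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("ChannelPat feature matrix: %d segments x %d features (C = %d)\n",
              nrow(x$x), ncol(x$x), x$n_channels))
  if (!is.null(x$labels)) print(table(x$labels))
  invisible(x)
}
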