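LOBES <- c("F", "T", "P", "O")

#' Decode feature bins to lobe-symbol pairs
#'
#' Each ChannelPat feature bin encodes an ordered channel pair; decoding the
#' bin with [pair_decode()] and mapping both channels through the lobe lookup
#' table yields two symbols of the four-letter lobe alphabet (F frontal,
#' T temporal, P parietal, O occipital).
#'
#' @param id feature bin index in `1..C^2` (vectorized).
#' @param lut a [lobe_lut()]; its length fixes C.
#' @return Character matrix with columns `from` and `to`.
#' @examples
#' feature_to_symbols(62, lobe_lut())   # channels (5,6) -> T P
#' @export
feature_to_symbols <- function(id, lut = lobe_lut()) {
  C <- length(lut)
  ab <- pair_decode(id, C)
  cbind(from = unclass(lut)[ab[, "from"]], to = unclass(lut)[ab[, "to"]])
}

#' Generate a Lobish sentence from selected features
#'
#' Concatenates the two lobe symbols of every feature id, in id order: a
#' selection of `m` features yields a sentence of `2m` symbols.
#'
#' @param ids ordered feature bin indices (e.g. `chosen_indices` of an
#'   [inca_select()] result).
#' @param lut a [lobe_lut()].
#' @return A character scalar of class `"lobish_sentence"` with the source
#'   ids in attribute `"provenance"`.
#' @export
lobish_sentence <- function(ids, lut = lobe_lut()) {
  if (length(ids) == 0L) {
    warning("no feature ids given; sentence is empty")
    return(structure("", provenance = integer(0),
                     class = "lobish_sentence"))
  }
  sym <- feature_to_symbols(ids, lut)
  structure(paste(as.vector(t(sym)), collapse = ""),
            provenance = as.integer(ids), class = "lobish_sentence")
}

#' @export
print.lobish_sentence <- function(x, ...) {
  cat(sprintf("Lobish sentence (%d symbols)\n", nchar(unclass(x))))
  cat(strwrap(unclass(x), width = 60), sep = "\n")
  invisible(x)
}

as_symbols <- function(sentence) {
  s <- if (is.character(sentence) && length(sentence) == 1L)
    strsplit(unclass(sentence), "")[[1L]] else as.character(sentence)
  bad <- setdiff(unique(s), LOBES)
  if (length(bad) > 0L)
    stop("symbols outside the {F,T,P,O} alphabet: ",
         paste(bad, collapse = ", "))
  s
}

#' Lobe symbol histogram
#'
#' @param sentence a Lobish sentence (single string or character vector of
#'   symbols).
#' @return Named integer vector of multiplicities over `F, T, P, O`.
#' @export
lobe_histogram <- function(sentence) {
  s <- as_symbols(sentence)
  if (length(s) == 0L) stop("empty sentence")
  counts <- table(factor(s, levels = LOBES))
  stats::setNames(as.integer(counts), LOBES)
}

#' Lobe transition counts
#'
#' Counts consecutive overlapping symbol pairs across the whole sentence
#' (positions i, i+1 for i = 1..len-1), including pairs that straddle the
#' boundary between the two symbols of adjacent features; the 16 counts
#' always sum to len - 1.
#'
#' @param sentence a Lobish sentence.
#' @return 4 x 4 integer matrix, rows = from-symbol, columns = to-symbol,
#'   in F, T, P, O order.
#' @export
transition_counts <- function(sentence) {
  s <- as_symbols(sentence)
  if (length(s) < 2L) stop("need at least 2 symbols to count transitions")
  from <- factor(s[-length(s)], levels = LOBES)
  to <- factor(s[-1L], levels = LOBES)
  tab <- table(from, to)
  matrix(as.integer(tab), 4L, 4L, dimnames = list(from = LOBES, to = LOBES))
}

#' Row-stochastic transition probability matrix
#'
#' Divides each row of a 4 x 4 transition count table by its row sum. Rows
#' with no outgoing transitions stay all-zero and are flagged in attribute
#' `"zero_rows"`.
#'
#' @param counts 4 x 4 transition count matrix from [transition_counts()].
#' @return 4 x 4 numeric matrix; every non-flagged row sums to 1.
#' @export
transition_matrix <- function(counts) {
  counts <- as.matrix(counts)
  if (!all(dim(counts) == 4L)) stop("'counts' must be 4 x 4")
  if (any(counts < 0)) stop("negative transition counts")
  rs <- rowSums(counts)
  out <- counts / ifelse(rs == 0, 1, rs)
  dimnames(out) <- dimnames(counts) %||% list(from = LOBES, to = LOBES)
  structure(out, zero_rows = which(rs == 0))
}

#' Shannon entropy of a count distribution
#'
#' `-sum(p * log2(p))` over the positive-probability cells of the empirical
#' distribution `p = counts / sum(counts)`, in bits; `0 * log 0` is 0. A
#' uniform distribution over m cells attains the maximum `log2(m)`.
#'
#' @param counts nonnegative numeric vector or matrix of counts with at
#'   least one positive entry.
#' @return Entropy in bits.
#' @examples
#' shannon_entropy(c(1, 1, 1, 1))  # 2 bits
#' @export
shannon_entropy <- function(counts) {
  counts <- as.numeric(counts)
  if (any(counts < 0)) stop("counts must be nonnegative")
  tot <- sum(counts)
  if (tot == 0) stop("all counts are zero; entropy is undefined")
  p <- counts[counts > 0] / tot
  -sum(p * log2(p))
}

#' Two-letter Lobish transition glosses
#'
#' Static annotation table pairing each of the 16 ordered lobe transitions
#' with its cognitive-process reading (e.g. FF = sustained cognitive effort,
#' OF = visual information feeding cognitive processes). Attached to reports
#' for interpretation; never used in computation.
#'
#' @return A 16-row data.frame with columns `transition` and `gloss`.
#' @export
lobish_gloss <- function() {
  data.frame(
    transition = c("FF", "TT", "PP", "OO", "FT", "FP", "FO", "TP",
                   "TO", "PO", "TF", "PF", "OF", "PT", "OT", "OP"),
    gloss = c(
      "sustained cognitive effort",
      "continuous auditory processing or memory recall",
      "ongoing sensory integration and spatial processing",
      "continuous visual processing",
      "planning/decision-making to memory or speech comprehension",
      "cognitive tasks to sensory integration",
      "planning/thinking to visual analysis",
      "auditory/memory information assisting sensory processing",
      "auditory input driving visual memory or interpretation",
      "sensory-spatial integration with visual processing",
      "auditory/memory information used for planning",
      "sensory information handed to cognitive tasks",
      "visual information feeding cognitive processes",
      "sensory information integrated with memory/audition",
      "visual stimuli associated with memory or audition",
      "visual information used for sensory-spatial awareness"),
    stringsAsFactors = FALSE)
}

#' Full Lobish report for a feature selection
#'
#' Generates the sentence for the given feature ids and computes every
#' symbolic summary: symbol histogram, 16 transition counts with glosses,
#' row-stochastic transition matrix, and the Shannon entropies of the symbol
#' and transition distributions (bounded by log2(4) = 2 and log2(16) = 4
#' bits).
#'
#' @param x ordered feature bin indices, or an existing Lobish sentence
#'   (class `"lobish_sentence"` or plain string over F/T/P/O).
#' @param lut a [lobe_lut()] (used only when `x` is a set of ids).
#' @return A list of class `"lobish_report"`: `sentence`, `symbol_counts`,
#'   `transition_counts`, `transition_matrix`, `symbol_entropy_bits`,
#'   `transition_entropy_bits`, `gloss`.
#' @export
lobish_report <- function(x, lut = lobe_lut()) {
  sentence <- if (is.numeric(x)) lobish_sentence(x, lut)
  else structure(paste(as_symbols(x), collapse = ""),
                 provenance = attr(x, "provenance") %||% "external",
                 class = "lobish_sentence")
  tc <- transition_counts(sentence)
  structure(list(sentence = sentence,
                 symbol_counts = lobe_histogram(sentence),
                 transition_counts = tc,
                 transition_matrix = transition_matrix(tc),
                 symbol_entropy_bits = shannon_entropy(lobe_histogram(sentence)),
                 transition_entropy_bits = shannon_entropy(tc),
                 gloss = lobish_gloss()),
            class = "lobish_report")
}

#' @export
print.lobish_report <- function(x, digits = 4L, ...) {
  print(x$sentence)
  cat("\nsymbol counts:\n"); print(x$symbol_counts)
  cat(sprintf("symbol entropy: %.*f bits (max 2)\n", digits,
              x$symbol_entropy_bits))
  cat("\ntransition counts (from row to column):\n")
  print(x$transition_counts)
  cat(sprintf("transition entropy: %.*f bits (max 4)\n", digits,
              x$transition_entropy_bits))
  cat("\ntransition probabilities:\n")
  print(round(unclass(x$transition_matrix), digits))
  invisible(x)
}
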