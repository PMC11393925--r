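#' Channel-to-lobe lookup table
#'
#' Maps each channel index 1..C to the brain lobe its electrode sits over:
#' `F` frontal, `T` temporal, `P` parietal, `O` occipital. The default is the
#' 14-channel Emotiv Epoc layout (AF3, F7, F3, FC5, T7, P7, O1, O2, P8, T8,
#' FC6, F4, F8, AF4), giving the lobe sequence
#' F F F F T P O O P T F F F F.
#'
#' @param mapping character vector over `{"F","T","P","O"}`, one symbol per
#'   channel; `NULL` returns the 14-channel default.
#' @param channel_names optional names for the mapping entries.
#' @return A character vector of class `"lobe_lut"`; `lut[i]` is the lobe of
#'   channel `i`.
#' @examples
#' lut <- lobe_lut()
#' lut[5]            # "T": channel 5 is T7
#' table(unclass(lut))
#' @export
lobe_lut <- function(mapping = NULL, channel_names = NULL) {
  if (is.null(mapping)) {
    mapping <- c("F", "F", "F", "F", "T", "P", "O", "O", "P", "T",
                 "F", "F", "F", "F")
    if (is.null(channel_names))
      channel_names <- c("AF3", "F7", "F3", "FC5", "T7", "P7", "O1",
                         "O2", "P8", "T8", "FC6", "F4", "F8", "AF4")
  }
  mapping <- as.character(mapping)
  if (length(mapping) < 2L) stop("a lobe LUT needs at least 2 channels")
  bad <- setdiff(unique(mapping), c("F", "T", "P", "O"))
  if (length(bad) > 0L)
    stop("lobe symbols must be in {F, T, P, O}; got: ",
         paste(bad, collapse = ", "))
  if (!is.null(channel_names)) {
    if (length(channel_names) != length(mapping))
      stop("'channel_names' length must match the mapping")
    names(mapping) <- channel_names
  }
  structure(mapping, class = "lobe_lut")
}

#' @export
print.lobe_lut <- function(x, ...) {
  cat(sprintf("channel -> lobe lookup table (%d channels)\n", length(x)))
  print(stats::setNames(unclass(x), names(x) %||% seq_along(x)))
  invisible(x)
}

#' @export
`[.lobe_lut` <- function(x, i) unname(unclass(x)[i])

`%||%` <- function(a, b) if (is.null(a)) b else a
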