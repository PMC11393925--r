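#' Construct an EEG segment
#'
#' An EEG segment is one fixed-length recording window held as a C x N numeric
#' matrix: rows are channels (order is significant and preserved everywhere),
#' columns are time points. Amplitude units (typically microvolts) are carried
#' but never used by any downstream algorithm, which depends only on the
#' per-timepoint ordering of the channels.
#'
#' @param data numeric matrix, channels x samples. At least 2 rows and
#'   2 columns; no missing or non-finite values.
#' @param channel_names optional character vector of row names; defaults to
#'   the matrix rownames or `"ch1"..."chC"`.
#' @param segment_id identifier string carried through feature extraction.
#' @return An object of class `"eeg_segment"`: the validated matrix with
#'   channel names as rownames and the id as an attribute.
#' @examples
#' seg <- eeg_segment(matrix(rnorm(28), 14, 2))
#' nrow(seg)
#' @export
eeg_segment <- function(data, channel_names = NULL, segment_id = "segment") {
  if (!is.matrix(data) || !is.numeric(data))
    stop("'data' must be a numeric matrix (channels x samples)")
  if (nrow(data) < 2L) stop("an EEG segment needs at least 2 channels")
  if (ncol(data) < 2L) stop("an EEG segment needs at least 2 samples")
  bad <- which(!is.finite(data), arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop(sprintf("non-finite value in segment '%s' at channel %d, sample %d",
                 segment_id, bad[1L, 1L], bad[1L, 2L]))
  if (is.null(channel_names)) channel_names <- rownames(data)
  if (is.null(channel_names)) channel_names <- paste0("ch", seq_len(nrow(data)))
  if (length(channel_names) != nrow(data))
    stop("'channel_names' length must equal the number of channels")
  rownames(data) <- as.character(channel_names)
  structure(data, segment_id = as.character(segment_id), class = "eeg_segment")
}

#' @export
print.eeg_segment <- function(x, ...) {
  cat(sprintf("EEG segment '%s': %d channels x %d samples\n",
              attr(x, "segment_id"), nrow(x), ncol(x)))
  cat("channels:", paste(rownames(x), collapse = ", "), "\n")
  invisible(x)
}

#' Read an EEG segment from CSV or EDF
#'
#' CSV layout: one row per channel, one column per sample, comma separated,
#' decimal point. An optional first header row gives channel names; it is
#' detected by attempting numeric conversion of the first line.
#'
#' @param path file to read.
#' @param format `"csv"` or `"edf"`; default guessed from the file extension.
#' @param channels for EDF, character vector of channel labels to select (in
#'   the given order); `NULL` keeps all channels in file order.
#' @param segment_id identifier; defaults to the file name without extension.
#' @return An [eeg_segment()].
#' @seealso [write_segment_csv()], [read_manifest()]
#' @export
read_segment <- function(path, format = c("auto", "csv", "edf"),
                         channels = NULL, segment_id = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf" else "csv"
  }
  if (is.null(segment_id))
    segment_id <- sub("\\.[^.]*$", "", basename(path))
  if (format == "edf") {
    rec <- read_edf(path, channels = channels)
    return(eeg_segment(rec$data, rec$channel_names, segment_id))
  }
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty CSV file: ", path)
  first <- trimws(strsplit(lines[1L], ",", fixed = TRUE)[[1L]])
  # optional header row holds the channel names (one per subsequent data row);
  # literal NA/NaN/Inf tokens are (bad) data, not names
  numeric_tokens <- c("NA", "NaN", "Inf", "-Inf", "")
  has_header <- any(is.na(suppressWarnings(as.numeric(first))) &
                      !(toupper(first) %in% toupper(numeric_tokens)))
  cn <- NULL
  if (has_header) {
    cn <- trimws(first)
    lines <- lines[-1L]
    if (length(cn) != length(lines))
      stop(sprintf("header of '%s' names %d channels but file has %d data rows",
                   path, length(cn), length(lines)))
  }
  rows <- lapply(lines, function(l)
    suppressWarnings(as.numeric(strsplit(l, ",", fixed = TRUE)[[1L]])))
  ns <- lengths(rows)
  if (length(unique(ns)) != 1L)
    stop("ragged CSV in '", path, "': rows have differing sample counts")
  m <- do.call(rbind, rows)
  bad <- which(!is.finite(m), arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop(sprintf("non-numeric or missing value in '%s' at data row %d, column %d",
                 path, bad[1L, 1L], bad[1L, 2L]))
  eeg_segment(m, channel_names = cn, segment_id = segment_id)
}

#' Write an EEG segment as CSV
#'
#' Inverse of the CSV branch of [read_segment()]: rows are channels, columns
#' samples, full double precision (17 significant digits), preceded by a
#' header row of channel names.
#'
#' @param segment an [eeg_segment()].
#' @param path output file.
#' @param header write the channel-name header row (default `TRUE`).
#' @return `path`, invisibly.
#' @export
write_segment_csv <- function(segment, path, header = TRUE) {
  stopifnot(inherits(segment, "eeg_segment"))
  con <- file(path, "w")
  on.exit(close(con))
  if (header) writeLines(paste(rownames(segment), collapse = ","), con)
  m <- unclass(segment)
  writeLines(apply(m, 1L, function(r)
    paste(formatC(r, digits = 17, format = "g"), collapse = ",")), con)
  invisible(path)
}

#' Read a dataset manifest
#'
#' A manifest is a two-column delimited text file (`path,label`) pairing
#' segment files with class labels. Relative paths are resolved against the
#' manifest's own directory. A header line `path,label` is optional.
#'
#' @param path manifest file.
#' @param check_paths verify every referenced file exists (default `TRUE`).
#' @return A data.frame with columns `path` and `label` (factor).
#' @export
read_manifest <- function(path, check_paths = TRUE) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  df <- utils::read.csv(path, header = FALSE, stringsAsFactors = FALSE,
                        col.names = c("path", "label"))
  if (nrow(df) > 0L && identical(tolower(df$path[1L]), "path"))
    df <- df[-1L, , drop = FALSE]
  if (nrow(df) == 0L) stop("manifest is empty: ", path)
  base <- dirname(normalizePath(path))
  abs <- ifelse(grepl("^(/|[A-Za-z]:)", df$path), df$path,
                file.path(base, df$path))
  if (check_paths) {
    missing <- abs[!file.exists(abs)]
    if (length(missing) > 0L)
      stop("manifest references missing file(s): ",
           paste(utils::head(missing, 3L), collapse = ", "))
  }
  out <- data.frame(path = abs, label = factor(df$label),
                    stringsAsFactors = FALSE)
  if (nlevels(out$label) < 2L)
    warning("manifest has fewer than 2 classes; classification needs >= 2")
  out
}
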