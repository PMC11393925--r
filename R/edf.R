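# Minimal EDF (European Data Format) reader. EDF stores a 256-byte ASCII
# global header, 256 bytes of ASCII header per signal, then data records of
# little-endian 16-bit integers, per record: spr[1] samples of signal 1,
# spr[2] of signal 2, ... Digital values map linearly to physical units via
# the per-signal (digmin, digmax) -> (physmin, physmax) calibration.

read_ascii <- function(con, n) trimws(readChar(con, n, useBytes = TRUE))

#' Read an EDF recording
#'
#' Parses a standard EDF file and returns the calibrated signal matrix.
#' All selected channels must share a common sampling rate (equal samples
#' per data record); no filtering or resampling is applied.
#'
#' @param path EDF file.
#' @param channels character vector of signal labels to keep, in the desired
#'   order; `NULL` keeps every signal in file order.
#' @return A list with `data` (channels x samples numeric matrix, physical
#'   units) and `channel_names`.
#' @export
read_edf <- function(path, channels = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  version <- read_ascii(con, 8L)
  if (!identical(version, "0"))
    stop("not an EDF file (version field '", version, "'): ", path)
  readChar(con, 80L + 80L + 8L + 8L, useBytes = TRUE)   # patient, recording, date, time
  header_bytes <- as.integer(read_ascii(con, 8L))
  read_ascii(con, 44L)                                   # reserved
  n_records <- as.integer(read_ascii(con, 8L))
  read_ascii(con, 8L)                                    # record duration (s)
  ns <- as.integer(read_ascii(con, 4L))
  if (is.na(ns) || ns < 1L) stop("EDF header reports no signals: ", path)

  field <- function(w) vapply(seq_len(ns), function(i) read_ascii(con, w), "")
  labels   <- field(16L)
  field(80L)                                             # transducer
  field(8L)                                              # physical dimension
  physmin  <- as.numeric(field(8L))
  physmax  <- as.numeric(field(8L))
  digmin   <- as.numeric(field(8L))
  digmax   <- as.numeric(field(8L))
  field(80L)                                             # prefiltering
  spr      <- as.integer(field(8L))
  field(32L)                                             # reserved
  stopifnot(seek(con) == header_bytes)

  keep <- seq_len(ns)
  if (!is.null(channels)) {
    keep <- match(channels, labels)
    if (anyNA(keep))
      stop("channel(s) not present in EDF: ",
           paste(channels[is.na(keep)], collapse = ", "))
  }
  if (length(unique(spr[keep])) != 1L)
    stop("selected EDF channels have differing samples per record")

  rec_len <- sum(spr)
  raw <- readBin(con, "integer", n = n_records * rec_len, size = 2L,
                 signed = TRUE, endian = "little")
  if (length(raw) < n_records * rec_len)
    stop("EDF data truncated: ", path)
  offsets <- c(0L, cumsum(spr))
  gain <- (physmax - physmin) / (digmax - digmin)
  data <- matrix(0, nrow = length(keep), ncol = n_records * spr[keep[1L]])
  for (j in seq_along(keep)) {
    s <- keep[j]
    idx <- as.vector(outer(seq_len(spr[s]) + offsets[s],
                           (seq_len(n_records) - 1L) * rec_len, `+`))
    data[j, ] <- physmin[s] + (raw[idx] - digmin[s]) * gain[s]
  }
  list(data = data, channel_names = labels[keep])
}
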