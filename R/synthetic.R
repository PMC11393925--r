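#' Synthetic labeled EEG segments with class-specific channel orderings
#'
#' Generates two-class multi-channel segments whose *per-timepoint channel
#' amplitude orderings* differ between classes — the property the rank
#' transform reads — while absolute amplitudes stay comparable. Each class
#' `g` assigns channel `c` a gain `1 + effect * delta(g, c)` with fixed
#' opposite gain ramps (`delta` ascends linearly over channels for the first
#' class and descends for the second, centered at zero). Sample `t` of
#' channel `c` is `gain * |oscillation(t)| + noise`, where the oscillation is
#' a sinusoid with a random per-segment phase and the noise is Gaussian with
#' standard deviation `noise_sd`. At `effect = 0` the two classes are
#' exchangeable; as `effect` grows the channel ranking becomes
#' class-deterministic and the transition histograms separate.
#'
#' @param n_channels channels per segment (default 14, the Emotiv layout).
#' @param n_samples samples per segment (default 256).
#' @param segments_per_class segments per class (default 30).
#' @param effect nonnegative gain-separation strength (default 0.8).
#' @param noise_sd Gaussian noise standard deviation, > 0 (default 0.2).
#' @param classes two class names (default `c("A", "B")`).
#' @param seed integer seed; the dataset is a deterministic function of it.
#' @return A list of class `"synth_dataset"`: `segments` (list of
#'   [eeg_segment()]), `labels` (factor), `params`.
#' @examples
#' d <- synth_eeg_dataset(segments_per_class = 3, n_samples = 32, seed = 7)
#' table(d$labels)
#' @export
synth_eeg_dataset <- function(n_channels = 14L, n_samples = 256L,
                              segments_per_class = 30L, effect = 0.8,
                              noise_sd = 0.2, classes = c("A", "B"),
                              seed = 1L) {
  stopifnot(n_channels >= 2L, n_samples >= 2L, segments_per_class >= 1L,
            effect >= 0, noise_sd > 0, length(classes) == 2L)
  rs <- local_rng(seed)
  on.exit(rs())
  C <- as.integer(n_channels); N <- as.integer(n_samples)
  ramp <- seq(-0.5, 0.5, length.out = C)
  delta <- list(ramp, rev(ramp))
  segments <- list(); labels <- character(0)
  t_grid <- seq_len(N) / N
  for (g in 1:2) {
    gain <- 1 + effect * delta[[g]]
    for (s in seq_len(segments_per_class)) {
      phase <- stats::runif(1, 0, 2 * pi)
      osc <- abs(sin(2 * pi * 4 * t_grid + phase))
      m <- outer(gain, osc) + matrix(stats::rnorm(C * N, 0, noise_sd), C, N)
      id <- sprintf("%s_%03d", classes[g], s)
      segments[[id]] <- eeg_segment(m, segment_id = id)
      labels <- c(labels, classes[g])
    }
  }
  structure(list(segments = segments,
                 labels = factor(labels, levels = classes),
                 params = list(n_channels = C, n_samples = N,
                               segments_per_class = segments_per_class,
                               effect = effect, noise_sd = noise_sd,
                               classes = classes, seed = seed)),
            class = "synth_dataset")
}

#' @export
print.synth_dataset <- function(x, ...) {
  p <- x$params
  cat(sprintf("synthetic EEG dataset: %d segments (%d per class), %d x %d, effect %.2f, noise sd %.2f, seed %d\n",
              length(x$segments), p$segments_per_class, p$n_channels,
              p$n_samples, p$effect, p$noise_sd, p$seed))
  invisible(x)
}

#' Write a synthetic dataset to disk
#'
#' Writes one CSV per segment plus a `manifest.csv` (`path,label`) readable
#' by [read_manifest()].
#'
#' @param dataset a [synth_eeg_dataset()] result.
#' @param dir output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
write_synth_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "synth_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(length(dataset$segments))
  for (i in seq_along(dataset$segments)) {
    seg <- dataset$segments[[i]]
    files[i] <- paste0(attr(seg, "segment_id"), ".csv")
    write_segment_csv(seg, file.path(dir, files[i]))
  }
  manifest <- file.path(dir, "manifest.csv")
  utils::write.table(data.frame(path = files, label = dataset$labels),
                     manifest, sep = ",", row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  invisible(manifest)
}
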