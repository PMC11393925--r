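#' Fit the full channel-rank EEG classification model
#'
#' End-to-end fit on labeled segments: (1) rank-transform each segment and
#' extract its ChannelPat transition histogram; (2) select an
#' accuracy-maximizing feature prefix with [inca_select()]; (3) classify the
#' selected features with the [tknn()] ensemble; (4) decode the selected
#' feature ids into a Lobish sentence and its symbolic statistics. One
#' stratified fold split, derived from `seed`, is shared by the INCA loss and
#' every tkNN configuration so all cross-validated outcomes are comparable.
#'
#' @param x a list of [eeg_segment()] objects, a manifest data.frame from
#'   [read_manifest()], a `"synth_dataset"`, or a ready `"feature_matrix"`.
#' @param labels class labels (not needed when `x` carries them).
#' @param lut channel-to-lobe [lobe_lut()]; must match the channel count.
#' @param size_range INCA prefix-size range; default `c(10, C^2)` clipped to
#'   the feature count.
#' @param nfolds cross-validation folds (default 10).
#' @param seed master seed; fans out to the fold split and any stage
#'   randomness, and is recorded in the fit.
#' @param ... further arguments to [inca_select()] (e.g. `lambda`, loss kNN
#'   overrides).
#' @return An object of class `"channel_model"`: `features`
#'   (`"feature_matrix"`), `selection` (`"inca_selection"`), `fit`
#'   (`"tknn"`), `metrics` (`"classification_metrics"`), `lobish`
#'   (`"lobish_report"`), `lut`, `seed`, `call`.
#' @examples
#' d <- synth_eeg_dataset(segments_per_class = 10, n_samples = 64,
#'                        effect = 1, noise_sd = 0.05, seed = 3)
#' fit <- channel_model(d, size_range = c(5, 20), nfolds = 5, seed = 3)
#' fit$fit$final_accuracy
#' @export
channel_model <- function(x, labels = NULL, lut = NULL, size_range = NULL,
                          nfolds = 10L, seed = 1L, ...) {
  cl <- match.call()
  if (inherits(x, "synth_dataset")) {
    labels <- x$labels
    x <- x$segments
  }
  feats <- if (inherits(x, "feature_matrix")) x
  else build_feature_matrix(x, labels)
  if (is.null(feats$labels)) {
    if (is.null(labels)) stop("class labels are required")
    feats$labels <- factor(labels)
  }
  C <- feats$n_channels
  if (is.null(lut)) {
    lut <- if (C == 14L) lobe_lut() else
      stop("supply a 'lut' for channel counts other than 14")
  }
  if (length(lut) != C)
    stop("LUT length ", length(lut), " does not match channel count ", C)

  folds <- make_folds(feats$labels, nfolds, seed)
  selection <- inca_select(feats$x, feats$labels, size_range = size_range,
                           folds = folds, ...)
  fit <- tknn(feats$x[, selection$chosen_indices, drop = FALSE],
              feats$labels, folds = folds)
  structure(list(features = feats,
                 selection = selection,
                 fit = fit,
                 metrics = classification_metrics(fit$confusion),
                 lobish = lobish_report(selection$chosen_indices, lut),
                 lut = lut,
                 seed = seed,
                 nfolds = nfolds,
                 call = cl),
            class = "channel_model")
}

#' @export
print.channel_model <- function(x, ...) {
  cat("channel-rank EEG classification model\n")
  cat("call: "); print(x$call)
  cat(sprintf("segments: %d, features: %d -> %d selected, seed %d\n",
              nrow(x$features$x), ncol(x$features$x),
              x$selection$chosen_size, x$seed))
  src <- if (x$fit$source$type == "classifier")
    sprintf("kNN config %d", x$fit$source$index)
  else sprintf("vote of top %d configs", x$fit$source$q)
  cat(sprintf("final CV accuracy: %.4f (%s)\n", x$fit$final_accuracy, src))
  invisible(x)
}

#' @export
summary.channel_model <- function(object, ...) {
  structure(list(model = object), class = "summary.channel_model")
}

#' @export
print.summary.channel_model <- function(x, ...) {
  m <- x$model
  print(m)
  cat("\n"); print(m$selection)
  cat("\n"); print(m$metrics)
  cat(sprintf("\nLobish sentence: %d symbols; entropies %.4f / %.4f bits\n",
              nchar(unclass(m$lobish$sentence)),
              m$lobish$symbol_entropy_bits, m$lobish$transition_entropy_bits))
  invisible(x)
}

#' Predict class labels for new EEG segments
#'
#' Transforms and featurizes the new segments, subsets the columns chosen at
#' fit time, and applies the winning tkNN outcome refitted on the full
#' training data.
#'
#' @param object a [channel_model()] fit.
#' @param newdata a list of [eeg_segment()], a manifest data.frame, a
#'   `"synth_dataset"`, or a precomputed `"feature_matrix"` / numeric matrix
#'   of full ChannelPat histograms.
#' @param ... unused.
#' @return Factor of predicted class labels.
#' @export
predict.channel_model <- function(object, newdata, ...) {
  if (inherits(newdata, "synth_dataset")) newdata <- newdata$segments
  xm <- if (inherits(newdata, "feature_matrix")) newdata$x
  else if (is.matrix(newdata)) newdata
  else build_feature_matrix(newdata)$x
  if (ncol(xm) != ncol(object$features$x))
    stop("'newdata' has ", ncol(xm), " features; expected ",
         ncol(object$features$x))
  predict(object$fit, xm[, object$selection$chosen_indices, drop = FALSE])
}

#' Extract the Lobish report of a fitted model
#'
#' @param object a fitted object carrying a symbolic interpretation.
#' @param ... unused.
#' @return The `"lobish_report"` of the fit.
#' @export
lobish <- function(object, ...) UseMethod("lobish")

#' @rdname lobish
#' @export
lobish.channel_model <- function(object, ...) object$lobish

#' Write a machine-readable model report
#'
#' Serializes the selection, the 118 outcome accuracies, winner provenance,
#' metrics and Lobish statistics of a fitted [channel_model()] to JSON.
#'
#' @param model a [channel_model()] fit.
#' @param path output JSON file.
#' @return `path`, invisibly.
#' @export
write_model_json <- function(model, path) {
  stopifnot(inherits(model, "channel_model"))
  rep <- model$lobish
  out <- list(
    seed = model$seed,
    nfolds = model$nfolds,
    n_segments = nrow(model$features$x),
    n_features = ncol(model$features$x),
    selection = list(chosen_size = model$selection$chosen_size,
                     chosen_indices = model$selection$chosen_indices,
                     per_size_accuracy = as.list(model$selection$per_size_accuracy)),
    tknn = list(classifier_accuracy = model$fit$classifier_accuracy,
                voted_accuracy = model$fit$voted_accuracy,
                final_accuracy = model$fit$final_accuracy,
                source = model$fit$source[setdiff(names(model$fit$source),
                                                  "config")]),
    confusion = unclass(model$fit$confusion),
    metrics = list(accuracy = model$metrics$accuracy,
                   per_class = model$metrics$per_class,
                   overall = as.list(model$metrics$overall)),
    lobish = list(sentence = unclass(rep$sentence),
                  symbol_counts = as.list(rep$symbol_counts),
                  transition_counts = unclass(rep$transition_counts),
                  transition_matrix = unclass(rep$transition_matrix),
                  symbol_entropy_bits = rep$symbol_entropy_bits,
                  transition_entropy_bits = rep$transition_entropy_bits))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
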