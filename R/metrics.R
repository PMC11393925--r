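#' Confusion matrix
#'
#' Rows are true classes, columns predicted classes, in the factor-level
#' order of `truth`.
#'
#' @param truth true labels.
#' @param predicted predicted labels (coerced to the levels of `truth`).
#' @return K x K integer matrix of class `"confusion_matrix"`.
#' @export
confusion_matrix <- function(truth, predicted) {
  truth <- factor(truth)
  predicted <- factor(predicted, levels = levels(truth))
  tab <- table(truth, predicted)
  structure(matrix(as.integer(tab), nlevels(truth),
                   dimnames = list(truth = levels(truth),
                                   predicted = levels(truth))),
            class = c("confusion_matrix", "matrix"))
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat("confusion matrix (rows = truth):\n")
  print(unclass(x))
  invisible(x)
}

round_half_up <- function(x, digits = 2L) floor(x * 10^digits + 0.5) / 10^digits

#' Confusion-matrix performance metrics
#'
#' Per-class one-vs-rest sensitivity (recall), specificity, precision,
#' F1-score and geometric mean `sqrt(sensitivity * specificity)`, plus the
#' overall row: the unweighted macro mean of the per-class values, except
#' accuracy, which is the global fraction correct. Cells with a zero
#' denominator are reported as `NA` (undefined), not 0. For two classes the
#' macro-averaged sensitivity and specificity coincide, since each class's
#' specificity is the other's sensitivity.
#'
#' @param cm a [confusion_matrix()] or plain K x K count matrix (K >= 2),
#'   rows = truth.
#' @return A list of class `"classification_metrics"`: `accuracy` (global),
#'   `per_class` (data.frame), `overall` (named macro means), `confusion`.
#'   All values are proportions in `[0, 1]`; the print method shows
#'   percentages rounded half-up to 2 decimals.
#' @examples
#' cm <- matrix(c(1492, 22, 23, 1653), 2, byrow = TRUE)
#' classification_metrics(cm)
#' @export
classification_metrics <- function(cm) {
  cm <- unclass(as.matrix(cm))
  K <- nrow(cm)
  if (K < 2L || ncol(cm) != K) stop("'cm' must be a square matrix, K >= 2")
  if (any(cm < 0)) stop("negative confusion counts")
  n <- sum(cm)
  classes <- rownames(cm) %||% paste0("class", seq_len(K))
  tp <- diag(cm)
  fn <- rowSums(cm) - tp
  fp <- colSums(cm) - tp
  tn <- n - tp - fn - fp
  safe_div <- function(a, b) ifelse(b == 0, NA_real_, a / b)
  sens <- safe_div(tp, tp + fn)
  spec <- safe_div(tn, tn + fp)
  prec <- safe_div(tp, tp + fp)
  f1 <- ifelse(is.na(prec) | is.na(sens) | (prec + sens) == 0,
               NA_real_, 2 * prec * sens / (prec + sens))
  gmean <- sqrt(sens * spec)
  per_class <- data.frame(class = classes, sensitivity = sens,
                          specificity = spec, precision = prec, f1 = f1,
                          geometric_mean = gmean, row.names = NULL,
                          stringsAsFactors = FALSE)
  overall <- c(accuracy = sum(tp) / n,
               sensitivity = mean(sens), specificity = mean(spec),
               precision = mean(prec), f1 = mean(f1),
               geometric_mean = mean(gmean))
  structure(list(accuracy = sum(tp) / n, per_class = per_class,
                 overall = overall, confusion = cm),
            class = "classification_metrics")
}

#' @export
print.classification_metrics <- function(x, ...) {
  pc <- x$per_class
  num <- vapply(pc[-1L], function(v) round_half_up(100 * v), numeric(nrow(pc)))
  if (is.null(dim(num))) num <- matrix(num, nrow = 1L,
                                       dimnames = list(NULL, names(pc)[-1L]))
  cat(sprintf("accuracy (global): %.2f%%\n", round_half_up(100 * x$accuracy)))
  out <- data.frame(class = pc$class, num, check.names = FALSE)
  ov <- data.frame(class = "overall",
                   t(round_half_up(100 * x$overall[colnames(num)])),
                   check.names = FALSE)
  print(rbind(out, ov), row.names = FALSE)
  invisible(x)
}
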