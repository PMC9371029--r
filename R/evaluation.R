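# Accuracy statistics: confusion matrix, kappa, OA, PA/UA, normalized matrix.

#' Confusion matrix
#'
#' Cross-tabulates reference against predicted class codes. Rows are the true
#' class, columns the predicted class, so all correct predictions lie on the
#' diagonal. The object carries the marginal totals used by the agreement
#' statistics: `x_i_plus` (row sums), `x_plus_i` (column sums) and the grand
#' total `N`.
#'
#' @param truth,predicted Equal-length vectors of class codes.
#' @param class_list Ordered class codes defining rows/columns; defaults to
#'   the sorted union of both vectors. Values outside `class_list` are a
#'   validation error.
#' @return An object of class `crop_confusion`.
#' @examples
#' confusion(c(1, 1, 2), c(1, 2, 2))
#' @export
confusion <- function(truth, predicted, class_list = NULL) {
  if (length(truth) != length(predicted))
    stopf("truth and predicted must have equal length")
  if (is.null(class_list)) class_list <- sort(unique(c(truth, predicted)))
  if (!all(truth %in% class_list) || !all(predicted %in% class_list))
    stopf("validation error: labels outside class_list")
  ft <- factor(truth, levels = class_list)
  fp <- factor(predicted, levels = class_list)
  counts <- unclass(table(ft, fp))
  dimnames(counts) <- list(true = as.character(class_list),
                           predicted = as.character(class_list))
  structure(list(classes = class_list, counts = counts,
                 r = length(class_list),
                 x_i_plus = rowSums(counts), x_plus_i = colSums(counts),
                 N = sum(counts)),
            class = "crop_confusion")
}

#' @rdname confusion
#' @param counts For `as_confusion()`: an r x r non-negative integer matrix
#'   of counts (rows = true class, columns = predicted class).
#' @export
as_confusion <- function(counts, class_list = seq_len(nrow(counts))) {
  counts <- as.matrix(counts)
  if (nrow(counts) != ncol(counts) || any(counts < 0) ||
      any(counts != round(counts)))
    stopf("counts must be a square matrix of non-negative integers")
  if (length(class_list) != nrow(counts))
    stopf("class_list length must match the matrix dimension")
  dimnames(counts) <- list(true = as.character(class_list),
                           predicted = as.character(class_list))
  structure(list(classes = class_list, counts = counts,
                 r = length(class_list),
                 x_i_plus = rowSums(counts), x_plus_i = colSums(counts),
                 N = sum(counts)),
            class = "crop_confusion")
}

#' @export
print.crop_confusion <- function(x, ...) {
  cat(sprintf("<crop_confusion> %d classes, N = %d (rows = true, cols = predicted)\n",
              x$r, x$N))
  print(x$counts)
  invisible(x)
}

#' Kappa coefficient of a confusion matrix
#'
#' Chance-corrected agreement:
#' \deqn{\kappa = \frac{N\sum_i x_{ii} - \sum_i x_{i+}x_{+i}}
#'                     {N^2 - \sum_i x_{i+}x_{+i}}}
#' where \eqn{x_{ii}} are the diagonal counts, \eqn{x_{i+}}/\eqn{x_{+i}} the
#' row/column totals and \eqn{N} the grand total. Equivalently
#' \eqn{\kappa = (OA - p_e)/(1 - p_e)} with expected chance agreement
#' \eqn{p_e = \sum_i x_{i+}x_{+i}/N^2}. For the degenerate case where the
#' denominator vanishes (all mass in a single cell) the statistic is
#' undefined and `NA` is returned with a warning.
#'
#' @param cm A [confusion()] object.
#' @return Numeric scalar in \[-1, 1\], or `NA` when undefined.
#' @examples
#' kappa_coefficient(confusion(c(1, 1, 2, 2), c(1, 1, 2, 2)))
#' @export
kappa_coefficient <- function(cm) {
  stopifnot(inherits(cm, "crop_confusion"))
  if (cm$N <= 0) stopf("kappa undefined for an empty confusion matrix")
  N <- as.numeric(cm$N)
  chance <- sum(as.numeric(cm$x_i_plus) * as.numeric(cm$x_plus_i))
  denom <- N^2 - chance
  if (denom == 0) {
    warnf("kappa undefined: chance agreement equals 1 (single-cell matrix)")
    return(NA_real_)
  }
  (N * sum(as.numeric(diag(cm$counts))) - chance) / denom
}

#' Accuracy report from a confusion matrix
#'
#' Computes overall accuracy (OA, proportion of correctly classified
#' samples), per-class producer accuracy (PA, recall: diagonal over row
#' total), per-class user accuracy (UA, precision: diagonal over column
#' total), the kappa coefficient, and the row-normalized percentage matrix
#' with the UA percentages appended as a final row (the rendering used for
#' per-class misclassification analysis). PA/UA for classes with an empty
#' row/column are reported as `NA`, not 0, so they cannot silently drag down
#' averages.
#'
#' @param cm A [confusion()] object.
#' @return A list of class `accuracy_report` with fields `kappa`, `oa`, `pa`,
#'   `ua`, `normalized`.
#' @export
accuracy_report <- function(cm) {
  stopifnot(inherits(cm, "crop_confusion"))
  if (cm$N <= 0) stopf("report undefined for an empty confusion matrix")
  diagc <- as.numeric(diag(cm$counts))
  oa <- sum(diagc) / as.numeric(cm$N)
  pa <- ifelse(cm$x_i_plus > 0, diagc / as.numeric(cm$x_i_plus), NA_real_)
  ua <- ifelse(cm$x_plus_i > 0, diagc / as.numeric(cm$x_plus_i), NA_real_)
  norm <- cm$counts
  norm <- sweep(norm, 1, pmax(cm$x_i_plus, 1), "/") * 100
  norm[cm$x_i_plus == 0, ] <- NA_real_
  normalized <- rbind(norm, UA = ua * 100)
  names(pa) <- names(ua) <- as.character(cm$classes)
  structure(list(kappa = suppressWarnings(kappa_coefficient(cm)), oa = oa,
                 pa = pa, ua = ua, normalized = normalized),
            class = "accuracy_report")
}

#' @export
print.accuracy_report <- function(x, ...) {
  cat(sprintf("<accuracy_report> OA = %.4f, kappa = %.4f\n", x$oa, x$kappa))
  cat("normalized confusion matrix (%, rows = true; last row = UA):\n")
  print(round(x$normalized, 2))
  invisible(x)
}
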