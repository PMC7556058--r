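#' Three-class confusion matrix
#'
#' Cross-tabulates predictions against actual classes in the fixed order
#' high, medium, low. Rows are the predicted class, columns the actual
#' class, so column sums equal the actual class counts.
#'
#' @param predicted,actual Vectors (factor or character) of equal, nonzero
#'   length with values among high/medium/low.
#' @return 3x3 integer matrix with dimnames `predicted` x `actual`.
#' @export
confusion_matrix3 <- function(predicted, actual) {
  lv <- c("high", "medium", "low")
  if (length(predicted) != length(actual) || length(predicted) == 0L)
    stop("`predicted` and `actual` must be non-empty and of equal length",
         call. = FALSE)
  p <- factor(as.character(predicted), levels = lv)
  a <- factor(as.character(actual), levels = lv)
  if (anyNA(p) || anyNA(a))
    stop("classes must be among: ", paste(lv, collapse = ", "), call. = FALSE)
  m <- table(predicted = p, actual = a)
  matrix(as.integer(m), 3, 3, dimnames = list(predicted = lv, actual = lv))
}

check_cm3 <- function(m) {
  if (!is.matrix(m) || nrow(m) != 3L || ncol(m) != 3L || any(m < 0))
    stop("expected a 3x3 non-negative confusion matrix", call. = FALSE)
  if (sum(m) == 0) stop("empty confusion matrix", call. = FALSE)
  m
}

#' Overall accuracy (percent)
#'
#' Multiclass generalisation of the correct-classification ratio:
#' 100 x trace / total. Full precision is returned; truncate at the
#' reporting layer (see [metrics_report()]).
#'
#' @param m 3x3 confusion matrix, rows predicted, columns actual.
#' @return Percentage in \[0, 100\].
#' @export
accuracy_pct <- function(m) {
  m <- check_cm3(m)
  100 * sum(diag(m)) / sum(m)
}

#' Per-class recall (percent)
#'
#' One-vs-rest recall: for each class, 100 x the diagonal cell over the
#' class's *column* sum (the number of records actually in the class).
#' Undefined recalls (empty class) are returned as `NA` rather than raising
#' an error.
#'
#' @param m 3x3 confusion matrix, rows predicted, columns actual.
#' @param class Optional single class (`"high"`, `"medium"`, `"low"`); when
#'   omitted, all three are returned as a named vector.
#' @return Percentage(s) in \[0, 100\], `NA` where undefined.
#' @export
recall_pct <- function(m, class = NULL) {
  m <- check_cm3(m)
  denom <- colSums(m)
  out <- ifelse(denom > 0, 100 * diag(m) / denom, NA_real_)
  names(out) <- colnames(m)
  if (is.null(class)) out else out[[class]]
}

#' Per-class precision (percent)
#'
#' One-vs-rest precision: for each class, 100 x the diagonal cell over the
#' class's *row* sum (the number of records predicted into the class).
#' Undefined precisions (class never predicted) are returned as `NA`.
#'
#' @inheritParams recall_pct
#' @return Percentage(s) in \[0, 100\], `NA` where undefined.
#' @export
precision_pct <- function(m, class = NULL) {
  m <- check_cm3(m)
  denom <- rowSums(m)
  out <- ifelse(denom > 0, 100 * diag(m) / denom, NA_real_)
  names(out) <- rownames(m)
  if (is.null(class)) out else out[[class]]
}

#' Mean absolute error of output concepts
#'
#' \eqn{MAE = (1/N) \sum_{L=1}^{N} \sum_{J=1}^{C} |OC^{real}_{JL} -
#' OC^{pred}_{JL}|} for `N` records and `C` output concepts. Note the
#' normalisation is by `N` only, per the reference definition.
#'
#' @param real,predicted Numeric matrices (or vectors) of identical shape,
#'   records by output concepts.
#' @return Non-negative scalar.
#' @export
mae <- function(real, predicted) {
  real <- as.matrix(real); predicted <- as.matrix(predicted)
  if (!identical(dim(real), dim(predicted)))
    stop("`real` and `predicted` must have identical shape", call. = FALSE)
  sum(abs(real - predicted)) / nrow(real)
}

#' Root mean squared error of output concepts
#'
#' \eqn{RMSE = \sqrt{(1/(NC)) \sum_{L=1}^{N} \sum_{J=1}^{C}
#' (OC^{real}_{JL} - OC^{pred}_{JL})^2}}.
#'
#' @inheritParams mae
#' @return Non-negative scalar.
#' @export
rmse <- function(real, predicted) {
  real <- as.matrix(real); predicted <- as.matrix(predicted)
  if (!identical(dim(real), dim(predicted)))
    stop("`real` and `predicted` must have identical shape", call. = FALSE)
  sqrt(sum((real - predicted)^2) / length(real))
}

#' Full metrics report for a three-class classifier
#'
#' Per-class recall and precision, overall accuracy, and (optionally) MAE
#' and RMSE. Reported percentages are truncated — floored, not rounded — to
#' `digits` decimal places, the convention of the reference tables
#' (90.476 reports as 90.47); full-precision values are kept alongside.
#'
#' @param m 3x3 confusion matrix, rows predicted, columns actual.
#' @param mae,rmse Optional precomputed error indices to carry through.
#' @param digits Reporting precision for percentages.
#' @return A list of class `"metrics_report"` with components `confusion`,
#'   `recall`, `precision`, `accuracy` (truncated), `recall_full`,
#'   `precision_full`, `accuracy_full`, `mae`, `rmse`.
#' @export
metrics_report <- function(m, mae = NULL, rmse = NULL, digits = 2) {
  m <- check_cm3(m)
  rec <- recall_pct(m)
  prec <- precision_pct(m)
  acc <- accuracy_pct(m)
  structure(
    list(confusion = m,
         recall = trunc_digits(rec, digits),
         precision = trunc_digits(prec, digits),
         accuracy = trunc_digits(acc, digits),
         recall_full = rec, precision_full = prec, accuracy_full = acc,
         mae = mae, rmse = rmse, digits = digits),
    class = "metrics_report"
  )
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("Confusion matrix (rows predicted, columns actual):\n")
  print(x$confusion)
  tab <- data.frame(class = colnames(x$confusion),
                    `recall %` = x$recall,
                    `precision %` = x$precision,
                    check.names = FALSE)
  print(tab, row.names = FALSE)
  cat(sprintf("overall accuracy: %.*f%%\n", x$digits, x$accuracy))
  if (!is.null(x$mae)) cat("MAE: ", format(x$mae), "\n", sep = "")
  if (!is.null(x$rmse)) cat("RMSE: ", format(x$rmse), "\n", sep = "")
  invisible(x)
}
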