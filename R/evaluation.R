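#' Regression metrics
#'
#' Coefficient of determination, mean absolute error, mean squared error and
#' its square root, for predicted vs observed protein percentages:
#' R2 = 1 - sum((y - yhat)^2) / sum((y - mean(y))^2).
#'
#' @param y observed values.
#' @param yhat predicted values of the same length (>= 2).
#' @return `list(r2, mae, mse, rmse)`.
#' @export
regression_metrics <- function(y, yhat) {
  if (length(y) != length(yhat)) stop("length mismatch: ", length(y), " vs ", length(yhat))
  if (length(y) < 2L) stop("need at least 2 observations")
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot == 0) stop("y is constant; R2 is undefined")
  res <- y - yhat
  mse <- mean(res^2)
  list(r2 = 1 - sum(res^2) / ss_tot,
       mae = mean(abs(res)),
       mse = mse,
       rmse = sqrt(mse))
}

#' Classification metrics over protein classes
#'
#' Accuracy ((TP + TN) / n, i.e. the fraction of correct predictions),
#' precision TP/(TP+FP), recall TP/(TP+FN) and their harmonic mean F1,
#' computed per class then averaged. A class with a zero denominator
#' contributes 0 (with a warning). Macro averaging (unweighted mean over
#' classes) is the default; micro averaging pools counts over classes.
#'
#' @param labels true labels (subset of low/medium/high, or any factor).
#' @param preds predicted labels of the same length.
#' @param averaging `"macro"` or `"micro"`.
#' @return `list(accuracy, precision, recall, f1, averaging, per_class)`
#'   where `per_class` is a data frame of per-class counts and metrics.
#' @export
classification_metrics <- function(labels, preds, averaging = c("macro", "micro")) {
  averaging <- match.arg(averaging)
  if (length(labels) == 0L) stop("empty input")
  if (length(labels) != length(preds)) stop("length mismatch")
  classes <- if (is.factor(labels)) levels(labels) else sort(unique(c(as.character(labels), as.character(preds))))
  labels <- as.character(labels); preds <- as.character(preds)
  n <- length(labels)
  per <- lapply(classes, function(cl) {
    tp <- sum(labels == cl & preds == cl)
    fp <- sum(labels != cl & preds == cl)
    fn <- sum(labels == cl & preds != cl)
    tn <- n - tp - fp - fn
    prec <- if (tp + fp == 0) { warning("no predictions of class '", cl,
                                        "'; precision set to 0"); 0 } else tp / (tp + fp)
    rec <- if (tp + fn == 0) { warning("no instances of class '", cl,
                                       "'; recall set to 0"); 0 } else tp / (tp + fn)
    f1 <- if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
    data.frame(class = cl, tp = tp, fp = fp, fn = fn, tn = tn,
               precision = prec, recall = rec, f1 = f1)
  })
  per <- do.call(rbind, per)
  acc <- sum(labels == preds) / n
  if (averaging == "macro") {
    prec <- mean(per$precision); rec <- mean(per$recall); f1 <- mean(per$f1)
  } else {
    tp <- sum(per$tp); fp <- sum(per$fp); fn <- sum(per$fn)
    prec <- if (tp + fp == 0) 0 else tp / (tp + fp)
    rec <- if (tp + fn == 0) 0 else tp / (tp + fn)
    f1 <- if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
  }
  list(accuracy = acc, precision = prec, recall = rec, f1 = f1,
       averaging = averaging, per_class = per)
}
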