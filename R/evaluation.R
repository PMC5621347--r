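#' Absolute ordinal classification error
#'
#' `e_i = |predicted_i - true_i|`, the number of severity steps by which a
#' prediction misses the clinician-consensus UPDRS score.
#'
#' @param truth,pred integer labels in 0-4, equal length.
#' @return integer vector of per-sample errors in 0-4.
#' @export
abs_error <- function(truth, pred) {
  truth <- as.integer(truth); pred <- as.integer(pred)
  if (length(truth) != length(pred)) {
    stop("truth and pred lengths differ (", length(truth), " vs ",
         length(pred), ")")
  }
  stopifnot(all(truth %in% 0:4), all(pred %in% 0:4))
  abs(pred - truth)
}

#' Cumulative distribution of the absolute error
#'
#' `cdf(x) = P(e <= x)` evaluated at `x = 0, 1, 2, 3, 4`. `cdf(0)` is the
#' accuracy; `cdf(4)` is always 1.
#'
#' @param e integer vector of absolute errors (from [abs_error()]).
#' @return named numeric vector of length 5 over `x = 0:4`.
#' @export
error_cdf <- function(e) {
  if (length(e) == 0) stop("empty error vector")
  stopifnot(all(e %in% 0:4))
  stats::setNames(vapply(0:4, function(x) mean(e <= x), numeric(1)),
                  as.character(0:4))
}

#' Normalized area under the error CDF
#'
#' Trapezoidal area of the CDF over the error axis `[0, 4]`, divided by the
#' total area 4. A perfect classifier (CDF identically 1) scores 1;
#' pointwise-dominating CDFs never score lower.
#'
#' @param cdf numeric vector of length 5 (from [error_cdf()]).
#' @return value in `[0, 1]`.
#' @export
nauc <- function(cdf) {
  stopifnot(length(cdf) == 5, !is.unsorted(cdf), cdf[5] == 1)
  sum((cdf[-5] + cdf[-1]) / 2) / 4
}

#' Root-mean-square error variants of the ordinal error
#'
#' Two labelled conventions are reported: `"rms"` is
#' `sqrt(mean(e^2))` (the standard definition) and `"rms_over_n"` is
#' `sqrt(sum(e^2)) / n`. Both are descriptive outputs; neither is used in
#' acceptance checks.
#'
#' @param e integer vector of absolute errors.
#' @param variant `"rms"` or `"rms_over_n"`.
#' @return a single value.
#' @export
rmse_error <- function(e, variant = c("rms", "rms_over_n")) {
  variant <- match.arg(variant)
  if (length(e) == 0) stop("empty error vector")
  switch(variant,
         rms = sqrt(mean(e^2)),
         rms_over_n = sqrt(sum(e^2)) / length(e))
}

#' Tally a confusion matrix from labels
#' @param truth,pred integer labels in 0-4.
#' @return a [confusion_matrix()] with rows = true class.
#' @export
confusion <- function(truth, pred) {
  truth <- factor(as.integer(truth), levels = 0:4)
  pred <- factor(as.integer(pred), levels = 0:4)
  if (length(truth) != length(pred)) stop("length mismatch")
  confusion_matrix(unclass(table(truth, pred)))
}

wald_halfwidth <- function(p, n, z) z * sqrt(p * (1 - p) / n)

#' Per-class recall and precision with Wald intervals
#'
#' Recall of class c is the diagonal count over the row sum, precision the
#' diagonal count over the column sum. A class never predicted has
#' undefined precision, reported as `NA` with `precision_defined = FALSE`
#' (never coerced to 0). Confidence half-widths use the Wald formula
#' `z * sqrt(p (1 - p) / n)`; by default n is the grand total of the
#' matrix, the convention under which the printed intervals of the
#' reference confusion matrix reproduce (`n_convention = "per_class"`
#' uses the row/column sum instead).
#'
#' @param cm a [confusion_matrix()].
#' @param z normal quantile for the interval (1.96 for 95%).
#' @param n_convention `"grand"` or `"per_class"`.
#' @return data frame with one row per class: `class`, `recall`,
#'   `recall_ci`, `precision`, `precision_ci`, `precision_defined`.
#' @export
class_metrics <- function(cm, z = 1.96, n_convention = c("grand", "per_class")) {
  stopifnot(inherits(cm, "tremor_confusion"))
  n_convention <- match.arg(n_convention)
  total <- sum(cm)
  rows <- rowSums(cm)
  cols <- colSums(cm)
  diagc <- diag(cm)
  out <- data.frame(class = 0:4, recall = NA_real_, recall_ci = NA_real_,
                    precision = NA_real_, precision_ci = NA_real_,
                    precision_defined = cols > 0)
  for (c in 1:5) {
    if (rows[c] > 0) {
      p <- diagc[c] / rows[c]
      out$recall[c] <- p
      out$recall_ci[c] <- wald_halfwidth(
        p, if (n_convention == "grand") total else rows[c], z)
    }
    if (cols[c] > 0) {
      p <- diagc[c] / cols[c]
      out$precision[c] <- p
      out$precision_ci[c] <- wald_halfwidth(
        p, if (n_convention == "grand") total else cols[c], z)
    }
  }
  rownames(out) <- NULL
  out
}

#' Full evaluation report
#'
#' Computes every evaluation quantity from either paired labels or a
#' confusion matrix: accuracy with Wald interval, error CDF, NAuC,
#' labelled RMSE variants, per-class recall/precision with intervals, and
#' the confusion matrix itself.
#'
#' @param truth integer labels 0-4, or a [confusion_matrix()] (then `pred`
#'   is omitted).
#' @param pred integer predicted labels 0-4.
#' @param z normal quantile for Wald intervals.
#' @param n_convention see [class_metrics()].
#' @return An object of class `eval_report`.
#' @export
eval_report <- function(truth, pred = NULL, z = 1.96,
                        n_convention = c("grand", "per_class")) {
  n_convention <- match.arg(n_convention)
  if (inherits(truth, "tremor_confusion")) {
    cm <- truth
    idx <- which(cm > 0, arr.ind = TRUE)
    truth <- rep(idx[, 1] - 1L, cm[idx])
    pred <- rep(idx[, 2] - 1L, cm[idx])
  } else {
    cm <- confusion(truth, pred)
  }
  e <- abs_error(truth, pred)
  cdf <- error_cdf(e)
  acc <- unname(cdf[1])
  n <- length(e)
  structure(
    list(n = n,
         accuracy = acc,
         accuracy_ci = wald_halfwidth(acc, n, z),
         cdf = cdf,
         nauc = nauc(cdf),
         rmse = c(rms = rmse_error(e, "rms"),
                  rms_over_n = rmse_error(e, "rms_over_n")),
         class_metrics = class_metrics(cm, z = z,
                                       n_convention = n_convention),
         confusion = cm),
    class = "eval_report"
  )
}

#' @export
print.eval_report <- function(x, digits = 3, ...) {
  cat(sprintf("Evaluation over %d recordings\n", x$n))
  cat(sprintf("  accuracy: %.1f%% (+/- %.2f%%, 95%% Wald)\n",
              100 * x$accuracy, 100 * x$accuracy_ci))
  cat(sprintf("  P(e <= 1): %.2f%%\n", 100 * x$cdf[2]))
  cat(sprintf("  NAuC: %.3f\n", x$nauc))
  cat(sprintf("  RMSE [rms]: %.3f   [rms/n]: %.4f\n",
              x$rmse["rms"], x$rmse["rms_over_n"]))
  cat("  per-class metrics:\n")
  cm <- x$class_metrics
  for (i in 1:5) {
    prec <- if (cm$precision_defined[i]) {
      sprintf("%.3f (+/-%.3f)", cm$precision[i], cm$precision_ci[i])
    } else "undefined"
    rec <- if (is.na(cm$recall[i])) "no samples" else
      sprintf("%.3f (+/-%.3f)", cm$recall[i], cm$recall_ci[i])
    cat(sprintf("    UPDRS %d: recall %s, precision %s\n",
                cm$class[i], rec, prec))
  }
  cat("  confusion matrix (rows = true):\n")
  print(unclass(x$confusion))
  invisible(x)
}
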