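#' Exact (Clopper-Pearson) binomial confidence interval
#'
#' Two-sided exact interval for a binomial proportion via the beta-quantile
#' closed form: `lower = qbeta(a/2, x, n - x + 1)`,
#' `upper = qbeta(1 - a/2, x + 1, n - x)`, with the boundary cases
#' `x = 0 -> lower = 0` and `x = n -> upper = 1`. At `x = n` the lower
#' bound reduces to `(a/2)^(1/n)`.
#'
#' @param successes number of successes (0..n).
#' @param n number of trials (>= 1).
#' @param level confidence level (default 0.95).
#' @return named numeric `c(lower, upper)` on the proportion scale.
#' @examples
#' exact_binomial_ci(24, 24)   # lower = 0.025^(1/24) ~ 0.858
#' @export
exact_binomial_ci <- function(successes, n, level = 0.95) {
  if (n < 1 || successes < 0 || successes > n)
    stop("require 0 <= successes <= n and n >= 1")
  if (level <= 0 || level >= 1) stop("level must be in (0, 1)")
  alpha <- 1 - level
  lower <- if (successes == 0) 0 else qbeta(alpha / 2, successes, n - successes + 1)
  upper <- if (successes == n) 1 else qbeta(1 - alpha / 2, successes + 1, n - successes)
  c(lower = lower, upper = upper)
}

#' Confusion-matrix metrics for induction-mode predictions
#'
#' Benchmarks predicted SdP/SiP calls against experimental truth.
#' Sensitivity and specificity are with respect to `positive_label`;
#' accuracy gets an exact binomial confidence interval
#' ([exact_binomial_ci()]). SuP predictions have no experimental
#' counterpart: by default they count as wrong against either truth
#' (`sup_policy = "count_wrong"`); `"exclude"` drops those cases instead.
#'
#' @param truth character vector over `{SdP, SiP}`.
#' @param predicted character vector over `{SdP, SiP, SuP}`, same length.
#' @param positive_label the class treated as positive (default `"SdP"`).
#' @param sup_policy `"count_wrong"` or `"exclude"`.
#' @param level confidence level for the accuracy interval.
#' @return a `validation_result` (list with `n`, `tp`, `tn`, `fp`, `fn`,
#'   `sensitivity`, `specificity`, `accuracy`, `accuracy_ci`, `level`).
#' @export
confusion_metrics <- function(truth, predicted, positive_label = "SdP",
                              sup_policy = c("count_wrong", "exclude"),
                              level = 0.95) {
  sup_policy <- match.arg(sup_policy)
  if (length(truth) != length(predicted))
    stop("truth and predicted have different lengths")
  if (!all(truth %in% c("SdP", "SiP")))
    stop("truth labels must be SdP or SiP")
  if (!all(predicted %in% c("SdP", "SiP", "SuP")))
    stop("predicted labels must be SdP, SiP or SuP")
  if (sup_policy == "exclude") {
    keep <- predicted != "SuP"
    truth <- truth[keep]; predicted <- predicted[keep]
  }
  pos <- truth == positive_label
  pred_pos <- predicted == positive_label
  # an SuP prediction (under count_wrong) is neither positive nor negative:
  # it is wrong against both truths, i.e. FN if truth positive else FP
  sup <- predicted == "SuP"
  tp <- sum(pos & pred_pos)
  tn <- sum(!pos & !pred_pos & !sup)
  fn <- sum(pos & !pred_pos)
  fp <- sum(!pos & (pred_pos | sup))
  n <- length(truth)
  sens <- if (sum(pos) == 0) NA_real_ else tp / sum(pos)
  spec <- if (sum(!pos) == 0) NA_real_ else tn / sum(!pos)
  acc <- if (n == 0) NA_real_ else (tp + tn) / n
  ci <- if (n > 0) exact_binomial_ci(tp + tn, n, level) else c(lower = NA_real_, upper = NA_real_)
  structure(list(n = n, tp = tp, tn = tn, fp = fp, fn = fn,
                 sensitivity = sens, specificity = spec, accuracy = acc,
                 accuracy_ci = ci, level = level,
                 positive_label = positive_label, sup_policy = sup_policy),
            class = "validation_result")
}

#' @export
print.validation_result <- function(x, ...) {
  cat(sprintf("<validation_result> n=%d (positive = %s)\n", x$n, x$positive_label))
  cat(sprintf("  tp=%d tn=%d fp=%d fn=%d\n", x$tp, x$tn, x$fp, x$fn))
  cat(sprintf("  sensitivity %.1f%%, specificity %.1f%%, accuracy %.1f%% (%g%% CI %.1f-%.1f%%)\n",
              100 * x$sensitivity, 100 * x$specificity, 100 * x$accuracy,
              100 * x$level, 100 * x$accuracy_ci[["lower"]],
              100 * x$accuracy_ci[["upper"]]))
  invisible(x)
}

#' @rdname confusion_metrics
#' @param x a `validation_result`.
#' @param ... unused.
#' @export
tidy.validation_result <- function(x, ...) {
  tibble(metric = c("sensitivity", "specificity", "accuracy"),
         estimate = c(x$sensitivity, x$specificity, x$accuracy),
         conf.low = c(NA_real_, NA_real_, x$accuracy_ci[["lower"]]),
         conf.high = c(NA_real_, NA_real_, x$accuracy_ci[["upper"]]))
}

#' @rdname confusion_metrics
#' @export
glance.validation_result <- function(x, ...) {
  tibble(n = x$n, tp = x$tp, tn = x$tn, fp = x$fp, fn = x$fn,
         sensitivity = x$sensitivity, specificity = x$specificity,
         accuracy = x$accuracy,
         ci_lower = x$accuracy_ci[["lower"]],
         ci_upper = x$accuracy_ci[["upper"]],
         level = x$level)
}
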