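#' Screening performance metrics with 95% confidence intervals
#'
#' Tallies the 2x2 confusion table of predicted versus true labels (+1 =
#' low bone mineral density, the screening-positive class) and reports
#' sensitivity, specificity, positive and negative predictive values,
#' accuracy and the positive likelihood ratio. Proportions carry Wald
#' normal-approximation intervals `p +/- z * sqrt(p (1 - p) / m)` clipped
#' to \[0, 1\], where `m` is the denominator of each proportion. The
#' likelihood ratio uses the standard log-scale interval; with perfect
#' specificity it is flagged as infinite rather than raising an error.
#'
#' @param predictions Predicted labels (-1/+1 or 0/1).
#' @param labels True labels, same coding, same length.
#' @param conf_level Confidence level for the intervals.
#' @return A tibble of class `mcw_metrics` with columns `metric`,
#'   `estimate`, `conf_low`, `conf_high`, and the confusion counts stored
#'   in the `counts` attribute.
#' @examples
#' screening_metrics(rep(c(1, -1), c(12, 18)), rep(c(1, -1), c(10, 20)))
#' @export
screening_metrics <- function(predictions, labels, conf_level = 0.95) {
  pred <- normalize_labels(predictions)
  y <- normalize_labels(labels)
  if (length(pred) != length(y)) {
    abort("predictions and labels must have equal length")
  }
  if (!any(y == 1) || !any(y == -1)) {
    abort("labels must include at least one positive and one negative")
  }
  tp <- sum(pred == 1 & y == 1)
  fn <- sum(pred == -1 & y == 1)
  fp <- sum(pred == 1 & y == -1)
  tn <- sum(pred == -1 & y == -1)
  n <- length(y)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)

  prop_ci <- function(num, den) {
    if (den == 0L) return(c(NA_real_, NA_real_, NA_real_))
    p <- num / den
    half <- z * sqrt(p * (1 - p) / den)
    c(p, max(0, p - half), min(1, p + half))
  }
  sens <- prop_ci(tp, tp + fn)
  spec <- prop_ci(tn, tn + fp)
  ppv <- prop_ci(tp, tp + fp)
  npv <- prop_ci(tn, tn + fn)
  acc <- prop_ci(tp + tn, n)

  if (spec[1L] >= 1) {
    lr <- c(Inf, Inf, Inf) # perfect specificity: flagged infinite, not an error
  } else if (sens[1L] == 0) {
    lr <- c(0, NA_real_, NA_real_)
  } else {
    est <- sens[1L] / (1 - spec[1L])
    if (tp > 0 && fp > 0) {
      se_log <- sqrt(1 / tp - 1 / (tp + fn) + 1 / fp - 1 / (fp + tn))
      lr <- c(est, est * exp(-z * se_log), est * exp(z * se_log))
    } else {
      lr <- c(est, NA_real_, NA_real_)
    }
  }

  out <- tibble(
    metric = c("sensitivity", "specificity", "ppv", "npv", "accuracy", "lr_plus"),
    estimate = c(sens[1L], spec[1L], ppv[1L], npv[1L], acc[1L], lr[1L]),
    conf_low = c(sens[2L], spec[2L], ppv[2L], npv[2L], acc[2L], lr[2L]),
    conf_high = c(sens[3L], spec[3L], ppv[3L], npv[3L], acc[3L], lr[3L])
  )
  structure(out,
    class = c("mcw_metrics", class(tibble())),
    counts = c(TP = tp, FN = fn, FP = fp, TN = tn),
    conf_level = conf_level
  )
}
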