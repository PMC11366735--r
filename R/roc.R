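# ROC construction, AUC and Youden's-J-optimal threshold selection.
#
# Direction convention: "positive_class_low" encodes rules of the form
# score < t (e.g. "ADC tumor ratio < 0.87 detects mCNSL");
# "positive_class_high" encodes score > t. Candidate thresholds are placed
# at midpoints between adjacent distinct scores, plus -Inf/+Inf sentinels,
# so reported cut-offs reproduce the open-interval rules.

#' Empirical ROC curve
#'
#' @param scores Numeric scores, one per record.
#' @param labels Positive-class indicator (logical, or coercible 0/1).
#' @param direction `"positive_class_low"`, `"positive_class_high"`, or
#'   `NULL` to auto-orient towards AUC >= 0.5.
#' @return A `lesiondx_roc` list: `curve` (tibble of `threshold`,
#'   `sensitivity`, `specificity`), `auc`, `direction`, `n_pos`, `n_neg`,
#'   and `score_median` (used by the threshold tie-break).
#' @export
roc_curve <- function(scores, labels, direction = NULL) {
  labels <- as.logical(labels)
  keep <- !is.na(scores) & !is.na(labels)
  scores <- scores[keep]
  labels <- labels[keep]
  n_pos <- as.numeric(sum(labels))
  n_neg <- as.numeric(sum(!labels))
  if (n_pos == 0 || n_neg == 0) {
    abort("both classes must be present", class = "lesiondx_domain_error")
  }
  if (!is.null(direction)) {
    direction <- match.arg(direction,
                           c("positive_class_low", "positive_class_high"))
  }

  # Mann-Whitney AUC with half credit for ties (equals the trapezoidal
  # area under the empirical staircase)
  r <- rank(scores, ties.method = "average")
  auc_high <- (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  if (is.null(direction)) {
    direction <- if (auc_high >= 0.5) "positive_class_high" else
      "positive_class_low"
  }
  auc_val <- if (direction == "positive_class_high") auc_high else
    1 - auc_high

  s <- sort(unique(scores))
  k <- length(s)
  thresholds <- c(-Inf, if (k > 1) (s[-1] + s[-k]) / 2, Inf)
  idx <- match(scores, s)
  cum_pos <- cumsum(tabulate(idx[labels], nbins = k))
  cum_neg <- cumsum(tabulate(idx[!labels], nbins = k))
  # counts predicted positive at each cut (cuts sit between distinct scores)
  if (direction == "positive_class_low") {
    tp <- c(0, cum_pos)
    fp <- c(0, cum_neg)
  } else {
    tp <- c(n_pos, n_pos - cum_pos)
    fp <- c(n_neg, n_neg - cum_neg)
  }
  curve <- tibble(
    threshold = thresholds,
    sensitivity = tp / n_pos,
    specificity = 1 - fp / n_neg
  )

  structure(
    list(curve = curve, auc = auc_val, direction = direction,
         n_pos = n_pos, n_neg = n_neg,
         score_median = stats::median(scores)),
    class = "lesiondx_roc"
  )
}

#' Area under the ROC curve
#'
#' Equals the Mann-Whitney probability that a positive-class score beats a
#' negative-class score in the chosen direction, with half credit for
#' ties.
#'
#' @param roc A `lesiondx_roc` object.
#' @return The AUC in `[0, 1]`.
#' @export
auc <- function(roc) {
  stopifnot(inherits(roc, "lesiondx_roc"))
  roc$auc
}

#' Youden's-J-optimal threshold
#'
#' Maximizes J = sensitivity + specificity - 1 over the candidate
#' thresholds of the curve. Ties are broken by higher specificity, then by
#' proximity of the threshold to the grand score median (high-specificity
#' rules are preferred, mirroring the rule ordering of the diagnostic
#' algorithm).
#'
#' @param roc A `lesiondx_roc` object.
#' @return A one-row tibble: `threshold`, `J`, `sensitivity`,
#'   `specificity`, `direction`.
#' @export
youden_optimal_threshold <- function(roc) {
  stopifnot(inherits(roc, "lesiondx_roc"))
  cv <- roc$curve
  J <- cv$sensitivity + cv$specificity - 1
  best <- which(J >= max(J) - 1e-12)
  if (length(best) > 1) {
    top_spec <- best[cv$specificity[best] >= max(cv$specificity[best]) - 1e-12]
    dist <- abs(cv$threshold[top_spec] - roc$score_median)
    dist[!is.finite(cv$threshold[top_spec])] <- Inf
    best <- top_spec[which.min(dist)]
    if (length(best) == 0) best <- top_spec[1]
  }
  tibble(
    threshold = cv$threshold[best],
    J = J[best],
    sensitivity = cv$sensitivity[best],
    specificity = cv$specificity[best],
    direction = roc$direction
  )
}

#' Closed-form AUC of two Gaussian score distributions
#'
#' For scores distributed N(mean_pos, sd_pos) and N(mean_neg, sd_neg) the
#' ROC AUC (in the favorable direction) is
#' `pnorm(|mean_pos - mean_neg| / sqrt(sd_pos^2 + sd_neg^2))`. Serves as
#' the analytic oracle for the empirical AUC on simulated cohorts.
#'
#' @param mean_pos,sd_pos Positive-class score mean and SD.
#' @param mean_neg,sd_neg Negative-class score mean and SD.
#' @return The AUC in `[0.5, 1]`.
#' @export
auc_gaussian_closed_form <- function(mean_pos, sd_pos, mean_neg, sd_neg) {
  if (sd_pos <= 0 || sd_neg <= 0) {
    abort("standard deviations must be positive",
          class = "lesiondx_domain_error")
  }
  stats::pnorm(abs(mean_pos - mean_neg) / sqrt(sd_pos^2 + sd_neg^2))
}
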