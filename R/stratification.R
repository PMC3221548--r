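#' Screening metrics at every possible high-risk threshold
#'
#' The high-risk group at threshold t is every individual with score >= t.
#' One row is produced per candidate threshold: each distinct observed score
#' value plus one sentinel above the maximum (empty high-risk group), or an
#' explicit grid supplied via `thresholds`. Per row: the confusion counts
#' (TP, FP, TN, FN), the high-risk-group frequency q = (TP+FP)/n,
#' sensitivity, specificity, PPV and NPV. PPV is `NA` when nobody is flagged
#' and NPV is `NA` when everybody is flagged (0/0 has no screening meaning
#' and would corrupt replicate means).
#'
#' @param scores Numeric vector or `risk_score`.
#' @param status 0/1 disease-status vector of the same length; both classes
#'   must be present.
#' @param thresholds Optional numeric vector of thresholds to evaluate
#'   (default: distinct observed scores plus a sentinel).
#' @return A data.frame of class `threshold_table`, rows ordered by
#'   threshold ascending, columns `threshold`, `highrisk_frequency`,
#'   `sensitivity`, `specificity`, `ppv`, `npv`, `tp`, `fp`, `tn`, `fn`.
#' @examples
#' threshold_table(c(1, 2, 3, 4), c(0, 0, 1, 1))
#' @export
threshold_table <- function(scores, status, thresholds = NULL) {
  sc <- score_values(scores)
  if (length(sc) != length(status))
    stop("'scores' and 'status' must have equal length", call. = FALSE)
  if (!all(status %in% c(0L, 1L))) stop("'status' must be binary 0/1",
                                        call. = FALSE)
  n1 <- sum(status == 1L)
  n0 <- sum(status == 0L)
  if (n1 == 0L || n0 == 0L)
    stop("both affected and unaffected individuals are required ",
         "(sensitivity or specificity undefined otherwise)", call. = FALSE)
  n <- n1 + n0

  u <- sort(unique(sc))
  sentinel <- if (all(sc == round(sc))) max(u) + 1 else Inf
  if (is.null(thresholds)) thresholds <- c(u, sentinel)
  thresholds <- sort(unique(thresholds))

  # cumulative counts over distinct values give #(score < t) for any t
  pos <- match(sc, u)
  cases_at <- vapply(split(status == 1L, pos), sum, numeric(1))
  below_cases <- c(0, cumsum(cases_at))
  below_all   <- c(0, cumsum(tabulate(pos, length(u))))
  strictly_below <- findInterval(thresholds, u, left.open = TRUE)
  tp <- as.integer(round(n1 - below_cases[strictly_below + 1L]))
  flagged <- as.integer(round(n - below_all[strictly_below + 1L]))
  fp <- flagged - tp
  fn <- n1 - tp
  tn <- n0 - fp

  out <- data.frame(
    threshold = thresholds,
    highrisk_frequency = flagged / n,
    sensitivity = tp / n1,
    specificity = tn / n0,
    ppv = ifelse(tp + fp > 0, tp / (tp + fp), NA_real_),
    npv = ifelse(tn + fn > 0, tn / (tn + fn), NA_real_),
    tp = tp, fp = fp, tn = tn, fn = fn)
  class(out) <- c("threshold_table", "data.frame")
  attr(out, "n_cases") <- n1
  attr(out, "n_controls") <- n0
  out
}

#' Rank-based AUC with confidence interval
#'
#' The area under the empirical ROC curve, computed as the Mann-Whitney
#' statistic with midrank tie handling:
#' `[#(case > control) + 0.5 #(ties)] / (n_cases * n_controls)`. This equals
#' the trapezoidal area under the empirical ROC exactly. The 95% (or
#' `conf_level`) confidence interval uses the DeLong variance estimator by
#' default, with the Hanley-McNeil approximation as an option; intervals are
#' clamped to \[0, 1\].
#'
#' @param scores Numeric vector or `risk_score`.
#' @param status 0/1 vector; both classes must be present.
#' @param ci_method `"delong"` (default) or `"hanley"`.
#' @param conf_level Confidence level (default 0.95).
#' @return A `discrimination_result`: list with `auc`, `ci_low`, `ci_high`,
#'   `se`, `n_cases`, `n_controls`, `ci_method`, `conf_level`.
#' @examples
#' auc(c(1, 3, 2, 4), c(0, 0, 1, 1))  # 3 of 4 pairs concordant -> 0.75
#' @export
auc <- function(scores, status, ci_method = c("delong", "hanley"),
                conf_level = 0.95) {
  ci_method <- match.arg(ci_method)
  sc <- score_values(scores)
  if (length(sc) != length(status))
    stop("'scores' and 'status' must have equal length", call. = FALSE)
  if (!all(status %in% c(0L, 1L))) stop("'status' must be binary 0/1",
                                        call. = FALSE)
  is_case <- status == 1L
  n1 <- sum(is_case); n0 <- sum(!is_case)
  if (n1 == 0L || n0 == 0L)
    stop("both affected and unaffected individuals are required",
         call. = FALSE)
  r <- rank(sc)  # midranks
  a <- (sum(r[is_case]) - n1 * (n1 + 1) / 2) / (n1 * n0)

  if (ci_method == "delong") {
    # placement values: V10_i = P-hat(control < case_i) (ties half)
    v10 <- (r[is_case] - rank(sc[is_case])) / n0
    v01 <- 1 - (r[!is_case] - rank(sc[!is_case])) / n1
    s2 <- stats::var(v10) / n1 + stats::var(v01) / n0
    se <- sqrt(s2)
  } else {
    q1 <- a / (2 - a)
    q2 <- 2 * a^2 / (1 + a)
    se <- sqrt((a * (1 - a) + (n1 - 1) * (q1 - a^2) +
                  (n0 - 1) * (q2 - a^2)) / (n1 * n0))
  }
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  structure(list(auc = a,
                 ci_low = max(0, a - z * se),
                 ci_high = min(1, a + z * se),
                 se = se, n_cases = n1, n_controls = n0,
                 ci_method = ci_method, conf_level = conf_level),
            class = "discrimination_result")
}

#' @export
print.discrimination_result <- function(x, ...) {
  cat(sprintf("AUC = %.4f (%d%% CI %.4f-%.4f, %s; %d cases, %d controls)\n",
              x$auc, round(100 * x$conf_level), x$ci_low, x$ci_high,
              x$ci_method, x$n_cases, x$n_controls))
  invisible(x)
}

#' Threshold giving a high-risk group of a target frequency
#'
#' Among the candidate thresholds (distinct observed scores plus the empty
#' sentinel), returns the one whose achieved high-risk-group frequency is
#' closest to `target_q`; exact ties are broken towards the smaller group
#' (the higher threshold).
#'
#' @param scores Numeric vector or `risk_score`.
#' @param target_q Target high-risk-group frequency, in (0, 1).
#' @return List with `threshold` and `achieved_q`.
#' @examples
#' threshold_for_group_frequency(c(1, 1, 1, 2), 0.5)  # -> threshold 2
#' @export
threshold_for_group_frequency <- function(scores, target_q) {
  sc <- score_values(scores)
  if (target_q <= 0 || target_q >= 1)
    stop("'target_q' must lie strictly between 0 and 1", call. = FALSE)
  u <- sort(unique(sc))
  sentinel <- if (all(sc == round(sc))) max(u) + 1 else Inf
  cand <- c(u, sentinel)
  n <- length(sc)
  q <- vapply(cand, function(t) sum(sc >= t) / n, numeric(1))
  d <- abs(q - target_q)
  best <- which(d == min(d))
  best <- best[length(best)]  # highest threshold among ties (smaller group)
  list(threshold = cand[best], achieved_q = q[best])
}

#' Re-index a threshold table by high-risk-group frequency
#'
#' Returns the same screening table keyed (and ordered) by the frequency of
#' the high-risk group q instead of the threshold, the view in which the
#' sensitivity and PPV curves cross where q equals the disease frequency
#' (the ratio law sens/PPV = q/p).
#'
#' @param table A `threshold_table`.
#' @return A data.frame ordered by `highrisk_frequency` ascending with the
#'   same metric columns.
#' @export
metrics_vs_group_frequency <- function(table) {
  stopifnot(inherits(table, "threshold_table") || is.data.frame(table))
  out <- table[order(table$highrisk_frequency), , drop = FALSE]
  rownames(out) <- NULL
  cols <- c("highrisk_frequency", "threshold", "sensitivity", "specificity",
            "ppv", "npv")
  out[, c(cols, setdiff(names(out), cols)), drop = FALSE]
}
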