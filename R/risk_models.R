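#' Construct a risk-score vector
#'
#' Light container pairing per-individual score values with the kind of score
#' (`"count"`, `"bayes_risk"` or `"logistic_risk"`). Count scores must be
#' integers; risks must lie in \[0, 1\].
#'
#' @param values Numeric vector.
#' @param kind One of `"count"`, `"bayes_risk"`, `"logistic_risk"`.
#' @return A `risk_score` object (numeric vector with a `kind` attribute).
#' @export
risk_score <- function(values, kind = c("count", "bayes_risk",
                                        "logistic_risk")) {
  kind <- match.arg(kind)
  if (!is.numeric(values)) stop("scores must be numeric", call. = FALSE)
  if (kind == "count" && any(values != round(values)))
    stop("count scores must be integers", call. = FALSE)
  if (kind != "count" && (any(values < 0) || any(values > 1)))
    stop("predicted risks must lie in [0, 1]", call. = FALSE)
  structure(as.numeric(values), kind = kind, class = "risk_score")
}

#' @export
print.risk_score <- function(x, ...) {
  cat(sprintf("risk score (%s), n=%d, range %.4g..%.4g\n", attr(x, "kind"),
              length(x), min(x), max(x)))
  invisible(x)
}

score_values <- function(scores) {
  if (inherits(scores, "risk_score")) as.numeric(scores)
  else if (is.numeric(scores)) scores
  else stop("scores must be numeric or a risk_score", call. = FALSE)
}

#' Count-of-risk-genotypes score
#'
#' The simple genetic risk score: the number of risk genotypes an individual
#' carries across the panel. In homogeneous panels (all variants sharing the
#' same frequency and effect size) this count orders individuals exactly as
#' the model-based predicted risk does.
#'
#' @param x A `cohort` from [simulate_cohort()] or an n x m 0/1 matrix.
#' @return A `risk_score` of kind `"count"`.
#' @export
count_score <- function(x) {
  g <- if (inherits(x, "cohort")) x$genotypes else x
  if (!is.matrix(g)) stop("expected a cohort or a genotype matrix",
                          call. = FALSE)
  if (!all(g == 0L | g == 1L))
    stop("genotype matrix must be binary (0/1)", call. = FALSE)
  risk_score(rowSums(g), "count")
}

#' Bayes posterior disease risk under the multiplicative odds model
#'
#' Per individual, the posterior odds of disease are the prior odds
#' `p/(1-p)` multiplied by one likelihood ratio per variant:
#' `a_j/b_j` if the risk genotype is carried and `(1-a_j)/(1-b_j)` otherwise,
#' where `a_j`/`b_j` are the case/control risk-genotype frequencies. The
#' returned risk is `odds/(1+odds)`.
#'
#' @param genotypes n x m 0/1 matrix.
#' @param case_control_freqs data.frame with columns `freq_cases`,
#'   `freq_controls` (one row per variant), e.g. from
#'   [solve_case_control_freqs()] applied per variant, or the
#'   `case_control_freqs` element of an odds-model cohort.
#' @param p Population disease risk, in (0, 1).
#' @return A `risk_score` of kind `"bayes_risk"`.
#' @export
bayes_risk <- function(genotypes, case_control_freqs, p) {
  if (!is.matrix(genotypes) || !all(genotypes == 0L | genotypes == 1L))
    stop("genotype matrix must be binary (0/1)", call. = FALSE)
  a <- case_control_freqs$freq_cases
  b <- case_control_freqs$freq_controls
  if (length(a) != ncol(genotypes))
    stop("one case/control frequency pair is required per variant",
         call. = FALSE)
  if (any(a <= 0 | a >= 1 | b <= 0 | b >= 1))
    stop("degenerate likelihood: case/control frequencies must lie strictly ",
         "between 0 and 1", call. = FALSE)
  if (p <= 0 || p >= 1) stop("'p' must lie strictly between 0 and 1",
                             call. = FALSE)
  log_lr <- genotypes %*% log(a / b) +
    (1 - genotypes) %*% log((1 - a) / (1 - b))
  odds <- p / (1 - p) * exp(as.vector(log_lr))
  risk_score(odds / (1 + odds), "bayes_risk")
}

#' Predicted risks from logistic regression on categorical genotypes
#'
#' Fits a maximum-likelihood logistic regression of disease status on the
#' genotype categories of each locus (indicator coding against the stated
#' reference levels) and returns the fitted probabilities. Fitting uses
#' iteratively reweighted least squares with relative deviance tolerance
#' 1e-8 and at most 100 iterations.
#'
#' @param genotypes data.frame of factors, one column per locus (e.g. the
#'   `genotypes` element of [simulate_amd_cohort()]'s result).
#' @param status 0/1 vector of disease status.
#' @param reference_levels Optional character vector, one reference category
#'   per locus; defaults to the existing first factor level of each column.
#' @return A `risk_score` of kind `"logistic_risk"` with attributes `fit`
#'   (the `glm` object) and `coefficients`.
#' @export
logistic_risk <- function(genotypes, status, reference_levels = NULL) {
  if (!is.data.frame(genotypes)) stop("'genotypes' must be a data.frame",
                                      call. = FALSE)
  if (nrow(genotypes) != length(status))
    stop("'genotypes' and 'status' must have matching length", call. = FALSE)
  if (!all(status %in% c(0L, 1L))) stop("'status' must be binary 0/1",
                                        call. = FALSE)
  dat <- genotypes
  for (j in seq_along(dat)) {
    if (!is.factor(dat[[j]])) dat[[j]] <- factor(dat[[j]])
    observed <- levels(dat[[j]])[levels(dat[[j]]) %in% unique(as.character(dat[[j]]))]
    if (length(observed) < nlevels(dat[[j]])) {
      warning("dropping unobserved categories at locus '", names(dat)[j], "'",
              call. = FALSE)
      dat[[j]] <- factor(as.character(dat[[j]]), levels = observed)
    }
    if (!is.null(reference_levels)) {
      ref <- reference_levels[j]
      if (!ref %in% levels(dat[[j]]))
        stop("reference level '", ref, "' not observed at locus '",
             names(dat)[j], "'", call. = FALSE)
      dat[[j]] <- stats::relevel(dat[[j]], ref)
    }
  }
  # loci reduced to a single observed category carry no information; the
  # model then collapses towards intercept-only
  keep <- vapply(dat, nlevels, integer(1)) >= 2L
  dat <- dat[keep]
  dat$.status <- as.integer(status)
  fit <- withCallingHandlers(
    stats::glm(.status ~ ., family = stats::binomial(), data = dat,
               control = stats::glm.control(epsilon = 1e-8, maxit = 100)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        stop("logistic fit failed: perfect (or quasi-perfect) separation",
             call. = FALSE)
      invokeRestart("muffleWarning")
    })
  if (!fit$converged)
    stop("logistic fit did not converge within 100 iterations", call. = FALSE)
  out <- risk_score(as.numeric(stats::fitted(fit)), "logistic_risk")
  attr(out, "fit") <- fit
  attr(out, "coefficients") <- stats::coef(fit)
  out
}
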