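#' riskstrat: simulation and evaluation of genetic risk stratification
#'
#' Tools to simulate cohorts whose risk-genotype frequencies, per-variant
#' effect sizes and population disease risk match prespecified values, to turn
#' genotypes into genetic risk scores, and to characterise the screening
#' performance (sensitivity, specificity, PPV, NPV, AUC) of every possible
#' high-risk threshold.
#'
#' @section Effect models:
#' Two generative models are available. `"multiplicative_risk"` (the default)
#' draws risk genotypes at their population frequencies and assigns each
#' individual a disease probability equal to a baseline risk multiplied by the
#' per-variant effect size for every risk genotype carried, capped at 1; the
#' baseline is calibrated by root finding so that the cohort mean risk equals
#' the population disease risk. `"multiplicative_odds"` draws disease status
#' first at the population risk and then risk genotypes at case/control
#' frequencies solved so that the marginal frequency and the 2x2 odds ratio of
#' every variant match their prespecified values exactly (see
#' [solve_case_control_freqs()]).
#'
#' @keywords internal
#' @importFrom stats rbinom uniroot
"_PACKAGE"

#' Specify one genetic variant
#'
#' A variant is reduced to its risk-genotype indicator: the population
#' frequency `frequency` of the risk genotype and the effect size
#' `odds_ratio` of carrying it (odds ratio under the multiplicative-odds
#' model, risk ratio under the multiplicative-risk model).
#'
#' @param frequency Population frequency of the risk genotype, in (0, 1).
#' @param odds_ratio Positive effect size of the risk genotype.
#' @return A `variant_spec` object (named list).
#' @examples
#' variant_spec(0.3, 1.5)
#' @export
variant_spec <- function(frequency, odds_ratio) {
  stopifnot(is.numeric(frequency), length(frequency) == 1L,
            is.numeric(odds_ratio), length(odds_ratio) == 1L)
  if (!is.finite(frequency) || frequency <= 0 || frequency >= 1)
    stop("variant 'frequency' must lie strictly between 0 and 1, got ",
         frequency, call. = FALSE)
  if (!is.finite(odds_ratio) || odds_ratio <= 0)
    stop("variant 'odds_ratio' must be a positive number, got ",
         odds_ratio, call. = FALSE)
  structure(list(frequency = frequency, odds_ratio = odds_ratio),
            class = "variant_spec")
}

#' Assemble a simulation scenario
#'
#' Bundles everything needed to simulate replicate cohorts: the cohort size,
#' the population disease risk, the variant panel, the number of replicates,
#' the master seed, and the effect model.
#'
#' Homogeneous panels can be given in shorthand via `n_variants`,
#' `frequency` and `odds_ratio` instead of an explicit `variants` list.
#'
#' @param n_individuals Cohort size (positive integer).
#' @param disease_risk Population disease risk, in (0, 1).
#' @param variants List of [variant_spec()] objects, or a data.frame with
#'   columns `frequency` and `odds_ratio`.
#' @param n_variants,frequency,odds_ratio Shorthand for a homogeneous panel of
#'   `n_variants` identical variants.
#' @param n_replicates Number of replicate cohorts (positive integer).
#' @param seed Master seed; replicate streams are derived from it so every
#'   replicate is individually reproducible.
#' @param effect_model `"multiplicative_risk"` (default) or
#'   `"multiplicative_odds"`; see the package help page.
#' @return A `scenario_config` object.
#' @examples
#' scenario_config(10000, 0.3, n_variants = 50, frequency = 0.3,
#'                 odds_ratio = 1.1, n_replicates = 100, seed = 1)
#' @export
scenario_config <- function(n_individuals, disease_risk, variants = NULL,
                            n_variants = NULL, frequency = NULL,
                            odds_ratio = NULL, n_replicates = 1L, seed = 1L,
                            effect_model = c("multiplicative_risk",
                                             "multiplicative_odds")) {
  effect_model <- match.arg(effect_model)
  if (!is.numeric(n_individuals) || length(n_individuals) != 1L ||
      n_individuals < 1 || n_individuals != round(n_individuals))
    stop("'n_individuals' must be a positive integer", call. = FALSE)
  if (!is.numeric(disease_risk) || length(disease_risk) != 1L ||
      disease_risk <= 0 || disease_risk >= 1)
    stop("'disease_risk' must lie strictly between 0 and 1", call. = FALSE)
  if (!is.numeric(n_replicates) || length(n_replicates) != 1L ||
      n_replicates < 1 || n_replicates != round(n_replicates))
    stop("'n_replicates' must be a positive integer", call. = FALSE)
  if (!is.numeric(seed) || length(seed) != 1L || seed != round(seed))
    stop("'seed' must be an integer", call. = FALSE)

  if (is.null(variants)) {
    if (is.null(n_variants) || is.null(frequency) || is.null(odds_ratio))
      stop("supply either 'variants' or the homogeneous shorthand ",
           "'n_variants' + 'frequency' + 'odds_ratio'", call. = FALSE)
    if (n_variants < 1 || n_variants != round(n_variants))
      stop("'n_variants' must be a positive integer", call. = FALSE)
    vs <- variant_spec(frequency, odds_ratio)  # validates ranges
    variants <- data.frame(frequency = rep(vs$frequency, n_variants),
                           odds_ratio = rep(vs$odds_ratio, n_variants))
  } else if (is.data.frame(variants)) {
    if (!all(c("frequency", "odds_ratio") %in% names(variants)))
      stop("'variants' data.frame needs columns 'frequency' and 'odds_ratio'",
           call. = FALSE)
    invisible(Map(variant_spec, variants$frequency, variants$odds_ratio))
    variants <- variants[c("frequency", "odds_ratio")]
  } else if (is.list(variants)) {
    ok <- vapply(variants, inherits, logical(1), "variant_spec")
    if (length(variants) == 0L) stop("'variants' must be non-empty",
                                     call. = FALSE)
    if (!all(ok)) stop("'variants' must be a list of variant_spec objects",
                       call. = FALSE)
    variants <- data.frame(
      frequency  = vapply(variants, `[[`, numeric(1), "frequency"),
      odds_ratio = vapply(variants, `[[`, numeric(1), "odds_ratio"))
  } else stop("invalid 'variants'", call. = FALSE)
  if (nrow(variants) == 0L) stop("'variants' must be non-empty", call. = FALSE)

  structure(list(n_individuals = as.integer(n_individuals),
                 disease_risk  = disease_risk,
                 variants      = variants,
                 n_replicates  = as.integer(n_replicates),
                 seed          = as.integer(seed),
                 effect_model  = effect_model),
            class = "scenario_config")
}

#' @export
print.scenario_config <- function(x, ...) {
  cat(sprintf(paste0("scenario: n=%d, disease risk=%.3g, %d variants, ",
                     "%d replicate(s), seed=%d, model=%s\n"),
              x$n_individuals, x$disease_risk, nrow(x$variants),
              x$n_replicates, x$seed, x$effect_model))
  invisible(x)
}

#' Case/control risk-genotype frequencies matching a marginal frequency and OR
#'
#' Solves for the risk-genotype frequency among affected (`freq_cases`, a) and
#' unaffected (`freq_controls`, b) individuals such that the population
#' mixture reproduces the marginal frequency, `p*a + (1-p)*b = f`, and the
#' 2x2 odds ratio equals the prespecified value,
#' `[a/(1-a)] / [b/(1-b)] = OR`. Substituting the odds constraint into the
#' mixture yields a quadratic in b,
#' `(1-p)(OR-1) b^2 + [p*OR + (1-p) - f(OR-1)] b - f = 0`,
#' which always has exactly one root in (0, 1) for in-domain parameters
#' (the polynomial is -f < 0 at b = 0 and OR(1-f) > 0 at b = 1).
#'
#' @param f Marginal (total population) risk-genotype frequency, in (0, 1).
#' @param odds_ratio Odds ratio of the risk genotype, > 0.
#' @param p Population disease risk, in (0, 1).
#' @return List with `freq_cases`, `freq_controls` and the inputs.
#' @examples
#' solve_case_control_freqs(0.3, 2, 0.3)
#' @export
solve_case_control_freqs <- function(f, odds_ratio, p) {
  if (!is.numeric(f) || length(f) != 1L || !is.finite(f) || f <= 0 || f >= 1)
    stop("parameter infeasibility: marginal frequency f=", f,
         " must lie strictly between 0 and 1", call. = FALSE)
  if (!is.numeric(p) || length(p) != 1L || !is.finite(p) || p <= 0 || p >= 1)
    stop("parameter infeasibility: disease risk p=", p,
         " must lie strictly between 0 and 1", call. = FALSE)
  if (!is.numeric(odds_ratio) || length(odds_ratio) != 1L ||
      !is.finite(odds_ratio) || odds_ratio <= 0)
    stop("parameter infeasibility: odds ratio ", odds_ratio,
         " must be positive", call. = FALSE)

  if (odds_ratio == 1) {
    a <- b <- f
  } else {
    A <- (1 - p) * (odds_ratio - 1)
    B <- p * odds_ratio + (1 - p) - f * (odds_ratio - 1)
    C <- -f
    disc <- B^2 - 4 * A * C
    roots <- c((-B + sqrt(disc)) / (2 * A), (-B - sqrt(disc)) / (2 * A))
    b <- roots[roots > 0 & roots < 1]
    if (length(b) != 1L)
      stop("parameter infeasibility: no unique control frequency in (0,1) ",
           "for f=", f, ", OR=", odds_ratio, ", p=", p, call. = FALSE)
    odds_a <- odds_ratio * b / (1 - b)
    a <- odds_a / (1 + odds_a)
    if (a <= 0 || a >= 1)
      stop("parameter infeasibility: case frequency outside (0,1) for f=", f,
           ", OR=", odds_ratio, ", p=", p, call. = FALSE)
  }
  list(freq_cases = a, freq_controls = b, frequency = f,
       odds_ratio = odds_ratio, disease_risk = p)
}

# internal: case/control frequency table for a whole panel
panel_case_control_freqs <- function(variants, p) {
  sol <- lapply(seq_len(nrow(variants)), function(j) {
    tryCatch(
      solve_case_control_freqs(variants$frequency[j],
                               variants$odds_ratio[j], p),
      error = function(e)
        stop("variant ", j, ": ", conditionMessage(e), call. = FALSE))
  })
  data.frame(freq_cases    = vapply(sol, `[[`, numeric(1), "freq_cases"),
             freq_controls = vapply(sol, `[[`, numeric(1), "freq_controls"))
}

#' Derive the seed of one replicate stream
#'
#' Deterministic 31-bit mix of the scenario master seed and a replicate
#' index, so that replicates are mutually independent streams and each one is
#' individually reproducible.
#'
#' @param seed Master seed (integer).
#' @param index Replicate index (non-negative integer).
#' @return An integer seed in 1..2147483645.
#' @export
derive_stream_seed <- function(seed, index) {
  s <- as.double(seed) %% 2147483647
  x <- (s * 48271 + as.double(index) * 1664525 + 1013904223) %% 2147483647
  x <- (x * 69621) %% 2147483647
  as.integer(x %% 2147483645 + 1)
}

#' Simulate one replicate cohort
#'
#' Generates disease status and the binary risk-genotype matrix of one
#' replicate under the scenario's effect model. Deterministic given
#' `(config$seed, replicate_index)`.
#'
#' Under `"multiplicative_odds"`, status is an independent Bernoulli draw at
#' the population disease risk and, conditional on status, each variant's
#' risk-genotype indicator is Bernoulli at its case or control frequency from
#' [solve_case_control_freqs()]; marginal frequencies and 2x2 odds ratios
#' match their prespecified values in expectation.
#'
#' Under `"multiplicative_risk"`, risk genotypes are Bernoulli draws at the
#' population frequencies; each individual's disease risk is
#' `min(1, c * prod(OR_j^g_ij))` with the baseline `c` calibrated by root
#' finding so that the mean risk over the realized cohort equals the disease
#' risk; status is then Bernoulli at that individual risk.
#'
#' @param config A [scenario_config()].
#' @param replicate_index Replicate number, 1-based.
#' @return A `cohort` object: list with `status` (0/1 integer vector),
#'   `genotypes` (n x m 0/1 integer matrix), `risk` (per-individual disease
#'   probability; only for the multiplicative-risk model), `effect_model`,
#'   `disease_risk`, `variants`, `case_control_freqs` (odds model only),
#'   `seed`, `replicate_index`.
#' @examples
#' cfg <- scenario_config(500, 0.3, n_variants = 10, frequency = 0.3,
#'                        odds_ratio = 1.5, seed = 7)
#' ch <- simulate_cohort(cfg, 1)
#' mean(ch$status)
#' @export
simulate_cohort <- function(config, replicate_index = 1L) {
  stopifnot(inherits(config, "scenario_config"))
  if (replicate_index < 1 || replicate_index != round(replicate_index))
    stop("'replicate_index' must be a positive integer", call. = FALSE)
  n <- config$n_individuals
  m <- nrow(config$variants)
  p <- config$disease_risk
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  set.seed(derive_stream_seed(config$seed, replicate_index))

  ccf <- NULL
  risk <- NULL
  if (config$effect_model == "multiplicative_odds") {
    ccf <- panel_case_control_freqs(config$variants, p)
    status <- rbinom(n, 1L, p)
    genotypes <- matrix(0L, n, m)
    for (j in seq_len(m)) {
      pj <- ifelse(status == 1L, ccf$freq_cases[j], ccf$freq_controls[j])
      genotypes[, j] <- rbinom(n, 1L, pj)
    }
  } else {
    genotypes <- matrix(0L, n, m)
    for (j in seq_len(m))
      genotypes[, j] <- rbinom(n, 1L, config$variants$frequency[j])
    log_mult <- as.vector(genotypes %*% log(config$variants$odds_ratio))
    risk <- calibrated_risk(log_mult, p)
    status <- rbinom(n, 1L, risk)
  }
  if (!is.null(old)) assign(".Random.seed", old, globalenv())

  structure(list(status = as.integer(status), genotypes = genotypes,
                 risk = risk, effect_model = config$effect_model,
                 disease_risk = p, variants = config$variants,
                 case_control_freqs = ccf, seed = config$seed,
                 replicate_index = as.integer(replicate_index)),
            class = "cohort")
}

# internal: risk_i = min(1, exp(c + log_mult_i)) with c solved so that
# mean(risk) == p. Monotone in c, so uniroot is safe; bracket endpoints give
# mean <= p (all risks <= p) and mean = 1 respectively.
calibrated_risk <- function(log_mult, p) {
  lo <- log(p) - max(log_mult) - 1e-9
  hi <- -min(log_mult)
  h <- function(lc) mean(pmin(1, exp(lc + log_mult))) - p
  if (h(hi) <= 0) return(pmin(1, exp(hi + log_mult)))  # degenerate: all 1s cap
  lc <- uniroot(h, c(lo, hi), tol = 1e-13)$root
  pmin(1, exp(lc + log_mult))
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("cohort: %d individuals, %d variants, %d affected (%.1f%%), %s model\n",
              length(x$status), ncol(x$genotypes), sum(x$status),
              100 * mean(x$status), x$effect_model))
  invisible(x)
}

#' Export a cohort as a data.frame
#'
#' One row per individual: `id`, `status`, then one 0/1 column per variant
#' (`g1`..`gm`).
#'
#' @param cohort A `cohort` from [simulate_cohort()].
#' @return A data.frame.
#' @export
cohort_to_data_frame <- function(cohort) {
  stopifnot(inherits(cohort, "cohort"))
  g <- as.data.frame(cohort$genotypes)
  names(g) <- paste0("g", seq_len(ncol(g)))
  cbind(data.frame(id = seq_along(cohort$status), status = cohort$status), g)
}
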