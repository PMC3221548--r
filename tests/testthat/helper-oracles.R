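# Independent oracles used across the suite. These deliberately share no code
# with the package: bisection instead of the closed-form quadratic, explicit
# ROC trapezoids instead of ranks, and logical-indexing confusion tables.

# bisection on the control frequency b: p*a + (1-p)*b = f with a tied to b
# through the odds constraint a/(1-a) = OR * b/(1-b)
oracle_case_control_freqs <- function(f, or, p, tol = 1e-13) {
  a_of_b <- function(b) {
    o <- or * b / (1 - b)
    o / (1 + o)
  }
  g <- function(b) p * a_of_b(b) + (1 - p) * b - f
  lo <- 1e-12; hi <- 1 - 1e-12
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (g(mid) > 0) hi <- mid else lo <- mid
    if (hi - lo < tol) break
  }
  b <- (lo + hi) / 2
  list(freq_cases = a_of_b(b), freq_controls = b)
}

# trapezoidal area under the empirical ROC curve (thresholds at every
# distinct score value, descending)
oracle_trapezoid_auc <- function(scores, status) {
  thr <- sort(unique(scores), decreasing = TRUE)
  n1 <- sum(status == 1); n0 <- sum(status == 0)
  tpr <- c(0, vapply(thr, function(t) sum(scores >= t & status == 1) / n1,
                     numeric(1)))
  fpr <- c(0, vapply(thr, function(t) sum(scores >= t & status == 0) / n0,
                     numeric(1)))
  sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
}

# direct confusion-table metrics at one threshold (score >= t is high risk)
oracle_confusion <- function(scores, status, t) {
  flag <- scores >= t
  tp <- sum(flag & status == 1); fp <- sum(flag & status == 0)
  fn <- sum(!flag & status == 1); tn <- sum(!flag & status == 0)
  list(tp = tp, fp = fp, tn = tn, fn = fn,
       q = (tp + fp) / length(scores),
       sens = tp / (tp + fn), spec = tn / (fp + tn),
       ppv = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
       npv = if (tn + fn > 0) tn / (tn + fn) else NA_real_)
}

# empirical log odds ratio and its Woolf SE from a 2x2 of (genotype, status)
woolf_log_or <- function(genotype, status) {
  n11 <- sum(genotype == 1 & status == 1)
  n01 <- sum(genotype == 0 & status == 1)
  n10 <- sum(genotype == 1 & status == 0)
  n00 <- sum(genotype == 0 & status == 0)
  list(log_or = log(n11 * n00 / (n01 * n10)),
       se = sqrt(1 / n11 + 1 / n01 + 1 / n10 + 1 / n00))
}

make_headline_config <- function(or, n_replicates = 1L, seed = 1L,
                                 n = 10000L, p = 0.3,
                                 effect_model = "multiplicative_risk") {
  scenario_config(n, p, n_variants = 50, frequency = 0.3, odds_ratio = or,
                  n_replicates = n_replicates, seed = seed,
                  effect_model = effect_model)
}

# tiny all-null categorical parameter table (two loci)
null_amd_params <- function() {
  data.frame(
    locus = rep(c("L1", "L2"), c(3, 2)),
    genotype_label = c("aa", "aA", "AA", "bb", "bB"),
    control_frequency = c(0.5, 0.4, 0.1, 0.8, 0.2),
    odds_ratio = 1,
    is_reference = c(TRUE, FALSE, FALSE, TRUE, FALSE))
}
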