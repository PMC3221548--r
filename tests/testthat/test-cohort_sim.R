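test_that("solve_case_control_freqs matches the bisection oracle and its constraints", {
  # OR = 1 forces equal frequencies
  for (ex in list(c(0.3, 1.0, 0.3), c(0.5, 1.0, 0.1))) {
    s <- solve_case_control_freqs(ex[1], ex[2], ex[3])
    expect_equal(s$freq_cases, ex[1])
    expect_equal(s$freq_controls, ex[1])
  }
  # derived example against the independent bisection oracle
  s <- solve_case_control_freqs(0.3, 2.0, 0.3)
  o <- oracle_case_control_freqs(0.3, 2.0, 0.3)
  expect_equal(s$freq_cases, o$freq_cases, tolerance = 1e-9)
  expect_equal(s$freq_controls, o$freq_controls, tolerance = 1e-9)

  # constraint residuals across a parameter grid, protective ORs included
  grid <- expand.grid(f = c(0.01, 0.1, 0.3, 0.5, 0.9, 0.99),
                      or = c(0.2, 0.5, 1.1, 2, 10, 100),
                      p = c(0.01, 0.1, 0.3, 0.9))
  for (i in seq_len(nrow(grid))) {
    f <- grid$f[i]; or <- grid$or[i]; p <- grid$p[i]
    s <- solve_case_control_freqs(f, or, p)
    a <- s$freq_cases; b <- s$freq_controls
    expect_lt(abs(p * a + (1 - p) * b - f), 1e-9)
    expect_lt(abs((a / (1 - a)) / (b / (1 - b)) / or - 1), 1e-6)
    if (or >= 1) expect_true(b <= a) else expect_true(a <= b)
  }
})

test_that("solve_case_control_freqs rejects out-of-domain parameters", {
  expect_error(solve_case_control_freqs(0, 2, 0.3), "infeasibility")
  expect_error(solve_case_control_freqs(1.5, 2, 0.3), "infeasibility")
  expect_error(solve_case_control_freqs(0.3, -1, 0.3), "infeasibility")
  expect_error(solve_case_control_freqs(0.3, 2, 1), "infeasibility")
  # offending variant is named when a panel is solved
  cfg <- scenario_config(10, 0.3, variants = data.frame(
    frequency = c(0.3, 0.3), odds_ratio = c(1.5, 2)),
    effect_model = "multiplicative_odds")
  cfg$variants$frequency[2] <- 2  # corrupt after validation
  expect_error(simulate_cohort(cfg, 1), "variant 2")
})

test_that("odds-model cohorts match prespecified frequencies, ORs and risk", {
  cfg <- make_headline_config(1.1, seed = 11,
                              effect_model = "multiplicative_odds")
  ch <- simulate_cohort(cfg, 1)
  n <- cfg$n_individuals
  expect_equal(dim(ch$genotypes), c(n, 50))
  expect_true(all(ch$genotypes %in% 0:1))
  expect_true(all(ch$status %in% 0:1))

  # disease frequency within 3 binomial SEs of 0.3
  se_p <- sqrt(0.3 * 0.7 / n)
  expect_lt(abs(mean(ch$status) - 0.3), 3 * se_p)
  # marginal risk-genotype frequencies: 50 simultaneous checks, so demand
  # the ensemble rather than every single 3-SE event
  freqs <- colMeans(ch$genotypes)
  se_f <- sqrt(0.3 * 0.7 / n)
  expect_true(all(abs(freqs - 0.3) < 4.5 * se_f))
  expect_gt(mean(abs(freqs - 0.3) < 3 * se_f), 0.9)
  expect_lt(abs(mean(freqs) - 0.3), 3 * se_f / sqrt(50) * 2)
  # per-variant empirical ORs around 1.1 (Woolf SEs, ensemble criterion)
  z <- vapply(1:50, function(j) {
    w <- woolf_log_or(ch$genotypes[, j], ch$status)
    abs(w$log_or - log(1.1)) / w$se
  }, numeric(1))
  expect_true(all(z < 4.5))
  expect_gt(mean(z < 3), 0.9)
})

test_that("risk-model cohorts match the prespecified frequency, risk ratio and disease risk", {
  cfg <- make_headline_config(1.5, seed = 12)
  ch <- simulate_cohort(cfg, 1)
  n <- cfg$n_individuals
  # calibration makes the mean of the assigned risks equal p exactly
  expect_equal(mean(ch$risk), 0.3, tolerance = 1e-9)
  expect_lt(abs(mean(ch$status) - 0.3), 3 * sqrt(0.3 * 0.7 / n))
  se_f <- sqrt(0.3 * 0.7 / n)
  expect_true(all(abs(colMeans(ch$genotypes) - 0.3) < 4.5 * se_f))

  # the generating effect size acts on the risk scale; the marginal risk
  # ratio equals it exactly only while the risk cap never binds, so check
  # recovery on an uncapped configuration (max risk < 1 by construction)
  cfg2 <- scenario_config(20000, 0.15, n_variants = 8, frequency = 0.3,
                          odds_ratio = 1.3, seed = 13)
  ch2 <- simulate_cohort(cfg2, 1)
  expect_lt(max(ch2$risk), 1)
  for (j in 1:8) {
    g <- ch2$genotypes[, j]
    r1 <- mean(ch2$status[g == 1]); r0 <- mean(ch2$status[g == 0])
    se_log_rr <- sqrt((1 - r1) / (r1 * sum(g)) + (1 - r0) / (r0 * sum(1 - g)))
    expect_lt(abs(log(r1 / r0) - log(1.3)), 3.5 * se_log_rr)
  }
})

test_that("null scenarios carry no association", {
  for (model in c("multiplicative_risk", "multiplicative_odds")) {
    cfg <- scenario_config(8000, 0.3, n_variants = 10, frequency = 0.3,
                           odds_ratio = 1, seed = 5, effect_model = model)
    ch <- simulate_cohort(cfg, 1)
    a <- auc(count_score(ch), ch$status)
    expect_lt(abs(a$auc - 0.5), 3 * a$se)
  }
})

test_that("cohorts are reproducible per (seed, replicate) and differ across replicates", {
  cfg <- scenario_config(500, 0.2, n_variants = 5, frequency = 0.25,
                         odds_ratio = 1.4, n_replicates = 3, seed = 99)
  c1 <- simulate_cohort(cfg, 2)
  c2 <- simulate_cohort(cfg, 2)
  expect_identical(c1$status, c2$status)
  expect_identical(c1$genotypes, c2$genotypes)
  c3 <- simulate_cohort(cfg, 3)
  expect_false(identical(c1$genotypes, c3$genotypes))
  # the odds model is reproducible too
  cfg2 <- scenario_config(500, 0.2, n_variants = 5, frequency = 0.25,
                          odds_ratio = 1.4, seed = 99,
                          effect_model = "multiplicative_odds")
  expect_identical(simulate_cohort(cfg2, 1)$genotypes,
                   simulate_cohort(cfg2, 1)$genotypes)
})

test_that("status-first and Bayes risk-first constructions agree in distribution (odds model)", {
  # two variants, exact joint probabilities of (status, g1, g2)
  f <- c(0.3, 0.6); or <- c(2, 0.7); p <- 0.25; n <- 100000
  sol <- lapply(1:2, function(j) solve_case_control_freqs(f[j], or[j], p))
  a <- vapply(sol, `[[`, numeric(1), "freq_cases")
  b <- vapply(sol, `[[`, numeric(1), "freq_controls")
  cell_prob <- function(d, g1, g2) {
    fg <- function(g, freq) if (g == 1) freq else 1 - freq
    if (d == 1) p * fg(g1, a[1]) * fg(g2, a[2])
    else (1 - p) * fg(g1, b[1]) * fg(g2, b[2])
  }
  # probs indexed identically to the tabulation key d*4 + g1 + 2*g2 + 1
  probs <- numeric(8)
  for (d in 0:1) for (g1 in 0:1) for (g2 in 0:1)
    probs[d * 4 + g1 + 2 * g2 + 1] <- cell_prob(d, g1, g2)
  expect_equal(sum(probs), 1, tolerance = 1e-12)

  cfg <- scenario_config(n, p, variants = data.frame(frequency = f,
                                                     odds_ratio = or),
                         seed = 31, effect_model = "multiplicative_odds")
  ch <- simulate_cohort(cfg, 1)
  key <- ch$status * 4 + ch$genotypes[, 1] * 1 + ch$genotypes[, 2] * 2
  obs_status_first <- tabulate(key + 1, 8)

  # risk-first: genotypes at population frequencies, Bernoulli on the Bayes
  # posterior risk
  set.seed(32)
  g1 <- rbinom(n, 1, f[1]); g2 <- rbinom(n, 1, f[2])
  risk <- bayes_risk(cbind(g1, g2),
                     data.frame(freq_cases = a, freq_controls = b), p)
  d <- rbinom(n, 1, as.numeric(risk))
  obs_risk_first <- tabulate(d * 4 + g1 * 1 + g2 * 2 + 1, 8)

  for (obs in list(obs_status_first, obs_risk_first)) {
    gof <- suppressWarnings(chisq.test(obs, p = probs))
    expect_gt(gof$p.value, 0.01)
  }
})

test_that("config validation and shorthand behave", {
  cfg <- scenario_config(100, 0.3, n_variants = 7, frequency = 0.2,
                         odds_ratio = 1.3)
  expect_equal(nrow(cfg$variants), 7)
  expect_error(scenario_config(100, 0, n_variants = 1, frequency = 0.2,
                               odds_ratio = 1.3), "disease_risk")
  expect_error(scenario_config(100, 0.3, n_variants = 1, frequency = 1.5,
                               odds_ratio = 1.3), "frequency")
  expect_error(variant_spec(0.3, -2), "odds_ratio")
  expect_error(scenario_config(100, 0.3), "variants")
})
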