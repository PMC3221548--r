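#' Run one simulation scenario over its replicates
#'
#' For each replicate: simulate the cohort, compute the count score, the full
#' threshold/metric table and the AUC. Metrics are then averaged pointwise
#' across replicates at matched thresholds (the count score makes the integer
#' grid 0..m+1 common to all replicates), with Monte-Carlo standard errors of
#' the replicate means.
#'
#' @param config A [scenario_config()].
#' @param keep_tables Keep the per-replicate threshold tables (needed by
#'   [summarize_at_group_frequency()]; default TRUE).
#' @param verbose Print per-replicate progress.
#' @return An `experiment_result`: list with `config`, `replicate_auc`,
#'   `auc` (mean), `auc_se` (MC SE of the mean), `metrics_by_threshold`
#'   (data.frame of replicate means with `*_se` columns), `tables`
#'   (per-replicate list, if kept), `n_replicates`.
#' @examples
#' cfg <- scenario_config(1000, 0.3, n_variants = 10, frequency = 0.3,
#'                        odds_ratio = 2, n_replicates = 3, seed = 42)
#' res <- run_scenario(cfg)
#' res$auc
#' @export
run_scenario <- function(config, keep_tables = TRUE, verbose = FALSE) {
  stopifnot(inherits(config, "scenario_config"))
  m <- nrow(config$variants)
  grid <- 0:(m + 1)
  reps <- config$n_replicates
  aucs <- numeric(reps)
  tables <- if (keep_tables) vector("list", reps) else NULL
  sens <- spec <- ppv <- npv <- q <- matrix(NA_real_, length(grid), reps)
  for (i in seq_len(reps)) {
    ch <- simulate_cohort(config, i)
    sc <- count_score(ch)
    tt <- threshold_table(sc, ch$status, thresholds = grid)
    aucs[i] <- auc(sc, ch$status)$auc
    sens[, i] <- tt$sensitivity; spec[, i] <- tt$specificity
    ppv[, i] <- tt$ppv; npv[, i] <- tt$npv
    q[, i] <- tt$highrisk_frequency
    if (keep_tables) tables[[i]] <- tt
    if (verbose) message("replicate ", i, "/", reps,
                         ": AUC = ", formatC(aucs[i], digits = 4,
                                             format = "f"))
  }
  mean_se <- function(x) {
    mu <- rowMeans(x, na.rm = TRUE)
    nn <- rowSums(!is.na(x))
    se <- ifelse(nn > 1, apply(x, 1, stats::sd, na.rm = TRUE) / sqrt(nn),
                 NA_real_)
    list(mean = ifelse(nn > 0, mu, NA_real_), se = se)
  }
  s <- mean_se(sens); sp <- mean_se(spec); pv <- mean_se(ppv)
  nv <- mean_se(npv); qq <- mean_se(q)
  metrics <- data.frame(
    threshold = grid,
    highrisk_frequency = qq$mean, highrisk_frequency_se = qq$se,
    sensitivity = s$mean, sensitivity_se = s$se,
    specificity = sp$mean, specificity_se = sp$se,
    ppv = pv$mean, ppv_se = pv$se,
    npv = nv$mean, npv_se = nv$se)
  structure(list(config = config,
                 replicate_auc = aucs,
                 auc = mean(aucs),
                 auc_se = if (reps > 1) stats::sd(aucs) / sqrt(reps) else NA_real_,
                 metrics_by_threshold = metrics,
                 tables = tables,
                 n_replicates = reps),
            class = "experiment_result")
}

#' @export
print.experiment_result <- function(x, ...) {
  cat(sprintf("experiment: %d replicate(s), mean AUC = %.4f (MC SE %.4f)\n",
              x$n_replicates, x$auc,
              if (is.na(x$auc_se)) 0 else x$auc_se))
  invisible(x)
}

#' Replicate-mean metrics at a target high-risk-group frequency
#'
#' Per replicate, selects the threshold whose achieved high-risk-group
#' frequency is closest to `target_q` (ties towards the smaller group) and
#' averages the metrics of that row across replicates.
#'
#' @param result An `experiment_result` with per-replicate tables.
#' @param target_q Target frequency of the high-risk group, in (0, 1).
#' @return One-row data.frame: `target_q`, mean `achieved_q`, `threshold`
#'   (mean), `sensitivity`, `specificity`, `ppv`, `npv` and their MC SEs.
#' @export
summarize_at_group_frequency <- function(result, target_q) {
  stopifnot(inherits(result, "experiment_result"))
  if (is.null(result$tables))
    stop("per-replicate tables were not kept; rerun with keep_tables = TRUE",
         call. = FALSE)
  rows <- lapply(result$tables, function(tt) {
    # candidate rows: observed score values only (plus the sentinel row),
    # i.e. rows where q actually changes
    d <- abs(tt$highrisk_frequency - target_q)
    i <- which(d == min(d))
    tt[i[length(i)], , drop = FALSE]
  })
  picked <- do.call(rbind, rows)
  agg <- function(v) mean(v, na.rm = TRUE)
  ses <- function(v) {
    v <- v[!is.na(v)]
    if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else NA_real_
  }
  data.frame(target_q = target_q,
             achieved_q = agg(picked$highrisk_frequency),
             achieved_q_se = ses(picked$highrisk_frequency),
             threshold = agg(picked$threshold),
             sensitivity = agg(picked$sensitivity),
             sensitivity_se = ses(picked$sensitivity),
             specificity = agg(picked$specificity),
             specificity_se = ses(picked$specificity),
             ppv = agg(picked$ppv), ppv_se = ses(picked$ppv),
             npv = agg(picked$npv), npv_se = ses(picked$npv))
}

#' Panel-size sweep: AUC and threshold metrics versus number of variants
#'
#' Reruns the scenario for each panel size (all variants identical to
#' `base_variant`) and reports the replicate-mean AUC together with
#' sensitivity and PPV at thresholds achieving each target high-risk-group
#' frequency. Increasing the panel size increases the AUC, which is how the
#' sweep traces screening performance against discrimination.
#'
#' @param panel_sizes Integer vector of panel sizes.
#' @param base_variant A [variant_spec()] shared by every variant.
#' @param disease_risk Population disease risk.
#' @param target_qs Target high-risk-group frequencies (default 5%, 30%,
#'   50%).
#' @param n_individuals Cohort size (default 10000).
#' @param n_replicates Replicates per panel size (default 100).
#' @param seed Master seed; each panel size gets a derived stream.
#' @param effect_model Passed to [scenario_config()].
#' @param verbose Print progress per panel size.
#' @return An `experiment_sweep`: list with `by_panel` (data.frame: one row
#'   per (panel size, target q)), `auc_by_panel` (data.frame), and the call
#'   parameters.
#' @export
sweep_auc_by_panel_size <- function(panel_sizes, base_variant,
                                    disease_risk = 0.3,
                                    target_qs = c(0.05, 0.30, 0.50),
                                    n_individuals = 10000L,
                                    n_replicates = 100L, seed = 1L,
                                    effect_model = "multiplicative_risk",
                                    verbose = FALSE) {
  stopifnot(inherits(base_variant, "variant_spec"), all(panel_sizes >= 1))
  auc_rows <- vector("list", length(panel_sizes))
  q_rows <- vector("list", length(panel_sizes))
  for (k in seq_along(panel_sizes)) {
    msize <- panel_sizes[k]
    cfg <- scenario_config(n_individuals, disease_risk,
                           n_variants = msize,
                           frequency = base_variant$frequency,
                           odds_ratio = base_variant$odds_ratio,
                           n_replicates = n_replicates,
                           seed = derive_stream_seed(seed, k),
                           effect_model = effect_model)
    res <- run_scenario(cfg)
    auc_rows[[k]] <- data.frame(panel_size = msize, auc = res$auc,
                                auc_se = res$auc_se)
    q_rows[[k]] <- do.call(rbind, lapply(target_qs, function(tq) {
      cbind(panel_size = msize, summarize_at_group_frequency(res, tq))
    }))
    if (verbose) message("panel size ", msize, ": mean AUC = ",
                         formatC(res$auc, digits = 4, format = "f"))
  }
  structure(list(auc_by_panel = do.call(rbind, auc_rows),
                 by_panel = do.call(rbind, q_rows),
                 panel_sizes = panel_sizes, base_variant = base_variant,
                 disease_risk = disease_risk, target_qs = target_qs,
                 n_individuals = n_individuals, n_replicates = n_replicates,
                 seed = seed, effect_model = effect_model),
            class = "experiment_sweep")
}

#' Six-locus AMD risk-prediction experiment
#'
#' Simulates a categorical-genotype cohort from the parameter table, fits
#' logistic-regression predicted risks, and evaluates stratification: the
#' full threshold table over predicted-risk cutoffs, the AUC with confidence
#' interval, and the predicted-risk distribution by disease status.
#'
#' @param params Parameter table (default the packaged synthetic table,
#'   [amd_params()]).
#' @param n Cohort size (default 10000).
#' @param prevalence Disease prevalence (default 0.09).
#' @param seed Integer seed.
#' @param n_replicates Number of replicate cohorts (default 1; the AUC/CI and
#'   tables of the first replicate are reported, replicate AUCs are kept).
#' @return An `amd_experiment`: list with `auc` (a `discrimination_result`
#'   for replicate 1), `replicate_auc`, `threshold_table`,
#'   `metrics_by_group_frequency`, `risk_summary` (predicted-risk quantiles
#'   by status), `cohort`, `fit_coefficients`.
#' @export
run_amd_experiment <- function(params = amd_params(), n = 10000L,
                               prevalence = 0.09, seed = 1L,
                               n_replicates = 1L) {
  aucs <- numeric(n_replicates)
  first <- NULL
  for (i in seq_len(n_replicates)) {
    ch <- simulate_amd_cohort(params, prevalence, n,
                              derive_stream_seed(seed, i))
    pr <- logistic_risk(ch$genotypes, ch$status)
    res <- auc(pr, ch$status)
    aucs[i] <- res$auc
    if (i == 1L) {
      tt <- threshold_table(pr, ch$status)
      qs <- c(0, 0.01, 0.05, 0.1, 0.25, 0.5, 0.75, 0.9, 0.95, 0.99, 1)
      risk_summary <- rbind(
        data.frame(status = "affected", q = qs,
                   risk = as.numeric(stats::quantile(as.numeric(pr)[ch$status == 1L], qs))),
        data.frame(status = "unaffected", q = qs,
                   risk = as.numeric(stats::quantile(as.numeric(pr)[ch$status == 0L], qs))))
      first <- list(auc = res, threshold_table = tt,
                    metrics_by_group_frequency = metrics_vs_group_frequency(tt),
                    risk_summary = risk_summary, cohort = ch,
                    fit_coefficients = attr(pr, "coefficients"),
                    predicted_risk = as.numeric(pr))
    }
  }
  structure(c(first, list(replicate_auc = aucs, params = params, n = n,
                          prevalence = prevalence, seed = seed)),
            class = "amd_experiment")
}

#' @export
print.amd_experiment <- function(x, ...) {
  cat("six-locus categorical-genotype risk-prediction experiment\n")
  print(x$auc)
  cat(sprintf("predicted risks span %.4f .. %.4f (prevalence %.3g)\n",
              min(x$predicted_risk), max(x$predicted_risk), x$prevalence))
  invisible(x)
}
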