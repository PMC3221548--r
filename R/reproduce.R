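#' Reproduce the study tables behind one figure
#'
#' Maps a figure identifier to its scenario grid, runs it, and writes the CSV
#' table(s) behind the figure. Deterministic given `seed`.
#'
#' * `fig1` — distribution of count scores by disease status, 50 variants,
#'   OR in (1.1, 1.5, 2.0), f = 0.3, p = 0.3.
#' * `fig2` — replicate-mean sensitivity/PPV by threshold for the same grid.
#' * `s2` — specificity/NPV view of the same table.
#' * `fig3` — metrics keyed by high-risk-group frequency for the same grid.
#' * `s3` — `fig3` rerun at disease risk 0.1.
#' * `fig4` — panel-size sweep (5..600 variants, OR 1.1) with sensitivity and
#'   PPV at high-risk-group frequencies 5%, 30%, 50%.
#' * `fig5` — six-locus AMD experiment: metrics versus high-risk-group
#'   frequency of the predicted risk.
#' * `s4` — predicted-risk distribution by status for the AMD experiment.
#'
#' @param figure_id One of `"fig1"`, `"fig2"`, `"fig3"`, `"fig4"`, `"fig5"`,
#'   `"s2"`, `"s3"`, `"s4"`.
#' @param out_dir Output directory (created if needed).
#' @param seed Master seed (default 2011).
#' @param n_replicates Replicates per scenario (default 100; the AMD figures
#'   use a single cohort).
#' @param n_individuals Cohort size (default 10000).
#' @return Invisibly, the paths of the files written.
#' @export
reproduce <- function(figure_id, out_dir = ".", seed = 2011L,
                      n_replicates = 100L, n_individuals = 10000L) {
  known <- c("fig1", "fig2", "fig3", "fig4", "fig5", "s2", "s3", "s4")
  if (!figure_id %in% known)
    stop("unknown figure_id '", figure_id, "'; expected one of ",
         paste(known, collapse = ", "), call. = FALSE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  ors <- c(1.1, 1.5, 2.0)

  headline <- function(p) lapply(seq_along(ors), function(k) {
    run_scenario(scenario_config(
      n_individuals, p, n_variants = 50, frequency = 0.3,
      odds_ratio = ors[k], n_replicates = n_replicates,
      seed = derive_stream_seed(seed, k)))
  })

  files <- character(0)
  if (figure_id == "fig1") {
    rows <- do.call(rbind, lapply(seq_along(ors), function(k) {
      cfg <- scenario_config(n_individuals, 0.3, n_variants = 50,
                             frequency = 0.3, odds_ratio = ors[k],
                             seed = derive_stream_seed(seed, k))
      ch <- simulate_cohort(cfg, 1)
      sc <- as.numeric(count_score(ch))
      do.call(rbind, lapply(sort(unique(sc)), function(v) {
        data.frame(odds_ratio = ors[k], score = v,
                   n_affected = sum(sc == v & ch$status == 1L),
                   n_unaffected = sum(sc == v & ch$status == 0L))
      }))
    }))
    f <- file.path(out_dir, "fig1_score_distribution.csv")
    utils::write.csv(rows, f, row.names = FALSE)
    files <- f
  } else if (figure_id %in% c("fig2", "s2", "fig3", "s3")) {
    p <- if (figure_id == "s3") 0.1 else 0.3
    res <- headline(p)
    rows <- do.call(rbind, lapply(seq_along(ors), function(k)
      cbind(odds_ratio = ors[k], res[[k]]$metrics_by_threshold)))
    if (figure_id %in% c("fig3", "s3"))
      rows <- rows[order(rows$odds_ratio, rows$highrisk_frequency), ]
    f <- file.path(out_dir, paste0(figure_id, "_metrics.csv"))
    utils::write.csv(rows, f, row.names = FALSE)
    files <- f
    for (k in seq_along(ors))
      files <- c(files, write_metrics(
        res[[k]], file.path(out_dir, sprintf("%s_or%.1f", figure_id, ors[k])),
        label = sprintf("%s_or%.1f", figure_id, ors[k])))
  } else if (figure_id == "fig4") {
    sw <- sweep_auc_by_panel_size(
      c(5, 10, 25, 50, 100, 200, 400, 600), variant_spec(0.3, 1.1),
      disease_risk = 0.3, n_individuals = n_individuals,
      n_replicates = n_replicates, seed = seed)
    f1 <- file.path(out_dir, "fig4_sweep.csv")
    utils::write.csv(sw$by_panel, f1, row.names = FALSE)
    f2 <- file.path(out_dir, "fig4_auc_by_panel.csv")
    utils::write.csv(sw$auc_by_panel, f2, row.names = FALSE)
    files <- c(f1, f2)
  } else {  # fig5 / s4
    amd <- run_amd_experiment(amd_params(), n = n_individuals,
                              prevalence = 0.09, seed = seed)
    if (figure_id == "fig5") {
      f <- file.path(out_dir, "fig5_amd_metrics.csv")
      utils::write.csv(amd$metrics_by_group_frequency, f, row.names = FALSE)
    } else {
      f <- file.path(out_dir, "s4_amd_risk_distribution.csv")
      utils::write.csv(amd$risk_summary, f, row.names = FALSE)
    }
    files <- f
  }
  invisible(files)
}
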