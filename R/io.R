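#' Load a scenario configuration from a JSON file
#'
#' The file must provide `n_individuals`, `disease_risk`, `n_replicates`,
#' `seed` and either an explicit `variants` array of
#' `{frequency, odds_ratio}` objects or the homogeneous shorthand
#' `n_variants` + `frequency` + `odds_ratio`. An optional `effect_model`
#' selects the generative model. All values are validated; violations raise
#' errors naming the offending field.
#'
#' @param path Path to the JSON configuration file.
#' @return A [scenario_config()].
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  for (field in c("n_individuals", "disease_risk"))
    if (is.null(raw[[field]]))
      stop("config schema error: missing required field '", field, "'",
           call. = FALSE)
  args <- list(n_individuals = raw$n_individuals,
               disease_risk = raw$disease_risk,
               n_replicates = if (is.null(raw$n_replicates)) 1L else raw$n_replicates,
               seed = if (is.null(raw$seed)) 1L else raw$seed)
  if (!is.null(raw$effect_model)) args$effect_model <- raw$effect_model
  if (!is.null(raw$variants)) {
    v <- raw$variants
    if (!is.data.frame(v)) v <- as.data.frame(v)
    if (!all(c("frequency", "odds_ratio") %in% names(v)))
      stop("config schema error: each variant needs 'frequency' and ",
           "'odds_ratio'", call. = FALSE)
    args$variants <- v
  } else {
    for (field in c("n_variants", "frequency", "odds_ratio"))
      if (is.null(raw[[field]]))
        stop("config schema error: supply 'variants' or the shorthand ",
             "field '", field, "'", call. = FALSE)
    args$n_variants <- raw$n_variants
    args$frequency <- raw$frequency
    args$odds_ratio <- raw$odds_ratio
  }
  do.call(scenario_config, args)
}

#' Write experiment outputs as CSV tables
#'
#' Writes `metrics_by_threshold.csv` (the replicate-mean screening table with
#' Monte-Carlo SEs) and `auc_summary.csv`, plus a JSON run manifest
#' sufficient to re-run the experiment bit-identically (config echo, seed,
#' package version, timestamp, file list). Proportions are written as
#' proportions (0.67, not 67%); pass `percent = TRUE` to scale the metric
#' columns by 100.
#'
#' @param result An `experiment_result` from [run_scenario()].
#' @param out_dir Output directory (created if needed).
#' @param label Scenario label used in `auc_summary.csv`.
#' @param percent Write percentage-scaled metric columns (default FALSE).
#' @return Invisibly, the paths of the files written.
#' @export
write_metrics <- function(result, out_dir, label = "scenario",
                          percent = FALSE) {
  stopifnot(inherits(result, "experiment_result"))
  if (result$n_replicates < 1 || length(result$replicate_auc) == 0)
    stop("empty replicate list: nothing to write", call. = FALSE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  metrics <- result$metrics_by_threshold
  if (percent) {
    pc <- c("highrisk_frequency", "sensitivity", "specificity", "ppv", "npv")
    pc <- c(pc, paste0(pc, "_se"))
    metrics[pc] <- lapply(metrics[pc], function(v) 100 * v)
  }
  f1 <- file.path(out_dir, "metrics_by_threshold.csv")
  utils::write.csv(metrics, f1, row.names = FALSE)
  asum <- data.frame(scenario = label,
                     n_replicates = result$n_replicates,
                     mean_auc = result$auc,
                     auc_se = result$auc_se,
                     ci_low = result$auc - 1.96 * result$auc_se,
                     ci_high = result$auc + 1.96 * result$auc_se)
  f2 <- file.path(out_dir, "auc_summary.csv")
  utils::write.csv(asum, f2, row.names = FALSE)
  files <- c(f1, f2)
  manifest <- write_manifest(out_dir, config = unclass(result$config),
                             files = files)
  invisible(c(files, manifest))
}

# internal: run manifest beside the outputs
write_manifest <- function(out_dir, config, files) {
  path <- file.path(out_dir, "run_manifest.json")
  config$variants <- as.data.frame(config$variants)
  jsonlite::write_json(
    list(config = config,
         package = "riskstrat",
         version = as.character(utils::packageVersion("riskstrat")),
         timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
         files = basename(files)),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  path
}
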