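# Workflow orchestration: run a full screening assessment from files to
# files, and draw the standard diagnostic plots.

#' Assemble a run configuration
#'
#' Bundles everything [run_assessment()] needs. `input` may be a path to a
#' monitoring CSV or an in-memory `water_samples` table.
#'
#' @param input path to a monitoring CSV, or a `water_samples` table.
#' @param out_dir output directory (created if absent).
#' @param dialect monitoring CSV dialect, `"long"` or `"wide"`.
#' @param pd_table path to a permitted-dose CSV, a `pd_table`, or `NULL`
#'   for the packaged table.
#' @param scenario an [exposure_scenario()] or path to a scenario config.
#' @param policies non-detect policies to run (default: both).
#' @param min_detects sample filter threshold (default 5).
#' @param hi_cutoff HI classification threshold (default 1).
#' @return an object of class `run_config`.
#' @export
run_config <- function(input, out_dir, dialect = "long", pd_table = NULL,
                       scenario = exposure_scenario(),
                       policies = nondetect_policies(),
                       min_detects = 5, hi_cutoff = 1) {
  if (is.character(input) && !file.exists(input))
    abort("input file not found: %s", input)
  if (is.character(scenario)) scenario <- read_scenario_config(scenario)
  if (!length(policies)) abort("at least one non-detect policy is required")
  for (p in policies) check_policy(p)
  structure(list(input = input, out_dir = out_dir, dialect = dialect,
                 pd_table = pd_table, scenario = scenario,
                 policies = policies, min_detects = min_detects,
                 hi_cutoff = hi_cutoff),
            class = "run_config")
}

#' Run a full MCR screening assessment
#'
#' Reads the monitoring data, drops samples with fewer than `min_detects`
#' detected chemicals, and for each requested non-detect policy computes
#' per-sample metrics, group summaries by n, the HI/MCR summary table and
#' the correlation suite. Results are written under `out_dir`:
#' `metrics_<policy>.csv`, `groups_<policy>.csv`, `summary.csv`,
#' `statistics.csv` and a plain-text `assessment.log` recording removed
#' samples, chemicals excluded for lack of a permitted dose and
#' undefined-metric counts.
#'
#' @param config a [run_config()].
#' @return invisibly, a list with the computed objects and output paths.
#' @export
run_assessment <- function(config) {
  if (!inherits(config, "run_config"))
    abort("config must be created with run_config()")
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- character(0)
  note <- function(fmt, ...) {
    log_lines <<- c(log_lines, sprintf(fmt, ...))
  }

  samples <- if (inherits(config$input, "water_samples")) config$input
    else read_monitoring_csv(config$input, config$dialect)
  pd_table <- if (inherits(config$pd_table, "pd_table")) config$pd_table
    else load_permitted_doses(config$pd_table)
  n_in <- length(unique(samples$sample_id))
  note("samples read: %d", n_in)

  kept <- withCallingHandlers(
    filter_samples(samples, config$min_detects),
    message = function(m) { note("%s", trimws(conditionMessage(m)))
      invokeRestart("muffleMessage") })
  n_kept <- length(unique(kept$sample_id))
  note("samples retained after >=%g-detect filter: %d", config$min_detects,
       n_kept)
  if (n_kept == 0L)
    abort("no samples remain after the %g-detect filter (read %d, removed %d)",
          config$min_detects, n_in, n_in)

  results <- list()
  summaries <- list()
  stats_rows <- list()
  for (policy in config$policies) {
    metrics <- withCallingHandlers(
      compute_sample_metrics(kept, pd_table, config$scenario, policy),
      warning = function(w) { note("[%s] %s", policy, trimws(conditionMessage(w)))
        invokeRestart("muffleWarning") },
      message = function(m) { note("[%s] %s", policy, trimws(conditionMessage(m)))
        invokeRestart("muffleMessage") })
    groups <- suppressMessages(group_by_n(metrics))
    summaries[[policy]] <- summarize_dataset(metrics, config$hi_cutoff)
    stats_rows[[policy]] <- withCallingHandlers(
      correlation_suite(metrics, groups, config$hi_cutoff),
      warning = function(w) { note("[%s] %s", policy, trimws(conditionMessage(w)))
        invokeRestart("muffleWarning") })
    mpath <- file.path(config$out_dir, sprintf("metrics_%s.csv", policy))
    write_metrics_csv(metrics, mpath)
    gpath <- file.path(config$out_dir, sprintf("groups_%s.csv", policy))
    utils::write.csv(groups, gpath, row.names = FALSE)
    results[[policy]] <- list(metrics = metrics, groups = groups,
                              metrics_path = mpath, groups_path = gpath)
  }
  summary_path <- file.path(config$out_dir, "summary.csv")
  utils::write.csv(do.call(rbind, summaries), summary_path, row.names = FALSE)
  stats_path <- file.path(config$out_dir, "statistics.csv")
  utils::write.csv(do.call(rbind, stats_rows), stats_path, row.names = FALSE)
  log_path <- file.path(config$out_dir, "assessment.log")
  writeLines(log_lines, log_path)

  invisible(list(policies = results,
                 summary = do.call(rbind, summaries),
                 statistics = do.call(rbind, stats_rows),
                 paths = list(summary = summary_path, statistics = stats_path,
                              log = log_path)))
}

#' Draw the standard screening plots
#'
#' Produces, from one or more per-policy metrics tables: an MCR-vs-HI
#' scatter over all samples (HI on a log axis, one plotting symbol per
#' policy), the same restricted to samples with HI above the cutoff, and
#' per-policy HI-vs-n and MCR-vs-n box plots. Records with undefined
#' metrics (and, on log-HI axes, non-positive HI) are dropped.
#'
#' @param metrics_list a `sample_metrics` table or a list of them (one per
#'   policy).
#' @param out_dir directory for the figure files.
#' @param format `"png"`, `"pdf"` or `"svg"`.
#' @param hi_cutoff threshold for the above-cutoff subset plot.
#' @return character vector of the files written, invisibly.
#' @export
make_plots <- function(metrics_list, out_dir, format = c("png", "pdf", "svg"),
                       hi_cutoff = 1) {
  format <- match.arg(format)
  if (inherits(metrics_list, "data.frame")) metrics_list <- list(metrics_list)
  all_m <- do.call(rbind, lapply(metrics_list, as.data.frame))
  ok <- !is.na(all_m$hi) & !is.na(all_m$mcr)
  if (!any(ok)) abort("no defined metrics to plot")
  all_m <- all_m[ok, , drop = FALSE]
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  policies <- unique(all_m$policy)

  open_dev <- function(name) {
    path <- file.path(out_dir, paste0(name, ".", format))
    switch(format,
           png = grDevices::png(path, width = 800, height = 600),
           pdf = grDevices::pdf(path, width = 8, height = 6),
           svg = grDevices::svg(path, width = 8, height = 6))
    path
  }
  files <- character(0)

  scatter <- function(d, name, main) {
    d <- d[d$hi > 0, , drop = FALSE]
    if (!nrow(d)) return(invisible(NULL))
    path <- open_dev(name)
    on.exit(grDevices::dev.off())
    pch <- match(d$policy, policies)
    graphics::plot(d$hi, d$mcr, log = "x", pch = pch, col = pch,
                   xlab = "Hazard Index (log scale)", ylab = "MCR",
                   main = main)
    graphics::legend("topright", legend = policies,
                     pch = seq_along(policies), col = seq_along(policies))
    files <<- c(files, path)
  }
  scatter(all_m, "mcr_vs_hi", "MCR vs HI, all samples")
  scatter(all_m[all_m$hi > hi_cutoff, , drop = FALSE], "mcr_vs_hi_above",
          sprintf("MCR vs HI, samples with HI > %g", hi_cutoff))

  for (policy in policies) {
    d <- all_m[all_m$policy == policy, , drop = FALSE]
    dpos <- d[d$hi > 0, , drop = FALSE]
    if (nrow(dpos)) {
      path <- open_dev(paste0("hi_vs_n_", policy))
      graphics::boxplot(hi ~ n_effective, data = dpos, log = "y",
                        xlab = "n (mixture size)", ylab = "Hazard Index",
                        main = sprintf("HI by n (%s)", policy))
      grDevices::dev.off()
      files <- c(files, path)
    }
    path <- open_dev(paste0("mcr_vs_n_", policy))
    graphics::boxplot(mcr ~ n_effective, data = d,
                      xlab = "n (mixture size)", ylab = "MCR",
                      main = sprintf("MCR by n (%s)", policy))
    grDevices::dev.off()
    files <- c(files, path)
  }
  invisible(files)
}
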