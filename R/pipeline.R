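#' Run the full analysis pipeline
#'
#' Orchestrates simulate (or load) -> rates -> selectivity -> dynamics ->
#' context -> latency on one session and writes every stage's table as CSV
#' plus a JSON provenance record (package version, seed, window definitions,
#' generator configuration) and a plain-text summary. Stages that cannot run
#' on the given session (e.g., no suppressed units for the lag analysis) are
#' recorded as skipped in the summary rather than failing the run.
#'
#' @param config Path to a YAML file, or an equivalent named list, with
#'   either a `simulate:` block (fields of [generator_config()] plus `seed`)
#'   or a `session:` block (`spikes`, `trials`, `task` paths/values), and an
#'   optional `windows:` block overriding [analysis_windows()] defaults.
#' @param out_dir Output directory.
#' @return Invisibly, a named list of the stage results.
#' @export
run_pipeline <- function(config, out_dir) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  windows <- do.call(analysis_windows, cfg$windows %||% list())

  if (!is.null(cfg$simulate)) {
    gen_args <- cfg$simulate
    seed <- gen_args$seed %||% 1L
    gen_args$seed <- NULL
    gcfg <- do.call(generator_config, gen_args)
    gen <- generate_session(gcfg, seed = seed)
    session <- gen$session
    write_ground_truth(gen$truth, file.path(out_dir, "ground_truth.json"))
    write_session(session, file.path(out_dir, "session"))
  } else if (!is.null(cfg$session)) {
    miss <- setdiff(c("spikes", "trials"), names(cfg$session))
    if (length(miss)) abort(paste0("config session block missing key: ",
                                   paste(miss, collapse = ", ")))
    session <- read_session(cfg$session$spikes, cfg$session$trials,
                            task = cfg$session$task %||% "discrimination")
    seed <- cfg$seed %||% 1L
  } else {
    abort("config needs a 'simulate' or a 'session' block")
  }

  tensor <- rate_tensor(session, window = c(windows$baseline[1],
                                            windows$response[2]),
                        bin = windows$bias_bin)
  ztensor <- zscore_tensor(tensor, session, windows = windows)
  tr <- session$trials
  kept <- filter_disengaged_cr(tr)
  engaged <- tr$trial_id %in% kept$trial_id & engaged_trials(tr)

  write_results(psth(ztensor, trials = engaged), file.path(out_dir, "psth.csv"))

  classes <- classify_units(session, tensor, windows = windows)
  write_results(classes, file.path(out_dir, "unit_classes.csv"))

  bias <- stimulus_bias(tensor, engaged & tr$stimulus == "positive",
                        engaged & tr$stimulus == "negative", windows = windows)
  write_results(bias, file.path(out_dir, "bias_series.csv"))
  write_results(summarize_bias(bias, windows), file.path(out_dir, "bias_summary.csv"))
  pref <- tryCatch(population_preference_stats(classes[classes$responsive, ]),
                   error = function(e) NULL)

  lag <- tryCatch(session_lag(session, windows = windows, classes = classes),
                  warning = function(w) NULL, error = function(e) NULL)
  if (!is.null(lag)) write_results(tidy(lag), file.path(out_dir, "pair_lags.csv"))

  modulation <- list()
  for (ct in c("Hit_vs_Miss", "Home_vs_Away")) {
    for (wd in c("evoked", "baseline")) {
      m <- tryCatch(condition_modulation(ztensor, session, contrast = ct,
                                         window = wd, windows = windows),
                    error = function(e) NULL)
      if (!is.null(m)) modulation[[paste(ct, wd, sep = "_")]] <- m
    }
  }
  if (length(modulation)) {
    write_results(dplyr::bind_rows(lapply(modulation, as.data.frame)),
                  file.path(out_dir, "modulation.csv"))
  }

  latcor <- tryCatch(baseline_latency_correlation(tensor, session,
                                                  windows = windows),
                     error = function(e) NULL)
  if (!is.null(latcor)) write_results(latcor, file.path(out_dir, "latency_correlation.csv"))

  provenance <- list(
    package = "whiskerbias",
    version = as.character(utils::packageVersion("whiskerbias")),
    seed = seed,
    windows = unclass(windows),
    generator = if (!is.null(cfg$simulate)) unclass(gcfg) else NULL,
    stages = list(
      lag = !is.null(lag),
      modulation = names(modulation),
      latency_correlation = !is.null(latcor)))
  jsonlite::write_json(provenance, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")

  summary_lines <- c(
    sprintf("units: %d  trials: %d  engaged: %d", nrow(session$units),
            nrow(tr), sum(engaged)),
    if (!is.null(pref)) sprintf("positive-preferring fraction: %.3f (p=%.3g vs 50/50)",
                                pref$fraction_positive, pref$p_equal_split),
    if (!is.null(lag)) sprintf("facilitation-suppression lag: %.1f ms over %d pairs",
                               1000 * lag$summary_lag, nrow(lag$pairs))
    else "facilitation-suppression lag: skipped",
    vapply(names(modulation), function(nm) {
      g <- glance(modulation[[nm]])
      sprintf("%s: %d/%d units significant", nm, g$n_significant, g$n_units)
    }, character(1)))
  writeLines(summary_lines, file.path(out_dir, "summary.txt"))

  invisible(list(session = session, classes = classes, bias = bias,
                 preference = pref, lag = lag, modulation = modulation,
                 latency = latcor))
}
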