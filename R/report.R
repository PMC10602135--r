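#' Configure a reporting run
#'
#' Bundles the inputs, policies and output location shared by the report
#' drivers [run_summarize()], [run_transitions()], [run_simulate()] and
#' [run_report()]. All randomness in a run flows through `seed`; outputs
#' are pure functions of (inputs, config, seed), so repeated runs are
#' byte-identical. Progress is logged to standard error; data goes only to
#' files.
#'
#' @param events,metadata,catalog Input file paths (catalog `NULL` = the
#'   built-in 21-step card; metadata `NULL` = operative times absent).
#' @param overlap_policy Passed to [validate_cohort()].
#' @param merge_gap_s Same-step visit fusion window, seconds (>= 0).
#' @param threshold Classification threshold (>= 0), see [classify_step()].
#' @param include_self See [neighbor_counts()].
#' @param out Output directory (created if needed).
#' @param seed Integer seed for simulation.
#' @param n Number of procedures for [run_simulate()].
#' @param model Optional model YAML path for [run_simulate()].
#' @param chord Optional SVG path: [run_transitions()] renders a best-effort
#'   transition-frequency figure there (requires ggplot2).
#' @param verbose Log progress to standard error.
#' @return A list of class `run_config`.
#' @export
run_config <- function(events = NULL, metadata = NULL, catalog = NULL,
                       overlap_policy = "error", merge_gap_s = 0,
                       threshold = 10, include_self = FALSE,
                       out = ".", seed = 1L, n = 31L, model = NULL,
                       chord = NULL, verbose = TRUE) {
  stopifnot(threshold >= 0, merge_gap_s >= 0, n >= 1)
  if (!dir.exists(out)) dir.create(out, recursive = TRUE)
  structure(list(events = events, metadata = metadata, catalog = catalog,
                 overlap_policy = overlap_policy, merge_gap_s = merge_gap_s,
                 threshold = threshold, include_self = include_self,
                 out = out, seed = as.integer(seed), n = as.integer(n),
                 model = model, chord = chord, verbose = isTRUE(verbose)),
            class = "run_config")
}

say <- function(config, ...) if (config$verbose) message(...)

load_config_cohort <- function(config) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(config$events)) stop("config$events is required", call. = FALSE)
  coh <- load_annotations(config$events, metadata_path = config$metadata,
                          catalog_path = config$catalog)
  v <- validate_cohort(coh, overlap_policy = config$overlap_policy)
  nw <- sum(v$findings$severity != "info")
  if (nw > 0) say(config, "validation: ", nw, " non-informational finding(s)")
  v$cohort
}

fmt2 <- function(v) ifelse(is.na(v), "NA", sprintf("%.2f", v))

#' Write the step-summary report
#'
#' Loads and validates the configured cohort, runs [summarize_steps()],
#' and writes `summary.csv` (one row per step, Table-1-style columns,
#' times and correlations rounded to 2 decimals, `NA` rendered literally)
#' plus `cohort_stats.csv` (cohort-level means +/- SDs).
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with the `cohort_summary` and the paths
#'   written.
#' @export
run_summarize <- function(config) {
  coh <- load_config_cohort(config)
  s <- summarize_steps(coh)
  tab <- tibble::tibble(
    step_name = s$steps$step_name,
    sum_time_min = fmt2(s$steps$cumulative_time_min),
    mean_time_min = fmt2(s$steps$mean_time_min),
    sd_time_min = fmt2(s$steps$sd_time_min),
    rho_time_tot = fmt2(s$steps$rho_time_tot),
    rho_time_ct = fmt2(s$steps$rho_time_ct),
    sum_visits = s$steps$cumulative_visits,
    mean_visits = fmt2(s$steps$mean_visits),
    sd_visits = fmt2(s$steps$sd_visits),
    rho_visits_tot = fmt2(s$steps$rho_visits_tot),
    rho_visits_ct = fmt2(s$steps$rho_visits_ct),
    n_procedures = s$steps$n_procedures
  )
  summary_path <- file.path(config$out, "summary.csv")
  readr::write_csv(tab, summary_path)
  stats_path <- file.path(config$out, "cohort_stats.csv")
  readr::write_csv(tibble::tibble(
    statistic = c("n_procedures", "mean_occurrences_per_procedure",
                  "sd_occurrences_per_procedure", "mean_ct_min", "sd_ct_min",
                  "mean_tot_min", "sd_tot_min"),
    value = c(s$n_procedures, fmt2(s$mean_occurrences_per_procedure),
              fmt2(s$sd_occurrences_per_procedure), fmt2(s$mean_ct_min),
              fmt2(s$sd_ct_min), fmt2(s$mean_tot_min), fmt2(s$sd_tot_min))
  ), stats_path)
  say(config, "wrote ", summary_path, " and ", stats_path)
  invisible(list(summary = s, paths = c(summary_path, stats_path)))
}

#' Write the transition reports
#'
#' Loads and validates the configured cohort, builds the cohort
#' [transition_matrix()], and writes `transitions.tsv` (chord-diagram
#' matrix, see [export_chord_matrix()]) and `classification.csv`
#' (Table-2-style [profile_steps()] output). If `config$chord` is set and
#' ggplot2 is installed, a transition-frequency figure is rendered there
#' (best effort, non-normative).
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with the matrix, the profiles tibble and the
#'   paths written.
#' @export
run_transitions <- function(config) {
  coh <- load_config_cohort(config)
  m <- transition_matrix(coh, merge_gap_s = config$merge_gap_s)
  prof <- profile_steps(coh, threshold = config$threshold,
                        include_self = config$include_self,
                        merge_gap_s = config$merge_gap_s)
  matrix_path <- file.path(config$out, "transitions.tsv")
  export_chord_matrix(m, matrix_path)
  class_path <- file.path(config$out, "classification.csv")
  readr::write_csv(prof, class_path)
  paths <- c(matrix_path, class_path)
  if (!is.null(config$chord)) {
    plot_transition_frequencies(m, config$chord)
    paths <- c(paths, config$chord)
  }
  say(config, "wrote ", paste(paths, collapse = ", "))
  invisible(list(matrix = m, profiles = prof, paths = paths))
}

#' Simulate a cohort and write its annotation files
#'
#' Uses the model YAML at `config$model` (or [default_model()]), simulates
#' `config$n` procedures under `config$seed`, and writes `events.csv`,
#' `metadata.csv` and `catalog.csv` into `config$out`. Identical seeds
#' reproduce identical files.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with the simulated cohort and paths written.
#' @export
run_simulate <- function(config) {
  stopifnot(inherits(config, "run_config"))
  model <- if (is.null(config$model)) default_model() else
    read_workflow_model(config$model)
  coh <- simulate_cohort(model, n = config$n, seed = config$seed)
  paths <- save_annotations(coh,
                            events_path = file.path(config$out, "events.csv"),
                            metadata_path = file.path(config$out, "metadata.csv"),
                            catalog_path = file.path(config$out, "catalog.csv"))
  say(config, "simulated ", config$n, " procedure(s), ", nrow(coh$events),
      " visit(s); wrote ", paste(paths, collapse = ", "))
  invisible(list(cohort = coh, paths = paths))
}

#' Run the full report bundle
#'
#' [run_summarize()] plus [run_transitions()] on the same configured
#' inputs.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with both results.
#' @export
run_report <- function(config) {
  invisible(list(summary = run_summarize(config),
                 transitions = run_transitions(config)))
}

#' Classify steps from a neighbor-counts table
#'
#' Counts-only entry point: takes a delimited file (or data frame) with
#' columns `n_preceding_types` and `n_following_types` (plus any carry-over
#' columns such as `step_name`) and appends the `step_class` column.
#'
#' @param x A file path or data frame.
#' @param threshold See [classify_step()].
#' @return A tibble with `step_class` appended.
#' @export
classify_counts <- function(x, threshold = 10) {
  if (is.character(x)) {
    x <- read_delimited(x, c("n_preceding_types", "n_following_types"))
  }
  x <- tibble::as_tibble(x)
  pre <- as.integer(x$n_preceding_types)
  post <- as.integer(x$n_following_types)
  x$step_class <- classify_step(pre, post, threshold)
  x
}
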