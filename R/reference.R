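#' Reference cohort marginals
#'
#' Published per-step summary statistics of the 31-procedure robotic
#' proctectomy reference cohort: cumulative and mean (+/- SD) step time in
#' minutes, cumulative and mean (+/- SD) visit counts, and Spearman
#' correlations of step time and visit frequency with total operative time
#' and console time. `reference_transition_profiles()` carries the
#' published transition profiles (cumulative visits, distinct
#' preceding/following step-type counts, and step class) for the four
#' steps that earned a class.
#'
#' These tables calibrate [default_model()] and anchor the arithmetic
#' checks in the test suite; the raw annotations behind them are not
#' distributed. Note two internal discrepancies carried as published: the
#' lateral-to-medial descending & sigmoid mobilization step lists 90
#' cumulative visits in the step-statistics table but 87 in the transition
#' table, and the IMV dissection marginals imply 5 occurring procedures
#' while the cohort narrative says 4.
#'
#' @return A tibble (see column list in the description).
#' @export
reference_step_stats <- function() {
  path <- system.file("extdata", "reference_step_stats.csv",
                      package = "procflow", mustWork = TRUE)
  readr::read_csv(path, col_types = readr::cols(
    step_id = "i", step_name = "c", .default = "d"))
}

#' @rdname reference_step_stats
#' @export
reference_transition_profiles <- function() {
  path <- system.file("extdata", "reference_transition_profiles.csv",
                      package = "procflow", mustWork = TRUE)
  readr::read_csv(path, col_types = readr::cols(
    step_id = "i", step_name = "c", step_class = "c", .default = "i"))
}

#' Reconstruct a synthetic cohort from per-step marginals
#'
#' Builds an annotated cohort whose per-step occurring-procedure counts,
#' cumulative times and cumulative visit counts reproduce a marginal table
#' exactly: each step's visits are spread as evenly as possible over its
#' occurring procedures and every visit gets the step's average per-visit
#' duration. The reconstruction is synthetic — only the marginals that
#' [summarize_steps()] aggregates are faithful; visit order, correlations
#' and transition structure are artifacts of the layout. Use it to check
#' summary arithmetic against printed tables, not as a stand-in for real
#' workflow.
#'
#' @param stats A marginal table shaped like [reference_step_stats()]
#'   (columns `step_id`, `sum_time_min`, `sum_visits`, `mean_visits`).
#' @param n_procedures Cohort size the marginals refer to.
#' @param catalog The step catalog.
#' @return A `workflow_cohort` with `NA` operative-time metadata.
#' @examples
#' coh <- marginal_cohort()
#' s <- summarize_steps(coh)
#' s$mean_occurrences_per_procedure            # 1518 / 31 = 48.97
#' s$steps$mean_time_min[5]                    # 5.55 / 6  = 0.925
#' @export
marginal_cohort <- function(stats = reference_step_stats(),
                            n_procedures = 31,
                            catalog = default_catalog()) {
  n_occ <- as.integer(round(stats$sum_visits / stats$mean_visits))
  stopifnot(all(n_occ >= 1), all(n_occ <= n_procedures),
            all(stats$sum_visits >= n_occ))
  ids <- sprintf("P%04d", seq_len(n_procedures))
  cursor <- setNames(rep(0, n_procedures), ids)
  rows <- vector("list", nrow(stats))
  for (r in seq_len(nrow(stats))) {
    v <- as.integer(stats$sum_visits[r])
    per_visit_s <- stats$sum_time_min[r] / v * 60
    # visits spread as evenly as possible over n_occ procedures; the
    # occurring window rotates with the step index so every procedure in
    # the cohort carries some annotation
    counts <- rep(v %/% n_occ[r], n_occ[r])
    extra <- v %% n_occ[r]
    if (extra > 0) counts[seq_len(extra)] <- counts[seq_len(extra)] + 1L
    window <- (r - 1L + seq_len(n_occ[r]) - 1L) %% n_procedures + 1L
    proc <- rep(ids[window], counts)
    start <- numeric(v)
    for (j in seq_len(v)) {
      start[j] <- cursor[proc[j]] + 1          # 1 s gap between visits
      cursor[proc[j]] <- start[j] + per_visit_s
    }
    rows[[r]] <- tibble::tibble(procedure_id = proc,
                                step_id = stats$step_id[r],
                                start_s = start,
                                stop_s = start + per_visit_s)
  }
  cohort(dplyr::bind_rows(rows), catalog = catalog)
}
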