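#' Per-procedure step time and visit count
#'
#' Step time is the per-procedure sum of a step's visit durations in
#' minutes; step visits is the number of annotated visits. Both are 0 when
#' the step does not occur in the procedure.
#'
#' @param procedure A `procedure_record` (see [get_procedure()]).
#' @param step_id A step identifier present in the catalog.
#' @return `step_time()`: minutes (non-negative); `step_visits()`: count.
#' @examples
#' ev <- data.frame(procedure_id = "P1", step_id = 2,
#'                  start_s = c(0, 300), stop_s = c(120, 360))
#' p <- get_procedure(cohort(ev), "P1")
#' step_time(p, 2)    # 3 minutes
#' step_visits(p, 2)  # 2 visits
#' @export
step_time <- function(procedure, step_id) {
  stopifnot(inherits(procedure, "procedure_record"))
  check_step(procedure$catalog, step_id)
  ev <- procedure$events[procedure$events$step_id == step_id, ]
  sum(ev$stop_s - ev$start_s) / 60
}

#' @rdname step_time
#' @export
step_visits <- function(procedure, step_id) {
  stopifnot(inherits(procedure, "procedure_record"))
  check_step(procedure$catalog, step_id)
  sum(procedure$events$step_id == step_id)
}

check_step <- function(catalog, step_id) {
  if (length(step_id) != 1 || !(step_id %in% catalog$step_id)) {
    stop("unknown step_id: ", paste(step_id, collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}

#' Spearman rank correlation with degenerate-case handling
#'
#' Ties receive average ranks and the coefficient is the product-moment
#' correlation of the two rank vectors. Returns `NA` when fewer than 3
#' complete pairs remain or when either vector is constant over them —
#' the convention used for steps whose visit count never varies (e.g. a
#' step visited exactly once in every procedure where it occurs).
#'
#' @param x,y Numeric vectors of equal length.
#' @return A coefficient in `[-1, 1]`, or `NA`.
#' @examples
#' spearman_rho(1:3, c(10, 20, 30))   # 1
#' spearman_rho(1:5, rep(2, 5))       # NA (no variance)
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) {
    stop("x and y must have equal length", call. = FALSE)
  }
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) return(NA_real_)
  if (length(unique(x)) < 2 || length(unique(y)) < 2) return(NA_real_)
  cor(x, y, method = "spearman")
}

#' Correlate one step's time or visit frequency with CT or TOT
#'
#' Pairs are formed only from procedures where the step occurs at least
#' once AND the chosen operative time is recorded; the occurring-procedures
#' subset is not zero-filled, so rarely performed steps are correlated on
#' the procedures that actually contain them. Delegates to [spearman_rho()]
#' (hence `NA` for fewer than 3 pairs or zero variance).
#'
#' @param x A `workflow_cohort`.
#' @param step_id A catalog step identifier.
#' @param metric `"time"` (per-procedure step minutes) or `"visits"`.
#' @param against `"CT"` (console time) or `"TOT"` (total operative time).
#' @return Spearman coefficient or `NA`.
#' @export
correlate_step <- function(x, step_id, metric = c("time", "visits"),
                           against = c("TOT", "CT")) {
  stopifnot(inherits(x, "workflow_cohort"))
  metric <- match.arg(metric)
  against <- match.arg(against)
  check_step(x$catalog, step_id)
  ps <- per_procedure_step(x)
  ps <- ps[ps$step_id == step_id, ]
  ref <- if (against == "CT") "console_time_min" else "total_operative_time_min"
  ps$ref <- x$metadata[[ref]][match(ps$procedure_id, x$metadata$procedure_id)]
  ps <- ps[!is.na(ps$ref), ]
  val <- if (metric == "time") ps$time_min else ps$visits
  spearman_rho(val, ps$ref)
}

# Per-(procedure, step) time and visit aggregation over occurring pairs only.
per_procedure_step <- function(x) {
  x$events |>
    dplyr::group_by(.data$procedure_id, .data$step_id) |>
    dplyr::summarise(time_min = sum(.data$stop_s - .data$start_s) / 60,
                     visits = dplyr::n(), .groups = "drop")
}

#' Summarize step times, visits and operative-time correlations
#'
#' Produces one row per catalog step: cumulative step time and visit count
#' over the cohort, mean +/- SD of the per-procedure values over only the
#' procedures where the step occurs (the occurring-procedures denominator,
#' so a step performed in 6 of 31 procedures with 5.55 cumulative minutes
#' has mean 5.55/6 = 0.925), and Spearman correlations of step time and
#' visit frequency against console time (CT) and total operative time
#' (TOT). SDs are sample SDs (n-1 denominator), `NA` when a step occurs in
#' a single procedure. Steps never occurring get `n_procedures = 0`, zero
#' sums and `NA` statistics.
#'
#' @param x A validated `workflow_cohort` with at least one procedure.
#' @return An object of class `cohort_summary`: list with
#'   * `steps`: tibble with columns `step_id`, `step_name`, `n_procedures`,
#'     `cumulative_time_min`, `mean_time_min`, `sd_time_min`,
#'     `rho_time_tot`, `rho_time_ct`, `cumulative_visits`, `mean_visits`,
#'     `sd_visits`, `rho_visits_tot`, `rho_visits_ct`;
#'   * cohort-level fields `n_procedures`, `mean_occurrences_per_procedure`,
#'     `sd_occurrences_per_procedure`, `mean_ct_min`, `sd_ct_min`,
#'     `mean_tot_min`, `sd_tot_min`.
#' @export
summarize_steps <- function(x) {
  stopifnot(inherits(x, "workflow_cohort"))
  if (n_procedures(x) == 0) stop("empty cohort", call. = FALSE)
  ps <- per_procedure_step(x)
  ps <- dplyr::left_join(ps, x$metadata, by = "procedure_id")

  per_step <- ps |>
    dplyr::group_by(.data$step_id) |>
    dplyr::summarise(
      n_procedures = dplyr::n(),
      cumulative_time_min = sum(.data$time_min),
      mean_time_min = mean(.data$time_min),
      sd_time_min = sd(.data$time_min),
      cumulative_visits = sum(.data$visits),
      mean_visits = mean(.data$visits),
      sd_visits = sd(.data$visits),
      rho_time_tot = spearman_rho(.data$time_min, .data$total_operative_time_min),
      rho_time_ct = spearman_rho(.data$time_min, .data$console_time_min),
      rho_visits_tot = spearman_rho(as.double(.data$visits),
                                    .data$total_operative_time_min),
      rho_visits_ct = spearman_rho(as.double(.data$visits),
                                   .data$console_time_min),
      .groups = "drop")

  steps <- tibble::tibble(step_id = x$catalog$step_id,
                          step_name = x$catalog$step_name) |>
    dplyr::left_join(per_step, by = "step_id")
  steps$n_procedures[is.na(steps$n_procedures)] <- 0L
  steps$cumulative_time_min[steps$n_procedures == 0] <- 0
  steps$cumulative_visits[steps$n_procedures == 0] <- 0L
  steps$cumulative_visits <- as.integer(steps$cumulative_visits)

  occ <- x$events |>
    dplyr::count(.data$procedure_id) |>
    dplyr::right_join(tibble::tibble(procedure_id = procedure_ids(x)),
                      by = "procedure_id")
  occ$n[is.na(occ$n)] <- 0L

  structure(list(
    steps = steps,
    n_procedures = n_procedures(x),
    mean_occurrences_per_procedure = mean(occ$n),
    sd_occurrences_per_procedure = sd(occ$n),
    mean_ct_min = mean_or_na(x$metadata$console_time_min),
    sd_ct_min = sd_or_na(x$metadata$console_time_min),
    mean_tot_min = mean_or_na(x$metadata$total_operative_time_min),
    sd_tot_min = sd_or_na(x$metadata$total_operative_time_min)
  ), class = "cohort_summary")
}

mean_or_na <- function(v) if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
sd_or_na <- function(v) if (sum(!is.na(v)) < 2) NA_real_ else sd(v, na.rm = TRUE)

#' @export
print.cohort_summary <- function(x, digits = 2, ...) {
  cat("<cohort_summary> ", x$n_procedures, " procedure(s)\n", sep = "")
  cat(sprintf("  step occurrences per procedure: %.1f (+/- %.1f)\n",
              x$mean_occurrences_per_procedure, x$sd_occurrences_per_procedure))
  cat(sprintf("  console time:        %s (+/- %s) min\n",
              format(round(x$mean_ct_min)), format(round(x$sd_ct_min))))
  cat(sprintf("  total operative time: %s (+/- %s) min\n",
              format(round(x$mean_tot_min)), format(round(x$sd_tot_min))))
  print(x$steps, n = nrow(x$steps))
  invisible(x)
}
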