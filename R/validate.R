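#' Validate a cohort's interval structure
#'
#' Steps may legitimately be skipped or revisited, but the annotation
#' protocol implies one active step at a time on the console, so two visits
#' of one procedure must not overlap in time. Intervals are half-open
#' `[start_s, stop_s)`: sharing a boundary is not an overlap.
#'
#' Overlap handling depends on `overlap_policy`:
#' * `"error"` (default): any overlap aborts with an error;
#' * `"truncate"`: the later event's start is clipped to the running stop of
#'   the earlier events (events rendered empty by clipping are dropped), and
#'   each repair is recorded as a finding;
#' * `"warn"`: findings are recorded, data left unchanged.
#'
#' Missing console/total operative time yields an informational finding;
#' a recorded total operative time below console time is an error-severity
#' finding (and aborts under `"error"`).
#'
#' @param x A `workflow_cohort` with at least one procedure.
#' @param overlap_policy One of `"error"`, `"truncate"`, `"warn"`.
#' @return An object of class `cohort_validation`: list with `cohort` (the
#'   possibly repaired cohort) and `findings`, a tibble with columns
#'   `severity` (`"error"`, `"warning"`, `"info"`), `procedure_id`,
#'   `event_index` (index into the procedure's sorted events, `NA` for
#'   procedure-level findings) and `message`.
#' @examples
#' ev <- data.frame(procedure_id = "P1", step_id = c(1, 2),
#'                  start_s = c(0, 50), stop_s = c(100, 150))
#' v <- validate_cohort(cohort(ev), overlap_policy = "truncate")
#' v$findings
#' v$cohort$events  # second event clipped to [100, 150)
#' @export
validate_cohort <- function(x, overlap_policy = c("error", "truncate", "warn")) {
  stopifnot(inherits(x, "workflow_cohort"))
  overlap_policy <- match.arg(overlap_policy)
  if (n_procedures(x) == 0) stop("empty cohort", call. = FALSE)

  findings <- list()
  add <- function(severity, pid, idx, msg) {
    findings[[length(findings) + 1L]] <<- tibble::tibble(
      severity = severity, procedure_id = pid,
      event_index = as.integer(idx), message = msg)
  }

  overlap_sev <- if (overlap_policy == "error") "error" else "warning"
  keep <- rep(TRUE, nrow(x$events))
  events <- x$events
  for (pid in procedure_ids(x)) {
    rows <- which(events$procedure_id == pid)
    if (length(rows) < 2) next
    cursor <- events$stop_s[rows[1]]
    for (k in seq_along(rows)[-1]) {
      i <- rows[k]
      if (events$start_s[i] < cursor) {
        if (overlap_policy == "truncate") {
          if (cursor >= events$stop_s[i]) {
            keep[i] <- FALSE
            add("warning", pid, k, sprintf(
              "event %d [%g,%g) fully covered by earlier events; dropped",
              k, events$start_s[i], events$stop_s[i]))
          } else {
            add("warning", pid, k, sprintf(
              "event %d start clipped from %g to %g",
              k, events$start_s[i], cursor))
            events$start_s[i] <- cursor
          }
        } else {
          add(overlap_sev, pid, k, sprintf(
            "event %d [%g,%g) overlaps earlier annotation (running stop %g)",
            k, events$start_s[i], events$stop_s[i], cursor))
        }
      }
      cursor <- max(cursor, events$stop_s[i])
    }
  }

  for (j in seq_len(nrow(x$metadata))) {
    pid <- x$metadata$procedure_id[j]
    ct <- x$metadata$console_time_min[j]
    tot <- x$metadata$total_operative_time_min[j]
    if (is.na(ct)) add("info", pid, NA, "console_time_min not recorded")
    if (is.na(tot)) add("info", pid, NA, "total_operative_time_min not recorded")
    if (!is.na(ct) && !is.na(tot) && tot < ct) {
      add("error", pid, NA, sprintf(
        "total_operative_time_min (%g) < console_time_min (%g)", tot, ct))
    }
  }

  findings <- if (length(findings) > 0) {
    dplyr::bind_rows(findings)
  } else {
    tibble::tibble(severity = character(), procedure_id = character(),
                   event_index = integer(), message = character())
  }

  if (overlap_policy == "error" && any(findings$severity == "error")) {
    bad <- findings[findings$severity == "error", ]
    stop("cohort validation failed:\n  ",
         paste(sprintf("[%s] %s", bad$procedure_id, bad$message),
               collapse = "\n  "), call. = FALSE)
  }

  out <- x
  if (overlap_policy == "truncate") {
    out <- cohort(events[keep, ], metadata = x$metadata, catalog = x$catalog)
  }
  structure(list(cohort = out, findings = findings),
            class = "cohort_validation")
}

#' @export
print.cohort_validation <- function(x, ...) {
  n <- table(factor(x$findings$severity, c("error", "warning", "info")))
  cat("<cohort_validation> ", n[["error"]], " error(s), ", n[["warning"]],
      " warning(s), ", n[["info"]], " info finding(s)\n", sep = "")
  invisible(x)
}
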