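#' Build an annotated-procedure cohort
#'
#' A cohort bundles a step catalog, one row per step visit (the events
#' table) and per-procedure operative-time metadata. Times are seconds from
#' each procedure's own clock origin (the first event need not start at 0);
#' all reported durations are minutes. Visit intervals are half-open
#' `[start_s, stop_s)`, so adjacent events sharing a boundary do not
#' overlap.
#'
#' Events are grouped by procedure and sorted by `start_s`; ties keep input
#' order (a warning is emitted, since the annotation protocol implies one
#' active step at a time).
#'
#' @param events Data frame with columns `procedure_id`, `step_id`,
#'   `start_s`, `stop_s`; one row per step visit.
#' @param metadata Optional data frame with columns `procedure_id`,
#'   `console_time_min`, `total_operative_time_min` (`NA` = not recorded).
#'   Procedures absent from `metadata` carry `NA` times.
#' @param catalog A [step_catalog()]; defaults to the 21-step proctectomy
#'   card.
#'
#' @return An object of class `workflow_cohort`: a list with elements
#'   `catalog`, `events`, `metadata`.
#' @examples
#' ev <- data.frame(procedure_id = "P1", step_id = c(2, 9, 2),
#'                  start_s = c(0, 100, 250), stop_s = c(60, 200, 300))
#' coh <- cohort(ev)
#' n_procedures(coh)
#' @export
cohort <- function(events, metadata = NULL, catalog = default_catalog()) {
  catalog <- validate_catalog(catalog)
  events <- tibble::as_tibble(events)
  req <- c("procedure_id", "step_id", "start_s", "stop_s")
  missing <- setdiff(req, names(events))
  if (length(missing) > 0) {
    stop("events is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  events <- events[, req]
  events$procedure_id <- as.character(events$procedure_id)
  events$step_id <- as.integer(events$step_id)
  events$start_s <- as.double(events$start_s)
  events$stop_s <- as.double(events$stop_s)

  if (nrow(events) > 0) {
    bad <- !(events$step_id %in% catalog$step_id)
    if (any(bad)) {
      stop("unknown step_id: ", paste(unique(events$step_id[bad]), collapse = ", "),
           call. = FALSE)
    }
    if (anyNA(events$start_s) || anyNA(events$stop_s) || any(events$start_s < 0)) {
      stop("start_s/stop_s must be non-negative numbers", call. = FALSE)
    }
    nonpos <- events$stop_s <= events$start_s
    if (any(nonpos)) {
      stop("events with stop_s <= start_s at row(s): ",
           paste(which(nonpos), collapse = ", "), call. = FALSE)
    }
    # stable per-procedure sort by start_s; ties keep input order
    ord <- order(match(events$procedure_id, unique(events$procedure_id)),
                 events$start_s, method = "radix")
    events <- events[ord, ]
    tied <- dplyr::summarise(
      dplyr::group_by(events, .data$procedure_id),
      tie = anyDuplicated(.data$start_s) > 0, .groups = "drop")
    if (any(tied$tie)) {
      warning("events with equal start_s within procedure(s) ",
              paste(tied$procedure_id[tied$tie], collapse = ", "),
              "; input order preserved", call. = FALSE)
    }
  }

  meta_cols <- c("procedure_id", "console_time_min", "total_operative_time_min")
  ids <- unique(events$procedure_id)
  if (is.null(metadata)) {
    metadata <- tibble::tibble(procedure_id = ids,
                               console_time_min = NA_real_,
                               total_operative_time_min = NA_real_)
  } else {
    metadata <- tibble::as_tibble(metadata)
    missing <- setdiff(meta_cols, names(metadata))
    if (length(missing) > 0) {
      stop("metadata is missing column(s): ", paste(missing, collapse = ", "),
           call. = FALSE)
    }
    metadata <- metadata[, meta_cols]
    metadata$procedure_id <- as.character(metadata$procedure_id)
    metadata$console_time_min <- as.double(metadata$console_time_min)
    metadata$total_operative_time_min <- as.double(metadata$total_operative_time_min)
    if (anyDuplicated(metadata$procedure_id)) {
      stop("duplicate procedure_id in metadata", call. = FALSE)
    }
    extra <- setdiff(metadata$procedure_id, ids)
    if (length(extra) > 0 && length(ids) > 0) {
      warning("metadata for procedure(s) with no events ignored: ",
              paste(extra, collapse = ", "), call. = FALSE)
    }
    metadata <- tibble::tibble(procedure_id = ids) |>
      dplyr::left_join(metadata, by = "procedure_id")
    bad_ct <- !is.na(metadata$console_time_min) & metadata$console_time_min <= 0
    bad_tot <- !is.na(metadata$total_operative_time_min) &
      metadata$total_operative_time_min <= 0
    if (any(bad_ct) || any(bad_tot)) {
      stop("console/total operative times must be positive minutes", call. = FALSE)
    }
  }

  structure(list(catalog = catalog, events = events, metadata = metadata),
            class = "workflow_cohort")
}

#' @rdname cohort
#' @param x A `workflow_cohort`.
#' @export
n_procedures <- function(x) length(procedure_ids(x))

#' @rdname cohort
#' @export
procedure_ids <- function(x) {
  stopifnot(inherits(x, "workflow_cohort"))
  x$metadata$procedure_id
}

#' Extract one procedure from a cohort
#'
#' @param x A `workflow_cohort`.
#' @param procedure_id Procedure identifier.
#' @return A `procedure_record`: list with `procedure_id`, `events` (sorted
#'   by `start_s`), `console_time_min`, `total_operative_time_min`, and the
#'   cohort `catalog`.
#' @export
get_procedure <- function(x, procedure_id) {
  stopifnot(inherits(x, "workflow_cohort"))
  if (!procedure_id %in% x$metadata$procedure_id) {
    stop("unknown procedure_id: ", procedure_id, call. = FALSE)
  }
  m <- x$metadata[x$metadata$procedure_id == procedure_id, ]
  structure(list(
    procedure_id = procedure_id,
    events = x$events[x$events$procedure_id == procedure_id, ],
    console_time_min = m$console_time_min,
    total_operative_time_min = m$total_operative_time_min,
    catalog = x$catalog
  ), class = "procedure_record")
}

#' @export
print.workflow_cohort <- function(x, ...) {
  cat("<workflow_cohort> ", n_procedures(x), " procedure(s), ",
      nrow(x$events), " step visit(s), ", nrow(x$catalog), "-step catalog\n",
      sep = "")
  invisible(x)
}

#' @export
print.procedure_record <- function(x, ...) {
  cat("<procedure_record> ", x$procedure_id, ": ", nrow(x$events),
      " visit(s); CT ", format(x$console_time_min), " min, TOT ",
      format(x$total_operative_time_min), " min\n", sep = "")
  invisible(x)
}
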