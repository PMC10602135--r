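#' Load annotation and metadata files into a cohort
#'
#' Events files are delimited text (comma default, tab accepted) with header
#' `procedure_id,step_id,start_s,stop_s` and one row per step visit; an
#' optional `step_name` column is cross-checked against the catalog.
#' Metadata files carry `procedure_id,console_time_min,total_operative_time_min`
#' with empty cells meaning "not recorded". Malformed rows are reported with
#' their file line number.
#'
#' @param events_path Path to the events file.
#' @param metadata_path Optional path to the metadata file.
#' @param catalog_path Optional path to a catalog file; overrides `catalog`.
#' @param catalog A [step_catalog()]; defaults to the built-in 21-step card.
#' @return A [cohort()] with events grouped by procedure and sorted by
#'   `start_s`.
#' @seealso [save_annotations()] for the inverse operation.
#' @export
load_annotations <- function(events_path, metadata_path = NULL,
                             catalog_path = NULL, catalog = default_catalog()) {
  if (!is.null(catalog_path)) catalog <- read_catalog(catalog_path)
  catalog <- validate_catalog(catalog)

  df <- read_delimited(events_path, c("procedure_id", "step_id", "start_s", "stop_s"))
  n <- nrow(df)
  line <- seq_len(n) + 1L  # data row i is file line i+1 (header on line 1)

  fail <- function(rows, why) {
    stop("malformed row in ", events_path, " at line(s) ",
         paste(head(line[rows], 5L), collapse = ", "), ": ", why,
         call. = FALSE)
  }
  if (n > 0) {
    step_id <- suppressWarnings(as.integer(df$step_id))
    start_s <- suppressWarnings(as.double(df$start_s))
    stop_s <- suppressWarnings(as.double(df$stop_s))
    if (anyNA(step_id)) fail(is.na(step_id), "step_id is not an integer")
    if (anyNA(start_s)) fail(is.na(start_s), "start_s is not a number")
    if (anyNA(stop_s)) fail(is.na(stop_s), "stop_s is not a number")
    unknown <- !(step_id %in% catalog$step_id)
    if (any(unknown)) fail(unknown, "unknown step_id")
    nonpos <- stop_s <= start_s
    if (any(nonpos)) fail(nonpos, "stop_s <= start_s")
    if (any(start_s < 0)) fail(start_s < 0, "negative start_s")
    if ("step_name" %in% names(df)) {
      expect_name <- catalog$step_name[match(step_id, catalog$step_id)]
      mismatch <- df$step_name != "" & df$step_name != expect_name
      if (any(mismatch)) fail(mismatch, "step_name does not match catalog")
    }
    key <- paste(df$procedure_id, start_s, step_id, sep = "\r")
    dup <- duplicated(key)
    if (any(dup)) fail(dup, "duplicate (procedure_id, start_s, step_id)")
    events <- tibble::tibble(procedure_id = df$procedure_id, step_id = step_id,
                             start_s = start_s, stop_s = stop_s)
  } else {
    events <- tibble::tibble(procedure_id = character(), step_id = integer(),
                             start_s = double(), stop_s = double())
  }

  metadata <- NULL
  if (!is.null(metadata_path)) {
    md <- read_delimited(metadata_path,
                         c("procedure_id", "console_time_min", "total_operative_time_min"))
    blank_to_na <- function(x) suppressWarnings(as.double(ifelse(x == "", NA, x)))
    ct <- blank_to_na(md$console_time_min)
    tot <- blank_to_na(md$total_operative_time_min)
    bad <- (md$console_time_min != "" & is.na(ct)) |
      (md$total_operative_time_min != "" & is.na(tot))
    if (any(bad)) {
      stop("malformed row in ", metadata_path, " at line(s) ",
           paste(which(bad) + 1L, collapse = ", "),
           ": operative times must be numbers or empty", call. = FALSE)
    }
    metadata <- tibble::tibble(procedure_id = md$procedure_id,
                               console_time_min = ct,
                               total_operative_time_min = tot)
  }

  cohort(events, metadata = metadata, catalog = catalog)
}

#' Write a cohort back to annotation files
#'
#' Emits the same delimited schema that [load_annotations()] reads; times
#' are serialized with fixed 3-decimal precision (millisecond resolution),
#' so save -> load is the identity on cohorts whose times carry at most
#' three decimals (the synthetic generator emits such times). An empty
#' cohort yields header-only files.
#'
#' @param x A `workflow_cohort`.
#' @param events_path Output path for the events file.
#' @param metadata_path Optional output path for the metadata file.
#' @param catalog_path Optional output path for the catalog sidecar.
#' @return Invisibly, the paths written.
#' @export
save_annotations <- function(x, events_path, metadata_path = NULL,
                             catalog_path = NULL) {
  stopifnot(inherits(x, "workflow_cohort"))
  num <- function(v) ifelse(is.na(v), "", sprintf("%.3f", v))
  ev <- tibble::tibble(
    procedure_id = x$events$procedure_id,
    step_id = x$events$step_id,
    start_s = sprintf("%.3f", x$events$start_s),
    stop_s = sprintf("%.3f", x$events$stop_s),
    step_name = x$catalog$step_name[match(x$events$step_id, x$catalog$step_id)]
  )
  readr::write_csv(ev, events_path)
  paths <- events_path
  if (!is.null(metadata_path)) {
    md <- tibble::tibble(
      procedure_id = x$metadata$procedure_id,
      console_time_min = num(x$metadata$console_time_min),
      total_operative_time_min = num(x$metadata$total_operative_time_min)
    )
    readr::write_csv(md, metadata_path)
    paths <- c(paths, metadata_path)
  }
  if (!is.null(catalog_path)) {
    write_catalog(x$catalog, catalog_path)
    paths <- c(paths, catalog_path)
  }
  invisible(paths)
}
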