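#' Ordered visit sequence of one procedure
#'
#' The step identifiers of a procedure's visits in ascending `start_s`
#' order. Consecutive visits to the same step are kept as distinct visits
#' unless `merge_gap_s > 0`, in which case same-step visits separated by an
#' off-step gap shorter than `merge_gap_s` seconds are fused into a single
#' visit spanning both.
#'
#' @param procedure A `procedure_record`.
#' @param merge_gap_s Non-negative seconds; 0 (default) disables fusion.
#' @return Integer vector of step ids, one entry per visit (empty for a
#'   procedure without events).
#' @export
visit_sequence <- function(procedure, merge_gap_s = 0) {
  stopifnot(inherits(procedure, "procedure_record"), merge_gap_s >= 0)
  merge_visits(procedure$events, merge_gap_s)$step_id
}

# Fuse same-step consecutive events whose inter-visit gap is < merge_gap_s.
# Events are assumed sorted by start_s (cohort construction guarantees it).
merge_visits <- function(events, merge_gap_s = 0) {
  if (merge_gap_s <= 0 || nrow(events) < 2) return(events)
  keep <- rep(TRUE, nrow(events))
  prev <- 1L
  for (i in 2:nrow(events)) {
    same <- events$step_id[i] == events$step_id[prev]
    gap <- events$start_s[i] - events$stop_s[prev]
    if (same && gap < merge_gap_s) {
      events$stop_s[prev] <- max(events$stop_s[prev], events$stop_s[i])
      keep[i] <- FALSE
    } else {
      prev <- i
    }
  }
  events[keep, ]
}

#' Consecutive transition pairs of a visit sequence
#'
#' @param sequence Integer vector of step ids (see [visit_sequence()]).
#' @return A two-column integer matrix (`from`, `to`) with one row per
#'   consecutive pair; `max(0, length(sequence) - 1)` rows. Self-pairs
#'   (consecutive visits to the same step) are retained — they are the
#'   ribbons entering and exiting the same step on a chord diagram.
#' @examples
#' transition_pairs(c(2, 9, 2, 12))
#' @export
transition_pairs <- function(sequence) {
  sequence <- as.integer(sequence)
  n <- length(sequence)
  if (n < 2) {
    return(matrix(integer(), ncol = 2, dimnames = list(NULL, c("from", "to"))))
  }
  cbind(from = sequence[-n], to = sequence[-1])
}

#' Cohort step-transition matrix
#'
#' Entry `(i, j)` counts the observed direct transitions from step `i` to
#' step `j`, summed over procedures; transitions never cross procedure
#' boundaries. Rows read as "where the workflow goes next after step i"
#' (divergence); columns as "where the workflow arrives at step j from"
#' (convergence). Raw counts, no normalization — chord-diagram ribbons
#' encode frequencies.
#'
#' @param x A validated `workflow_cohort` with at least one procedure.
#' @param merge_gap_s Passed to [visit_sequence()].
#' @return An integer matrix of class `transition_matrix` with one
#'   row/column per catalog step, labelled `S<step_id>`; the catalog is
#'   attached as attribute `catalog`.
#' @export
transition_matrix <- function(x, merge_gap_s = 0) {
  stopifnot(inherits(x, "workflow_cohort"))
  if (n_procedures(x) == 0) stop("empty cohort", call. = FALSE)
  k <- nrow(x$catalog)
  labels <- step_labels(x$catalog)
  pairs <- do.call(rbind, lapply(procedure_ids(x), function(pid) {
    transition_pairs(visit_sequence(get_procedure(x, pid), merge_gap_s))
  }))
  # row-major linear index so tabulate() aggregates duplicate pairs at once
  counts <- tabulate((pairs[, 1] - 1L) * k + pairs[, 2], nbins = k * k)
  m <- matrix(as.integer(counts), k, k, byrow = TRUE,
              dimnames = list(from = labels, to = labels))
  structure(m, class = c("transition_matrix", class(m)), catalog = x$catalog)
}

#' Distinct predecessor and successor counts of a step
#'
#' The number of distinct step types with at least one transition into
#' (`n_preceding_types`) and out of (`n_following_types`) the given step.
#' Self-transitions are excluded from both counts by default: the
#' classification counts *different* steps preceding/following, while the
#' transition matrix itself retains self-loops.
#'
#' @param m A [transition_matrix()].
#' @param step_id Catalog step identifier.
#' @param include_self Count the step itself among its own neighbors when
#'   it has self-transitions.
#' @return Named integer vector `c(n_preceding_types, n_following_types)`.
#' @export
neighbor_counts <- function(m, step_id, include_self = FALSE) {
  stopifnot(inherits(m, "transition_matrix"))
  catalog <- attr(m, "catalog")
  check_step(catalog, step_id)
  i <- match(step_id, catalog$step_id)
  pre <- which(m[, i] > 0)
  post <- which(m[i, ] > 0)
  if (!include_self) {
    pre <- setdiff(pre, i)
    post <- setdiff(post, i)
  }
  c(n_preceding_types = length(pre), n_following_types = length(post))
}

#' Classify a step as nodal, convergent, divergent or unclassified
#'
#' A *nodal* step has at least `threshold` different step types both
#' preceding and following it; a *divergent* step has fewer than
#' `threshold` preceding but more than `threshold` following; a
#' *convergent* step the reverse. Rules are evaluated in that order, so at
#' exactly `threshold` on both sides a step is nodal. Steps matching no
#' rule are *unclassified* — only a subset of steps earns a class.
#'
#' @param n_preceding_types,n_following_types Non-negative counts of
#'   distinct neighbor step types (vectors recycle).
#' @param threshold Class threshold (default 10 distinct step types).
#' @return Character vector over
#'   `c("nodal", "divergent", "convergent", "unclassified")`.
#' @examples
#' classify_step(16, 15)  # nodal
#' classify_step(13, 7)   # convergent
#' classify_step(6, 12)   # divergent
#' @export
classify_step <- function(n_preceding_types, n_following_types, threshold = 10) {
  if (any(n_preceding_types < 0) || any(n_following_types < 0)) {
    stop("neighbor counts must be non-negative", call. = FALSE)
  }
  stopifnot(threshold >= 0)
  pre <- n_preceding_types
  post <- n_following_types
  dplyr::case_when(
    pre >= threshold & post >= threshold ~ "nodal",
    pre < threshold & post > threshold ~ "divergent",
    pre > threshold & post < threshold ~ "convergent",
    .default = "unclassified"
  )
}

#' Transition profiles for every catalog step
#'
#' Combines cumulative visit counts, [neighbor_counts()] and
#' [classify_step()] into one row per step (the Table-2-style report).
#'
#' @param x A validated `workflow_cohort`.
#' @param threshold,include_self See [classify_step()], [neighbor_counts()].
#' @param merge_gap_s See [visit_sequence()].
#' @return A tibble with columns `step_id`, `step_name`,
#'   `cumulative_visits`, `n_preceding_types`, `n_following_types`,
#'   `step_class`.
#' @export
profile_steps <- function(x, threshold = 10, include_self = FALSE,
                          merge_gap_s = 0) {
  stopifnot(inherits(x, "workflow_cohort"))
  if (n_procedures(x) == 0) stop("empty cohort", call. = FALSE)
  m <- transition_matrix(x, merge_gap_s)
  visits <- vapply(procedure_ids(x), function(pid) {
    tabulate(visit_sequence(get_procedure(x, pid), merge_gap_s),
             nbins = nrow(x$catalog))
  }, integer(nrow(x$catalog)))
  nb <- t(vapply(x$catalog$step_id,
                 function(s) neighbor_counts(m, s, include_self),
                 c(n_preceding_types = 0L, n_following_types = 0L)))
  tibble::tibble(
    step_id = x$catalog$step_id,
    step_name = x$catalog$step_name,
    cumulative_visits = as.integer(rowSums(visits)),
    n_preceding_types = nb[, "n_preceding_types"],
    n_following_types = nb[, "n_following_types"],
    step_class = classify_step(nb[, "n_preceding_types"],
                               nb[, "n_following_types"], threshold)
  )
}

#' Export / import a chord-diagram matrix
#'
#' Writes the transition matrix as a tab-delimited labelled square grid in
#' the Circos tableviewer convention: first row and first column carry the
#' step labels, rows are transition sources, columns destinations. The file
#' loads back to an equal matrix with [read_chord_matrix()].
#'
#' @param m A [transition_matrix()] (or any labelled square count matrix).
#' @param path Output (input) path.
#' @return `export_chord_matrix()` returns `path` invisibly;
#'   `read_chord_matrix()` returns an integer matrix with dimnames.
#' @export
export_chord_matrix <- function(m, path) {
  stopifnot(is.matrix(m), nrow(m) == ncol(m))
  labels <- rownames(m)
  if (is.null(labels)) labels <- paste0("S", seq_len(nrow(m)))
  lines <- c(paste(c("step", labels), collapse = "\t"),
             vapply(seq_len(nrow(m)), function(i) {
               paste(c(labels[i], m[i, ]), collapse = "\t")
             }, character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname export_chord_matrix
#' @export
read_chord_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, row.names = 1)
  m <- as.matrix(df)
  storage.mode(m) <- "integer"
  dimnames(m) <- list(from = rownames(df), to = colnames(df))
  m
}
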