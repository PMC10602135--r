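#' Generative workflow model
#'
#' A first-order Markov model of an annotated procedure: a procedure draws
#' a per-step availability mask (steps can be skipped wholesale), walks a
#' row-stochastic transition kernel over the available steps until an
#' absorbing END state (or a hard visit cap), and assigns each visit a
#' log-normal duration and each inter-visit gap a log-normal length, so
#' events are chronologic and never overlap. Console time is annotated time
#' plus a log-normal console overhead; total operative time adds a further
#' off-console overhead.
#'
#' @param catalog A [step_catalog()] with `k` steps.
#' @param initial_probs Length-`k` non-negative weights over starting
#'   steps (renormalized over the available steps of each procedure).
#' @param kernel `k x (k+1)` non-negative matrix; rows sum to 1; column
#'   `k+1` is the absorbing END state. Rows are renormalized over each
#'   procedure's available steps plus END.
#' @param occurrence_mask_probs Length-`k` per-procedure probability that a
#'   step is available at all (rare steps get small values).
#' @param duration_meanlog,duration_sdlog Length-`k` log-normal parameters
#'   of per-visit durations, seconds.
#' @param gap_meanlog,gap_sdlog Scalars: log-normal inter-visit gap,
#'   seconds.
#' @param ct_overhead_meanlog,ct_overhead_sdlog Scalars: log-normal
#'   non-annotated console minutes added to annotated time to form CT.
#' @param tot_overhead_meanlog,tot_overhead_sdlog Scalars: log-normal
#'   off-console minutes added to CT to form TOT.
#' @param max_visits Hard cap on visits per procedure (termination
#'   backstop; END must also carry positive weight in every row).
#' @return An object of class `workflow_model`.
#' @seealso [default_model()] for the calibrated 21-step proctectomy model,
#'   [simulate_cohort()] to draw cohorts.
#' @export
workflow_model <- function(catalog, initial_probs, kernel,
                           occurrence_mask_probs,
                           duration_meanlog, duration_sdlog,
                           gap_meanlog, gap_sdlog,
                           ct_overhead_meanlog, ct_overhead_sdlog,
                           tot_overhead_meanlog, tot_overhead_sdlog,
                           max_visits = 300L) {
  catalog <- validate_catalog(catalog)
  k <- nrow(catalog)
  model <- structure(list(
    catalog = catalog,
    initial_probs = as.double(initial_probs),
    kernel = unname(as.matrix(kernel)),
    occurrence_mask_probs = as.double(occurrence_mask_probs),
    duration_meanlog = as.double(duration_meanlog),
    duration_sdlog = as.double(duration_sdlog),
    gap_meanlog = as.double(gap_meanlog),
    gap_sdlog = as.double(gap_sdlog),
    ct_overhead_meanlog = as.double(ct_overhead_meanlog),
    ct_overhead_sdlog = as.double(ct_overhead_sdlog),
    tot_overhead_meanlog = as.double(tot_overhead_meanlog),
    tot_overhead_sdlog = as.double(tot_overhead_sdlog),
    max_visits = as.integer(max_visits)
  ), class = "workflow_model")
  validate_model(model)
}

validate_model <- function(model) {
  k <- nrow(model$catalog)
  with(model, {
    stopifnot(
      length(initial_probs) == k, all(initial_probs >= 0),
      sum(initial_probs) > 0,
      is.matrix(kernel), nrow(kernel) == k, ncol(kernel) == k + 1,
      all(kernel >= 0),
      length(occurrence_mask_probs) == k,
      all(occurrence_mask_probs >= 0), all(occurrence_mask_probs <= 1),
      length(duration_meanlog) == k, length(duration_sdlog) == k,
      all(duration_sdlog >= 0), gap_sdlog >= 0,
      ct_overhead_sdlog >= 0, tot_overhead_sdlog >= 0,
      max_visits >= 1
    )
  })
  rs <- rowSums(model$kernel)
  if (any(abs(rs - 1) > 1e-8)) {
    stop("kernel rows must sum to 1 (max deviation ",
         format(max(abs(rs - 1))), ")", call. = FALSE)
  }
  # END must be reachable from every step: END weight in the row itself or
  # a path to a row that has it. With renormalization over arbitrary masks
  # the robust guarantee is direct END weight everywhere.
  if (any(model$kernel[, k + 1] <= 0)) {
    stop("every kernel row needs positive END weight (termination guarantee)",
         call. = FALSE)
  }
  model
}

#' @export
print.workflow_model <- function(x, ...) {
  cat("<workflow_model> ", nrow(x$catalog), " steps + END; max_visits ",
      x$max_visits, "\n", sep = "")
  invisible(x)
}

#' Default 21-step proctectomy workflow model
#'
#' A calibrated instance of [workflow_model()] emulating the structure of
#' the 31-procedure robotic proctectomy reference cohort: per-step
#' availability masks and per-visit mean durations derived from the
#' reference per-step marginals (occurring-procedure counts, cumulative
#' times and visits), a kernel mixing forward progression through the step
#' order with locality-weighted revisit attraction (which produces the
#' heavy revisit load on the rectal-dissection steps and dense
#' neighborhoods around the colon-mobilization steps), and log-normal
#' durations, gaps and console/off-console overheads. Large simulated
#' cohorts yield roughly 40-60 visits per procedure, console time around
#' 170-260 min and a 40-100 min console-to-total gap; the IMV steps appear
#' in under a quarter of procedures.
#'
#' @return A `workflow_model` over [default_catalog()].
#' @export
default_model <- function() {
  ref <- reference_step_stats()
  k <- nrow(ref)
  # occurring-procedure counts implied by the reference marginals
  n_occ <- round(ref$sum_visits / ref$mean_visits)
  mask <- n_occ / 31
  visit_share <- ref$sum_visits / sum(ref$sum_visits)
  per_visit_min <- ref$sum_time_min / ref$sum_visits

  # kernel row i: forward-neighbor progression + locality-damped revisit
  # attraction proportional to cohort visit shares + END weight late in
  # the order (small END weight everywhere guarantees termination)
  fwd <- 5
  attract <- 11
  kappa <- 0.9
  end_w <- rep(0.06, k)
  end_w[k - 2L] <- 1.5
  end_w[k - 1L] <- 4
  end_w[k] <- 30
  kernel <- matrix(0, k, k + 1)
  for (i in seq_len(k)) {
    w <- attract * visit_share * kappa^abs(seq_len(k) - i)
    if (i < k) w[i + 1L] <- w[i + 1L] + fwd
    kernel[i, seq_len(k)] <- w
    kernel[i, k + 1L] <- end_w[i]
  }
  kernel <- kernel / rowSums(kernel)

  initial <- rep(0, k)
  initial[1] <- 0.70   # initial exposure
  initial[2] <- 0.10   # IMA dissection first
  initial[9] <- 0.10   # medial-to-lateral pelvic start
  initial[10] <- 0.05
  initial[11] <- 0.05

  cv_dur <- 0.9  # per-visit duration coefficient of variation
  sdlog_dur <- sqrt(log(1 + cv_dur^2))
  meanlog_dur <- log(per_visit_min * 60) - sdlog_dur^2 / 2

  lnorm_pars <- function(mean, cv) {
    sdlog <- sqrt(log(1 + cv^2))
    c(meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
  }
  gap <- lnorm_pars(30, 1)      # seconds between visits
  ct_over <- lnorm_pars(85, 0.5)  # console minutes not inside annotated steps
  tot_over <- lnorm_pars(70, 0.45) # off-console minutes

  workflow_model(
    catalog = default_catalog(),
    initial_probs = initial,
    kernel = kernel,
    occurrence_mask_probs = mask,
    duration_meanlog = meanlog_dur,
    duration_sdlog = rep(sdlog_dur, k),
    gap_meanlog = gap[["meanlog"]], gap_sdlog = gap[["sdlog"]],
    ct_overhead_meanlog = ct_over[["meanlog"]],
    ct_overhead_sdlog = ct_over[["sdlog"]],
    tot_overhead_meanlog = tot_over[["meanlog"]],
    tot_overhead_sdlog = tot_over[["sdlog"]],
    max_visits = 300L
  )
}

#' Simulate one annotated procedure
#'
#' Draws the availability mask, walks the masked renormalized kernel from
#' an initial step to END (or `max_visits`), then lays visits on the clock
#' sequentially (start = previous stop + gap), so events never overlap.
#' Times are rounded to milliseconds — the serialization precision of
#' [save_annotations()] — keeping save/load an exact round trip. The same
#' seed always reproduces the identical record.
#'
#' @param model A `workflow_model`.
#' @param seed Integer seed for this procedure's private RNG stream.
#' @param procedure_id Identifier for the record.
#' @return A `procedure_record`.
#' @export
simulate_procedure <- function(model, seed, procedure_id = "P0001") {
  validate_model(model)
  k <- nrow(model$catalog)
  withr::with_seed(as.integer(seed), {
    avail <- runif(k) < model$occurrence_mask_probs
    if (!any(avail)) {
      stop("no available steps after masking (all steps masked out)",
           call. = FALSE)
    }
    init <- model$initial_probs * avail
    if (sum(init) == 0) init <- as.double(avail)
    cols <- c(which(avail), k + 1L)
    # per-row cumulative probabilities over available steps + END
    cum <- lapply(seq_len(k), function(i) {
      w <- model$kernel[i, cols]
      cumsum(w / sum(w))
    })
    path <- integer(model$max_visits)
    cur <- sample.int(k, 1L, prob = init)
    n <- 0L
    while (n < model$max_visits) {
      n <- n + 1L
      path[n] <- cur
      nxt <- cols[findInterval(runif(1), cum[[cur]], left.open = TRUE) + 1L]
      if (nxt == k + 1L) break
      cur <- nxt
    }
    path <- path[seq_len(n)]

    dur <- rlnorm(n, model$duration_meanlog[path], model$duration_sdlog[path])
    gaps <- rlnorm(n, model$gap_meanlog, model$gap_sdlog)
    dur <- pmax(round(dur, 3), 0.001)
    gaps <- round(gaps, 3)
    stops <- cumsum(gaps + dur)
    starts <- stops - dur
    annotated_min <- sum(dur) / 60
    ct <- annotated_min +
      rlnorm(1, model$ct_overhead_meanlog, model$ct_overhead_sdlog)
    tot <- ct + rlnorm(1, model$tot_overhead_meanlog, model$tot_overhead_sdlog)

    structure(list(
      procedure_id = procedure_id,
      events = tibble::tibble(procedure_id = procedure_id, step_id = path,
                              start_s = starts, stop_s = stops),
      console_time_min = round(ct, 3),
      total_operative_time_min = round(tot, 3),
      catalog = model$catalog
    ), class = "procedure_record")
  })
}

#' Simulate a cohort of annotated procedures
#'
#' The master seed spawns one sub-seed per procedure (so cohorts are
#' reproducible and procedures independent); ids are `P0001`, `P0002`, ...
#' Generated cohorts pass [validate_cohort()] with zero overlap findings by
#' construction.
#'
#' @param model A `workflow_model`.
#' @param n Number of procedures (>= 1).
#' @param seed Integer master seed.
#' @return A `workflow_cohort`.
#' @examples
#' coh <- simulate_cohort(default_model(), n = 5, seed = 7)
#' summarize_steps(coh)$mean_occurrences_per_procedure
#' @export
simulate_cohort <- function(model, n, seed) {
  validate_model(model)
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  sub_seeds <- withr::with_seed(as.integer(seed),
                                sample.int(2147483646L, n))
  ids <- sprintf("P%04d", seq_len(n))
  recs <- lapply(seq_len(n), function(i) {
    simulate_procedure(model, sub_seeds[i], ids[i])
  })
  events <- dplyr::bind_rows(lapply(recs, `[[`, "events"))
  metadata <- tibble::tibble(
    procedure_id = ids,
    console_time_min = vapply(recs, `[[`, 0, "console_time_min"),
    total_operative_time_min = vapply(recs, `[[`, 0, "total_operative_time_min")
  )
  cohort(events, metadata = metadata, catalog = model$catalog)
}

#' Estimate a transition kernel from a cohort
#'
#' Row-normalized empirical transition frequencies, with the terminal visit
#' of each procedure counted as a transition to END (last column). The
#' sampling inverse of [simulate_cohort()] when no occurrence masking is in
#' play; with masking the estimate converges to the mask-averaged kernel,
#' not the generating rows.
#'
#' @param x A `workflow_cohort`.
#' @return A `k x (k+1)` matrix of probabilities (rows with no visits are
#'   `NA`).
#' @export
estimate_kernel <- function(x) {
  stopifnot(inherits(x, "workflow_cohort"))
  k <- nrow(x$catalog)
  counts <- matrix(0, k, k + 1,
                   dimnames = list(step_labels(x$catalog),
                                   c(step_labels(x$catalog), "END")))
  counts[, seq_len(k)] <- unclass(transition_matrix(x))
  last <- vapply(procedure_ids(x), function(pid) {
    s <- visit_sequence(get_procedure(x, pid))
    if (length(s) == 0) NA_integer_ else s[length(s)]
  }, integer(1))
  counts[, k + 1] <- tabulate(last[!is.na(last)], nbins = k)
  rs <- rowSums(counts)
  out <- counts / rs
  out[rs == 0, ] <- NA_real_
  out
}
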