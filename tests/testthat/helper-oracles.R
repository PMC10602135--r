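# Independent oracles and fixture builders shared across test files.

# Average ranks computed by explicit tie-group scan (no call to rank()).
oracle_avg_rank <- function(v) {
  n <- length(v)
  o <- order(v)
  s <- v[o]
  r <- numeric(n)
  i <- 1L
  while (i <= n) {
    j <- i
    while (j < n && s[j + 1L] == s[i]) j <- j + 1L
    r[o[i:j]] <- mean(i:j)
    i <- j + 1L
  }
  r
}

# Product-moment correlation from raw sums (no call to cor()).
oracle_pearson <- function(x, y) {
  n <- length(x)
  num <- n * sum(x * y) - sum(x) * sum(y)
  den <- sqrt(n * sum(x^2) - sum(x)^2) * sqrt(n * sum(y^2) - sum(y)^2)
  num / den
}

oracle_spearman <- function(x, y) {
  oracle_pearson(oracle_avg_rank(x), oracle_avg_rank(y))
}

# A 3-procedure hand-built cohort exercising skips, revisits and metadata.
tiny_cohort <- function() {
  ev <- tibble::tibble(
    procedure_id = c("A", "A", "A", "B", "B", "C"),
    step_id = c(2L, 9L, 2L, 9L, 12L, 2L),
    start_s = c(0, 100, 250, 0, 700, 5),
    stop_s = c(60, 200, 300, 600, 760, 65)
  )
  md <- tibble::tibble(procedure_id = c("A", "B", "C"),
                       console_time_min = c(120, 200, NA),
                       total_operative_time_min = c(180, 260, 300))
  cohort(ev, metadata = md)
}

# Every procedure performs steps 1..21 exactly once, in catalog order.
chain_cohort <- function(n_proc = 3) {
  ev <- do.call(rbind, lapply(seq_len(n_proc), function(p) {
    tibble::tibble(procedure_id = sprintf("P%02d", p), step_id = 1:21,
                   start_s = (0:20) * 100, stop_s = (0:20) * 100 + 60)
  }))
  cohort(ev)
}

# One procedure alternating a hub step with 12 distinct partners, so the
# hub has 12 distinct predecessors and successors.
hub_cohort <- function(hub = 3L) {
  partners <- setdiff(1:21, hub)[1:12]
  seq_ids <- c(rbind(rep(hub, 12), partners), hub)
  starts <- seq_along(seq_ids) * 100
  cohort(tibble::tibble(procedure_id = "H", step_id = seq_ids,
                        start_s = starts, stop_s = starts + 50))
}

# Wrap a plain count matrix as a transition_matrix over a toy catalog.
as_tm <- function(m) {
  k <- nrow(m)
  cat <- step_catalog(seq_len(k), paste0("step ", seq_len(k)))
  dimnames(m) <- list(from = paste0("S", seq_len(k)),
                      to = paste0("S", seq_len(k)))
  structure(m, class = c("transition_matrix", class(m)), catalog = cat)
}

# Plain matrix view of a transition_matrix (drops class and catalog attr).
strip_tm <- function(m) {
  a <- unclass(m)
  attr(a, "catalog") <- NULL
  a
}

# Small 4-step model with every step always available; uniform-ish kernel.
small_model <- function() {
  k <- 4
  kernel <- matrix(0, k, k + 1)
  kernel[1, ] <- c(0.10, 0.40, 0.25, 0.15, 0.10)
  kernel[2, ] <- c(0.20, 0.05, 0.45, 0.20, 0.10)
  kernel[3, ] <- c(0.15, 0.25, 0.10, 0.30, 0.20)
  kernel[4, ] <- c(0.10, 0.20, 0.25, 0.05, 0.40)
  workflow_model(
    catalog = step_catalog(1:k, paste0("step ", 1:k)),
    initial_probs = c(0.7, 0.1, 0.1, 0.1),
    kernel = kernel,
    occurrence_mask_probs = rep(1, k),
    duration_meanlog = rep(log(60), k), duration_sdlog = rep(0.5, k),
    gap_meanlog = log(10), gap_sdlog = 0.5,
    ct_overhead_meanlog = log(30), ct_overhead_sdlog = 0.3,
    tot_overhead_meanlog = log(20), tot_overhead_sdlog = 0.3,
    max_visits = 200L
  )
}

# Empty procedure record (a procedure with no annotated visits).
empty_procedure <- function() {
  structure(list(
    procedure_id = "E",
    events = tibble::tibble(procedure_id = character(), step_id = integer(),
                            start_s = double(), stop_s = double()),
    console_time_min = NA_real_, total_operative_time_min = NA_real_,
    catalog = default_catalog()
  ), class = "procedure_record")
}
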