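test_that("step_time and step_visits do per-procedure interval arithmetic", {
  p <- get_procedure(tiny_cohort(), "A")
  expect_equal(step_time(p, 2), (60 + 50) / 60)  # [0,60) + [250,300)
  expect_equal(step_visits(p, 2), 2)
  expect_equal(step_time(p, 12), 0)   # absent step
  expect_equal(step_visits(p, 12), 0)
  expect_error(step_time(p, 99), "unknown step_id")

  ev <- tibble::tibble(procedure_id = "X", step_id = 2L,
                       start_s = c(0, 300), stop_s = c(120, 360))
  px <- get_procedure(cohort(ev), "X")
  expect_equal(step_time(px, 2), 3.0)
})

test_that("visit counts partition the event total", {
  coh <- simulate_cohort(default_model(), n = 5, seed = 3)
  for (pid in procedure_ids(coh)) {
    p <- get_procedure(coh, pid)
    expect_equal(sum(vapply(1:21, function(s) step_visits(p, s), 0L)),
                 nrow(p$events))
  }
})

test_that("step_time equals an independent per-event summation loop", {
  coh <- simulate_cohort(default_model(), n = 3, seed = 17)
  p <- get_procedure(coh, "P0002")
  for (s in 1:21) {
    acc <- 0
    for (i in seq_len(nrow(p$events))) {
      if (p$events$step_id[i] == s) {
        acc <- acc + (p$events$stop_s[i] - p$events$start_s[i])
      }
    }
    expect_equal(step_time(p, s), acc / 60)
  }
})

test_that("spearman_rho handles monotone, tied and degenerate inputs", {
  expect_equal(spearman_rho(1:3, c(10, 20, 30)), 1.0)
  expect_equal(spearman_rho(1:4, c(8, 6, 4, 2)), -1.0)
  expect_true(is.na(spearman_rho(1:5, rep(2, 5))))   # zero variance
  expect_true(is.na(spearman_rho(1:2, 2:1)))          # fewer than 3 pairs
  expect_error(spearman_rho(1:3, 1:4), "equal length")
})

test_that("spearman_rho matches the rank-then-Pearson oracle with ties", {
  withr::with_seed(101, {
    for (i in 1:200) {
      n <- sample(3:25, 1)
      x <- sample(1:8, n, replace = TRUE) + runif(n) * (i %% 2)
      y <- sample(1:8, n, replace = TRUE) + runif(n) * ((i + 1) %% 2)
      got <- spearman_rho(x, y)
      want <- oracle_spearman(x, y)
      if (length(unique(x)) < 2 || length(unique(y)) < 2) {
        expect_true(is.na(got))
      } else {
        expect_equal(got, want, tolerance = 1e-12)
      }
    }
  })
})

test_that("spearman_rho is invariant under strictly increasing transforms", {
  withr::with_seed(7, {
    x <- rnorm(30); y <- rnorm(30)
    base <- spearman_rho(x, y)
    expect_equal(spearman_rho(exp(x), y), base)
    expect_equal(spearman_rho(x, y^3 + 5 * y), base)
    expect_equal(spearman_rho(2 * x + 1, exp(y)), base)
  })
})

test_that("summarize_steps uses the occurring-procedures denominator", {
  s <- summarize_steps(tiny_cohort())
  row2 <- s$steps[s$steps$step_id == 2, ]
  # step 2 occurs in A (110 s) and C (60 s), not B
  expect_equal(row2$n_procedures, 2)
  expect_equal(row2$cumulative_time_min, 170 / 60)
  expect_equal(row2$mean_time_min, 170 / 60 / 2)
  expect_equal(row2$cumulative_visits, 3L)
  expect_equal(row2$mean_visits, 1.5)

  # step 12 occurs once: SD undefined, not zero
  row12 <- s$steps[s$steps$step_id == 12, ]
  expect_equal(row12$n_procedures, 1)
  expect_true(is.na(row12$sd_time_min))

  # never-occurring step: zero sums, NA statistics
  row21 <- s$steps[s$steps$step_id == 21, ]
  expect_equal(row21$n_procedures, 0)
  expect_equal(row21$cumulative_visits, 0L)
  expect_true(is.na(row21$mean_time_min))
  expect_true(is.na(row21$rho_time_tot))
})

test_that("sd_visits is exactly zero when every occurring count is identical", {
  ev <- tibble::tibble(procedure_id = c("A", "B", "C"),
                       step_id = 5L, start_s = 0, stop_s = c(50, 60, 70))
  s <- summarize_steps(cohort(ev))
  expect_equal(s$steps$sd_visits[5], 0)
  expect_equal(s$steps$mean_visits[5], 1)
})

test_that("cumulative step time is conserved across the step partition", {
  coh <- simulate_cohort(default_model(), n = 10, seed = 5)
  s <- summarize_steps(coh)
  total_by_step <- sum(s$steps$cumulative_time_min)
  total_by_proc <- sum(coh$events$stop_s - coh$events$start_s) / 60
  expect_equal(total_by_step, total_by_proc, tolerance = 1e-9)
  # mean = cumulative / n for every occurring step, both metrics
  occ <- s$steps[s$steps$n_procedures > 0, ]
  expect_equal(occ$mean_time_min, occ$cumulative_time_min / occ$n_procedures)
  expect_equal(occ$mean_visits, occ$cumulative_visits / occ$n_procedures)
})

test_that("mean occurrences per procedure equals a direct event count", {
  coh <- simulate_cohort(default_model(), n = 12, seed = 9)
  s <- summarize_steps(coh)
  expect_equal(s$mean_occurrences_per_procedure, nrow(coh$events) / 12)
  expect_equal(sum(s$steps$cumulative_visits), nrow(coh$events))
})

test_that("correlate_step pairs only occurring procedures with recorded times", {
  # two occurring procedures -> NA under the < 3 pairs rule
  expect_true(is.na(correlate_step(tiny_cohort(), 2, "time", "TOT")))

  coh <- simulate_cohort(default_model(), n = 15, seed = 21)
  s <- 12  # posterior rectal dissection: occurs in essentially all
  ids <- procedure_ids(coh)
  t_by_proc <- vapply(ids, function(p) step_time(get_procedure(coh, p), s), 0)
  occ <- t_by_proc > 0
  ct <- coh$metadata$console_time_min
  expect_equal(correlate_step(coh, s, "time", "CT"),
               spearman_rho(t_by_proc[occ], ct[occ]))

  # all CT missing -> NA
  coh$metadata$console_time_min <- NA_real_
  expect_true(is.na(correlate_step(coh, s, "time", "CT")))
})

test_that("a monotone step-time/CT link is recovered within 0.05", {
  n <- 2000
  coh <- withr::with_seed(31, {
    ct <- runif(n, 100, 400)
    minutes <- pmax(0.05 * ct + rnorm(n, 0, 3), 0.1)
    cohort(
      tibble::tibble(procedure_id = sprintf("P%04d", 1:n), step_id = 1L,
                     start_s = 0, stop_s = minutes * 60),
      metadata = tibble::tibble(procedure_id = sprintf("P%04d", 1:n),
                                console_time_min = ct,
                                total_operative_time_min = ct + 50))
  })
  # rank correlation of the generating law, from an independent large draw
  rho_gen <- withr::with_seed(99, {
    ct2 <- runif(2e5, 100, 400)
    min2 <- pmax(0.05 * ct2 + rnorm(2e5, 0, 3), 0.1)
    cor(ct2, min2, method = "spearman")
  })
  expect_equal(correlate_step(coh, 1, "time", "CT"), rho_gen,
               tolerance = 0.05)
})
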