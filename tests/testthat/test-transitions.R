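test_that("visit_sequence orders visits and honors the merge window", {
  ev <- tibble::tibble(procedure_id = "P1", step_id = c(2L, 9L, 2L),
                       start_s = c(0, 100, 250), stop_s = c(60, 200, 300))
  p <- get_procedure(cohort(ev), "P1")
  expect_equal(visit_sequence(p), c(2L, 9L, 2L))

  ev2 <- tibble::tibble(procedure_id = "P1", step_id = c(5L, 5L),
                        start_s = c(0, 70), stop_s = c(60, 120))
  p2 <- get_procedure(cohort(ev2), "P1")
  expect_equal(visit_sequence(p2), c(5L, 5L))                 # no merging
  expect_equal(visit_sequence(p2, merge_gap_s = 30), 5L)      # gap 10 < 30
  expect_equal(visit_sequence(p2, merge_gap_s = 5), c(5L, 5L))
  # fused visit spans both originals
  merged <- procflow:::merge_visits(p2$events, 30)
  expect_equal(c(merged$start_s, merged$stop_s), c(0, 120))

  expect_equal(visit_sequence(empty_procedure()), integer())
})

test_that("transition_pairs slides a window of consecutive visits", {
  expect_equal(transition_pairs(c(2, 9, 2, 12)),
               cbind(from = c(2L, 9L, 2L), to = c(9L, 2L, 12L)))
  expect_equal(nrow(transition_pairs(5L)), 0)
  expect_equal(nrow(transition_pairs(integer())), 0)

  withr::with_seed(12, {
    for (i in 1:20) {
      s <- sample(1:6, sample(1:30, 1), replace = TRUE)
      got <- transition_pairs(s)
      want <- if (length(s) < 2) {
        matrix(integer(), ncol = 2)
      } else {
        t(vapply(seq_len(length(s) - 1),
                 function(j) c(s[j], s[j + 1]), integer(2)))
      }
      expect_equal(unname(got), unname(want))
    }
  })
})

test_that("transition_matrix counts within procedures only", {
  ev <- tibble::tibble(
    procedure_id = c("A", "A", "B", "B", "C"),
    step_id = c(1L, 2L, 2L, 1L, 3L),
    start_s = c(0, 100, 0, 100, 0), stop_s = c(50, 150, 50, 150, 50))
  m <- transition_matrix(cohort(ev))
  expect_equal(sum(m), 2)              # single-visit C contributes nothing
  expect_equal(m["S1", "S2"], 1L)
  expect_equal(m["S2", "S1"], 1L)
  # no cross-procedure A-last -> B-first artifact
  expect_equal(m["S2", "S2"], 0L)
})

test_that("matrix totals and margins obey flow conservation", {
  coh <- simulate_cohort(default_model(), n = 8, seed = 13)
  m <- transition_matrix(coh)
  seqs <- lapply(procedure_ids(coh),
                 function(p) visit_sequence(get_procedure(coh, p)))
  expect_equal(sum(m), sum(vapply(seqs, function(s) max(0L, length(s) - 1L),
                                  0L)))
  occ <- tabulate(unlist(seqs), nbins = 21)
  firsts <- tabulate(vapply(seqs, head, 0L, n = 1L), nbins = 21)
  lasts <- tabulate(vapply(seqs, tail, 0L, n = 1L), nbins = 21)
  expect_equal(unname(rowSums(m)), occ - lasts)
  expect_equal(unname(colSums(m)), occ - firsts)
})

test_that("per-procedure transition totals ignore uniform time shifts", {
  coh <- simulate_cohort(default_model(), n = 3, seed = 29)
  shifted <- coh$events
  for (pid in procedure_ids(coh)) {
    rows <- shifted$procedure_id == pid
    shift <- match(pid, procedure_ids(coh)) * 1000
    shifted$start_s[rows] <- shifted$start_s[rows] + shift
    shifted$stop_s[rows] <- shifted$stop_s[rows] + shift
  }
  coh2 <- cohort(shifted, metadata = coh$metadata, catalog = coh$catalog)
  expect_equal(transition_matrix(coh2), transition_matrix(coh))
})

test_that("neighbor_counts match a brute-force distinct-set oracle", {
  zero <- as_tm(matrix(0L, 6, 6))
  expect_equal(unname(neighbor_counts(zero, 3)), c(0L, 0L))

  m <- matrix(0L, 21, 21)
  m[c(2, 12, 15), 9] <- 3L
  tm <- as_tm(m)
  expect_equal(neighbor_counts(tm, 9)[["n_preceding_types"]], 3L)

  withr::with_seed(41, {
    for (i in 1:30) {
      k <- sample(4:12, 1)
      cm <- as_tm(matrix(rpois(k * k, 0.6), k, k))
      s <- sample(k, 1)
      for (self in c(FALSE, TRUE)) {
        pre <- sum(vapply(seq_len(k), function(j) {
          cm[j, s] > 0 && (self || j != s)
        }, TRUE))
        post <- sum(vapply(seq_len(k), function(j) {
          cm[s, j] > 0 && (self || j != s)
        }, TRUE))
        expect_equal(unname(neighbor_counts(cm, s, include_self = self)),
                     c(pre, post))
      }
    }
  })
  expect_error(neighbor_counts(zero, 99), "unknown step_id")
})

test_that("classify_step applies the rules in nodal-first order", {
  expect_equal(classify_step(16, 15), "nodal")
  expect_equal(classify_step(13, 11), "nodal")
  expect_equal(classify_step(13, 7), "convergent")
  expect_equal(classify_step(6, 12), "divergent")
  expect_equal(classify_step(10, 10), "nodal")        # boundary: nodal first
  expect_equal(classify_step(5, 5), "unclassified")
  expect_equal(classify_step(9, 10), "unclassified")  # 10 following not > 10
  expect_equal(classify_step(10, 9), "unclassified")
  expect_error(classify_step(-1, 5), "non-negative")
})

test_that("classify_step is monotone and degenerate thresholds behave", {
  withr::with_seed(53, {
    for (i in 1:100) {
      pre <- sample(0:21, 1); post <- sample(0:21, 1)
      if (classify_step(pre, post) == "nodal") {
        expect_equal(classify_step(pre + 1, post), "nodal")
        expect_equal(classify_step(pre, post + 1), "nodal")
      }
    }
  })
  # threshold 0: any step with traffic both ways is nodal
  coh <- simulate_cohort(default_model(), n = 5, seed = 2)
  prof0 <- profile_steps(coh, threshold = 0)
  expect_true(all(prof0$step_class == "nodal"))
  # threshold above catalog size: nothing is nodal
  prof22 <- profile_steps(coh, threshold = 22)
  expect_true(all(prof22$step_class != "nodal"))
})

test_that("profile_steps classifies chains and hubs as expected", {
  prof <- profile_steps(chain_cohort(4))
  interior <- prof[prof$step_id %in% 2:20, ]
  expect_true(all(interior$n_preceding_types == 1))
  expect_true(all(interior$n_following_types == 1))
  expect_true(all(prof$step_class == "unclassified"))
  expect_equal(prof$cumulative_visits, rep(4L, 21))

  hub <- profile_steps(hub_cohort(hub = 3L))
  expect_equal(hub$step_class[3], "nodal")
  expect_equal(hub$n_preceding_types[3], 12L)
  expect_equal(hub$n_following_types[3], 12L)
})

test_that("profile visits and matrix margins stay consistent", {
  coh <- simulate_cohort(default_model(), n = 6, seed = 77)
  prof <- profile_steps(coh)
  m <- transition_matrix(coh)
  expect_equal(sum(prof$cumulative_visits), nrow(coh$events))
  expect_true(all(rowSums(unclass(m)) <= prof$cumulative_visits))
  expect_true(all(colSums(unclass(m)) <= prof$cumulative_visits))
})

test_that("chord matrix export writes a labelled grid that round-trips", {
  m2 <- as_tm(matrix(c(0L, 3L, 1L, 2L), 2, 2, byrow = TRUE))
  p <- withr::local_tempfile(fileext = ".tsv")
  export_chord_matrix(m2, p)
  lines <- readLines(p)
  expect_length(lines, 3)                       # label row + 2 data rows
  expect_equal(lines[1], "step\tS1\tS2")
  expect_equal(read_chord_matrix(p), strip_tm(m2), ignore_attr = "class")

  coh <- simulate_cohort(default_model(), n = 5, seed = 4)
  m <- transition_matrix(coh)
  p2 <- withr::local_tempfile(fileext = ".tsv")
  export_chord_matrix(m, p2)
  expect_equal(read_chord_matrix(p2), strip_tm(m), ignore_attr = "class")

  zero <- as_tm(matrix(0L, 3, 3))
  p3 <- withr::local_tempfile(fileext = ".tsv")
  export_chord_matrix(zero, p3)
  expect_true(all(read_chord_matrix(p3) == 0))
})
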