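---
title: "Quantifying surgical workflow from step-level annotations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying surgical workflow from step-level annotations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(procflow)
```

## The problem

Operative reports describe surgical workflow subjectively. When a robotic
procedure is video-recorded, trained annotators can instead mark the start
and stop of each discrete surgical step on the timeline, using a
procedure-specific annotation card. For robotic proctectomy the card has 21
steps (`default_catalog()`), from initial exposure through IMA/IMV
dissection and ligation, colon and splenic flexure mobilization, the four
quadrants of rectal dissection, to transection, anastomosis and leak
testing. A surgeon may skip a step, perform it once, or revisit it many
times, so the annotation of one procedure is an ordered sequence of timed
*step visits*.

procflow turns such annotations into quantitative workflow descriptions:

1. **Per-step statistics** — how long each step takes, how often it is
   visited, and how strongly each metric associates (Spearman's rho) with
   the two traditional proficiency metrics, console time (CT) and total
   operative time (TOT).
2. **Transition structure** — a first-order transition count matrix over
   consecutive visits, from which each step gets counts of *distinct* step
   types preceding and following it, and a class: *nodal* (at least 10
   distinct types on both sides), *divergent* (fewer than 10 preceding,
   more than 10 following), *convergent* (the reverse), or *unclassified*.
3. **A synthetic cohort generator** — a seeded Markov model calibrated to
   the published marginals of a 31-procedure robotic proctectomy reference
   cohort, so the entire pipeline is testable without clinical data.

## Data model and validation

Events are half-open intervals `[start_s, stop_s)` in seconds on each
procedure's own clock; durations are reported in minutes (divide by 60 at
the presentation layer only, so annotation resolution is never lost).
Half-open intervals make boundary-sharing events non-overlapping, which
avoids double-counting time. The annotation clock origin (skin incision vs
first console event) is deliberately left unspecified: every statistic the
package computes is invariant under a uniform time shift of a procedure's
events, so the origin convention cannot matter.

One step is active at a time on the console, so overlapping visits within
a procedure are treated as annotation defects. `validate_cohort()` offers
three policies: `error` (default — reject), `truncate` (clip the later
event's start to the running stop of the earlier ones; events swallowed
whole are dropped; repair is idempotent) and `warn` (record findings,
leave data). Ties on `start_s` keep file order and emit a warning —
the data cannot disambiguate them, but determinism requires a rule.

CT and TOT are external metadata, never inferred from the annotations:
the reference cohort measured them independently, and annotated time is a
strict subset of console time.

```{r validate-example}
ev <- data.frame(procedure_id = "P1", step_id = c(1, 2),
                 start_s = c(0, 50), stop_s = c(100, 150))
v <- validate_cohort(cohort(ev), overlap_policy = "truncate")
v$findings$message
v$cohort$events
```

## Per-step statistics: the occurring-procedures denominator

`summarize_steps()` computes per-step means and SDs over **only the
procedures in which the step occurs**. This is the arithmetic that
reproduces the reference table: IMV ligation accumulated 5.55 min over 6
occurring procedures, hence a mean of 0.925 (printed 0.92) — not
5.55/31. Zero-filling absent procedures would drag rare-step means toward
zero and make their correlations statements about *whether* the step was
performed rather than *how it went*.

The same occurring subset feeds the correlations: pairs are formed only
from procedures where the step occurs and the operative time is recorded.
`spearman_rho()` assigns average ranks to ties and returns `NA` below 3
pairs or when either side has zero variance — exactly why the reference
cohort prints `NA` for IMV-ligation visit correlations: that step was
visited exactly once in every occurring procedure, so the visit vector is
constant. SDs are sample SDs (n−1), the convention for small clinical
cohorts, and are `NA` (not 0) for single-occurrence steps.

```{r summary-example}
coh <- marginal_cohort()       # reconstruction of the reference marginals
s <- summarize_steps(coh)
s$steps[c(1, 4, 5, 12, 21),
        c("step_name", "n_procedures", "cumulative_time_min", "mean_time_min")]
round(s$mean_occurrences_per_procedure, 1)
```

`marginal_cohort()` deserves a caveat: it reconstructs a cohort whose
sums, occurring-procedure counts and visit totals match a published
marginal table exactly, by spreading visits evenly and giving every visit
the step-average duration. It is a device for auditing summary arithmetic
against printed tables; its visit order and correlations are meaningless.
Cross-checking it against the reference table also surfaces that table's
internal inconsistencies: for three steps (both directed splenic-flexure
rows and right lateral rectal dissection) the printed mean time implies an
occurring-procedure count that contradicts the visit columns — for the
supracolic row even a non-integer one. The package follows the
visit-implied counts and reports the three mismatches rather than
arbitrating them.

## Transition structure and step classes

`transition_matrix()` counts consecutive-visit pairs within procedures
(never across), including self-transitions — chord diagrams of the
reference cohort show ribbons entering and exiting the same step, so they
are real traffic. The distinct-neighbor counts behind classification
exclude self-transitions by default, because the class definitions count
*different* steps preceding and following; `include_self = TRUE` reverses
this for sensitivity analysis.

Two conventions are worth stating because the class definitions overlap
at the threshold:

* **Rule order.** "At least 10" (nodal) intersects the strict ">10"/"<10"
  divergent/convergent rules at exactly 10; nodal is evaluated first.
  This order reproduces all four published classifications, including the
  (13, 11) nodal case that the strict rules alone would leave undecided.
* **Unclassified** is an explicit fourth outcome: the reference study
  classifies only a subset of steps, and a deterministic chain cohort
  (every interior step one predecessor, one successor) classifies nothing.

```{r classify-example}
classify_step(c(13, 16, 13, 6), c(11, 15, 7, 12))
profile_steps(marginal_cohort())[c(9, 10, 11, 17), ]
```

(Classes computed on `marginal_cohort()` are artifacts of its synthetic
layout — the real classification input is a genuinely ordered cohort, as
in `analysis/03_transitions.R`.)

The matrix obeys exact flow conservation — row sums equal occurrences
minus last-visit counts, column sums occurrences minus first-visit counts
— which the tests exploit as an oracle on hundreds of simulated cohorts.
`export_chord_matrix()` writes the labelled tab-delimited grid the Circos
tableviewer ingests; rendering itself is out of scope (a frequency
heatmap via `plot_transition_frequencies()` is the best-effort stand-in).

## The synthetic generator

`default_model()` is a first-order Markov model over the 21 steps plus an
absorbing END state, with:

* **Occurrence masks** drawn per procedure *before* the walk
  (probability = reference occurring-count / 31, e.g. ≈ 0.16 for IMV
  steps), reproducing wholesale step skipping independently of transition
  dynamics.
* **A kernel** mixing forward progression along the catalog order
  (weight 5 to the next available step) with revisit attraction
  proportional to reference visit shares, damped by 0.9^distance —
  yielding heavy revisits of the rectal-dissection block and dense
  neighborhoods around the mobilization steps. END carries weight 0.06
  everywhere (termination is guaranteed, `max_visits = 300` is a
  backstop) and substantial weight on the last three steps, so walks end
  where procedures do.
* **Log-normal durations** per visit (mean = reference per-visit mean,
  CV 0.9 — strictly positive and right-skewed, matching SDs of the same
  order as the means), log-normal inter-visit gaps (mean 30 s), and
  log-normal console (mean 85 min) and off-console (mean 70 min)
  overheads. Events are laid out sequentially (start = previous stop +
  gap), so overlap is impossible by construction; times are rounded to
  milliseconds, the save/load serialization precision, making file
  round-trips exact.
* **Seeding**: a master seed spawns per-procedure sub-seeds, so cohorts
  are byte-reproducible and procedures independent.

Calibration is to coarse ranges, not exact moment-matching of 21 coupled
marginals: at n = 500 (seed 1) the model yields 48.4 visits per
procedure (reference 49.0 ± 20.3), mean CT 209 min (213 ± 90) and a
71-min CT-to-TOT gap (70). Two known departures from the reference
cohort: the per-procedure visit-count SD (~50) is far above 20.3,
because a first-order Markov walk has a near-geometric length
distribution — matching the SD would need a duration- or
progress-dependent stopping model; and step durations are independent
draws, so the generator encodes no step-time/CT correlation beyond the
mechanical one (CT contains annotated time). Tests that pass on
synthetic cohorts therefore certify the *pipeline arithmetic*, not any
clinical claim.

One estimation subtlety: with occurrence masking active, empirical
transition frequencies estimate the *mask-averaged* kernel, not the
generating rows (each procedure renormalizes rows over its own available
steps). Kernel-recovery tests therefore run on a masks-all-1 variant,
where `estimate_kernel()` recovers every generating probability ≥ 0.05
within ±0.02 at n = 5000.

## Numerical conventions

* Full precision internally; presentation rounds times and rho to 2
  decimals; `NA` prints as `NA`, never 0.
* Annotation files serialize times at 3 decimals; model YAML at 15
  significant digits (round trips are exact at serialized precision,
  kernel rows revalidated to sum to 1 within 1e-8 on load).
* Problem sizes in the test suite — 2 000 procedures for rank-correlation
  recovery, 5 000 for kernel recovery, 200 seeded cohorts for flow
  conservation, 1 000 random vectors against the brute-force rank oracle
  — were chosen as the smallest sizes at which the corresponding sampling
  error is comfortably below the asserted tolerance.

## Limitations

Beyond the generator caveats above: the transition model is first-order
(no higher-order or duration-dependent dynamics, no process-mining
conformance checking); chord-diagram rendering is a heatmap, not a Circos
reproduction; and CT/TOT modeling is additive-overhead only. The
annotation side deliberately excludes video decoding, annotation UIs and
de-identification.
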