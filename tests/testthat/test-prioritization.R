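# builders for a fully controlled evidence table
priority_inputs <- function(alt_length = 84, in_cds = TRUE, delta = 0.2,
                            wilcox_p = 0.01, logrank_p = 0.01,
                            na_fraction = 0, n_control_na = 0,
                            n_tumor = 9, n_control = 6) {
  samples <- c(sprintf("t%02d", seq_len(n_tumor)),
               sprintf("c%02d", seq_len(n_control)))
  groups <- tibble::tibble(sample_id = samples,
                           group = rep(c("tumor", "control"),
                                       c(n_tumor, n_control)))
  n_na <- round(na_fraction * length(samples))
  psi_na <- rep(FALSE, length(samples))
  if (n_control_na > 0) psi_na[n_tumor + seq_len(n_control_na)] <- TRUE
  extra <- n_na - sum(psi_na)
  if (extra > 0) psi_na[seq_len(extra)] <- TRUE
  psi <- tibble::tibble(event_id = "e1", sample_id = samples,
                        psi = ifelse(psi_na, NA_real_, 0.5))
  list(
    events = tibble::tibble(event_id = "e1", alt_length = alt_length,
                            in_cds = in_cds),
    differential = tibble::tibble(event_id = "e1", delta_psi = delta,
                                  wilcoxon_p = wilcox_p),
    survival = tibble::tibble(event_id = "e1", logrank_p = logrank_p),
    psi = psi, groups = groups
  )
}

run_cascade <- function(inp, ...) {
  apply_prioritization(inp$events, inp$differential, inp$survival, inp$psi,
                       inp$groups, ...)
}

test_that("an 84-bp in-frame tumor-high event with both p < 0.05 is retained", {
  res <- run_cascade(priority_inputs())
  expect_true(res$retained)
  expect_false(any(unlist(res[paste0("c", 1:6,
    c("_na_two_thirds", "_small_inframe", "_no_survival", "_no_differential",
      "_control_na", "_small_delta"))])))
})

test_that("each exclusion criterion fires on its boundary exactly as worded", {
  # c2: 12 bp is a multiple of 3 affecting 4 amino acids
  expect_false(run_cascade(priority_inputs(alt_length = 12))$retained)
  expect_true(run_cascade(priority_inputs(alt_length = 12))$c2_small_inframe)
  # 15 bp = 5 amino acids no longer fires c2 (but fails the 30-300 shortlist)
  r15 <- run_cascade(priority_inputs(alt_length = 15))
  expect_false(r15$c2_small_inframe)
  expect_false(r15$length_in_window)

  # c6: delta = 0.1 exactly is "no more than 0.1" -> excluded
  expect_true(run_cascade(priority_inputs(delta = 0.1))$c6_small_delta)
  expect_false(run_cascade(priority_inputs(delta = 0.1))$retained)
  expect_false(run_cascade(priority_inputs(delta = 0.100001))$c6_small_delta)

  # c1: NA in >= 2/3 of all samples
  expect_true(run_cascade(priority_inputs(na_fraction = 2 / 3))$c1_na_two_thirds)
  expect_false(run_cascade(priority_inputs(na_fraction = 0.6))$c1_na_two_thirds)

  # c5: NA in more than four control samples
  expect_true(run_cascade(priority_inputs(n_control_na = 5))$c5_control_na)
  expect_false(run_cascade(priority_inputs(n_control_na = 4))$c5_control_na)

  # c3/c4: p at alpha is "not significant"
  expect_true(run_cascade(priority_inputs(logrank_p = 0.05))$c3_no_survival)
  expect_true(run_cascade(priority_inputs(wilcox_p = 0.05))$c4_no_differential)

  # shortlist: boundaries 30 and 300 are inside the window
  expect_true(run_cascade(priority_inputs(alt_length = 30))$length_in_window)
  expect_true(run_cascade(priority_inputs(alt_length = 300))$length_in_window)
  expect_false(run_cascade(priority_inputs(alt_length = 301))$length_in_window)
  # tumor-high direction is required
  expect_false(run_cascade(priority_inputs(delta = -0.3))$retained)
  # coding-region preference is required
  expect_false(run_cascade(priority_inputs(in_cds = FALSE))$retained)
})

test_that("the cascade is monotone in its thresholds and order-independent", {
  set.seed(77)
  n_ev <- 40
  samples <- c(sprintf("t%02d", 1:9), sprintf("c%02d", 1:6))
  groups <- tibble::tibble(sample_id = samples,
                           group = rep(c("tumor", "control"), c(9, 6)))
  events <- tibble::tibble(event_id = sprintf("e%02d", 1:n_ev),
                           alt_length = sample(5:400, n_ev),
                           in_cds = sample(c(TRUE, FALSE), n_ev, replace = TRUE))
  differential <- tibble::tibble(event_id = events$event_id,
                                 delta_psi = runif(n_ev, -0.5, 0.5),
                                 wilcoxon_p = runif(n_ev))
  survres <- tibble::tibble(event_id = events$event_id, logrank_p = runif(n_ev))
  psi <- tidyr::crossing(event_id = events$event_id, sample_id = samples) |>
    dplyr::mutate(psi = ifelse(runif(dplyr::n()) < 0.1, NA, runif(dplyr::n())))
  strict <- apply_prioritization(events, differential, survres, psi, groups,
                                 alpha = 0.05, delta_psi_cutoff = 0.1)
  relaxed <- apply_prioritization(events, differential, survres, psi, groups,
                                  alpha = 0.5, delta_psi_cutoff = 0.01)
  expect_true(all(strict$event_id[strict$retained] %in%
                    relaxed$event_id[relaxed$retained]))

  # retained = intersection of per-criterion survivor sets
  flags <- c("c1_na_two_thirds", "c2_small_inframe", "c3_no_survival",
             "c4_no_differential", "c5_control_na", "c6_small_delta")
  survivors <- lapply(flags, function(f) strict$event_id[!strict[[f]]])
  shortlist <- strict$event_id[strict$length_in_window & strict$in_cds &
                                 strict$high_tumor_psi]
  expect_setequal(strict$event_id[strict$retained],
                  Reduce(intersect, c(survivors, list(shortlist))))

  # shuffling event order changes nothing
  perm <- sample(n_ev)
  shuffled <- apply_prioritization(events[perm, ], differential, survres, psi,
                                   groups, alpha = 0.05, delta_psi_cutoff = 0.1)
  expect_equal(dplyr::arrange(shuffled, event_id)$retained,
               dplyr::arrange(strict, event_id)$retained)
})

test_that("events with missing evidence are excluded with a reason", {
  inp <- priority_inputs()
  inp$events <- dplyr::bind_rows(
    inp$events, tibble::tibble(event_id = "e_orphan", alt_length = 84,
                               in_cds = TRUE))
  res <- run_cascade(inp)
  orphan <- res[res$event_id == "e_orphan", ]
  expect_false(orphan$retained)
  expect_equal(orphan$reason, "incomplete evidence")
})
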