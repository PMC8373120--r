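#' Candidate-prioritization cascade
#'
#' Applies the six exclusion criteria and the three shortlist requirements to
#' every event for which differential, survival and PSI evidence is
#' available. An event is retained iff no exclusion criterion fires and all
#' shortlist flags hold.
#'
#' Exclusion criteria (a `TRUE` flag excludes the event):
#' * `c1_na_two_thirds`: PSI is `NA` in at least 2/3 of all samples.
#' * `c2_small_inframe`: the alternative segment length is a multiple of 3
#'   and affects fewer than five amino acids (i.e. length < 15 bp and
#'   divisible by 3) — a trivially small in-frame change.
#' * `c3_no_survival`: log-rank p >= `alpha` (or `NA`).
#' * `c4_no_differential`: Wilcoxon p >= `alpha` (or `NA`).
#' * `c5_control_na`: PSI is `NA` in more than `max_control_na` control
#'   samples.
#' * `c6_small_delta`: |ΔPSI| <= `delta_psi_cutoff` ("no more than 0.1"
#'   excludes the boundary value itself).
#'
#' Shortlist flags (all must be `TRUE` to retain):
#' * `length_in_window`: alternative-segment length within `length_window`
#'   (inclusive, default 30--300 bp).
#' * `in_cds`: segment overlaps the coding region of an inclusion-form
#'   transcript.
#' * `high_tumor_psi`: mean tumor PSI exceeds mean control PSI
#'   (`delta_psi > 0`).
#'
#' By default p-values are used nominally; set `adjust = "BH"` for a
#' Benjamini--Hochberg FDR-adjusted screen.
#'
#' @param events Event catalog.
#' @param differential Output of [differential_psi()].
#' @param survival_results Output of [survival_association()].
#' @param psi Long PSI tibble (for the NA-based criteria).
#' @param groups Tibble `sample_id`, `group`.
#' @param alpha Significance threshold for criteria 3 and 4 (default 0.05).
#' @param delta_psi_cutoff ΔPSI magnitude that still fires criterion 6
#'   (default 0.1; the boundary fires).
#' @param length_window Inclusive shortlist length window (default
#'   `c(30, 300)`).
#' @param max_control_na Criterion 5 cutoff (default 4; "more than four"
#'   fires).
#' @param na_fraction_cutoff Criterion 1 cutoff (default 2/3; at or above
#'   fires).
#' @param adjust `"none"` (default, nominal p) or `"BH"`.
#' @param control Control group label (default `"control"`).
#' @return Tibble with one row per event: the evidence columns, the six
#'   criterion flags, the three shortlist flags, and `retained`. Events with
#'   incomplete evidence are excluded with `reason = "incomplete evidence"`.
#' @export
apply_prioritization <- function(events, differential, survival_results, psi,
                                 groups,
                                 alpha = 0.05,
                                 delta_psi_cutoff = 0.1,
                                 length_window = c(30, 300),
                                 max_control_na = 4,
                                 na_fraction_cutoff = 2 / 3,
                                 adjust = c("none", "BH"),
                                 control = "control") {
  adjust <- match.arg(adjust)
  assert_cols(events, c("event_id", "alt_length", "in_cds"))
  assert_cols(differential, c("event_id", "delta_psi", "wilcoxon_p"))
  assert_cols(survival_results, c("event_id", "logrank_p"))
  control_samples <- groups$sample_id[groups$group == control]

  na_stats <- psi |>
    group_by(.data$event_id) |>
    summarise(
      na_fraction = mean(is.na(.data$psi)),
      n_control_na = sum(is.na(.data$psi) &
                           .data$sample_id %in% control_samples),
      .groups = "drop"
    )

  diff_use <- differential |> select("event_id", "delta_psi", "wilcoxon_p")
  surv_use <- survival_results |> select("event_id", "logrank_p")
  if (adjust == "BH") {
    diff_use$wilcoxon_p <- stats::p.adjust(diff_use$wilcoxon_p, method = "BH")
    surv_use$logrank_p <- stats::p.adjust(surv_use$logrank_p, method = "BH")
  }

  tab <- events |>
    select("event_id", any_of(c("event_type", "gene_id")), "alt_length", "in_cds") |>
    left_join(diff_use, by = "event_id") |>
    left_join(surv_use, by = "event_id") |>
    left_join(na_stats, by = "event_id")

  complete <- !is.na(tab$na_fraction) &
    tab$event_id %in% diff_use$event_id &
    tab$event_id %in% surv_use$event_id
  incomplete <- tab[!complete, , drop = FALSE] |>
    mutate(reason = "incomplete evidence", retained = FALSE)

  out <- tab[complete, , drop = FALSE] |>
    mutate(
      c1_na_two_thirds = .data$na_fraction >= na_fraction_cutoff,
      c2_small_inframe = .data$alt_length %% 3 == 0 &
        .data$alt_length / 3 < 5,
      c3_no_survival = is.na(.data$logrank_p) | .data$logrank_p >= alpha,
      c4_no_differential = is.na(.data$wilcoxon_p) | .data$wilcoxon_p >= alpha,
      c5_control_na = .data$n_control_na > max_control_na,
      c6_small_delta = is.na(.data$delta_psi) |
        abs(.data$delta_psi) <= delta_psi_cutoff,
      length_in_window = .data$alt_length >= length_window[1] &
        .data$alt_length <= length_window[2],
      high_tumor_psi = !is.na(.data$delta_psi) & .data$delta_psi > 0,
      retained = !.data$c1_na_two_thirds & !.data$c2_small_inframe &
        !.data$c3_no_survival & !.data$c4_no_differential &
        !.data$c5_control_na & !.data$c6_small_delta &
        .data$length_in_window & .data$in_cds & .data$high_tumor_psi,
      reason = NA_character_
    )
  bind_rows(out, incomplete) |> arrange(.data$event_id)
}
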