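#' Differential PSI screen between two sample groups
#'
#' Per event, a two-sided Mann--Whitney/Wilcoxon rank-sum test on the non-NA
#' PSI values of the two groups, plus the PSI difference
#' \eqn{\Delta PSI = \bar{\psi}_{tumor} - \bar{\psi}_{control}}. The exact
#' rank-sum distribution is used when both group sizes are at most 8 and the
#' pooled values contain no ties; otherwise the normal approximation with tie
#' correction (and continuity correction) is used. The p-value is `NA` when
#' either group has fewer than 2 usable values.
#'
#' @param psi Long PSI tibble (`event_id`, `sample_id`, `psi`).
#' @param groups Tibble `sample_id`, `group`.
#' @param tumor,control The two group labels (defaults `"tumor"`,
#'   `"control"`).
#' @return Tibble: `event_id`, `delta_psi`, `wilcoxon_p`, `n_tumor_used`,
#'   `n_control_used`.
#' @export
differential_psi <- function(psi, groups, tumor = "tumor", control = "control") {
  assert_cols(psi, c("event_id", "sample_id", "psi"))
  assert_cols(groups, c("sample_id", "group"))
  if (!all(c(tumor, control) %in% groups$group)) {
    stop_sp("groups must contain both labels '", tumor, "' and '", control, "'")
  }
  dat <- psi |>
    inner_join(groups, by = "sample_id") |>
    filter(.data$group %in% c(tumor, control))
  dat |>
    group_by(.data$event_id) |>
    summarise(
      res = list(wilcoxon_screen(.data$psi[.data$group == tumor],
                                 .data$psi[.data$group == control])),
      .groups = "drop"
    ) |>
    unnest("res")
}

wilcoxon_screen <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  delta <- if (length(x) > 0 && length(y) > 0) mean(x) - mean(y) else NA_real_
  p <- NA_real_
  if (length(x) >= 2 && length(y) >= 2) {
    exact <- length(x) <= 8 && length(y) <= 8 && !any(duplicated(c(x, y)))
    p <- suppressWarnings(
      wilcox.test(x, y, alternative = "two.sided", exact = exact,
                  correct = TRUE)$p.value
    )
  }
  tibble(delta_psi = delta, wilcoxon_p = p,
         n_tumor_used = length(x), n_control_used = length(y))
}
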