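#' Heatmap of a PSI table
#'
#' @param psi Long PSI tibble.
#' @param groups Optional `sample_id`/`group` tibble used to order samples.
#' @return A ggplot object (tiles; `NA` cells grey).
#' @export
plot_psi_heatmap <- function(psi, groups = NULL) {
  dat <- psi
  if (!is.null(groups)) {
    ord <- groups |> arrange(.data$group, .data$sample_id)
    dat$sample_id <- factor(dat$sample_id, levels = ord$sample_id)
  }
  ggplot(dat, aes(x = .data$sample_id, y = .data$event_id, fill = .data$psi)) +
    geom_tile() +
    scale_fill_viridis_c(limits = c(0, 1), na.value = "grey85") +
    labs(x = "sample", y = "event", fill = "PSI") +
    theme_minimal(base_size = 9) +
    theme(axis.text.x = element_blank(), axis.ticks.x = element_blank())
}

#' Kaplan--Meier curves for a PSI median split
#'
#' @param records Survival tibble with `time`, `event` and a `group` column.
#' @return A ggplot step plot, one curve per group.
#' @export
plot_km <- function(records) {
  assert_cols(records, c("time", "event", "group"))
  curves <- records |>
    group_by(.data$group) |>
    group_split() |>
    map(function(d) {
      km <- km_estimate(d)
      bind_rows(tibble(time = 0, survival = 1),
                tidy(km) |> select("time", "survival")) |>
        mutate(group = d$group[1])
    }) |>
    list_rbind()
  ggplot(curves, aes(x = .data$time, y = .data$survival, colour = .data$group)) +
    geom_step(linewidth = 0.7) +
    coord_cartesian(ylim = c(0, 1)) +
    labs(x = "time (months)", y = "survival probability", colour = NULL) +
    theme_classic()
}

#' @export
autoplot.km_fit <- function(object, ...) {
  dat <- bind_rows(tibble(time = 0, survival = 1),
                   object$table |> select("time", "survival"))
  ggplot(dat, aes(x = .data$time, y = .data$survival)) +
    geom_step(linewidth = 0.7) +
    coord_cartesian(ylim = c(0, 1)) +
    labs(x = "time (months)", y = "survival probability") +
    theme_classic()
}

#' Dot plot of regulator correlation results
#'
#' @param ranking Output of [correlate_regulators()].
#' @param alpha Significance line (default 0.05).
#' @return A ggplot object: regulators ordered by p, -log10(p) vs r.
#' @export
plot_regulator_correlations <- function(ranking, alpha = 0.05) {
  dat <- ranking |> filter(!is.na(.data$p))
  ggplot(dat, aes(x = .data$r, y = -log10(.data$p))) +
    geom_point(aes(size = .data$r_squared), alpha = 0.8) +
    geom_hline(yintercept = -log10(alpha), linetype = 2, colour = "grey40") +
    labs(x = "Pearson r (PSI vs expression)", y = expression(-log[10](p)),
         size = expression(R^2)) +
    theme_classic()
}

#' Volcano-style plot of the differential PSI screen
#'
#' @param differential Output of [differential_psi()].
#' @param alpha,delta_cutoff Guide lines (defaults 0.05 and 0.1).
#' @return A ggplot object.
#' @export
plot_differential_psi <- function(differential, alpha = 0.05, delta_cutoff = 0.1) {
  dat <- differential |> filter(!is.na(.data$wilcoxon_p), !is.na(.data$delta_psi))
  ggplot(dat, aes(x = .data$delta_psi, y = -log10(.data$wilcoxon_p))) +
    geom_point(alpha = 0.6) +
    geom_hline(yintercept = -log10(alpha), linetype = 2, colour = "grey40") +
    geom_vline(xintercept = c(-delta_cutoff, delta_cutoff),
               linetype = 2, colour = "grey40") +
    labs(x = expression(Delta * PSI ~ "(tumor - control)"),
         y = expression(-log[10](p))) +
    theme_classic()
}
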