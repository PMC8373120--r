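#' Compute percent spliced-in (PSI) for one event in one sample
#'
#' PSI is estimated from junction-read support. Because the inclusion form of
#' a cassette exon spans two junctions while the exclusion form spans one,
#' raw inclusion counts are biased 2:1; counts are therefore normalized by
#' the number of junctions in each set before forming the ratio:
#' \deqn{\bar I = I / n_{inc}, \quad \bar S = S / n_{exc}, \quad
#'       \psi = \bar I / (\bar I + \bar S)}
#' where `I` and `S` are total reads over the event's inclusion and exclusion
#' junctions. PSI is `NA` when `I + S < min_total_reads` (insufficient
#' evidence), per the coverage rule.
#'
#' @param event One-row slice of an event catalog (needs the junction
#'   list-columns, `event_id` and `chrom`).
#' @param junctions Junction-count tibble for one sample
#'   (`chrom`, `donor`, `acceptor`, `count`). Strand is ignored for matching:
#'   minimal alignments carry no transcription strand.
#' @param min_total_reads Minimum `I + S` for a finite PSI (default 10).
#' @return One-row tibble: `event_id`, `sample_id`, `psi`, `inclusion_reads`,
#'   `exclusion_reads`.
#' @export
compute_psi <- function(event, junctions, min_total_reads = 10L) {
  if (nrow(event) != 1) stop_sp("compute_psi() expects a single event row")
  inc <- event$inclusion_junctions[[1]]
  exc <- event$exclusion_junctions[[1]]
  if (nrow(inc) == 0 || nrow(exc) == 0) {
    stop_sp("event ", event$event_id, " has an empty junction set; ",
            "PSI requires junction evidence on both forms ",
            "(retained-intron events are not junction-quantifiable)")
  }
  sample_id <- if ("sample_id" %in% names(junctions) && nrow(junctions) > 0) {
    junctions$sample_id[1]
  } else "sample"
  sum_counts <- function(j) {
    if (nrow(junctions) == 0) return(0L)
    total <- 0L
    for (i in seq_len(nrow(j))) {
      sel <- junctions$chrom == event$chrom &
        junctions$donor == j$donor[i] & junctions$acceptor == j$acceptor[i]
      total <- total + sum(junctions$count[sel])
    }
    total
  }
  I <- sum_counts(inc); S <- sum_counts(exc)
  psi <- if (I + S < min_total_reads) {
    NA_real_
  } else {
    ibar <- I / nrow(inc); sbar <- S / nrow(exc)
    ibar / (ibar + sbar)
  }
  tibble(event_id = event$event_id, sample_id = sample_id,
         psi = psi, inclusion_reads = as.integer(I), exclusion_reads = as.integer(S))
}

#' Compute the events-by-samples PSI table
#'
#' Vectorized PSI over an event catalog and a multi-sample junction-count
#' table. Events with an empty inclusion or exclusion junction set (e.g.
#' retained introns, which have no junction evidencing retention) are dropped
#' with a warning: they are not junction-quantifiable.
#'
#' @param events Event catalog from [enumerate_events()].
#' @param junctions Junction-count tibble covering all samples
#'   (`sample_id`, `chrom`, `donor`, `acceptor`, `count`).
#' @param samples Optional character vector fixing the sample universe
#'   (samples absent from `junctions` get `NA` PSI). Defaults to the samples
#'   present in `junctions`.
#' @param min_total_reads Coverage rule passed to the per-cell PSI.
#' @return Long tibble: `event_id`, `sample_id`, `psi`, `inclusion_reads`,
#'   `exclusion_reads`. The per-event NA fraction is attached as attribute
#'   `"na_fraction"` (named numeric).
#' @export
psi_matrix <- function(events, junctions, samples = NULL, min_total_reads = 10L) {
  assert_cols(junctions, c("sample_id", "chrom", "donor", "acceptor", "count"))
  if (nrow(events) == 0) stop_sp("psi_matrix() needs at least one event")
  quantifiable <- map_int(events$inclusion_junctions, nrow) > 0 &
    map_int(events$exclusion_junctions, nrow) > 0
  if (any(!quantifiable)) {
    warn(paste0("dropping ", sum(!quantifiable),
                " event(s) without junction evidence on both forms (e.g. RI)"))
    events <- events[quantifiable, , drop = FALSE]
  }
  if (nrow(events) == 0) stop_sp("no junction-quantifiable events")
  samples <- samples %||% unique(junctions$sample_id)
  if (length(samples) == 0) stop_sp("psi_matrix() needs at least one sample")

  jmap <- events |>
    select("event_id", "chrom", "inclusion_junctions", "exclusion_junctions") |>
    pivot_longer(c("inclusion_junctions", "exclusion_junctions"),
                 names_to = "role", values_to = "j") |>
    mutate(role = ifelse(.data$role == "inclusion_junctions", "inc", "exc")) |>
    unnest("j")
  n_j <- jmap |> count(.data$event_id, .data$role, name = "n_junc")

  counts <- jmap |>
    inner_join(junctions |> filter(.data$sample_id %in% samples),
               by = c("chrom", "donor", "acceptor"),
               relationship = "many-to-many") |>
    group_by(.data$event_id, .data$sample_id, .data$role) |>
    summarise(reads = sum(.data$count), .groups = "drop")

  grid <- crossing(event_id = events$event_id, sample_id = samples,
                   role = c("inc", "exc"))
  full <- grid |>
    left_join(counts, by = c("event_id", "sample_id", "role")) |>
    mutate(reads = replace_na(.data$reads, 0L)) |>
    left_join(n_j, by = c("event_id", "role")) |>
    pivot_wider(names_from = "role", values_from = c("reads", "n_junc"))

  out <- full |>
    mutate(
      total = .data$reads_inc + .data$reads_exc,
      ibar = .data$reads_inc / .data$n_junc_inc,
      sbar = .data$reads_exc / .data$n_junc_exc,
      psi = ifelse(.data$total < min_total_reads, NA_real_,
                   .data$ibar / (.data$ibar + .data$sbar))
    ) |>
    transmute(.data$event_id, .data$sample_id, .data$psi,
              inclusion_reads = as.integer(.data$reads_inc),
              exclusion_reads = as.integer(.data$reads_exc)) |>
    arrange(.data$event_id, .data$sample_id)
  na_frac <- out |>
    group_by(.data$event_id) |>
    summarise(f = mean(is.na(.data$psi)))
  attr(out, "na_fraction") <- setNames(na_frac$f, na_frac$event_id)
  out
}

#' Reshape a long PSI table to an events-by-samples matrix
#'
#' @param psi Long PSI tibble from [psi_matrix()].
#' @return Numeric matrix, rows = events, columns = samples.
#' @export
psi_to_matrix <- function(psi) {
  wide <- psi |>
    select("event_id", "sample_id", "psi") |>
    pivot_wider(names_from = "sample_id", values_from = "psi")
  m <- as.matrix(wide[, -1, drop = FALSE])
  rownames(m) <- wide$event_id
  m
}

#' Write / read a PSI table as an events-by-samples TSV
#'
#' Missing values are written as the literal `NA`.
#'
#' @param psi Long PSI tibble.
#' @param path File path.
#' @return `path` invisibly / a long PSI tibble (read).
#' @export
write_psi_tsv <- function(psi, path) {
  m <- psi_to_matrix(psi)
  readr::write_tsv(as_tibble(m, rownames = "event_id"), path, na = "NA")
  invisible(path)
}

#' @rdname write_psi_tsv
#' @export
read_psi_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE) |>
    pivot_longer(-"event_id", names_to = "sample_id", values_to = "psi")
}
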