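#' Rank candidate trans-acting regulators by PSI--expression correlation
#'
#' Pearson correlation (with the two-sided t-distribution p-value of
#' [stats::cor.test()]) between a target event's per-sample PSI and each
#' candidate regulator's expression, over pairwise-complete samples. The
#' output is sorted by p ascending, ties broken by |r| descending.
#'
#' @param expression Wide expression tibble: `gene_id` + one column per
#'   sample.
#' @param target_psi Tibble `sample_id`, `psi` for the target event.
#' @param regulator_ids Character vector of candidate regulator gene ids.
#' @return Tibble: `regulator_id`, `r`, `r_squared`, `p`, `n_used`, sorted.
#'   Regulators absent from the expression table are skipped with a warning;
#'   regulators with fewer than 3 usable sample pairs get `NA` statistics.
#' @export
correlate_regulators <- function(expression, target_psi, regulator_ids) {
  assert_cols(expression, "gene_id")
  assert_cols(target_psi, c("sample_id", "psi"))
  absent <- setdiff(regulator_ids, expression$gene_id)
  if (length(absent) > 0) {
    warn(paste0("regulator(s) absent from expression table, skipped: ",
                paste(head(absent, 5), collapse = ", ")))
  }
  present <- intersect(regulator_ids, expression$gene_id)
  samples <- intersect(setdiff(names(expression), "gene_id"),
                       target_psi$sample_id)
  psi_vec <- target_psi$psi[match(samples, target_psi$sample_id)]
  res <- map(present, function(reg) {
    ex <- as.numeric(expression[expression$gene_id == reg, samples][1, ])
    ok <- !is.na(ex) & !is.na(psi_vec)
    n <- sum(ok)
    if (n < 3 || sd(ex[ok]) == 0 || sd(psi_vec[ok]) == 0) {
      return(tibble(regulator_id = reg, r = NA_real_, r_squared = NA_real_,
                    p = NA_real_, n_used = n))
    }
    ct <- cor.test(ex[ok], psi_vec[ok], method = "pearson")
    tibble(regulator_id = reg, r = unname(ct$estimate),
           r_squared = unname(ct$estimate)^2, p = ct$p.value, n_used = n)
  }) |> list_rbind()
  if (is.null(res) || nrow(res) == 0) {
    return(tibble(regulator_id = character(0), r = numeric(0),
                  r_squared = numeric(0), p = numeric(0), n_used = integer(0)))
  }
  res |> arrange(.data$p, desc(abs(.data$r)))
}

#' Scan sequences for exact occurrences of a nucleotide motif
#'
#' All (possibly overlapping) exact matches of the motif on the given (mRNA
#' sense) strand are located; no IUPAC degeneracy is applied. Positions are
#' 0-based offsets within each sequence.
#'
#' @param sequences Named character vector (id -> sequence over `A C G T N`),
#'   or a tibble with `id`/`sequence` columns.
#' @param motif Motif string (default `"GGAA"`).
#' @return Tibble: `id`, `n_hits`, `positions` (list-column of 0-based
#'   integer offsets), `present`.
#' @export
scan_motif <- function(sequences, motif = "GGAA") {
  if (is.data.frame(sequences)) {
    assert_cols(sequences, c("id", "sequence"))
    sequences <- setNames(sequences$sequence, sequences$id)
  }
  if (!nzchar(motif)) stop_sp("motif must be non-empty")
  if (length(sequences) == 0) {
    return(tibble(id = character(0), n_hits = integer(0),
                  positions = list(), present = logical(0)))
  }
  ids <- names(sequences) %||% paste0("seq_", seq_along(sequences))
  pat <- Biostrings::DNAString(motif)
  hits <- map(unname(sequences), function(s) {
    m <- Biostrings::matchPattern(pat, Biostrings::DNAString(s))
    as.integer(Biostrings::start(m) - 1L)
  })
  tibble(id = ids,
         n_hits = map_int(hits, length),
         positions = hits,
         present = map_int(hits, length) > 0)
}

#' Gene-level motif-presence fraction
#'
#' The percentage of scanned ids containing at least one motif occurrence,
#' reported to one decimal place (e.g. 115 of 327 -> 35.2).
#'
#' @param hits Output of [scan_motif()].
#' @return A single number (percent, one decimal), `NA` for an empty scan.
#' @export
motif_summary <- function(hits) {
  if (nrow(hits) == 0) return(NA_real_)
  round(100 * mean(hits$present), 1)
}

#' Filter TF ChIP sites by promoter window and score
#'
#' Retains sites whose strand-aware offset from the target gene's
#' transcription start site lies inside the window (boundaries inclusive)
#' and whose ChIP score strictly exceeds `min_score`. For minus-strand genes
#' upstream offsets correspond to numerically greater coordinates, so the
#' offset is `tss - position`.
#'
#' @param sites Tibble: `tf_name`, `chrom`, `position`, `chip_score`,
#'   `target_gene` (an `offset_from_tss` column, if present, is recomputed).
#' @param tss_table Tibble: `gene_id`, `chrom`, `strand`, `tss`.
#' @param window Inclusive window, default `c(-2500, 500)` (negative =
#'   upstream).
#' @param min_score Strict lower bound on the ChIP score (default 50; a site
#'   scoring exactly 50 is dropped).
#' @return The retained subset with `offset_from_tss` added. Sites whose
#'   target gene has no TSS entry are dropped with a warning.
#' @export
filter_tf_sites <- function(sites, tss_table, window = c(-2500, 500),
                            min_score = 50) {
  assert_cols(sites, c("tf_name", "chrom", "position", "chip_score", "target_gene"))
  assert_cols(tss_table, c("gene_id", "strand", "tss"))
  sites$offset_from_tss <- NULL
  merged <- sites |>
    left_join(tss_table |> select("gene_id", tss_strand = "strand", "tss"),
              by = c(target_gene = "gene_id"))
  no_tss <- is.na(merged$tss)
  if (any(no_tss)) {
    warn(paste0("dropping ", sum(no_tss), " site(s) whose target gene has no TSS entry"))
    merged <- merged[!no_tss, , drop = FALSE]
  }
  merged |>
    mutate(offset_from_tss = ifelse(.data$tss_strand == "+",
                                    .data$position - .data$tss,
                                    .data$tss - .data$position)) |>
    filter(.data$offset_from_tss >= window[1],
           .data$offset_from_tss <= window[2],
           .data$chip_score > min_score) |>
    select(-"tss", -"tss_strand")
}

#' Rank transcription-factor candidates by expression correlation
#'
#' For each TF with at least one retained promoter site, the Pearson
#' correlation between TF expression and target-gene expression is computed
#' in every supplied cohort. TFs are ranked by worst-case (maximum) p across
#' cohorts, ties by minimum |r| descending; `significant_all_cohorts` flags
#' TFs with p < `alpha` in every cohort (intersection rule).
#'
#' @param retained_sites Output of [filter_tf_sites()].
#' @param expression A wide expression tibble or a (possibly named) list of
#'   them, one per cohort.
#' @param target_gene Target gene id (must be present in every cohort).
#' @param alpha Per-cohort significance threshold (default 0.05).
#' @return Tibble: `tf_name`, per-cohort `r_*`/`p_*` columns, `p_max`,
#'   `abs_r_min`, `significant_all_cohorts`, ranked.
#' @export
rank_tf_candidates <- function(retained_sites, expression, target_gene,
                               alpha = 0.05) {
  if (nrow(retained_sites) == 0) stop_sp("no retained TF sites to rank")
  cohorts <- if (is.data.frame(expression)) list(cohort1 = expression) else expression
  if (is.null(names(cohorts)) || any(!nzchar(names(cohorts)))) {
    names(cohorts) <- paste0("cohort", seq_along(cohorts))
  }
  tfs <- unique(retained_sites$tf_name)
  per_cohort <- imap(cohorts, function(ex, nm) {
    assert_cols(ex, "gene_id")
    if (!target_gene %in% ex$gene_id) {
      stop_sp("target gene '", target_gene, "' absent from cohort '", nm, "'")
    }
    samples <- setdiff(names(ex), "gene_id")
    target <- tibble(sample_id = samples,
                     psi = as.numeric(ex[ex$gene_id == target_gene, samples][1, ]))
    correlate_regulators(ex, target, tfs) |>
      select("regulator_id", "r", "p") |>
      rename(tf_name = "regulator_id") |>
      rename_with(function(x) paste0(x, "_", nm), c("r", "p"))
  })
  out <- purrr::reduce(per_cohort, full_join, by = "tf_name")
  p_cols <- grep("^p_", names(out), value = TRUE)
  r_cols <- grep("^r_", names(out), value = TRUE)
  pm <- as.matrix(out[, p_cols, drop = FALSE])
  rm_ <- abs(as.matrix(out[, r_cols, drop = FALSE]))
  out$p_max <- apply(pm, 1, function(x) if (all(is.na(x))) NA_real_ else max(x, na.rm = FALSE))
  out$abs_r_min <- apply(rm_, 1, function(x) if (all(is.na(x))) NA_real_ else min(x, na.rm = FALSE))
  out$significant_all_cohorts <- apply(pm < alpha, 1, function(x) all(!is.na(x) & x))
  out |> arrange(.data$p_max, desc(.data$abs_r_min))
}

#' Read a regulator id list (one id per line)
#'
#' @param path Text file path.
#' @return Character vector of ids (blank lines and `#` comments dropped).
#' @export
read_regulator_list <- function(path) {
  x <- trimws(readr::read_lines(path))
  x[nzchar(x) & !startsWith(x, "#")]
}
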