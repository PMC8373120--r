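#' Read transcript models from a GTF annotation
#'
#' Parses a GTF file (ensembl-style `gene_id`/`transcript_id` attributes) and
#' assembles one transcript model per transcript. Coordinates are converted
#' from GTF's 1-based inclusive convention to the package-internal 0-based
#' half-open convention, so that interval length is always `end - start`.
#'
#' @param path Path to a GTF file. `exon` features are required; `CDS`
#'   features, when present, populate the coding intervals used for the
#'   coding-region flag of splicing events.
#' @return A tibble with one row per transcript: `gene_id`, `transcript_id`,
#'   `chrom`, `strand`, `n_exons`, and list-columns `exons` and `cds`, each a
#'   tibble of 0-based half-open `start`/`end` intervals sorted by start.
#'   Transcripts with zero exon features are skipped with a warning.
#' @export
read_gtf_models <- function(path) {
  gr <- tryCatch(
    rtracklayer::import(path, format = "gtf"),
    error = function(e) stop_sp("failed to parse GTF '", path, "': ", conditionMessage(e))
  )
  df <- as_tibble(as.data.frame(gr))
  assert_cols(df, c("type", "gene_id", "transcript_id"), "GTF")
  feats <- df |>
    filter(.data$type %in% c("exon", "CDS"), !is.na(.data$transcript_id)) |>
    transmute(
      gene_id = .data$gene_id,
      transcript_id = .data$transcript_id,
      chrom = as.character(.data$seqnames),
      strand = as.character(.data$strand),
      type = as.character(.data$type),
      start = .data$start - 1L,  # to 0-based half-open
      end = .data$end
    )
  gtf_models(feats)
}

# assemble nested transcript models from a flat exon/CDS feature tibble
gtf_models <- function(feats) {
  empty_iv <- tibble(start = integer(0), end = integer(0))
  models <- feats |>
    group_by(.data$gene_id, .data$transcript_id, .data$chrom, .data$strand) |>
    summarise(
      exons = list(pick_intervals(.data$type, .data$start, .data$end, "exon")),
      cds = list(pick_intervals(.data$type, .data$start, .data$end, "CDS")),
      .groups = "drop"
    ) |>
    mutate(n_exons = map_int(.data$exons, nrow)) |>
    select("gene_id", "transcript_id", "chrom", "strand", "n_exons", "exons", "cds")
  no_exon <- models$n_exons == 0L
  if (any(no_exon)) {
    warn(paste0("skipping ", sum(no_exon), " transcript(s) with zero exons: ",
                paste(head(models$transcript_id[no_exon], 5), collapse = ", ")))
    models <- models[!no_exon, , drop = FALSE]
  }
  validate_models(models)
  models
}

pick_intervals <- function(type, start, end, which) {
  keep <- type == which
  iv <- tibble(start = as.integer(start[keep]), end = as.integer(end[keep]))
  iv[order(iv$start), , drop = FALSE]
}

validate_models <- function(models) {
  for (i in seq_len(nrow(models))) {
    ex <- models$exons[[i]]
    if (any(ex$end <= ex$start)) {
      stop_sp("transcript ", models$transcript_id[i], " has an empty/inverted exon")
    }
    if (nrow(ex) > 1 && any(ex$start[-1] < ex$end[-nrow(ex)])) {
      stop_sp("transcript ", models$transcript_id[i], " has overlapping exons")
    }
  }
  invisible(models)
}

#' Write transcript models as GTF
#'
#' Inverse of [read_gtf_models()]: emits `exon` (and `CDS`, when present)
#' features in 1-based inclusive GTF coordinates.
#'
#' @param models Transcript-model tibble as returned by [read_gtf_models()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(models, path) {
  lines <- character(0)
  for (i in seq_len(nrow(models))) {
    attrs <- sprintf('gene_id "%s"; transcript_id "%s";',
                     models$gene_id[i], models$transcript_id[i])
    fmt <- function(iv, type) {
      if (nrow(iv) == 0) return(character(0))
      sprintf("%s\tspliceprio\t%s\t%d\t%d\t.\t%s\t.\t%s",
              models$chrom[i], type, iv$start + 1L, iv$end,
              models$strand[i], attrs)
    }
    lines <- c(lines, fmt(models$exons[[i]], "exon"), fmt(models$cds[[i]], "CDS"))
  }
  writeLines(lines, path)
  invisible(path)
}
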