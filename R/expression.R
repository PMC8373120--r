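#' Transcripts-per-million (TPM) normalization
#'
#' \deqn{TPM_{gs} = 10^6 \cdot \frac{c_{gs}/\ell_g}{\sum_{g'} c_{g's}/\ell_{g'}}}
#' with \eqn{\ell_g} the gene's effective length in kilobases. Columns of the
#' result each sum to 1e6.
#'
#' @param counts Wide tibble of raw counts: a `gene_id` column plus one
#'   numeric column per sample.
#' @param gene_lengths Tibble `gene_id`, `length` (bp, > 0); every gene in
#'   `counts` must be present.
#' @return Tibble of the same shape holding TPM values.
#' @export
compute_tpm <- function(counts, gene_lengths) {
  assert_cols(counts, "gene_id")
  assert_cols(gene_lengths, c("gene_id", "length"))
  missing <- setdiff(counts$gene_id, gene_lengths$gene_id)
  if (length(missing) > 0) {
    stop_sp("gene length missing for: ", paste(head(missing, 5), collapse = ", "))
  }
  len <- gene_lengths$length[match(counts$gene_id, gene_lengths$gene_id)]
  if (any(len <= 0)) stop_sp("gene lengths must be positive")
  sample_cols <- setdiff(names(counts), "gene_id")
  out <- counts
  for (s in sample_cols) {
    rate <- counts[[s]] / (len / 1000)
    denom <- sum(rate)
    if (denom == 0) stop_sp("sample '", s, "' has zero total counts")
    out[[s]] <- rate / denom * 1e6
  }
  out
}

#' Remove genes with low mean expression
#'
#' Drops genes whose mean TPM across all samples is below `threshold`
#' (strictly: mean < threshold removed, so a gene at exactly the threshold is
#' retained). The retained rows are *not* renormalized; call [compute_tpm()]
#' on the retained counts if a renormalized TPM table is wanted.
#'
#' @param tpm Wide TPM tibble (`gene_id` + sample columns).
#' @param threshold Mean-TPM cutoff (default 2).
#' @return The filtered tibble.
#' @export
filter_low_expression <- function(tpm, threshold = 2) {
  assert_cols(tpm, "gene_id")
  sample_cols <- setdiff(names(tpm), "gene_id")
  if (nrow(tpm) == 0 || length(sample_cols) == 0) return(tpm)
  means <- rowMeans(as.matrix(tpm[, sample_cols, drop = FALSE]))
  tpm[means >= threshold, , drop = FALSE]
}

#' Immunohistochemistry staining score
#'
#' Score = staining intensity (integer grade 0--3) times the percentage of
#' stained cells (0--100), giving a 0--300 scale.
#'
#' @param intensity Integer vector in `{0,1,2,3}`.
#' @param percent_stained Numeric vector in `[0, 100]`.
#' @param sample_id Optional sample labels.
#' @return Tibble: `sample_id`, `intensity`, `percent_stained`, `score`.
#' @export
ihc_score <- function(intensity, percent_stained,
                      sample_id = paste0("sample_", seq_along(intensity))) {
  if (!all(intensity %in% 0:3)) stop_sp("intensity must be an integer in 0..3")
  if (any(percent_stained < 0 | percent_stained > 100)) {
    stop_sp("percent_stained must lie in [0, 100]")
  }
  tibble(sample_id = sample_id,
         intensity = as.integer(intensity),
         percent_stained = as.numeric(percent_stained),
         score = as.integer(intensity) * as.numeric(percent_stained))
}
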