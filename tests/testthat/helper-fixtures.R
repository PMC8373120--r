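# fixture builders shared across test files

# transcript-model tibble from a list of exon matrices (0-based half-open)
make_models <- function(exon_sets, gene_id = "g1", chrom = "chr1", strand = "+",
                        cds_sets = NULL) {
  tibble::tibble(
    gene_id = gene_id,
    transcript_id = paste0(gene_id, ".t", seq_along(exon_sets)),
    chrom = chrom, strand = strand,
    n_exons = vapply(exon_sets, nrow, integer(1)),
    exons = lapply(exon_sets, function(m) {
      tibble::tibble(start = as.integer(m[, 1]), end = as.integer(m[, 2]))
    }),
    cds = if (is.null(cds_sets)) {
      rep(list(tibble::tibble(start = integer(0), end = integer(0))),
          length(exon_sets))
    } else {
      lapply(cds_sets, function(m) {
        tibble::tibble(start = as.integer(m[, 1]), end = as.integer(m[, 2]))
      })
    }
  )
}

exons <- function(...) matrix(c(...), ncol = 2, byrow = TRUE)

# one-row cassette event tibble with explicit junctions
make_cassette_event <- function(event_id = "ev1", chrom = "chr1",
                                up_donor = 100L, alt_start = 200L,
                                alt_end = 260L, down_acceptor = 400L,
                                strand = "+", gene_id = "g1", in_cds = TRUE) {
  tibble::tibble(
    event_id = event_id, event_type = "CASSETTE", gene_id = gene_id,
    chrom = chrom, strand = strand,
    alt_start = alt_start, alt_end = alt_end,
    alt_length = alt_end - alt_start, in_cds = in_cds,
    inclusion_junctions = list(tibble::tibble(
      donor = c(up_donor, alt_end), acceptor = c(alt_start, down_acceptor))),
    exclusion_junctions = list(tibble::tibble(
      donor = up_donor, acceptor = down_acceptor))
  )
}

# junction-count rows for one sample
jc_rows <- function(sample_id, chrom, donor, acceptor, count) {
  tibble::tibble(sample_id = sample_id, chrom = chrom, donor = donor,
                 acceptor = acceptor, strand = "*", count = count)
}

# a SAM line with the minimal fields extract_junctions() needs
sam_line <- function(rname, pos1, cigar, flag = 0L, qname = "r1") {
  paste(qname, flag, rname, pos1, 255, cigar, "*", 0, 0, "*", "*", sep = "\t")
}

# GTF text for a set of models (1-based inclusive), returned as a temp file
gtf_file <- function(models) {
  path <- withr::local_tempfile(fileext = ".gtf", .local_envir = parent.frame())
  spliceprio::write_gtf(models, path)
  path
}

# random gene structures over a fixed exon grid, with boundary variants,
# for event-enumeration property tests
random_gene_models <- function(gene_id = "g1", max_tx = 4) {
  base_starts <- c(100L, 400L, 700L, 1000L, 1300L, 1600L)
  base <- cbind(base_starts, base_starts + 150L)
  n_tx <- sample(2:max_tx, 1)
  sets <- lapply(seq_len(n_tx), function(t) {
    k <- sample(2:6, 1)
    idx <- sort(sample(6, k))
    m <- base[idx, , drop = FALSE]
    if (nrow(m) >= 2 && stats::runif(1) < 0.4) {
      kind <- sample(3, 1)
      if (kind == 1) {            # extend an exon end into the intron (A5SS-like)
        i <- sample(nrow(m) - 1, 1)
        m[i, 2] <- m[i, 2] + 50L
      } else if (kind == 2) {     # shift an exon start upstream (A3SS-like)
        i <- sample(2:nrow(m), 1)
        m[i, 1] <- m[i, 1] - 50L
      } else {                    # merge two adjacent exons (retained intron)
        i <- sample(nrow(m) - 1, 1)
        m <- rbind(m[seq_len(i - 1), , drop = FALSE],
                   c(m[i, 1], m[i + 1, 2]),
                   m[seq_len(nrow(m))[-seq_len(i + 1)], , drop = FALSE])
      }
    }
    m
  })
  make_models(sets, gene_id = gene_id,
              strand = sample(c("+", "-"), 1))
}

event_signatures <- function(events) {
  sort(paste(events$event_type, events$chrom, events$strand,
             events$alt_start, events$alt_end,
             vapply(events$exclusion_junctions,
                    function(j) paste(paste0(j$donor, "-", j$acceptor), collapse = ";"),
                    character(1)),
             sep = "|"))
}
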