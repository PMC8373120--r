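#' Enumerate and classify alternative-splicing events
#'
#' Compares transcript structures pairwise within each gene and emits a
#' deduplicated catalog of alternative-splicing events, classified into the
#' five standard categories: cassette exon (`CASSETTE`), mutually exclusive
#' exons (`MXE`), alternative 5'/3' splice site (`A5SS`/`A3SS`) and retained
#' intron (`RI`). The catalog is annotation-driven; novel junctions present
#' only in reads are not discovered.
#'
#' Event definitions follow standard usage: a cassette exon is present in one
#' transcript and absent in another whose flanking exons are joined by a
#' single junction; MXE requires two non-overlapping internal exons sharing
#' both flanking junction anchors that are never co-present in any transcript
#' of the gene; A5SS/A3SS share one junction boundary and differ in the
#' other, typed strand-aware by which splice site (donor or acceptor) moves;
#' RI is an intron of one transcript fully contained in an exon of another.
#'
#' For MXE the single `alt_segment` interval is the upstream (smaller-start)
#' alternative exon; its two junctions are the inclusion set and the
#' downstream exon's two junctions the exclusion set. RI events carry an
#' empty inclusion-junction set: retention has no junction evidence, so RI
#' events are catalogued but not quantifiable from junction counts.
#'
#' @param models Transcript-model tibble from [read_gtf_models()].
#' @return A tibble with one row per event: `event_id`, `event_type`,
#'   `gene_id`, `chrom`, `strand`, `alt_start`, `alt_end`, `alt_length`,
#'   `in_cds`, and list-columns `inclusion_junctions`/`exclusion_junctions`
#'   (tibbles of 0-based `donor`, `acceptor`). Duplicated events arising from
#'   multiple transcript pairs are merged on
#'   (type, chrom, strand, alt segment, exclusion junctions).
#' @export
enumerate_events <- function(models) {
  assert_cols(models, c("gene_id", "transcript_id", "chrom", "strand", "exons", "cds"))
  out <- models |>
    group_by(.data$gene_id) |>
    group_split() |>
    map(enumerate_gene_events) |>
    list_rbind()
  if (nrow(out) == 0) return(empty_event_catalog())
  # deduplicate: same type/position/exclusion-junction events from different pairs
  out <- out |>
    mutate(.key = paste(.data$event_type, .data$chrom, .data$strand,
                        .data$alt_start, .data$alt_end,
                        map_chr(.data$exclusion_junctions, junctions_to_string),
                        sep = "|")) |>
    distinct(.data$.key, .keep_all = TRUE) |>
    select(-".key") |>
    arrange(.data$chrom, .data$alt_start, .data$event_type)
  out$event_id <- sprintf("%s_%s_%s_%d_%d",
                          out$event_type, out$gene_id, out$chrom,
                          out$alt_start, out$alt_end)
  out$event_id <- make.unique(out$event_id, sep = "_v")
  out |>
    select("event_id", "event_type", "gene_id", "chrom", "strand",
           "alt_start", "alt_end", "alt_length", "in_cds",
           "inclusion_junctions", "exclusion_junctions")
}

empty_event_catalog <- function() {
  tibble(
    event_id = character(0), event_type = character(0), gene_id = character(0),
    chrom = character(0), strand = character(0),
    alt_start = integer(0), alt_end = integer(0), alt_length = integer(0),
    in_cds = logical(0),
    inclusion_junctions = list(), exclusion_junctions = list()
  )
}

# all events for one gene: pairwise comparison of its transcripts
enumerate_gene_events <- function(gene_models) {
  n <- nrow(gene_models)
  if (n < 2) return(empty_event_catalog())
  junc_of <- function(ex) {
    if (nrow(ex) < 2) return(tibble(donor = integer(0), acceptor = integer(0)))
    tibble(donor = ex$end[-nrow(ex)], acceptor = ex$start[-1])
  }
  exons <- gene_models$exons
  juncs <- map(exons, junc_of)
  found <- list()
  add <- function(type, alt, inc, exc) {
    found[[length(found) + 1]] <<- tibble(
      event_type = type, gene_id = gene_models$gene_id[1],
      chrom = gene_models$chrom[1], strand = gene_models$strand[1],
      alt_start = as.integer(alt[1]), alt_end = as.integer(alt[2]),
      alt_length = as.integer(alt[2] - alt[1]),
      in_cds = NA,
      inclusion_junctions = list(inc), exclusion_junctions = list(exc)
    )
  }
  has_junction <- function(j, donor, acceptor) {
    any(j$donor == donor & j$acceptor == acceptor)
  }
  overlaps_exon <- function(ex, s, e) any(ex$start < e & ex$end > s)
  has_exact_exon <- function(ex, s, e) any(ex$start == s & ex$end == e)

  for (a in seq_len(n)) for (b in seq_len(n)) {
    if (a == b) next
    exA <- exons[[a]]; exB <- exons[[b]]
    jA <- juncs[[a]]; jB <- juncs[[b]]

    # cassette: internal exon i of A skipped in B
    if (nrow(exA) >= 3) {
      for (i in 2:(nrow(exA) - 1)) {
        up_d <- exA$end[i - 1]; alt_s <- exA$start[i]
        alt_e <- exA$end[i]; down_a <- exA$start[i + 1]
        if (has_junction(jB, up_d, down_a) &&
            !overlaps_exon(exB, alt_s, alt_e)) {
          add("CASSETTE", c(alt_s, alt_e),
              inc = tibble(donor = c(up_d, alt_e), acceptor = c(alt_s, down_a)),
              exc = tibble(donor = up_d, acceptor = down_a))
        }
      }
    }

    # MXE: internal exon i of A and internal exon k of B, shared flank anchors,
    # non-overlapping, never co-present in any transcript of the gene
    if (nrow(exA) >= 3 && nrow(exB) >= 3) {
      for (i in 2:(nrow(exA) - 1)) for (k in 2:(nrow(exB) - 1)) {
        e2 <- c(exA$start[i], exA$end[i]); e3 <- c(exB$start[k], exB$end[k])
        if (e2[1] < e3[2] && e3[1] < e2[2]) next           # overlapping
        if (!(exA$end[i - 1] == exB$end[k - 1] &&
              exA$start[i + 1] == exB$start[k + 1])) next  # flank anchors differ
        co_present <- any(map_lgl(exons, function(ex) {
          has_exact_exon(ex, e2[1], e2[2]) && has_exact_exon(ex, e3[1], e3[2])
        }))
        if (co_present) next
        if (overlaps_exon(exB, e2[1], e2[2]) || overlaps_exon(exA, e3[1], e3[2])) next
        first <- if (e2[1] <= e3[1]) list(e2, exA, i) else list(e3, exB, k)
        second <- if (e2[1] <= e3[1]) list(e3, exB, k) else list(e2, exA, i)
        jn <- function(ex, i) tibble(donor = c(ex$end[i - 1], ex$end[i]),
                                     acceptor = c(ex$start[i], ex$start[i + 1]))
        add("MXE", first[[1]],
            inc = jn(first[[2]], first[[3]]),
            exc = jn(second[[2]], second[[3]]))
      }
    }

    # A5SS / A3SS: junctions sharing one boundary
    if (nrow(jA) > 0 && nrow(jB) > 0) {
      for (i in seq_len(nrow(jA))) {
        dA <- jA$donor[i]; aA <- jA$acceptor[i]
        # shared acceptor, different donor-side boundary (exon end moves)
        kk <- which(jB$acceptor == aA & jB$donor != dA)
        for (k in kk) {
          dB <- jB$donor[k]
          exa <- exA[exA$end == dA, , drop = FALSE]
          exb <- exB[exB$end == dB, , drop = FALSE]
          if (nrow(exa) == 0 || nrow(exb) == 0) next
          # the two alternative forms must be versions of the same exon
          if (!(exa$start[1] < min(dA, dB) && exb$start[1] < min(dA, dB))) next
          alt <- c(min(dA, dB), max(dA, dB))
          type <- if (gene_models$strand[1] == "+") "A5SS" else "A3SS"
          add(type, alt,
              inc = tibble(donor = max(dA, dB), acceptor = aA),
              exc = tibble(donor = min(dA, dB), acceptor = aA))
        }
        # shared donor, different acceptor-side boundary (exon start moves)
        kk <- which(jB$donor == dA & jB$acceptor != aA)
        for (k in kk) {
          aB <- jB$acceptor[k]
          exa <- exA[exA$start == aA, , drop = FALSE]
          exb <- exB[exB$start == aB, , drop = FALSE]
          if (nrow(exa) == 0 || nrow(exb) == 0) next
          if (!(exa$end[1] > max(aA, aB) && exb$end[1] > max(aA, aB))) next
          alt <- c(min(aA, aB), max(aA, aB))
          type <- if (gene_models$strand[1] == "+") "A3SS" else "A5SS"
          add(type, alt,
              inc = tibble(donor = dA, acceptor = min(aA, aB)),
              exc = tibble(donor = dA, acceptor = max(aA, aB)))
        }
      }
    }

    # RI: intron of A contained in an exon of B
    if (nrow(jA) > 0) {
      for (i in seq_len(nrow(jA))) {
        d <- jA$donor[i]; acc <- jA$acceptor[i]
        if (any(exB$start <= d & exB$end >= acc)) {
          add("RI", c(d, acc),
              inc = tibble(donor = integer(0), acceptor = integer(0)),
              exc = tibble(donor = d, acceptor = acc))
        }
      }
    }
  }

  if (length(found) == 0) return(empty_event_catalog())
  ev <- list_rbind(found)
  # coding flag: alt segment overlaps a CDS interval of any transcript whose
  # exon fully covers the segment (an inclusion-form transcript)
  ev$in_cds <- map_lgl(seq_len(nrow(ev)), function(i) {
    s <- ev$alt_start[i]; e <- ev$alt_end[i]
    any(map_lgl(seq_len(nrow(gene_models)), function(t) {
      ex <- gene_models$exons[[t]]
      if (!any(ex$start <= s & ex$end >= e)) return(FALSE)
      cd <- gene_models$cds[[t]]
      nrow(cd) > 0 && any(cd$start < e & cd$end > s)
    }))
  })
  ev$event_id <- NA_character_
  ev[, c("event_id", names(ev)[names(ev) != "event_id"])]
}

#' Extract alternative-segment sequences for a set of events
#'
#' Slices the genomic sequence of each event's alternative segment, reverse
#' complementing minus-strand events so the returned sequence is the mRNA
#' sense strand (the sequence a motif scanner should see).
#'
#' @param events Event catalog from [enumerate_events()].
#' @param genome Either a path to a FASTA file or a named character vector /
#'   `Biostrings::DNAStringSet` of contig sequences.
#' @return Named character vector, `event_id` -> alternative-segment sequence;
#'   each sequence's width equals the event's `alt_length`.
#' @export
event_sequences <- function(events, genome) {
  seqs <- load_genome(genome)
  vapply(seq_len(nrow(events)), function(i) {
    chrom <- events$chrom[i]
    if (!chrom %in% names(seqs)) {
      stop_sp("chromosome '", chrom, "' absent from the supplied genome")
    }
    contig <- seqs[[chrom]]
    s <- events$alt_start[i]; e <- events$alt_end[i]
    if (e > nchar(contig)) {
      stop_sp("event ", events$event_id[i], " extends beyond the end of '", chrom, "'")
    }
    seg <- substr(contig, s + 1L, e)  # 0-based half-open -> substr
    if (events$strand[i] == "-") revcomp(seg) else seg
  }, character(1)) |>
    setNames(events$event_id)
}

load_genome <- function(genome) {
  if (methods::is(genome, "DNAStringSet")) {
    return(setNames(as.character(genome), names(genome)))
  }
  if (is.character(genome) && length(genome) == 1 && file.exists(genome)) {
    ss <- Biostrings::readDNAStringSet(genome)
    names(ss) <- sub("\\s.*$", "", names(ss))
    return(setNames(as.character(ss), names(ss)))
  }
  if (is.character(genome) && !is.null(names(genome))) return(genome)
  stop_sp("genome must be a FASTA path, a named character vector, or a DNAStringSet")
}

#' Write / read an event catalog as TSV
#'
#' Junction sets are serialized as semicolon-joined `donor-acceptor` pairs.
#'
#' @param events Event catalog tibble.
#' @param path File path.
#' @return `write_event_catalog()` returns `path` invisibly;
#'   `read_event_catalog()` returns the catalog tibble.
#' @export
write_event_catalog <- function(events, path) {
  flat <- events |>
    mutate(
      inclusion_junctions = map_chr(.data$inclusion_junctions, junctions_to_string),
      exclusion_junctions = map_chr(.data$exclusion_junctions, junctions_to_string)
    )
  readr::write_tsv(flat, path)
  invisible(path)
}

#' @rdname write_event_catalog
#' @export
read_event_catalog <- function(path) {
  flat <- readr::read_tsv(path, show_col_types = FALSE,
                          col_types = readr::cols(
                            inclusion_junctions = readr::col_character(),
                            exclusion_junctions = readr::col_character()
                          ))
  flat |>
    mutate(
      inclusion_junctions = map(.data$inclusion_junctions,
                                function(s) string_to_junctions(s %||% NA_character_)),
      exclusion_junctions = map(.data$exclusion_junctions,
                                function(s) string_to_junctions(s %||% NA_character_))
    )
}
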