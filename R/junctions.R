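#' Extract splice junctions from spliced alignments
#'
#' Walks each alignment's CIGAR string and emits one junction per `N`
#' operation: the donor is the 0-based reference position immediately after
#' the last aligned base before the gap, the acceptor the position where
#' alignment resumes (half-open, matching the package's exon coordinates).
#' A junction is kept only if the alignment covers at least `min_overhang`
#' reference bases on both sides of the gap (within the same read, between
#' neighbouring `N` gaps). Supported CIGAR operations: `M I D N S H = X`.
#'
#' Only the FLAG, RNAME, POS and CIGAR fields are consumed; headerless SAM
#' text is accepted. Unmapped records (FLAG 0x4 or RNAME `*`) contribute
#' nothing; records whose CIGAR cannot be parsed are skipped and tallied.
#'
#' @param sam Path to a SAM file, or a character vector of SAM lines.
#' @param min_overhang Minimum aligned reference bases required on each side
#'   of a junction (default 6).
#' @param sample_id Sample label attached to the output (default `"sample"`).
#' @return A tibble of junction counts: `sample_id`, `chrom`, `donor`,
#'   `acceptor`, `strand` (always `"*"`: minimal records carry no
#'   transcription strand), `count`. The number of skipped records is
#'   attached as attribute `"skipped_records"`.
#' @export
extract_junctions <- function(sam, min_overhang = 6L, sample_id = "sample") {
  lines <- if (length(sam) == 1 && !grepl("\t", sam) && file.exists(sam)) {
    readr::read_lines(sam)
  } else {
    sam
  }
  lines <- lines[!startsWith(lines, "@") & nzchar(lines)]
  skipped <- 0L
  if (length(lines) == 0) {
    out <- tibble(sample_id = character(0), chrom = character(0),
                  donor = integer(0), acceptor = integer(0),
                  strand = character(0), count = integer(0))
    attr(out, "skipped_records") <- skipped
    return(out)
  }
  fields <- str_split(lines, "\t")
  recs <- map(fields, function(f) {
    if (length(f) < 6) return(NULL)
    flag <- suppressWarnings(as.integer(f[2]))
    pos <- suppressWarnings(as.integer(f[4]))
    if (is.na(flag) || is.na(pos)) return(NULL)
    list(flag = flag, rname = f[3], pos = pos, cigar = f[6])
  })
  bad <- map_lgl(recs, is.null)
  skipped <- skipped + sum(bad)
  recs <- recs[!bad]

  res <- map(recs, function(r) {
    if (bitwAnd(r$flag, 4L) != 0L || r$rname == "*" || r$cigar == "*") return(NULL)
    j <- cigar_junctions(r$cigar, r$pos - 1L, min_overhang)
    if (is.null(j)) return(NA)  # unparseable CIGAR
    if (nrow(j) == 0) return(NULL)
    j$chrom <- r$rname
    j
  })
  unparseable <- map_lgl(res, function(x) length(x) == 1 && is.logical(x) && is.na(x))
  skipped <- skipped + sum(unparseable)
  juncs <- list_rbind(res[!unparseable & !map_lgl(res, is.null)])

  if (is.null(juncs) || nrow(juncs) == 0) {
    out <- tibble(sample_id = character(0), chrom = character(0),
                  donor = integer(0), acceptor = integer(0),
                  strand = character(0), count = integer(0))
  } else {
    out <- juncs |>
      count(.data$chrom, .data$donor, .data$acceptor, name = "count") |>
      mutate(sample_id = sample_id, strand = "*") |>
      select("sample_id", "chrom", "donor", "acceptor", "strand", "count")
  }
  attr(out, "skipped_records") <- skipped
  out
}

# junctions implied by one CIGAR string; pos0 is the 0-based leftmost
# reference position. Returns NULL if the CIGAR is malformed.
cigar_junctions <- function(cigar, pos0, min_overhang) {
  m <- gregexpr("(\\d+)([MIDNSHP=X])", cigar)[[1]]
  if (m[1] == -1) return(NULL)
  toks <- regmatches(cigar, gregexpr("(\\d+)([MIDNSHP=X])", cigar))[[1]]
  if (sum(nchar(toks)) != nchar(cigar)) return(NULL)  # leftover characters
  lens <- as.integer(substr(toks, 1, nchar(toks) - 1))
  ops <- substr(toks, nchar(toks), nchar(toks))
  ref_pos <- pos0
  seg_aligned <- 0L        # aligned ref bases since read start / last N
  segs <- integer(0)       # aligned block lengths between gaps
  gaps <- list()           # (donor, acceptor)
  for (i in seq_along(ops)) {
    op <- ops[i]; len <- lens[i]
    if (op %in% c("M", "=", "X")) {
      ref_pos <- ref_pos + len; seg_aligned <- seg_aligned + len
    } else if (op == "D") {
      ref_pos <- ref_pos + len  # consumes reference, but adds no aligned bases
    } else if (op == "N") {
      gaps[[length(gaps) + 1]] <- c(ref_pos, ref_pos + len)
      segs <- c(segs, seg_aligned)
      seg_aligned <- 0L
      ref_pos <- ref_pos + len
    }
    # I, S, H, P consume no reference
  }
  segs <- c(segs, seg_aligned)
  if (length(gaps) == 0) {
    return(tibble(donor = integer(0), acceptor = integer(0)))
  }
  keep <- vapply(seq_along(gaps), function(k) {
    segs[k] >= min_overhang && segs[k + 1] >= min_overhang
  }, logical(1))
  g <- gaps[keep]
  tibble(donor = vapply(g, `[`, integer(1), 1L),
         acceptor = vapply(g, `[`, integer(1), 2L))
}

#' Read / write a junction-count table
#'
#' TSV columns: `chrom`, `donor`, `acceptor`, `strand`, `count`, `sample`.
#'
#' @param path File path.
#' @param junctions Junction-count tibble
#'   (`sample_id, chrom, donor, acceptor, strand, count`).
#' @return A junction-count tibble / `path` invisibly.
#' @export
read_junction_counts <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE) |>
    rename(sample_id = "sample") |>
    select("sample_id", "chrom", "donor", "acceptor", "strand", "count")
}

#' @rdname read_junction_counts
#' @export
write_junction_counts <- function(junctions, path) {
  junctions |>
    select("chrom", "donor", "acceptor", "strand", "count", sample = "sample_id") |>
    readr::write_tsv(path)
  invisible(path)
}
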