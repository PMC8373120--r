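clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' @noRd
stop_sp <- function(...) abort(paste0(...), class = "spliceprio_error")

assert_cols <- function(df, cols, what = deparse(substitute(df))) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    stop_sp(what, " is missing required column(s): ",
            paste(missing, collapse = ", "))
  }
  invisible(df)
}

# reverse complement for plain character vectors (delegates to Biostrings)
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# join a tibble of junctions (donor, acceptor) into "donor-acceptor;..."
junctions_to_string <- function(j) {
  if (is.null(j) || nrow(j) == 0) return("")
  paste(paste0(j$donor, "-", j$acceptor), collapse = ";")
}

string_to_junctions <- function(s) {
  if (is.na(s) || !nzchar(s)) {
    return(tibble(donor = integer(0), acceptor = integer(0)))
  }
  parts <- strsplit(strsplit(s, ";", fixed = TRUE)[[1]], "-", fixed = TRUE)
  tibble(
    donor = as.integer(vapply(parts, `[`, "", 1L)),
    acceptor = as.integer(vapply(parts, `[`, "", 2L))
  )
}
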