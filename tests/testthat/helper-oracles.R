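# independent oracle implementations used to validate the package's
# algorithms; deliberately written as plain definitional code

# ---- event enumeration oracle ----------------------------------------------
# definitional re-derivation of the five event categories from exon-presence
# patterns; works on the same model tibble but shares no code with the package
oracle_enumerate_signatures <- function(models) {
  sigs <- character(0)
  emit <- function(type, chrom, strand, s, e, exc) {
    sigs <<- c(sigs, paste(type, chrom, strand, s, e, exc, sep = "|"))
  }
  for (gene in unique(models$gene_id)) {
    gm <- models[models$gene_id == gene, ]
    if (nrow(gm) < 2) next
    chrom <- gm$chrom[1]; strand <- gm$strand[1]
    ex_list <- lapply(gm$exons, as.matrix)
    jun_str <- function(m) {
      if (nrow(m) < 2) return(character(0))
      paste(m[-nrow(m), 2], m[-1, 1], sep = "-")
    }
    jn_list <- lapply(ex_list, jun_str)
    for (a in seq_len(nrow(gm))) for (b in seq_len(nrow(gm))) {
      if (a == b) next
      A <- ex_list[[a]]; B <- ex_list[[b]]
      jB <- jn_list[[b]]
      # cassette: internal exon of A, flanks joined in B, exon absent from B
      if (nrow(A) >= 3) {
        for (i in 2:(nrow(A) - 1)) {
          skip_j <- paste(A[i - 1, 2], A[i + 1, 1], sep = "-")
          absent <- !any(B[, 1] < A[i, 2] & B[, 2] > A[i, 1])
          if (skip_j %in% jB && absent) {
            emit("CASSETTE", chrom, strand, A[i, 1], A[i, 2], skip_j)
          }
        }
      }
      # retained intron: an intron of A inside one exon of B
      if (nrow(A) >= 2) {
        for (i in seq_len(nrow(A) - 1)) {
          d <- A[i, 2]; acc <- A[i + 1, 1]
          if (any(B[, 1] <= d & B[, 2] >= acc)) {
            emit("RI", chrom, strand, d, acc, paste(d, acc, sep = "-"))
          }
        }
      }
      # alternative donor/acceptor: two versions of one exon sharing one
      # junction boundary
      if (nrow(A) >= 2 && nrow(B) >= 2) {
        for (i in seq_len(nrow(A) - 1)) {
          dA <- A[i, 2]; aA <- A[i + 1, 1]
          for (k in seq_len(nrow(B) - 1)) {
            dB <- B[k, 2]; aB <- B[k + 1, 1]
            if (aA == aB && dA != dB &&
                A[i, 1] < min(dA, dB) && B[k, 1] < min(dA, dB)) {
              type <- if (strand == "+") "A5SS" else "A3SS"
              emit(type, chrom, strand, min(dA, dB), max(dA, dB),
                   paste(min(dA, dB), aA, sep = "-"))
            }
            if (dA == dB && aA != aB &&
                A[i + 1, 2] > max(aA, aB) && B[k + 1, 2] > max(aA, aB)) {
              type <- if (strand == "+") "A3SS" else "A5SS"
              emit(type, chrom, strand, min(aA, aB), max(aA, aB),
                   paste(dA, max(aA, aB), sep = "-"))
            }
          }
        }
      }
      # mutually exclusive exons
      if (nrow(A) >= 3 && nrow(B) >= 3) {
        for (i in 2:(nrow(A) - 1)) for (k in 2:(nrow(B) - 1)) {
          e2 <- A[i, ]; e3 <- B[k, ]
          if (e2[1] < e3[2] && e3[1] < e2[2]) next
          if (A[i - 1, 2] != B[k - 1, 2] || A[i + 1, 1] != B[k + 1, 1]) next
          both <- vapply(ex_list, function(m) {
            any(m[, 1] == e2[1] & m[, 2] == e2[2]) &&
              any(m[, 1] == e3[1] & m[, 2] == e3[2])
          }, logical(1))
          if (any(both)) next
          if (any(B[, 1] < e2[2] & B[, 2] > e2[1])) next
          if (any(A[, 1] < e3[2] & A[, 2] > e3[1])) next
          first <- if (e2[1] <= e3[1]) e2 else e3
          sec_m <- if (e2[1] <= e3[1]) list(B, k) else list(A, i)
          Bm <- sec_m[[1]]; kk <- sec_m[[2]]
          exc <- paste(paste(Bm[kk - 1, 2], Bm[kk, 1], sep = "-"),
                       paste(Bm[kk, 2], Bm[kk + 1, 1], sep = "-"), sep = ";")
          emit("MXE", chrom, strand, first[1], first[2], exc)
        }
      }
    }
  }
  sort(unique(sigs))
}

# ---- exact two-sided Wilcoxon rank-sum p by full enumeration -----------------
oracle_wilcoxon_p <- function(x, y) {
  nx <- length(x); ny <- length(y); n <- nx + ny
  ranks <- rank(c(x, y))
  u_obs <- sum(ranks[seq_len(nx)]) - nx * (nx + 1) / 2
  combos <- utils::combn(n, nx)
  u_all <- apply(combos, 2, function(idx) sum(ranks[idx]) - nx * (nx + 1) / 2)
  p <- 2 * min(mean(u_all <= u_obs), mean(u_all >= u_obs))
  min(1, p)
}

# ---- log-rank statistic and permutation p, independent implementation -------
oracle_logrank_stat <- function(time, event, g) {
  ts <- sort(unique(time[event == 1]))
  O <- E <- V <- 0
  for (t in ts) {
    at <- time >= t
    d <- sum(event == 1 & time == t); n <- sum(at)
    n1 <- sum(at & g); d1 <- sum(event == 1 & time == t & g)
    O <- O + d1; E <- E + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  if (V == 0) return(NA_real_)
  (O - E)^2 / V
}

oracle_logrank_perm_p <- function(time, event, g, n_shuffles = 1e5) {
  obs <- oracle_logrank_stat(time, event, g)
  hits <- 0L
  for (b in seq_len(n_shuffles)) {
    s <- oracle_logrank_stat(time, event, sample(g))
    if (!is.na(s) && s >= obs - 1e-12) hits <- hits + 1L
  }
  hits / n_shuffles
}

# ---- quadratic brute-force substring scan -----------------------------------
oracle_motif_positions <- function(s, motif) {
  k <- nchar(motif); L <- nchar(s)
  if (L < k) return(integer(0))
  hits <- integer(0)
  for (i in seq_len(L - k + 1)) {
    if (substr(s, i, i + k - 1) == motif) hits <- c(hits, i - 1L)
  }
  hits
}

# ---- hand Kaplan-Meier ------------------------------------------------------
oracle_km <- function(time, event) {
  ts <- sort(unique(time[event == 1]))
  s <- 1
  out <- numeric(0)
  for (t in ts) {
    n <- sum(time >= t); d <- sum(time == t & event == 1)
    s <- s * (1 - d / n)
    out[as.character(t)] <- s
  }
  out
}
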