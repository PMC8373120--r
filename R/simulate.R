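#' Simulation configuration
#'
#' Assembles (and validates) the parameter set driving
#' [simulate_splice_study()]. Defaults mirror a bulk tumor/control splicing
#' cohort: 85 tumor and 10 control samples, ~100 junction reads per event per
#' sample, baseline PSI drawn from Beta(2, 2), a +0.25 tumor PSI shift for
#' planted differential events, exponential survival whose log hazard rises
#' with the PSI of a flagship event, one planted regulator (r = 0.8) among 30
#' decoys, a 35.2% motif-positive fraction of alternative segments, and one
#' planted promoter-binding TF among 20 decoys.
#'
#' @param n_events Number of cassette-exon event genes (two transcripts each).
#' @param n_filler_genes Extra single-transcript genes with no events.
#' @param n_tumor,n_control Group sizes.
#' @param depth_mean Expected junction reads per event per sample (Poisson).
#' @param psi_base_alpha,psi_base_beta Beta parameters of the baseline PSI.
#' @param psi_sample_sd Per-sample biological PSI variability (Gaussian SD
#'   added to the event baseline before binomial read sampling; default
#'   0.08).
#' @param delta_psi_effect Tumor-group PSI shift of planted differential
#'   events.
#' @param n_planted_differential Number of events carrying the shift.
#' @param n_planted_survival Number of planted events (taken from the
#'   differential set) whose mean true PSI drives the hazard.
#' @param hazard_baseline Baseline exponential hazard (per month) at
#'   PSI = 0.5.
#' @param hazard_log_ratio Log hazard ratio per unit PSI (hazard =
#'   `hazard_baseline * exp(hazard_log_ratio * (psi - 0.5))`). The default 4
#'   puts the flagship event's median-split groups at a log hazard ratio
#'   near 1 under the default 0.25 tumor shift — a strong prognostic
#'   splicing marker.
#' @param censoring_rate Target fraction censored (independent uniform
#'   censoring; horizon solved so the expectation matches at the baseline
#'   hazard).
#' @param regulator_r_target True Pearson r of the planted regulator.
#' @param n_decoy_regulators Independent decoy regulators.
#' @param motif_fraction Fraction of alternative segments carrying the motif.
#' @param motif Planted motif (default `"GGAA"`).
#' @param n_decoy_tfs Decoy transcription factors.
#' @param tf_sites_per_tf Candidate ChIP sites emitted per TF.
#' @param tf_r_target True Pearson r of the planted TF vs the target gene in
#'   both cohorts.
#' @param n_cohort2 Sample size of the second expression cohort.
#' @param read_length Simulated read length for SAM output (split evenly
#'   across each junction).
#' @param seed Integer seed; the full bundle is a deterministic function of
#'   the configuration.
#' @return A list of class `sim_config`.
#' @export
simulation_config <- function(n_events = 200,
                              n_filler_genes = 20,
                              n_tumor = 85,
                              n_control = 10,
                              depth_mean = 100,
                              psi_base_alpha = 2,
                              psi_base_beta = 2,
                              psi_sample_sd = 0.08,
                              delta_psi_effect = 0.25,
                              n_planted_differential = 20,
                              n_planted_survival = 1,
                              hazard_baseline = 0.02,
                              hazard_log_ratio = 4,
                              censoring_rate = 0.3,
                              regulator_r_target = 0.8,
                              n_decoy_regulators = 30,
                              motif_fraction = 0.352,
                              motif = "GGAA",
                              n_decoy_tfs = 20,
                              tf_sites_per_tf = 4,
                              tf_r_target = 0.7,
                              n_cohort2 = 60,
                              read_length = 100,
                              seed = 1) {
  cfg <- as.list(environment())
  stopifnot(
    cfg$n_events >= 1, cfg$n_tumor >= 1, cfg$n_control >= 1,
    cfg$depth_mean > 0, cfg$motif_fraction >= 0, cfg$motif_fraction <= 1,
    cfg$censoring_rate >= 0, cfg$censoring_rate < 1,
    cfg$n_planted_survival >= 0
  )
  if (cfg$n_planted_differential > cfg$n_events) {
    stop_sp("n_planted_differential exceeds n_events")
  }
  structure(cfg, class = "sim_config")
}

#' Generate random alternative-segment sequences with a planted motif
#'
#' Emits `n` random DNA sequences of which exactly `n_positive` contain at
#' least one occurrence of `motif` (planted at a random offset) and the rest
#' contain none (rejection-sampled).
#'
#' @param n Number of sequences.
#' @param n_positive Number of motif-positive sequences (first `n_positive`
#'   ids unless `shuffle`).
#' @param lengths Integer vector of sequence lengths (recycled to `n`).
#' @param motif Motif to plant/exclude (default `"GGAA"`).
#' @param shuffle Randomize which ids are positive (default `TRUE`).
#' @return Named character vector with attribute `"positive"` (logical).
#' @export
simulate_motif_sequences <- function(n, n_positive, lengths = 120,
                                     motif = "GGAA", shuffle = TRUE) {
  stopifnot(n_positive >= 0, n_positive <= n)
  lengths <- rep_len(as.integer(lengths), n)
  positive <- c(rep(TRUE, n_positive), rep(FALSE, n - n_positive))
  if (shuffle) positive <- sample(positive)
  seqs <- vapply(seq_len(n), function(i) {
    random_segment(lengths[i], motif, positive[i])
  }, character(1))
  names(seqs) <- sprintf("seq_%04d", seq_len(n))
  attr(seqs, "positive") <- positive
  seqs
}

random_dna <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

# one random segment with the motif planted (positive) or excluded (negative)
random_segment <- function(len, motif, positive) {
  k <- nchar(motif)
  if (positive && len < k) stop_sp("segment too short to hold the motif")
  for (try in 1:200) {
    s <- random_dna(len)
    has <- grepl(motif, s, fixed = TRUE)
    if (!positive && !has) return(s)
    if (positive) {
      at <- sample.int(len - k + 1L, 1)
      s <- paste0(substr(s, 1, at - 1L), motif, substr(s, at + k, len))
      return(s)
    }
  }
  stop_sp("could not sample a motif-free segment of length ", len)
}

# uniform-censoring horizon with expected censoring fraction `rate` at hazard h
censoring_horizon <- function(h, rate) {
  if (rate <= 0) return(Inf)
  f <- function(m) (1 - exp(-h * m)) / (h * m) - rate
  uniroot(f, lower = 1e-6, upper = 1e7, tol = 1e-10)$root
}

#' Simulate a complete splicing-study dataset with ground truth
#'
#' Builds, from one seeded configuration: a transcript annotation whose event
#' genes each carry one cassette exon (inclusion and exclusion transcript); a
#' genome with the motif planted into a configured fraction of alternative
#' segments (sense strand) and rejection-excluded from the rest; per-sample
#' junction counts with total event depth `d ~ Poisson(depth_mean)` and
#' inclusion reads `I ~ Binomial(d, 2*psi/(1+psi))` (the 2-junction inclusion
#' form), split evenly between the two inclusion junctions; a log-normal gene
#' count matrix; survival times `T ~ Exponential(h0 * exp(beta * (psi - 0.5)))`
#' driven by the flagship planted event, with independent uniform censoring;
#' regulator expression built as `r * z(psi) + sqrt(1 - r^2) * noise` for the
#' planted regulator and independent noise for decoys; and scored TF ChIP
#' sites with the planted TF's sites inside the promoter window.
#'
#' @param config A [simulation_config()] object (or arguments for one).
#' @param sequences Generate the genome and planted-motif sequences (default
#'   `TRUE`); `FALSE` skips them (faster, for screens that only need counts)
#'   and leaves `genome = NULL`.
#' @return A list of class `splice_sim`: `models`, `event_table` (the
#'   generator's intended cassette events, with lengths and coding flags),
#'   `genome`, `junction_counts`, `gene_counts`, `gene_lengths`, `survival`,
#'   `groups`,
#'   `regulator_expression`, `regulator_ids`, `tf_sites`, `tss_table`,
#'   `tf_expression` (list of two cohorts), `target_gene`, `samples`,
#'   `config`, and `truth` (the `SyntheticTruth` record: true PSI matrix,
#'   planted ids, planted regulator/TF and their r, motif-positive ids).
#' @export
simulate_splice_study <- function(config = simulation_config(), sequences = TRUE) {
  if (!inherits(config, "sim_config")) config <- do.call(simulation_config, config)
  set.seed(config$seed)
  n_ev <- config$n_events
  samples <- c(sprintf("tumor_%03d", seq_len(config$n_tumor)),
               sprintf("control_%02d", seq_len(config$n_control)))
  groups <- tibble(sample_id = samples,
                   group = rep(c("tumor", "control"),
                               c(config$n_tumor, config$n_control)))
  n_s <- length(samples)

  # ---- gene structures -----------------------------------------------------
  planted_diff <- sort(sample.int(n_ev, config$n_planted_differential))
  motif_pos <- sort(sample.int(n_ev, round(config$motif_fraction * n_ev)))
  gene_rows <- vector("list", n_ev)
  alt_info <- vector("list", n_ev)
  for (i in seq_len(n_ev)) {
    gene_id <- sprintf("GENE%04d", i)
    chrom <- sprintf("ctg%04d", i)
    strand <- if (runif(1) < 0.7) "+" else "-"
    n_ex <- sample(3:6, 1)
    internal <- 2:(n_ex - 1)
    alt_idx <- internal[sample.int(length(internal), 1)]
    lens <- sample(80:250, n_ex, replace = TRUE)
    lens[alt_idx] <- if (i %in% planted_diff) {
      sample(30:300, 1)
    } else {
      sample(21:400, 1)
    }
    introns <- sample(200:800, n_ex - 1, replace = TRUE)
    starts <- integer(n_ex)
    starts[1] <- 200L
    for (k in 2:n_ex) starts[k] <- starts[k - 1] + lens[k - 1] + introns[k - 1]
    ends <- starts + lens
    exons <- tibble(start = starts, end = ends)
    has_cds <- i %in% planted_diff || runif(1) < 0.9
    cds <- if (has_cds) {
      tibble(start = c(starts[1] + 30L, starts[-1]),
             end = c(ends[-n_ex], ends[n_ex] - 30L))
    } else {
      tibble(start = integer(0), end = integer(0))
    }
    cds_excl <- if (has_cds) cds[-alt_idx, , drop = FALSE] else cds
    gene_rows[[i]] <- tibble(
      gene_id = gene_id,
      transcript_id = paste0(gene_id, c(".inc", ".exc")),
      chrom = chrom, strand = strand,
      n_exons = c(n_ex, n_ex - 1L),
      exons = list(exons, exons[-alt_idx, , drop = FALSE]),
      cds = list(cds, cds_excl)
    )
    alt_info[[i]] <- tibble(
      gene_id = gene_id, chrom = chrom, strand = strand,
      alt_start = starts[alt_idx], alt_end = ends[alt_idx],
      up_donor = ends[alt_idx - 1], down_acceptor = starts[alt_idx + 1],
      contig_len = ends[n_ex] + 200L, in_cds = has_cds,
      event_id = sprintf("CASSETTE_%s_%s_%d_%d", gene_id, chrom,
                         starts[alt_idx], ends[alt_idx])
    )
  }
  filler <- vector("list", config$n_filler_genes)
  for (i in seq_len(config$n_filler_genes)) {
    gene_id <- sprintf("FILL%03d", i)
    chrom <- sprintf("ctgf%03d", i)
    n_ex <- sample(2:4, 1)
    lens <- sample(100:400, n_ex, replace = TRUE)
    starts <- 200L + cumsum(c(0L, head(lens, -1) + sample(200:600, n_ex - 1, replace = TRUE)))
    filler[[i]] <- tibble(
      gene_id = gene_id, transcript_id = paste0(gene_id, ".t1"),
      chrom = chrom, strand = "+", n_exons = n_ex,
      exons = list(tibble(start = starts, end = starts + lens)),
      cds = list(tibble(start = integer(0), end = integer(0)))
    )
  }
  models <- bind_rows(list_rbind(gene_rows), list_rbind(filler))
  alt <- list_rbind(alt_info)

  # ---- genome with planted/excluded motif in alternative segments ----------
  genome <- NULL
  if (sequences) {
    genome <- character(0)
    for (i in seq_len(n_ev)) {
      a <- alt[i, ]
      contig <- random_dna(a$contig_len)
      seg_len <- a$alt_end - a$alt_start
      sense <- random_segment(seg_len, config$motif, i %in% motif_pos)
      genomic <- if (a$strand == "-") revcomp(sense) else sense
      substr(contig, a$alt_start + 1L, a$alt_end) <- genomic
      genome[a$chrom] <- contig
    }
    for (i in seq_len(config$n_filler_genes)) {
      f <- filler[[i]]
      genome[f$chrom] <- random_dna(max(f$exons[[1]]$end) + 200L)
    }
  }

  # ---- true PSI and junction counts ---------------------------------------
  pi0 <- clamp(rbeta(n_ev, config$psi_base_alpha, config$psi_base_beta), 0.05, 0.95)
  psi_true <- matrix(rep(pi0, n_s), n_ev, n_s,
                     dimnames = list(alt$event_id, samples))
  is_tumor <- groups$group == "tumor"
  psi_true[planted_diff, is_tumor] <-
    psi_true[planted_diff, is_tumor] + config$delta_psi_effect
  # per-sample biological variability around the event/group mean
  if (config$psi_sample_sd > 0) {
    psi_true <- psi_true + rnorm(n_ev * n_s, sd = config$psi_sample_sd)
  }
  psi_true <- clamp(psi_true, 0.02, 0.98)

  d <- matrix(rpois(n_ev * n_s, config$depth_mean), n_ev, n_s)
  q <- 2 * psi_true / (1 + psi_true)
  I <- matrix(rbinom(n_ev * n_s, as.vector(d), as.vector(q)), n_ev, n_s)
  I1 <- matrix(rbinom(n_ev * n_s, as.vector(I), 0.5), n_ev, n_s)
  S <- d - I
  cell <- crossing(event_idx = seq_len(n_ev), sample_idx = seq_len(n_s))
  jc <- cell |>
    mutate(
      i1 = I1[cbind(.data$event_idx, .data$sample_idx)],
      i2 = (I - I1)[cbind(.data$event_idx, .data$sample_idx)],
      s = S[cbind(.data$event_idx, .data$sample_idx)]
    )
  a_rep <- alt[jc$event_idx, ]
  junction_counts <- bind_rows(
    tibble(sample_id = samples[jc$sample_idx], chrom = a_rep$chrom,
           donor = a_rep$up_donor, acceptor = a_rep$alt_start,
           strand = a_rep$strand, count = jc$i1),
    tibble(sample_id = samples[jc$sample_idx], chrom = a_rep$chrom,
           donor = a_rep$alt_end, acceptor = a_rep$down_acceptor,
           strand = a_rep$strand, count = jc$i2),
    tibble(sample_id = samples[jc$sample_idx], chrom = a_rep$chrom,
           donor = a_rep$up_donor, acceptor = a_rep$down_acceptor,
           strand = a_rep$strand, count = jc$s)
  ) |>
    filter(.data$count > 0) |>
    arrange(.data$sample_id, .data$chrom, .data$donor, .data$acceptor)

  # ---- gene expression ------------------------------------------------------
  gene_ids <- unique(models$gene_id)
  mu <- runif(length(gene_ids), 1.5, 6.5)
  low_idx <- which(startsWith(gene_ids, "FILL"))
  mu[low_idx[seq_len(ceiling(length(low_idx) / 2))]] <- runif(
    ceiling(length(low_idx) / 2), -2, 0.5)
  counts <- matrix(
    round(rlnorm(length(gene_ids) * n_s, meanlog = rep(mu, n_s), sdlog = 0.4)),
    length(gene_ids), n_s, dimnames = list(gene_ids, samples))
  gene_counts <- as_tibble(counts, rownames = "gene_id")
  gene_lengths <- models |>
    group_by(.data$gene_id) |>
    summarise(length = {
      ex <- bind_rows(.data$exons)
      sum(unique_interval_bases(ex))
    }, .groups = "drop")

  # ---- survival linked to the flagship event(s) -----------------------------
  planted_surv <- planted_diff[seq_len(min(config$n_planted_survival,
                                           length(planted_diff)))]
  psi_driver <- if (length(planted_surv) > 0) {
    colMeans(psi_true[planted_surv, , drop = FALSE])
  } else {
    rep(0.5, n_s)  # null configuration: hazard stays at baseline
  }
  rate <- config$hazard_baseline * exp(config$hazard_log_ratio * (psi_driver - 0.5))
  t_event <- rexp(n_s, rate)
  horizon <- censoring_horizon(config$hazard_baseline, config$censoring_rate)
  c_time <- if (is.finite(horizon)) runif(n_s, 0, horizon) else rep(Inf, n_s)
  survival <- tibble(
    sample_id = samples,
    time = pmax(pmin(t_event, c_time), 1e-3),
    event = as.integer(t_event <= c_time)
  )

  # ---- regulator expression -------------------------------------------------
  n_reg <- config$n_decoy_regulators + 1L
  regulator_ids <- sprintf("RBP_%02d", seq_len(n_reg))
  planted_reg <- sample(regulator_ids, 1)
  anchor <- if (length(planted_surv) > 0) planted_surv[1] else 1L
  z <- as.numeric(scale(psi_true[anchor, ]))
  if (any(!is.finite(z))) z <- rnorm(n_s)  # constant PSI row (null config)
  r <- config$regulator_r_target
  reg_mat <- matrix(8 + 2 * rnorm(n_reg * n_s), n_reg, n_s,
                    dimnames = list(regulator_ids, samples))
  reg_mat[planted_reg, ] <- 8 + 2 * (r * z + sqrt(1 - r^2) * rnorm(n_s))
  regulator_expression <- as_tibble(reg_mat, rownames = "gene_id")

  # ---- TF sites and two expression cohorts ----------------------------------
  target_gene <- "TARGET01"
  tss_table <- tibble(gene_id = target_gene, chrom = "ctg_tgt",
                      strand = "+", tss = 50000L)
  n_tf <- config$n_decoy_tfs + 1L
  tf_ids <- sprintf("TF_%02d", seq_len(n_tf))
  planted_tf <- sample(tf_ids, 1)
  tf_sites <- map(tf_ids, function(tf) {
    k <- config$tf_sites_per_tf
    if (tf == planted_tf) {
      off <- c(sample(-2500:500, max(2, k - 2), replace = TRUE),
               sample(c(-6000:-2501, 501:2000), min(2, k), replace = TRUE))
      score <- c(runif(max(2, k - 2), 55, 100), runif(min(2, k), 0, 100))
    } else {
      off <- sample(-6000:2000, k, replace = TRUE)
      score <- runif(k, 0, 100)
    }
    tibble(tf_name = tf, chrom = "ctg_tgt",
           position = tss_table$tss + off,
           chip_score = round(score, 2), target_gene = target_gene)
  }) |> list_rbind()
  cohorts <- list(
    cohort1 = samples,
    cohort2 = sprintf("c2_s%03d", seq_len(config$n_cohort2))
  )
  tf_expression <- map(cohorts, function(ss) {
    z0 <- rnorm(length(ss))
    mat <- matrix(8 + 2 * rnorm((n_tf + 1) * length(ss)), n_tf + 1, length(ss),
                  dimnames = list(c(target_gene, tf_ids), ss))
    mat[target_gene, ] <- 8 + 2 * z0
    rtf <- config$tf_r_target
    mat[planted_tf, ] <- 8 + 2 * (rtf * z0 + sqrt(1 - rtf^2) * rnorm(length(ss)))
    as_tibble(mat, rownames = "gene_id")
  })

  truth <- list(
    psi = psi_true,
    psi_baseline = setNames(pi0, alt$event_id),
    planted_differential = alt$event_id[planted_diff],
    planted_survival = alt$event_id[planted_surv],
    planted_regulator = planted_reg,
    regulator_r = r,
    motif_positive = alt$event_id[motif_pos],
    planted_tf = planted_tf,
    tf_r = config$tf_r_target
  )
  event_table <- alt |>
    transmute(.data$event_id, event_type = "CASSETTE", .data$gene_id,
              .data$chrom, .data$strand, .data$alt_start, .data$alt_end,
              alt_length = .data$alt_end - .data$alt_start, .data$in_cds,
              inclusion_junctions = map2(
                .data$up_donor, .data$alt_start,
                function(d, a) NULL),  # filled below (needs 4 coords)
              exclusion_junctions = map2(
                .data$up_donor, .data$down_acceptor,
                function(d, a) tibble(donor = d, acceptor = a)))
  event_table$inclusion_junctions <- pmap(
    list(alt$up_donor, alt$alt_start, alt$alt_end, alt$down_acceptor),
    function(ud, as_, ae, da) tibble(donor = c(ud, ae), acceptor = c(as_, da)))
  structure(
    list(models = models, event_table = event_table,
         genome = genome, junction_counts = junction_counts,
         gene_counts = gene_counts, gene_lengths = gene_lengths,
         survival = survival, groups = groups,
         regulator_expression = regulator_expression,
         regulator_ids = regulator_ids,
         tf_sites = tf_sites, tss_table = tss_table,
         tf_expression = tf_expression, target_gene = target_gene,
         samples = samples, config = config, truth = truth),
    class = "splice_sim"
  )
}

# total bases covered by a union of intervals
unique_interval_bases <- function(iv) {
  if (nrow(iv) == 0) return(0L)
  iv <- iv[order(iv$start), , drop = FALSE]
  total <- 0L; cur_s <- iv$start[1]; cur_e <- iv$end[1]
  for (i in seq_len(nrow(iv))[-1]) {
    if (iv$start[i] > cur_e) {
      total <- total + (cur_e - cur_s); cur_s <- iv$start[i]; cur_e <- iv$end[i]
    } else {
      cur_e <- max(cur_e, iv$end[i])
    }
  }
  total + (cur_e - cur_s)
}

#' Write a simulated study as a file bundle
#'
#' Emits GTF annotation, genome FASTA, junction counts (TSV) or minimal
#' single-end SAM reads, gene counts/lengths, survival, group labels,
#' regulator list and expression, TF sites, TSS table, the second expression
#' cohort, and the ground truth as JSON. All files are plain text.
#'
#' @param sim A `splice_sim` object.
#' @param dir Output directory (created if needed).
#' @param alignments `"junctions"` (default, junction-count TSV) or `"sam"`
#'   (one N-gapped read per junction count; read length from the config).
#' @return Named character vector of written paths, invisibly.
#' @export
write_study_bundle <- function(sim, dir, alignments = c("junctions", "sam")) {
  alignments <- match.arg(alignments)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  paths <- c(
    annotation = p("annotation.gtf"), genome = p("genome.fa"),
    gene_counts = p("gene_counts.tsv"), gene_lengths = p("gene_lengths.tsv"),
    survival = p("survival.tsv"), groups = p("groups.tsv"),
    regulators = p("regulators.txt"),
    regulator_expression = p("regulator_expression.tsv"),
    tf_sites = p("tf_sites.tsv"), tss = p("tss.tsv"),
    tf_expression_cohort2 = p("tf_expression_cohort2.tsv"),
    truth = p("truth.json")
  )
  write_gtf(sim$models, paths["annotation"])
  if (is.null(sim$genome)) {
    paths <- paths[names(paths) != "genome"]
  } else {
    Biostrings::writeXStringSet(Biostrings::DNAStringSet(sim$genome), paths["genome"])
  }
  readr::write_tsv(sim$gene_counts, paths["gene_counts"])
  readr::write_tsv(sim$gene_lengths, paths["gene_lengths"])
  readr::write_tsv(sim$survival, paths["survival"])
  readr::write_tsv(sim$groups, paths["groups"])
  writeLines(sim$regulator_ids, paths["regulators"])
  readr::write_tsv(sim$regulator_expression, paths["regulator_expression"])
  readr::write_tsv(sim$tf_sites, paths["tf_sites"])
  readr::write_tsv(sim$tss_table, paths["tss"])
  readr::write_tsv(sim$tf_expression$cohort2, paths["tf_expression_cohort2"])
  if (alignments == "sam") {
    paths["alignments"] <- p("reads.sam")
    write_sim_sam(sim, paths["alignments"])
  } else {
    paths["alignments"] <- p("junction_counts.tsv")
    write_junction_counts(sim$junction_counts, paths["alignments"])
  }
  truth_json <- sim$truth
  truth_json$psi <- list(
    event_id = rownames(sim$truth$psi),
    sample_id = colnames(sim$truth$psi),
    values = unname(as.data.frame(sim$truth$psi))
  )
  jsonlite::write_json(truth_json, paths["truth"], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

# one minimal single-end SAM read per junction count, split read_length/2 per side
write_sim_sam <- function(sim, path) {
  jc <- sim$junction_counts
  half <- max(sim$config$read_length %/% 2L, 10L)
  con <- file(path, "w")
  on.exit(close(con))
  contigs <- names(sim$genome)
  writeLines(c("@HD\tVN:1.6\tSO:unsorted",
               sprintf("@SQ\tSN:%s\tLN:%d", contigs, nchar(sim$genome))), con)
  rid <- 0L
  for (i in seq_len(nrow(jc))) {
    n <- jc$count[i]
    if (n == 0) next
    gap <- jc$acceptor[i] - jc$donor[i]
    pos1 <- jc$donor[i] - half + 1L  # 1-based POS
    cigar <- sprintf("%dM%dN%dM", half, gap, half)
    lines <- sprintf("read%07d\t0\t%s\t%d\t255\t%s\t*\t0\t0\t*\t*",
                     rid + seq_len(n), jc$chrom[i], pos1, cigar)
    writeLines(lines, con)
    rid <- rid + n
  }
  invisible(path)
}

#' Recovery metrics of a pipeline run against the simulation ground truth
#'
#' @param truth The `truth` element of a `splice_sim`.
#' @param psi Long estimated PSI tibble (must use the truth's event ids).
#' @param differential Output of [differential_psi()] (optional).
#' @param survival_results Output of [survival_association()] (optional).
#' @param regulator_ranking Output of [correlate_regulators()] (optional).
#' @param motif_hits Output of [scan_motif()] on event sequences (optional).
#' @param alpha Significance threshold used for sensitivity/specificity.
#' @return One-row tibble of recovery metrics (`psi_rmse`,
#'   `psi_within_3se_fraction`, differential sensitivity/specificity,
#'   planted regulator rank, recovered motif fraction, ...).
#' @export
truth_report <- function(truth, psi, differential = NULL,
                         survival_results = NULL, regulator_ranking = NULL,
                         motif_hits = NULL, alpha = 0.05) {
  assert_cols(psi, c("event_id", "sample_id", "psi"))
  bad <- setdiff(unique(psi$event_id), rownames(truth$psi))
  if (length(bad) > 0) {
    stop_sp("estimated PSI contains event ids absent from the truth: ",
            paste(head(bad, 3), collapse = ", "))
  }
  est <- psi |>
    mutate(true_psi = truth$psi[cbind(.data$event_id, .data$sample_id)],
           depth = .data$inclusion_reads + .data$exclusion_reads)
  fin <- est |> filter(!is.na(.data$psi), .data$depth > 0)
  out <- tibble(
    n_cells = nrow(est),
    n_quantified = nrow(fin),
    psi_rmse = sqrt(mean((fin$psi - fin$true_psi)^2)),
    psi_within_3se_fraction = mean(
      abs(fin$psi - fin$true_psi) <=
        3 * sqrt(fin$true_psi * (1 - fin$true_psi) / fin$depth)
    )
  )
  if (!is.null(differential)) {
    pos <- differential$event_id %in% truth$planted_differential
    sig <- !is.na(differential$wilcoxon_p) & differential$wilcoxon_p < alpha
    out$differential_sensitivity <- if (any(pos)) mean(sig[pos]) else NA_real_
    out$differential_specificity <- if (any(!pos)) mean(!sig[!pos]) else NA_real_
  }
  if (!is.null(survival_results)) {
    pos <- survival_results$event_id %in% truth$planted_survival
    out$survival_planted_p <- if (any(pos)) {
      min(survival_results$logrank_p[pos], na.rm = TRUE)
    } else NA_real_
  }
  if (!is.null(regulator_ranking)) {
    out$planted_regulator_rank <-
      match(truth$planted_regulator, regulator_ranking$regulator_id)
  }
  if (!is.null(motif_hits)) {
    out$motif_fraction_recovered <- motif_summary(motif_hits)
    out$motif_fraction_true <-
      round(100 * length(truth$motif_positive) / nrow(truth$psi), 1)
  }
  out
}
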