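#' Run configuration for an end-to-end pipeline run
#'
#' Collects the input paths and thresholds consumed by [run_full()]. Paths
#' default to the file names written by [write_study_bundle()], resolved
#' against `input_dir`.
#'
#' @param input_dir Directory holding the input bundle.
#' @param output_dir Directory for stage outputs and the manifest.
#' @param annotation,alignments,junction_counts,gene_counts,gene_lengths,survival,groups,regulators,regulator_expression,genome,tf_sites,tss,tf_expression_cohort2
#'   Input paths; `alignments` (SAM) takes precedence over `junction_counts`
#'   when both exist.
#' @param min_total_reads,min_overhang Quantification thresholds.
#' @param alpha,delta_psi_cutoff,length_window Prioritization thresholds.
#' @param tpm_threshold Low-expression filter threshold.
#' @param tf_window,tf_min_score Promoter-window filter parameters.
#' @param motif Motif scanned in alternative segments.
#' @param target_event Event used for regulator correlation; `NULL` picks the
#'   retained candidate with the largest |ΔPSI| (falling back to the largest
#'   overall).
#' @param seed Seed recorded in the manifest (the pipeline itself is
#'   deterministic given its inputs).
#' @return A list of class `run_config`.
#' @export
run_config <- function(input_dir, output_dir = file.path(input_dir, "results"),
                       annotation = "annotation.gtf",
                       alignments = "reads.sam",
                       junction_counts = "junction_counts.tsv",
                       gene_counts = "gene_counts.tsv",
                       gene_lengths = "gene_lengths.tsv",
                       survival = "survival.tsv",
                       groups = "groups.tsv",
                       regulators = "regulators.txt",
                       regulator_expression = "regulator_expression.tsv",
                       genome = "genome.fa",
                       tf_sites = "tf_sites.tsv",
                       tss = "tss.tsv",
                       tf_expression_cohort2 = "tf_expression_cohort2.tsv",
                       min_total_reads = 10L, min_overhang = 6L,
                       alpha = 0.05, delta_psi_cutoff = 0.1,
                       length_window = c(30, 300), tpm_threshold = 2,
                       tf_window = c(-2500, 500), tf_min_score = 50,
                       motif = "GGAA", target_event = NULL, seed = 1L) {
  cfg <- as.list(environment())
  rel <- c("annotation", "alignments", "junction_counts", "gene_counts",
           "gene_lengths", "survival", "groups", "regulators",
           "regulator_expression", "genome", "tf_sites", "tss",
           "tf_expression_cohort2")
  for (f in rel) {
    if (!is.null(cfg[[f]]) && !file.exists(cfg[[f]])) {
      cfg[[f]] <- file.path(input_dir, cfg[[f]])
    }
  }
  structure(cfg, class = "run_config")
}

#' Execute the full pipeline on a file bundle
#'
#' Stages, in dependency order: `catalog` (annotation -> event catalog),
#' `quantify` (alignments or junction counts -> PSI; counts -> TPM with the
#' low-expression filter), `prioritize` (differential PSI + survival
#' association -> candidate table), `regulators` (PSI--expression correlation
#' ranking + motif scan of alternative segments), `tf` (promoter-window site
#' filter + TF ranking across cohorts; skipped when TF inputs are absent).
#' Each stage writes a TSV under the output directory; a manifest records the
#' package version, the configuration, input checksums and per-stage row
#' counts. Reruns on identical inputs reproduce identical outputs.
#'
#' @param config A [run_config()].
#' @param quiet Suppress per-stage log lines.
#' @return An object of class `splice_run`: the stage outputs plus `manifest`.
#' @export
run_full <- function(config, quiet = FALSE) {
  if (!inherits(config, "run_config")) stop_sp("config must be a run_config")
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  stages <- list()
  log_stage <- function(stage, rows_in, rows_out, elapsed) {
    stages[[stage]] <<- tibble(stage = stage, rows_in = rows_in,
                               rows_out = rows_out,
                               elapsed_s = round(elapsed, 3))
    if (!quiet) {
      message(sprintf("[%s] rows in: %s, rows out: %s (%.2fs)",
                      stage, rows_in, rows_out, elapsed))
    }
  }
  run_stage <- function(stage, fn) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(fn(), error = function(e) {
      stop_sp("stage '", stage, "' failed: ", conditionMessage(e))
    })
    res
  }
  out <- list(config = config)

  # catalog
  t0 <- proc.time()[["elapsed"]]
  models <- run_stage("catalog", function() read_gtf_models(config$annotation))
  events <- run_stage("catalog", function() enumerate_events(models))
  write_event_catalog(events, file.path(config$output_dir, "event_catalog.tsv"))
  log_stage("catalog", nrow(models), nrow(events), proc.time()[["elapsed"]] - t0)

  # quantify
  t0 <- proc.time()[["elapsed"]]
  junctions <- run_stage("quantify", function() {
    if (!is.null(config$alignments) && file.exists(config$alignments)) {
      extract_junctions(config$alignments, min_overhang = config$min_overhang)
    } else if (file.exists(config$junction_counts)) {
      read_junction_counts(config$junction_counts)
    } else {
      stop_sp("neither alignments nor a junction-count table found")
    }
  })
  groups <- readr::read_tsv(config$groups, show_col_types = FALSE)
  psi <- run_stage("quantify", function() {
    quantifiable <- events[map_int(events$inclusion_junctions, nrow) > 0 &
                             map_int(events$exclusion_junctions, nrow) > 0, ]
    psi_matrix(quantifiable, junctions, samples = groups$sample_id,
               min_total_reads = config$min_total_reads)
  })
  write_psi_tsv(psi, file.path(config$output_dir, "psi_matrix.tsv"))
  tpm <- NULL
  if (file.exists(config$gene_counts) && file.exists(config$gene_lengths)) {
    tpm <- run_stage("quantify", function() {
      counts <- readr::read_tsv(config$gene_counts, show_col_types = FALSE)
      lens <- readr::read_tsv(config$gene_lengths, show_col_types = FALSE)
      filter_low_expression(compute_tpm(counts, lens),
                            threshold = config$tpm_threshold)
    })
    readr::write_tsv(tpm, file.path(config$output_dir, "tpm_filtered.tsv"))
  }
  log_stage("quantify", nrow(junctions), nrow(psi), proc.time()[["elapsed"]] - t0)

  # prioritize
  t0 <- proc.time()[["elapsed"]]
  survival_tbl <- readr::read_tsv(config$survival, show_col_types = FALSE)
  differential <- run_stage("prioritize", function() differential_psi(psi, groups))
  surv_res <- run_stage("prioritize", function() {
    survival_association(psi, survival_tbl)
  })
  candidates <- run_stage("prioritize", function() {
    apply_prioritization(events, differential, surv_res, psi, groups,
                         alpha = config$alpha,
                         delta_psi_cutoff = config$delta_psi_cutoff,
                         length_window = config$length_window)
  })
  readr::write_tsv(candidates, file.path(config$output_dir, "candidates.tsv"))
  log_stage("prioritize", nrow(psi), nrow(candidates),
            proc.time()[["elapsed"]] - t0)

  # regulators
  t0 <- proc.time()[["elapsed"]]
  target_event <- config$target_event
  if (is.null(target_event)) {
    pool <- candidates |> filter(!is.na(.data$delta_psi))
    retained <- pool |> filter(.data$retained)
    if (nrow(retained) > 0) pool <- retained
    target_event <- if (nrow(pool) > 0) {
      pool$event_id[which.max(abs(pool$delta_psi))]
    } else {
      candidates$event_id[1]
    }
  }
  reg_expr <- readr::read_tsv(config$regulator_expression, show_col_types = FALSE)
  reg_ids <- read_regulator_list(config$regulators)
  target_psi <- psi |>
    filter(.data$event_id == target_event) |>
    select("sample_id", "psi")
  reg_rank <- run_stage("regulators", function() {
    correlate_regulators(reg_expr, target_psi, reg_ids)
  })
  readr::write_tsv(reg_rank, file.path(config$output_dir, "regulator_ranking.tsv"))
  motif_hits <- NULL
  if (file.exists(config$genome)) {
    motif_hits <- run_stage("regulators", function() {
      seqs <- event_sequences(events, config$genome)
      scan_motif(seqs, motif = config$motif)
    })
    motif_flat <- motif_hits |>
      mutate(positions = map_chr(.data$positions, paste, collapse = ";")) |>
      rename(event_id = "id")
    readr::write_tsv(motif_flat, file.path(config$output_dir, "motif_hits.tsv"))
  }
  log_stage("regulators", length(reg_ids), nrow(reg_rank),
            proc.time()[["elapsed"]] - t0)

  # tf (optional)
  tf_rank <- NULL; tf_retained <- NULL
  if (file.exists(config$tf_sites) && file.exists(config$tss)) {
    t0 <- proc.time()[["elapsed"]]
    sites <- readr::read_tsv(config$tf_sites, show_col_types = FALSE)
    tss <- readr::read_tsv(config$tss, show_col_types = FALSE)
    tf_retained <- run_stage("tf", function() {
      filter_tf_sites(sites, tss, window = config$tf_window,
                      min_score = config$tf_min_score)
    })
    readr::write_tsv(tf_retained, file.path(config$output_dir, "tf_sites_retained.tsv"))
    if (nrow(tf_retained) > 0 && file.exists(config$tf_expression_cohort2)) {
      cohort2 <- readr::read_tsv(config$tf_expression_cohort2, show_col_types = FALSE)
      target_gene <- unique(tf_retained$target_gene)[1]
      cohort1 <- build_tf_cohort1(reg_expr, config, target_gene)
      tf_rank <- run_stage("tf", function() {
        cohorts <- if (is.null(cohort1)) list(cohort2 = cohort2) else
          list(cohort1 = cohort1, cohort2 = cohort2)
        rank_tf_candidates(tf_retained, cohorts, target_gene,
                           alpha = config$alpha)
      })
      readr::write_tsv(tf_rank, file.path(config$output_dir, "tf_ranking.tsv"))
    }
    log_stage("tf", nrow(sites), nrow(tf_retained), proc.time()[["elapsed"]] - t0)
  }

  manifest <- build_manifest(config, stages)
  readr::write_tsv(manifest$stages, file.path(config$output_dir, "manifest_stages.tsv"))
  jsonlite::write_json(manifest$meta, file.path(config$output_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  structure(
    list(events = events, psi = psi, tpm = tpm, differential = differential,
         survival_results = surv_res, candidates = candidates,
         target_event = target_event, regulator_ranking = reg_rank,
         motif_hits = motif_hits, tf_retained = tf_retained, tf_ranking = tf_rank,
         manifest = manifest, config = config),
    class = "splice_run"
  )
}

# cohort-1 expression for the TF step: prefer a dedicated cohort-1 file next
# to the cohort-2 file, else NULL (single-cohort ranking)
build_tf_cohort1 <- function(reg_expr, config, target_gene) {
  cand <- file.path(dirname(config$tf_expression_cohort2), "tf_expression_cohort1.tsv")
  if (file.exists(cand)) {
    return(readr::read_tsv(cand, show_col_types = FALSE))
  }
  NULL
}

build_manifest <- function(config, stages) {
  inputs <- c(config$annotation, config$alignments, config$junction_counts,
              config$gene_counts, config$gene_lengths, config$survival,
              config$groups, config$regulators, config$regulator_expression,
              config$genome, config$tf_sites, config$tss,
              config$tf_expression_cohort2)
  inputs <- unique(inputs[!is.na(inputs) & file.exists(inputs)])
  checksums <- tools::md5sum(inputs)
  list(
    meta = list(
      package = "spliceprio",
      version = as.character(utils::packageVersion("spliceprio")),
      seed = config$seed,
      thresholds = config[c("min_total_reads", "min_overhang", "alpha",
                            "delta_psi_cutoff", "length_window",
                            "tpm_threshold", "tf_window", "tf_min_score",
                            "motif")],
      input_checksums = as.list(checksums)
    ),
    stages = list_rbind(unname(stages))
  )
}

#' @export
print.splice_run <- function(x, ...) {
  cat("spliceprio run:", nrow(x$events), "events,",
      length(unique(x$psi$sample_id)), "samples\n")
  cat("retained candidates:", sum(x$candidates$retained), "\n")
  cat("target event:", x$target_event, "\n")
  invisible(x)
}

#' @export
glance.splice_run <- function(x, ...) {
  tibble(
    n_events = nrow(x$events),
    n_samples = length(unique(x$psi$sample_id)),
    n_retained = sum(x$candidates$retained),
    target_event = x$target_event,
    top_regulator = if (nrow(x$regulator_ranking) > 0) {
      x$regulator_ranking$regulator_id[1]
    } else NA_character_,
    n_stages = nrow(x$manifest$stages)
  )
}

#' @export
tidy.splice_run <- function(x, ...) x$candidates
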