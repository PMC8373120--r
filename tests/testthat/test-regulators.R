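expr_from <- function(rows, samples) {
  m <- do.call(rbind, rows)
  colnames(m) <- samples
  tibble::as_tibble(m) |>
    dplyr::mutate(gene_id = names(rows), .before = 1)
}

test_that("regulator correlation recovers exact affine relations", {
  samples <- sprintf("s%02d", 1:10)
  psi <- tibble::tibble(sample_id = samples, psi = seq(0.1, 1, by = 0.1))
  ex <- expr_from(list(up = 2 * psi$psi + 1, down = -psi$psi), samples)
  res <- correlate_regulators(ex, psi, c("up", "down"))
  expect_equal(res$r[res$regulator_id == "up"], 1)
  expect_equal(res$r_squared[res$regulator_id == "up"], 1)
  expect_equal(res$r[res$regulator_id == "down"], -1)

  # r is invariant to affine transforms (sign follows the scale factor)
  psi2 <- dplyr::mutate(psi, psi = 3 * psi - 0.2)
  res2 <- correlate_regulators(ex, psi2, c("up", "down"))
  expect_equal(res2$r, res$r, tolerance = 1e-12)

  # absent regulators are skipped with a warning; <3 pairs gives NA
  expect_warning(res3 <- correlate_regulators(ex, psi, c("up", "ghost")),
                 "absent")
  expect_false("ghost" %in% res3$regulator_id)
  psi_short <- psi[1:2, ]
  res4 <- correlate_regulators(ex, psi_short, "up")
  expect_true(is.na(res4$p))
  expect_equal(res4$n_used, 2L)
})

test_that("a planted regulator among 30 decoys ranks first almost always", {
  set.seed(303)
  n <- 95; wins <- 0L
  for (b in 1:100) {
    samples <- sprintf("s%02d", 1:n)
    z <- as.numeric(scale(rbeta(n, 2, 2)))
    planted <- 0.8 * z + sqrt(1 - 0.64) * rnorm(n)
    rows <- c(list(planted), replicate(30, rnorm(n), simplify = FALSE))
    names(rows) <- c("planted", sprintf("decoy%02d", 1:30))
    ex <- expr_from(rows, samples)
    psi <- tibble::tibble(sample_id = samples, psi = z)
    top <- correlate_regulators(ex, psi, names(rows))$regulator_id[1]
    if (top == "planted") wins <- wins + 1L
  }
  expect_gte(wins, 95)
})

test_that("regulator correlation p-values are calibrated under the null", {
  set.seed(808)
  n <- 50
  samples <- sprintf("s%02d", 1:n)
  rows <- replicate(2000, rnorm(n), simplify = FALSE)
  names(rows) <- sprintf("null%04d", 1:2000)
  ex <- expr_from(rows, samples)
  psi <- tibble::tibble(sample_id = samples, psi = runif(n))
  res <- correlate_regulators(ex, psi, names(rows))
  frac <- mean(res$p < 0.05)
  expect_gte(frac, 0.03)
  expect_lte(frac, 0.07)
})

test_that("motif scanning finds all overlapping occurrences", {
  hits <- scan_motif(c(a = "GGAAGGAA", b = "CCCC", c = "GGAGAA"))
  expect_equal(hits$positions[[1]], c(0L, 4L))
  expect_true(hits$present[1])
  expect_false(hits$present[2])
  expect_equal(hits$n_hits[3], 0L)
  # overlapping occurrences are all reported
  ov <- scan_motif(c(x = "AAAA"), motif = "AA")
  expect_equal(ov$positions[[1]], c(0L, 1L, 2L))

  expect_true(is.na(motif_summary(scan_motif(character(0)))))
  expect_error(scan_motif(c(a = "ACGT"), motif = ""), "non-empty")
})

test_that("motif scanning equals the quadratic brute-force oracle", {
  set.seed(99)
  seqs <- vapply(1:300, function(i) {
    paste(sample(c("A", "C", "G", "T"), sample(4:200, 1), replace = TRUE),
          collapse = "")
  }, character(1))
  names(seqs) <- paste0("s", 1:300)
  hits <- scan_motif(seqs, "GGAA")
  for (i in seq_along(seqs)) {
    expect_identical(hits$positions[[i]], oracle_motif_positions(seqs[[i]], "GGAA"))
  }
})

test_that("the printed motif-positive counts give the printed percentage", {
  # 115 motif-positive of 327: 35.2%
  set.seed(7)
  seqs <- simulate_motif_sequences(327, 115, lengths = 120)
  expect_equal(motif_summary(scan_motif(seqs)), 35.2)
})

test_that("TF site filtering applies inclusive window and strict score rules", {
  tss <- tibble::tibble(gene_id = c("gplus", "gminus"),
                        chrom = "chr1", strand = c("+", "-"),
                        tss = c(10000L, 50000L))
  sites <- tibble::tibble(
    tf_name = c("t1", "t2", "t3", "t4", "t5", "t6"),
    chrom = "chr1",
    position = c(10000L - 2500L,  # offset -2500, boundary in
                 10000L + 501L,   # offset +501, out
                 10000L,          # offset 0, score at 50 -> out
                 50000L + 2500L,  # minus strand: upstream = greater coord
                 50000L - 501L,   # minus strand: +501 downstream, out
                 10000L + 500L),  # offset +500, boundary in
    chip_score = c(51, 99, 50, 80, 80, 50.01),
    target_gene = c("gplus", "gplus", "gplus", "gminus", "gminus", "gplus")
  )
  kept <- filter_tf_sites(sites, tss)
  expect_setequal(kept$tf_name, c("t1", "t4", "t6"))
  expect_equal(kept$offset_from_tss[kept$tf_name == "t4"], -2500L)

  # subset + idempotence
  expect_true(all(kept$tf_name %in% sites$tf_name))
  expect_equal(filter_tf_sites(kept, tss), kept)

  # unknown target gene dropped with a warning
  bad <- dplyr::mutate(sites[1, ], target_gene = "ghost")
  expect_warning(res <- filter_tf_sites(dplyr::bind_rows(sites, bad), tss),
                 "no TSS")
  expect_setequal(res$tf_name, kept$tf_name)
})

test_that("TF ranking uses per-cohort correlations and the intersection rule", {
  set.seed(17)
  samples1 <- sprintf("a%02d", 1:40); samples2 <- sprintf("b%02d", 1:40)
  target1 <- rnorm(40); target2 <- rnorm(40)
  rows1 <- list(TGT = target1, tf_good = target1,
                tf_half = 0.9 * target1 + 0.43 * rnorm(40), tf_null = rnorm(40))
  rows2 <- list(TGT = target2, tf_good = target2,
                tf_half = rnorm(40), tf_null = rnorm(40))
  cohorts <- list(c1 = expr_from(rows1, samples1), c2 = expr_from(rows2, samples2))
  sites <- tibble::tibble(tf_name = c("tf_good", "tf_half", "tf_null"),
                          chrom = "chr1", position = 1L, chip_score = 60,
                          target_gene = "TGT", offset_from_tss = 0L)
  res <- rank_tf_candidates(sites, cohorts, "TGT")
  expect_equal(res$tf_name[1], "tf_good")
  expect_true(res$significant_all_cohorts[res$tf_name == "tf_good"])
  expect_false(res$significant_all_cohorts[res$tf_name == "tf_half"])
})
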