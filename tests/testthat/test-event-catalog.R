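test_that("GTF parsing builds transcript models with 0-based half-open coordinates", {
  models <- make_models(list(exons(100, 200, 400, 500, 700, 800)))
  path <- gtf_file(models)
  parsed <- read_gtf_models(path)
  expect_equal(nrow(parsed), 1)
  expect_equal(parsed$n_exons, 3L)
  expect_equal(parsed$exons[[1]], models$exons[[1]])

  # GTF 1-based inclusive 101..200 is internal (100, 200), length 100
  txt <- "chr1\tsrc\texon\t101\t200\t.\t+\t.\tgene_id \"g\"; transcript_id \"t\";"
  f <- withr::local_tempfile(fileext = ".gtf")
  writeLines(txt, f)
  one <- read_gtf_models(f)
  expect_equal(one$exons[[1]]$start, 100L)
  expect_equal(one$exons[[1]]$end, 200L)
  expect_equal(one$exons[[1]]$end - one$exons[[1]]$start, 100L)

  # two transcripts of one gene share gene_id
  two <- make_models(list(exons(100, 200, 400, 500), exons(100, 200)))
  parsed2 <- read_gtf_models(gtf_file(two))
  expect_equal(nrow(parsed2), 2)
  expect_equal(unique(parsed2$gene_id), "g1")
})

test_that("cassette and MXE events are enumerated with the expected junctions", {
  # {E1-E2-E3, E1-E3} -> one CASSETTE on E2
  m <- make_models(list(exons(100, 200, 400, 500, 700, 800),
                        exons(100, 200, 700, 800)))
  ev <- enumerate_events(m)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$event_type, "CASSETTE")
  expect_equal(ev$alt_start, 400L)
  expect_equal(ev$alt_end, 500L)
  expect_equal(nrow(ev$inclusion_junctions[[1]]), 2)
  expect_equal(nrow(ev$exclusion_junctions[[1]]), 1)
  # exclusion junction joins the flanks exactly
  expect_equal(ev$exclusion_junctions[[1]]$donor, 200L)
  expect_equal(ev$exclusion_junctions[[1]]$acceptor, 700L)

  # {E1-E2-E4, E1-E3-E4} with E2/E3 disjoint, never co-present -> one MXE
  m2 <- make_models(list(exons(100, 200, 400, 500, 1000, 1100),
                         exons(100, 200, 700, 800, 1000, 1100)))
  ev2 <- enumerate_events(m2)
  expect_equal(nrow(ev2), 1)
  expect_equal(ev2$event_type, "MXE")
  expect_equal(c(ev2$alt_start, ev2$alt_end), c(400L, 500L))

  # single-transcript gene contributes nothing
  expect_equal(nrow(enumerate_events(make_models(list(exons(1, 10, 20, 30))))), 0)
})

test_that("A5SS/A3SS typing is strand-aware and RI detects contained introns", {
  # same geometry, both strands: exon end moves (alternative donor on +)
  plus <- make_models(list(exons(100, 200, 400, 500),
                           exons(100, 250, 400, 500)), strand = "+")
  minus <- make_models(list(exons(100, 200, 400, 500),
                            exons(100, 250, 400, 500)), strand = "-")
  expect_equal(enumerate_events(plus)$event_type, "A5SS")
  expect_equal(enumerate_events(minus)$event_type, "A3SS")
  expect_equal(enumerate_events(plus)$alt_length, 50L)

  ri <- make_models(list(exons(100, 200, 400, 500), exons(100, 500)))
  ev <- enumerate_events(ri)
  expect_equal(ev$event_type, "RI")
  expect_equal(c(ev$alt_start, ev$alt_end), c(200L, 400L))
  expect_equal(nrow(ev$inclusion_junctions[[1]]), 0)
})

test_that("event enumeration is order-invariant and matches the brute-force oracle", {
  set.seed(42)
  for (rep in 1:25) {
    m <- random_gene_models(gene_id = sprintf("g%02d", rep))
    ev <- enumerate_events(m)
    expect_equal(event_signatures(ev), oracle_enumerate_signatures(m),
                 info = sprintf("random gene %d", rep))
    # permuting transcript order leaves the event set unchanged
    perm <- m[sample(nrow(m)), ]
    expect_equal(event_signatures(enumerate_events(perm)), event_signatures(ev))
    # every emitted alt segment has positive length equal to end - start
    if (nrow(ev) > 0) {
      expect_true(all(ev$alt_length >= 1))
      expect_equal(ev$alt_length, ev$alt_end - ev$alt_start)
      # inclusion and exclusion junction sets never intersect
      for (i in seq_len(nrow(ev))) {
        inc <- ev$inclusion_junctions[[i]]; exc <- ev$exclusion_junctions[[i]]
        shared <- dplyr::inner_join(inc, exc, by = c("donor", "acceptor"))
        expect_equal(nrow(shared), 0)
      }
    }
  }
})

test_that("the coding-region flag follows CDS overlap of inclusion transcripts", {
  cds_in <- make_models(list(exons(100, 200, 400, 500, 700, 800),
                             exons(100, 200, 700, 800)),
                        cds_sets = list(exons(150, 200, 400, 500, 700, 750),
                                        exons(150, 200, 700, 750)))
  expect_true(enumerate_events(cds_in)$in_cds)
  no_cds <- make_models(list(exons(100, 200, 400, 500, 700, 800),
                             exons(100, 200, 700, 800)),
                        cds_sets = list(exons(150, 200), exons(150, 200)))
  expect_false(enumerate_events(no_cds)$in_cds)
})

test_that("event sequences are sliced sense-strand with correct length", {
  ev <- make_cassette_event(alt_start = 2L, alt_end = 6L, up_donor = 0L,
                            down_acceptor = 8L)
  genome <- c(chr1 = "AAGGAACC")
  expect_equal(unname(event_sequences(ev, genome)), "GGAA")
  ev_minus <- dplyr::mutate(ev, strand = "-")
  expect_equal(unname(event_sequences(ev_minus, genome)), "TTCC")

  # an 84-bp alternative exon yields an 84-nt sequence
  ev84 <- make_cassette_event(alt_start = 100L, alt_end = 184L, up_donor = 50L,
                              down_acceptor = 300L)
  genome84 <- c(chr1 = paste(rep("ACGT", 100), collapse = ""))
  expect_equal(nchar(unname(event_sequences(ev84, genome84))), 84L)

  expect_error(event_sequences(ev, c(chr2 = "AAAA")), "absent")
  ev_far <- make_cassette_event(alt_start = 2L, alt_end = 600L)
  expect_error(event_sequences(ev_far, genome), "beyond")
})

test_that("the event catalog round-trips through its TSV serialization", {
  m <- make_models(list(exons(100, 200, 400, 500, 700, 800),
                        exons(100, 200, 700, 800)))
  ev <- enumerate_events(m)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_event_catalog(ev, f)
  back <- read_event_catalog(f)
  expect_equal(event_signatures(back), event_signatures(ev))
  expect_equal(back$inclusion_junctions[[1]], ev$inclusion_junctions[[1]])
})
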