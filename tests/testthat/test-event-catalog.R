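# Shared fixture: a two-isoform gene with one skipped internal exon.
se_db <- function(strand = "+") {
  mk_db(
    mk_tx("INC", "G", list(c(100, 200), c(300, 400), c(500, 600)),
          strand = strand, biotype = "nmd"),
    mk_tx("SKP", "G", list(c(100, 200), c(500, 600)),
          strand = strand, cds_end = if (strand == "+") 550 else 150)
  )
}

test_that("a two-isoform cassette gene yields exactly one SE event", {
  ev <- enumerate_events(se_db())
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$event_type, "SE")
  # inclusion junctions share the skipped exon's boundaries
  expect_equal(c(ev$j1_start, ev$j1_end), c(200L, 300L))
  expect_equal(c(ev$j2_start, ev$j2_end), c(400L, 500L))
  # skipping junction spans both
  expect_equal(c(ev$j3_start, ev$j3_end), c(200L, 500L))
  expect_equal(c(ev$alt_start, ev$alt_end), c(300L, 400L))
})

test_that("single-transcript genes yield no events", {
  db <- mk_db(mk_tx("T1", "G", list(c(100, 200), c(300, 400)),
                    biotype = "noncoding"))
  expect_equal(nrow(enumerate_events(db)), 0L)
})

test_that("alternative 3'ss with 176-nt shifted acceptor yields one A3 event", {
  # same donor at 400, acceptors at 800 vs 624 (176 nt apart), long/short
  # junction roles assigned by intron width
  db <- mk_db(
    mk_tx("P", "G", list(c(100, 400), c(800, 1100)), cds_end = 1050),
    mk_tx("N", "G", list(c(100, 400), c(624, 1100)), biotype = "nmd")
  )
  ev <- enumerate_events(db)
  expect_equal(ev$event_type, "A3")
  expect_equal(c(ev$j1_start, ev$j1_end), c(400L, 800L))   # long
  expect_equal(c(ev$j2_start, ev$j2_end), c(400L, 624L))   # short
  expect_equal(ev$alt_end - ev$alt_start, 176L)
})

test_that("A3/A5 orientation is strand-aware", {
  # on the minus strand the donor is the genomic-right end of the intron
  db_minus <- mk_db(
    mk_tx("P", "G", list(c(100, 400), c(800, 1100)), strand = "-",
          cds_end = 150),
    mk_tx("N", "G", list(c(100, 376), c(800, 1100)), strand = "-",
          biotype = "nmd")
  )
  ev <- enumerate_events(db_minus)
  expect_equal(ev$event_type, "A3")  # shared donor 800, acceptors differ
})

test_that("exitron geometry yields an RI event with its parent exon", {
  db <- mk_db(
    mk_tx("HOST", "G", list(c(100, 600), c(800, 1000)), cds_end = 950),
    mk_tx("SPLIT", "G", list(c(100, 250), c(400, 600), c(800, 1000)),
          biotype = "nmd")
  )
  ev <- enumerate_events(db)
  ri <- ev[ev$event_type == "RI", ]
  expect_equal(nrow(ri), 1L)
  expect_equal(c(ri$j1_start, ri$j1_end), c(250L, 400L))
  expect_equal(ri$parent_exons, "100-600")
  # an intron abutting the host exon edge is not an RI event
  db2 <- mk_db(
    mk_tx("HOST", "G", list(c(250, 600)), biotype = "noncoding"),
    mk_tx("EDGE", "G", list(c(100, 250), c(400, 600)), biotype = "nmd")
  )
  expect_equal(nrow(enumerate_events(db2)), 0L)
  db3 <- mk_db(
    mk_tx("HOST", "G", list(c(50, 400)), biotype = "noncoding"),
    mk_tx("IN", "G", list(c(100, 250), c(400, 600)), biotype = "nmd")
  )
  expect_equal(nrow(enumerate_events(db3)), 0L)  # right edge abuts
})

test_that("SE classification applies the skipping rule before inclusion", {
  db <- se_db()
  labs <- extract_junction_labels(db)
  ev <- classify_event_nmd(enumerate_events(db), labs)
  expect_equal(ev$label, "EI_NMD")  # inclusion junctions exclusive to nmd tx
  # force both skipping and inclusion junctions NMD: skipping wins
  labs2 <- data.table::copy(labs)[, label := "NMD"]
  ev2 <- classify_event_nmd(enumerate_events(db), labs2)
  expect_equal(ev2$label, "ES_NMD")
  # all junctions coding -> cassette exon
  labs3 <- data.table::copy(labs)[, label := "coding"]
  ev3 <- classify_event_nmd(enumerate_events(db), labs3)
  expect_equal(ev3$label, "cassette_exon")
})

test_that("A3 with both junctions NMD is dropped as complex", {
  db <- mk_db(
    mk_tx("P", "G", list(c(100, 400), c(800, 1100)), cds_end = 1050),
    mk_tx("N", "G", list(c(100, 400), c(624, 1100)), biotype = "nmd")
  )
  ev <- enumerate_events(db)
  labs <- extract_junction_labels(db)
  labs_both <- data.table::copy(labs)[, label := "NMD"]
  expect_equal(classify_event_nmd(ev, labs_both)$label, "dropped_complex")
  cl <- classify_event_nmd(ev, labs)
  expect_equal(cl$label, "A3_NMD")
  expect_equal(cl$nmd_role, "short")  # the shifted (shorter) intron is NMD
  labs_none <- data.table::copy(labs)[, label := "coding"]
  expect_equal(classify_event_nmd(ev, labs_none)$label, "non_NMD")
})

test_that("classification errors on junctions missing from the label table", {
  db <- se_db()
  ev <- enumerate_events(db)
  labs <- extract_junction_labels(db)[-1]
  expect_error(classify_event_nmd(ev, labs), "absent from label table")
})

test_that("native enumeration equals the pairwise-comparison oracle", {
  db <- simulate_gene_models(n_genes = 40, max_isoforms = 6, seed = 17)
  got <- canonical_events(enumerate_events(db))
  want <- oracle_enumerate_events(db)
  expect_equal(as.data.frame(got), as.data.frame(want))
})

test_that(".ioe event ids decode to the documented coordinates", {
  f <- tempfile(fileext = ".ioe")
  writeLines(c(
    "seqname\tgene_id\tevent_id\talternative_transcripts\ttotal_transcripts",
    "chr1\tG1\tG1;SE:chr1:200-301:400-501:+\tT2\tT1,T2",
    "chr1\tG1\tG1;MX:chr1:1-2:3-4:5-6:7-8:+\tT2\tT1,T2"
  ), f)
  expect_warning(ev <- read_ioe(f), "unsupported type")
  expect_equal(nrow(ev), 1L)
  # 1-based boundary pairs -> 0-based half-open introns
  expect_equal(c(ev$j1_start, ev$j1_end), c(200L, 300L))
  expect_equal(c(ev$j2_start, ev$j2_end), c(400L, 500L))
  expect_equal(c(ev$j3_start, ev$j3_end), c(200L, 500L))
})

test_that(".ioe ingest handles empty files and malformed ids", {
  f <- tempfile()
  writeLines("seqname\tgene_id\tevent_id\talternative_transcripts\ttotal_transcripts", f)
  expect_equal(nrow(read_ioe(f)), 0L)
  f2 <- tempfile()
  writeLines(c("seqname\tgene_id\tevent_id\ta\tb",
               "chr1\tG1\tnot_an_event_id\t.\t."), f2)
  expect_error(read_ioe(f2), "line 2")
})

test_that(".ioe round trip reproduces native enumeration exactly", {
  sim <- generate_annotation(sim_config(n_genes = 20, seed = 13))
  ev <- enumerate_events(sim$db)
  f <- tempfile(fileext = ".ioe")
  write_ioe(ev, f)
  ev2 <- read_ioe(f)
  cols <- c("event_type", "chrom", "strand", "j1_start", "j1_end",
            "j2_start", "j2_end", "j3_start", "j3_end", "alt_start",
            "alt_end", "parent_exons")
  o <- function(x) as.data.frame(data.table::setorder(
    as.data.table(x)[, ..cols], event_type, chrom, j1_start, j1_end))
  expect_equal(o(ev), o(ev2))
})
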