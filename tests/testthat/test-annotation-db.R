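test_that("GTF ingest maps biotypes and coordinates correctly", {
  gtf <- tempfile(fileext = ".gtf")
  writeLines(c(
    paste("chr1", "x", "exon", 101, 300, ".", "+", ".",
          'gene_id "G1"; transcript_id "T1"; gene_name "GN1"; transcript_type "nonsense_mediated_decay";',
          sep = "\t"),
    paste("chr1", "x", "exon", 501, 1000, ".", "+", ".",
          'gene_id "G1"; transcript_id "T1"; gene_name "GN1"; transcript_type "nonsense_mediated_decay";',
          sep = "\t")
  ), gtf)
  db <- load_annotations(gtf = gtf)
  expect_equal(nrow(db$transcripts), 1L)
  expect_equal(db$transcripts$biotype, "nmd")
  # 1-based inclusive GTF -> 0-based half-open internal
  expect_equal(db$exons$start, c(100L, 500L))
  expect_equal(db$exons$end, c(300L, 1000L))
})

test_that("empty annotation input yields an empty database", {
  f <- tempfile(fileext = ".gtf")
  file.create(f)
  db <- load_annotations(gtf = f)
  expect_s3_class(db, "transcript_db")
  expect_equal(nrow(db$transcripts), 0L)
  expect_equal(nrow(extract_junction_labels(db)), 0L)
})

test_that("genePred ingest assigns biotypes by accession prefix", {
  gp <- tempfile(fileext = ".txt")
  # NR_ with 2 exons and NM_ with 4 exons sharing one intron (1000-2000)
  writeLines(c(
    paste("NR_000001", "chr2", "+", 500, 2500, 500, 500, 2,
          "500,2000,", "1000,2500,", "GENEA", sep = "\t"),
    paste("NM_000001", "chr2", "+", 500, 5000, 500, 4800, 4,
          "500,2000,3000,4500,", "1000,2600,4000,5000,", "GENEA", sep = "\t")
  ), gp)
  db <- load_annotations(genepred = gp)
  expect_setequal(db$transcripts$biotype, c("noncoding", "protein_coding"))
  expect_true(is.na(db$transcripts[transcript_id == "NR_000001", cds_end]))
  expect_equal(db$transcripts[transcript_id == "NM_000001", cds_end], 4799L)
  # shared intron counted once: 3 distinct junction keys
  labs <- extract_junction_labels(db)
  expect_equal(nrow(labs), 3L)
  shared <- labs[intron_start == 1000 & intron_end == 2000]
  expect_equal(shared$label, "coding")  # NM_ support makes it coding
  only_nm <- labs[intron_start == 2600]
  expect_equal(only_nm$label, "coding")
})

test_that("malformed genePred rows raise a parse error naming the line", {
  gp <- tempfile()
  writeLines(paste("NM_1", "chr1", "+", "abc", 100, 0, 0, 1,
                   "10,", "100,", "G", sep = "\t"), gp)
  expect_error(load_annotations(genepred = gp), "line 1")
  gp2 <- tempfile()
  writeLines("too\tfew\tfields", gp2)
  expect_error(load_annotations(genepred = gp2), "line 1")
})

test_that("junction labels follow the transcript-exclusivity rule", {
  # shared junction 200-300 in a coding and an nmd transcript -> coding;
  # junction 400-500 only in the nmd transcript -> NMD
  db <- mk_db(
    mk_tx("C1", "G", list(c(100, 200), c(300, 400), c(500, 600)),
          biotype = "protein_coding", cds_end = 550),
    mk_tx("N1", "G", list(c(100, 200), c(300, 350), c(400, 450), c(500, 600)),
          biotype = "nmd")
  )
  labs <- extract_junction_labels(db)
  expect_equal(labs[intron_start == 200 & intron_end == 300, label], "coding")
  expect_equal(labs[intron_start == 350 & intron_end == 400, label], "NMD")
  # every junction appears exactly once
  expect_equal(anyDuplicated(labs[, .(chrom, intron_start, intron_end, strand)]), 0L)
})

test_that("single-exon-only databases yield no junctions", {
  db <- mk_db(mk_tx("S1", "G", list(c(100, 500)), biotype = "noncoding"))
  expect_equal(nrow(extract_junction_labels(db)), 0L)
})

test_that("unrecognized biotypes count as non-NMD for exclusivity", {
  db <- mk_db(
    mk_tx("O1", "G", list(c(100, 200), c(300, 400)), biotype = "other"),
    mk_tx("N1", "G", list(c(100, 200), c(300, 400)), biotype = "nmd")
  )
  labs <- extract_junction_labels(db)
  expect_equal(labs$label, "coding")
})

test_that("short introns are excluded from the junction table", {
  db <- mk_db(mk_tx("T1", "G", list(c(100, 200), c(210, 300), c(400, 500)),
                    biotype = "noncoding"))
  labs <- extract_junction_labels(db, min_intron_length = 20L)
  expect_equal(nrow(labs), 1L)
  expect_equal(labs$intron_start, 300L)
  labs0 <- extract_junction_labels(db, min_intron_length = 1L)
  expect_equal(nrow(labs0), 2L)
})

test_that("PTC rule: spliced-distance boundary at 50 nt, both strands", {
  # plus strand: exon1 200 nt, exon2 100 nt; junction at spliced pos 200.
  # stop last base at spliced pos p gives distance 200 - p.
  mk_boundary_db <- function(dist, strand = "+") {
    p <- 200L - dist          # spliced position of stop last base (1-based)
    if (strand == "+") {
      g <- 100L + p - 1L      # exon1 covers [100,300): base i at 100+i-1
      mk_tx("B", "G", list(c(100, 300), c(400, 500)), cds_end = g,
            strand = strand)
    } else {
      # mirrored: exon1 (5'-most) is the genomic-right exon [400,600)
      g <- 600L - p
      mk_tx("B", "G", list(c(100, 200), c(400, 600)), cds_end = g,
            strand = strand)
    }
  }
  for (st in c("+", "-")) {
    v49 <- evaluate_ptc_rule(mk_db(mk_boundary_db(49L, st)))
    v50 <- evaluate_ptc_rule(mk_db(mk_boundary_db(50L, st)))
    v51 <- evaluate_ptc_rule(mk_db(mk_boundary_db(51L, st)))
    expect_equal(v49$verdict, "not_nmd")
    expect_equal(v49$ptc_distance, 49L)
    expect_equal(v50$verdict, "nmd_predicted")
    expect_equal(v50$ptc_distance, 50L)
    expect_equal(v51$verdict, "nmd_predicted")
  }
})

test_that("PTC rule: stop in last exon, missing CDS, bad CDS", {
  last_exon <- mk_db(mk_tx("L", "G", list(c(100, 300), c(400, 500)),
                           cds_end = 450))
  expect_equal(evaluate_ptc_rule(last_exon)$verdict, "not_nmd")
  no_cds <- mk_db(mk_tx("N", "G", list(c(100, 300), c(400, 500)),
                        biotype = "noncoding"))
  expect_equal(evaluate_ptc_rule(no_cds)$verdict, "not_applicable")
  single <- mk_db(mk_tx("S", "G", list(c(100, 300)), cds_end = 150))
  expect_equal(evaluate_ptc_rule(single)$verdict, "not_applicable")
  # cds_end in an intron is a data error
  bad <- mk_db(mk_tx("X", "G", list(c(100, 200), c(400, 500)),
                     biotype = "noncoding"))
  bad$transcripts[, cds_end := 300L]
  expect_error(evaluate_ptc_rule(bad), "outside its exons")
})

test_that("junction labeling agrees with the brute-force exclusivity oracle", {
  db <- simulate_gene_models(n_genes = 60, max_isoforms = 5, seed = 42)
  got <- extract_junction_labels(db)
  want <- oracle_junction_labels(db)
  expect_equal(as.data.frame(got[, .(chrom, intron_start, intron_end, strand, label)]),
               as.data.frame(want))
})

test_that("loading identical files twice is byte-identical after reserialization", {
  sim <- generate_annotation(sim_config(n_genes = 10, seed = 3))
  d <- tempfile(); dir.create(d)
  write_fixtures(sim, d, n_replicates = 1)
  gtf <- file.path(d, "annotation.gtf")
  gp <- file.path(d, "annotation.genePred")
  db1 <- load_annotations(gtf = gtf, genepred = gp)
  db2 <- load_annotations(gtf = gtf, genepred = gp)
  f1 <- tempfile(); f2 <- tempfile()
  write_transcript_db(db1, f1)
  write_transcript_db(db2, f2)
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
})

test_that("transcript_db JSON-lines serialization round-trips", {
  sim <- generate_annotation(sim_config(n_genes = 8, seed = 9))
  f <- tempfile()
  write_transcript_db(sim$db, f)
  db2 <- read_transcript_db(f)
  expect_equal(as.data.frame(db2$transcripts), as.data.frame(sim$db$transcripts))
  expect_equal(as.data.frame(db2$exons), as.data.frame(sim$db$exons))
})
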