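test_that("STAR SJ.out.tab fields map onto junction records", {
  f <- tempfile()
  writeLines(c("chr1\t1001\t1100\t1\t0\t1\t7\t2\t38",
               "chr2\t501\t900\t2\t2\t1\t4\t0\t25"), f)
  sj <- read_star_sj(f, "s1")
  expect_equal(nrow(sj), 2L)
  expect_equal(sj$intron_start, c(1000L, 500L))  # 1-based first base -> 0-based
  expect_equal(sj$intron_end, c(1100L, 900L))
  expect_equal(sj$strand, c("+", "-"))            # strand code 2 = minus
  expect_equal(sj$unique_reads, c(7L, 4L))
})

test_that("SJ reader rejects malformed input and accepts empty files", {
  f <- tempfile(); file.create(f)
  expect_equal(nrow(read_star_sj(f, "s")), 0L)
  f2 <- tempfile()
  writeLines("chr1\t10\t20\t1\t0\t1\t5", f2)
  expect_error(read_star_sj(f2, "s"), "expected 9 columns")
  f3 <- tempfile()
  writeLines("chr1\t10\t20\t1\t0\t1\t-5\t0\t30", f3)
  expect_error(read_star_sj(f3, "s"), "negative")
})

test_that("cassette PSI follows the inclusion formula and its complement", {
  expect_equal(psi_cassette(12, 3, "EI"), 12 / 18)
  expect_equal(psi_cassette(12, 3, "ES"), 1 - 12 / 18)
  expect_equal(psi_cassette(5, 0, "EI"), 1)
  expect_true(is.na(psi_cassette(0, 0, "EI")))
  # complementarity on random counts
  set.seed(1)
  inc <- rpois(1000, 20); skp <- rpois(1000, 10)
  ok <- inc + skp > 0
  expect_equal(psi_cassette(inc, skp, "EI")[ok] + psi_cassette(inc, skp, "ES")[ok],
               rep(1, sum(ok)))
})

test_that("alternative splice-site PSI is the NMD fraction of junction reads", {
  expect_equal(psi_alt_ss(3, 97), 0.03)
  expect_equal(psi_alt_ss(0, 10), 0)
  expect_equal(psi_alt_ss(5, 0), 1)
  expect_true(is.na(psi_alt_ss(0, 0)))
})

test_that("alternative intron PSI clips at the exon-expression estimate", {
  expect_equal(psi_alt_intron(10, 8, 12), 1.0)
  expect_equal(psi_alt_intron(25, 8, 12), 1.0)  # clipped
  expect_equal(psi_alt_intron(0, 8, 12), 0)
  expect_equal(psi_alt_intron(5, 8, 12), 0.5)
  expect_true(is.na(psi_alt_intron(5, 0, 0)))
})

test_that("all PSI estimators stay in [0, 1] on random inputs", {
  set.seed(2)
  for (i in 1:200) {
    a <- sample(0:50, 3, replace = TRUE)
    v <- c(psi_cassette(a[1], a[2], "EI"), psi_cassette(a[1], a[2], "ES"),
           psi_alt_ss(a[1], a[2]), psi_alt_intron(a[1], a[2], a[3]))
    v <- v[!is.na(v)]
    expect_true(all(v >= 0 & v <= 1))
  }
})

test_that("SE role counts sum inclusion junctions and merge shared exons", {
  # two SE events over the same alternative exon via different flanks
  db <- mk_db(
    mk_tx("I1", "G", list(c(100, 200), c(300, 400), c(500, 600)),
          biotype = "nmd"),
    mk_tx("S1", "G", list(c(100, 200), c(500, 600)), cds_end = 550),
    mk_tx("I2", "G", list(c(50, 180), c(300, 400), c(650, 700)),
          biotype = "nmd"),
    mk_tx("S2", "G", list(c(50, 180), c(650, 700)), cds_end = 680)
  )
  labs <- extract_junction_labels(db)
  ev <- classify_event_nmd(enumerate_events(db), labs)
  expect_equal(sum(ev$event_type == "SE"), 2L)
  cnt <- mk_counts(c("chr1:200-300:+" = 4, "chr1:400-500:+" = 8,
                     "chr1:180-300:+" = 2, "chr1:400-650:+" = 1,
                     "chr1:200-500:+" = 3, "chr1:180-650:+" = 2))
  agg <- aggregate_event_counts(ev, cnt)
  expect_equal(nrow(agg), 1L)  # merged by shared alternative exon
  expect_equal(agg$sj_inc, 4L + 8L + 2L + 1L)
  expect_equal(agg$sj_skip, 3L + 2L)
  expect_equal(agg$n_events, 2L)
})

test_that("RI role counts sum all junctions at the parent exon splice sites", {
  db <- mk_db(
    mk_tx("HOST", "G", list(c(100, 600), c(800, 1000)), cds_end = 950),
    mk_tx("HOST2", "G", list(c(50, 600), c(800, 1000)), cds_end = 950),
    mk_tx("SPLIT", "G", list(c(100, 250), c(400, 600), c(800, 1000)),
          biotype = "nmd")
  )
  labs <- extract_junction_labels(db)
  ev <- classify_event_nmd(enumerate_events(db), labs)
  ri <- ev[ev$event_type == "RI", ]
  expect_equal(nrow(ri), 1L)
  expect_equal(ri$parent_exons, "50-600,100-600")
  # 5' splice sites of both parent exons end at 600 -> junction 600-800;
  # plant an extra upstream junction into exon start 100
  cnt <- mk_counts(c("chr1:250-400:+" = 10, "chr1:600-800:+" = 12,
                     "chr1:20-100:+" = 5, "chr1:20-50:+" = 7))
  agg <- aggregate_event_counts(ev, cnt)
  ragg <- agg[agg$event_type == "RI", ]
  expect_equal(ragg$sj_ai, 10L)
  expect_equal(ragg$sj_3p, 5L + 7L)   # junctions into either parent 3'ss
  expect_equal(ragg$sj_5p, 12L)
  expect_equal(psi_alt_intron(ragg$sj_ai, ragg$sj_3p, ragg$sj_5p), 10 / 12)
})

test_that("events with no observed junctions give zero counts and NA PSI", {
  db <- mk_db(
    mk_tx("INC", "G", list(c(100, 200), c(300, 400), c(500, 600)),
          biotype = "nmd"),
    mk_tx("SKP", "G", list(c(100, 200), c(500, 600)), cds_end = 550)
  )
  labs <- extract_junction_labels(db)
  ev <- classify_event_nmd(enumerate_events(db), labs)
  cnt <- mk_counts(c("chr9:1-100:+" = 5))
  recs <- quantify_events(ev, cnt)
  expect_equal(recs$sj_inc, 0L)
  expect_equal(recs$sj_skip, 0L)
  expect_true(is.na(recs$psi))
  filtered <- apply_filters(recs)
  expect_false(filtered$passed_filters)
  expect_match(filtered$fail_reasons, "zero_denominator")
})

test_that("undefined-strand junction rows match only when allowed", {
  db <- mk_db(
    mk_tx("INC", "G", list(c(100, 200), c(300, 400), c(500, 600)),
          biotype = "nmd"),
    mk_tx("SKP", "G", list(c(100, 200), c(500, 600)), cds_end = 550)
  )
  ev <- classify_event_nmd(enumerate_events(db), extract_junction_labels(db))
  cnt <- mk_counts(c("chr1:200-300:*" = 6, "chr1:400-500:+" = 6,
                     "chr1:200-500:+" = 6))
  strict <- quantify_events(ev, cnt)
  loose <- quantify_events(ev, cnt, allow_unstranded = TRUE)
  expect_equal(strict$sj_inc, 6L)
  expect_equal(loose$sj_inc, 12L)
})

test_that("abundance filters use inclusive thresholds on the NMD role", {
  recs <- data.table::data.table(
    group_id = sprintf("g%d", 1:5), event_type = "SE", label = "EI_NMD",
    gene_id = sprintf("G%d", 1:5), gene_symbol = sprintf("G%d", 1:5),
    chrom = "chr1", strand = "+", sample_id = "s1",
    event_ids = "e", n_events = 1L,
    sj_inc = c(2L, 3L, 3L, 50L, 0L), sj_skip = c(10L, 10L, 60L, 10L, 0L),
    sj_nmd = NA_integer_, sj_coding = NA_integer_, sj_ai = NA_integer_,
    sj_3p = NA_integer_, sj_5p = NA_integer_,
    psi = c(2 / 22, 3 / 23, 3 / 123, 50 / 70, NA),
    nmd_reads = c(2L, 3L, 3L, 50L, 0L))
  out <- apply_filters(recs, min_junction_reads = 3L, min_psi = 0.03)
  expect_equal(out$passed_filters, c(FALSE, TRUE, FALSE, TRUE, FALSE))
  expect_match(out$fail_reasons[1], "low_junction_reads")
  expect_match(out$fail_reasons[3], "low_psi")
  expect_match(out$fail_reasons[5], "zero_denominator")
  # exact boundary: psi == 0.03 with 3 NMD reads passes
  b <- data.table::copy(recs[2])[, `:=`(psi = 0.03)]
  expect_true(apply_filters(b)$passed_filters)
})

test_that("filters are monotone under threshold tightening", {
  set.seed(3)
  recs <- data.table::data.table(
    group_id = sprintf("g%d", 1:200), event_type = "SE", label = "EI_NMD",
    gene_id = "G", gene_symbol = "G", chrom = "chr1", strand = "+",
    sample_id = "s1", event_ids = "e", n_events = 1L,
    sj_inc = rpois(200, 5), sj_skip = rpois(200, 5),
    sj_nmd = NA_integer_, sj_coding = NA_integer_, sj_ai = NA_integer_,
    sj_3p = NA_integer_, sj_5p = NA_integer_)
  recs[, psi := psi_cassette(sj_inc, sj_skip, "EI")]
  recs[, nmd_reads := sj_inc]
  prev <- Inf
  for (mr in c(0, 2, 4, 8)) {
    n <- sum(apply_filters(recs, min_junction_reads = mr)$passed_filters)
    expect_lte(n, prev); prev <- n
  }
  prev <- Inf
  for (mp in c(0, 0.05, 0.2, 0.6)) {
    n <- sum(apply_filters(recs, min_psi = mp)$passed_filters)
    expect_lte(n, prev); prev <- n
  }
})

test_that("gene catalog counts each gene once across multiple event types", {
  recs <- data.table::data.table(
    group_id = c("e1", "e2", "e3"), event_type = c("SE", "RI", "SE"),
    label = c("EI_NMD", "AI_NMD", "EI_NMD"),
    gene_id = c("G1", "G1", "G2"), gene_symbol = c("S1", "S1", "S2"),
    chrom = "chr1", strand = "+", sample_id = "s1", event_ids = "e",
    n_events = 1L, sj_inc = 10L, sj_skip = 10L, sj_nmd = 10L,
    sj_coding = 10L, sj_ai = 10L, sj_3p = 10L, sj_5p = 10L,
    psi = c(0.4, 0.5, 0.001), nmd_reads = 10L)
  out <- summarize_gene_catalog(apply_filters(recs))
  expect_equal(out$summary$n_genes, 1L)  # G2 fails min_psi
  expect_equal(nrow(out$events), 2L)
  per <- out$summary$genes_per_label
  expect_equal(per[per$label == "EI_NMD", ]$n_genes, 1L)
  expect_equal(per[per$label == "AI_NMD", ]$n_genes, 1L)
  # empty input -> empty catalog
  empty <- summarize_gene_catalog(apply_filters(recs[0]))
  expect_equal(empty$summary$n_genes, 0L)
})

test_that("pooled aggregation sums counts across samples before PSI", {
  c1 <- mk_counts(c("chr1:200-300:+" = 2), "a")
  c2 <- mk_counts(c("chr1:200-300:+" = 5, "chr1:400-500:+" = 1), "b")
  pooled <- pool_junction_counts(list(c1, c2))
  expect_equal(nrow(pooled), 2L)
  expect_equal(pooled[pooled$intron_start == 200, ]$unique_reads, 7L)
})
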