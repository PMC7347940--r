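library(data.table)

# ---- hand-built transcript fixtures -------------------------------------
# mk_tx: one transcript spec; exons given as list of c(start, end),
# 0-based half-open, in genomic order.
mk_tx <- function(id, gene, exons, strand = "+", chrom = "chr1",
                  cds_end = NA_integer_, biotype = "protein_coding",
                  source = "gencode", symbol = gene) {
  ex <- rbindlist(lapply(exons, function(e)
    data.table(start = as.integer(e[1]), end = as.integer(e[2]))))
  setorder(ex, start)
  n <- nrow(ex)
  rk <- if (strand == "+") seq_len(n) else rev(seq_len(n))
  list(
    tx = data.table(source = source, transcript_id = id, gene_id = gene,
                    gene_symbol = symbol, chrom = chrom, strand = strand,
                    biotype = biotype, cds_end = as.integer(cds_end)),
    ex = data.table(source = source, transcript_id = id, gene_id = gene,
                    chrom = chrom, strand = strand, start = ex$start,
                    end = ex$end, exon_rank = as.integer(rk))
  )
}

mk_db <- function(...) {
  parts <- list(...)
  transcript_db(rbindlist(lapply(parts, `[[`, "tx")),
                rbindlist(lapply(parts, `[[`, "ex")))
}

# junction-count table from a named vector "chrom:start-end:strand" -> n
mk_counts <- function(counts, sample_id = "s1") {
  ks <- names(counts)
  parts <- strsplit(ks, "[:-]")
  data.table(
    sample_id = sample_id,
    chrom = vapply(parts, `[`, "", 1L),
    intron_start = as.integer(vapply(parts, `[`, "", 2L)),
    intron_end = as.integer(vapply(parts, `[`, "", 3L)),
    strand = vapply(parts, `[`, "", 4L),
    unique_reads = as.integer(unname(counts)),
    multimap_reads = 0L, max_overhang = 30L)
}

# ---- independent brute-force oracles ------------------------------------

# junction labels: for every junction of every multi-exon transcript,
# enumerate all transcripts containing it with plain loops and apply the
# exclusivity rule directly.
oracle_junction_labels <- function(db, min_intron_length = 20L) {
  tx <- as.data.frame(db$transcripts)
  ex <- as.data.frame(db$exons)
  jmap <- list()
  for (i in seq_len(nrow(tx))) {
    e <- ex[ex$source == tx$source[i] & ex$transcript_id == tx$transcript_id[i], ]
    e <- e[order(e$start), ]
    if (nrow(e) < 2L) next
    for (j in seq_len(nrow(e) - 1L)) {
      s <- e$end[j]; en <- e$start[j + 1L]
      if (en - s < min_intron_length) next
      key <- paste(e$chrom[1], s, en, e$strand[1], sep = ":")
      jmap[[key]] <- c(jmap[[key]], tx$biotype[i])
    }
  }
  if (!length(jmap))
    return(data.table(chrom = character(), intron_start = integer(),
                      intron_end = integer(), strand = character(),
                      label = character()))
  out <- rbindlist(lapply(names(jmap), function(k) {
    f <- strsplit(k, ":", fixed = TRUE)[[1]]
    data.table(chrom = f[1], intron_start = as.integer(f[2]),
               intron_end = as.integer(f[3]), strand = f[4],
               label = if (all(jmap[[k]] %in% c("nmd", "noncoding")))
                 "NMD" else "coding")
  }))
  setorder(out, chrom, intron_start, intron_end, strand)
  out[]
}

# event enumeration: exhaustive pairwise transcript comparison with
# explicit loops; returns canonical coordinate rows for SE/A3/A5/RI.
oracle_enumerate_events <- function(db, min_intron_length = 20L) {
  ex <- as.data.frame(db$exons)
  tx <- as.data.frame(db$transcripts)
  res <- list()
  emit <- function(type, chrom, strand, j1, j2, j3 = c(NA, NA)) {
    res[[length(res) + 1L]] <<- data.table(
      event_type = type, chrom = chrom, strand = strand,
      j1_start = as.integer(j1[1]), j1_end = as.integer(j1[2]),
      j2_start = as.integer(j2[1]), j2_end = as.integer(j2[2]),
      j3_start = as.integer(j3[1]), j3_end = as.integer(j3[2]))
  }
  for (g in unique(tx$gene_id)) {
    ids <- which(tx$gene_id == g)
    exl <- lapply(ids, function(i) {
      e <- ex[ex$source == tx$source[i] & ex$transcript_id == tx$transcript_id[i], ]
      e[order(e$start), c("start", "end")]
    })
    strand <- tx$strand[ids[1]]
    chrom <- tx$chrom[ids[1]]
    introns_of <- function(e) {
      if (nrow(e) < 2L) return(NULL)
      data.frame(s = e$end[-nrow(e)], e = e$start[-1L],
                 lx_s = e$start[-nrow(e)], lx_e = e$end[-nrow(e)],
                 rx_s = e$start[-1L], rx_e = e$end[-1L])
    }
    intl <- lapply(exl, introns_of)
    intl <- lapply(intl, function(d)
      if (is.null(d)) d else d[d$e - d$s >= min_intron_length, , drop = FALSE])
    for (ai in seq_along(exl)) for (bi in seq_along(exl)) {
      if (ai == bi) next
      A <- exl[[ai]]; B <- exl[[bi]]
      ia <- intl[[ai]]; ib <- intl[[bi]]
      # SE: internal exon of A skipped by a junction of B
      if (nrow(A) >= 3L && !is.null(ib)) {
        for (i in 2:(nrow(A) - 1L)) {
          up <- c(A$end[i - 1L], A$start[i]); dn <- c(A$end[i], A$start[i + 1L])
          if (up[2] - up[1] < min_intron_length ||
              dn[2] - dn[1] < min_intron_length) next
          for (j in seq_len(nrow(ib)))
            if (ib$s[j] == up[1] && ib$e[j] == dn[2])
              emit("SE", chrom, strand, up, dn, c(up[1], dn[2]))
        }
      }
      # A3/A5: intron pairs sharing one strand-aware end with
      # overlapping exons at the variable end
      if (!is.null(ia) && !is.null(ib)) {
        for (i in seq_len(nrow(ia))) for (j in seq_len(nrow(ib))) {
          x <- ia[i, ]; y <- ib[j, ]
          if (x$s == y$s && x$e == y$e) next
          don_x <- if (strand == "+") x$s else x$e
          don_y <- if (strand == "+") y$s else y$e
          acc_x <- if (strand == "+") x$e else x$s
          acc_y <- if (strand == "+") y$e else y$s
          aex_x <- if (strand == "+") c(x$rx_s, x$rx_e) else c(x$lx_s, x$lx_e)
          aex_y <- if (strand == "+") c(y$rx_s, y$rx_e) else c(y$lx_s, y$lx_e)
          dex_x <- if (strand == "+") c(x$lx_s, x$lx_e) else c(x$rx_s, x$rx_e)
          dex_y <- if (strand == "+") c(y$lx_s, y$lx_e) else c(y$rx_s, y$rx_e)
          wx <- x$e - x$s; wy <- y$e - y$s
          lo <- if (wx >= wy) c(x$s, x$e) else c(y$s, y$e)
          sh <- if (wx >= wy) c(y$s, y$e) else c(x$s, x$e)
          if (don_x == don_y && acc_x != acc_y &&
              aex_x[1] < aex_y[2] && aex_y[1] < aex_x[2])
            emit("A3", chrom, strand, lo, sh)
          if (acc_x == acc_y && don_x != don_y &&
              dex_x[1] < dex_y[2] && dex_y[1] < dex_x[2])
            emit("A5", chrom, strand, lo, sh)
        }
      }
      # RI: intron of A strictly inside an exon of B
      if (!is.null(ia)) {
        for (i in seq_len(nrow(ia))) for (j in seq_len(nrow(B))) {
          if (B$start[j] < ia$s[i] && ia$e[i] < B$end[j])
            emit("RI", chrom, strand, c(ia$s[i], ia$e[i]), c(NA, NA))
        }
      }
    }
  }
  if (!length(res))
    return(data.table(event_type = character(), chrom = character(),
                      strand = character(), j1_start = integer(),
                      j1_end = integer(), j2_start = integer(),
                      j2_end = integer(), j3_start = integer(),
                      j3_end = integer()))
  out <- unique(rbindlist(res))
  setorder(out, event_type, chrom, j1_start, j1_end, j2_start, na.last = TRUE)
  out[]
}

# per-base loop oracle for mean conservation over one interval
oracle_mean_conservation <- function(chrom, start, end, track) {
  tr <- as.data.frame(track)
  vals <- c()
  for (pos in start:(end - 1L)) {
    hit <- tr[tr$chrom == chrom & tr$start <= pos & pos < tr$end, ]
    if (nrow(hit) == 1L) vals <- c(vals, hit$score)
  }
  if (!length(vals)) NA_real_ else mean(vals)
}

# canonical event rows from a package events table, for oracle comparison
canonical_events <- function(ev) {
  cols <- c("event_type", "chrom", "strand", "j1_start", "j1_end",
            "j2_start", "j2_end", "j3_start", "j3_end")
  out <- unique(as.data.table(ev)[, ..cols])
  setorder(out, event_type, chrom, j1_start, j1_end, j2_start, na.last = TRUE)
  out[]
}
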