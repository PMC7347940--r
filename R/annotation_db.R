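# Transcript database: ingest of GTF / genePred annotations, junction
# labeling by transcript exclusivity, and the 50-nt PTC rule.
#
# All coordinates are held internally as 0-based half-open intervals
# [start, end). GTF (1-based inclusive), genePred (already 0-based
# half-open) and STAR junction tables (1-based inclusive intron bounds)
# are converted at the I/O boundary.

.BIOTYPES <- c("protein_coding", "nmd", "noncoding", "other")

# GENCODE-style biotype strings -> internal biotype. Anything unrecognized
# maps to "other", which counts as non-NMD for the exclusivity rule
# (conservative: avoids false NMD junction calls).
.NONCODING_BIOTYPES <- c(
  "lncRNA", "lincRNA", "antisense", "processed_transcript",
  "retained_intron", "non_coding", "noncoding", "misc_RNA", "snRNA",
  "snoRNA", "miRNA", "rRNA", "sense_intronic", "sense_overlapping"
)

map_biotype <- function(x) {
  out <- rep("other", length(x))
  out[x == "protein_coding"] <- "protein_coding"
  out[x == "nonsense_mediated_decay"] <- "nmd"
  out[x %in% .NONCODING_BIOTYPES] <- "noncoding"
  out[is.na(x)] <- "other"
  out
}

junction_id <- function(chrom, start, end, strand) {
  sprintf("%s:%d-%d:%s", chrom, start, end, strand)
}

#' Construct a transcript database
#'
#' A `transcript_db` bundles one table of transcripts with one table of
#' their exons. Exon coordinates are 0-based half-open; `cds_end` is the
#' 0-based genomic position of the last base of the stop codon (`NA` for
#' transcripts without an annotated stop).
#'
#' @param transcripts `data.frame` with columns `source`, `transcript_id`,
#'   `gene_id`, `gene_symbol`, `chrom`, `strand`, `biotype`, `cds_end`.
#' @param exons `data.frame` with columns `source`, `transcript_id`,
#'   `gene_id`, `chrom`, `strand`, `start`, `end`, `exon_rank` (1 is the
#'   5'-most exon in transcript orientation).
#' @return An object of class `transcript_db`.
#' @export
transcript_db <- function(transcripts, exons) {
  tx <- as.data.table(transcripts)
  ex <- as.data.table(exons)
  if (nrow(tx)) {
    stopifnot(all(tx$strand %in% c("+", "-")),
              all(tx$biotype %in% .BIOTYPES))
  }
  if (nrow(ex)) {
    if (any(ex$start >= ex$end))
      stop("exon intervals must satisfy start < end")
    bad <- ex[, {
      o <- order(start)
      list(bad = any(start[o][-1] < end[o][-.N]))
    }, by = .(source, transcript_id)][bad == TRUE]
    if (nrow(bad))
      stop("overlapping exons within transcript(s): ",
           paste(bad$transcript_id, collapse = ", "))
  }
  tx[, n_exons := 0L]
  if (nrow(ex)) {
    ne <- ex[, .(n = .N), by = .(source, transcript_id)]
    tx[ne, n_exons := i.n, on = c("source", "transcript_id")]
  }
  # protein_coding transcripts must carry a stop inside the exon span
  pc <- tx[biotype == "protein_coding" & !is.na(cds_end)]
  if (nrow(pc) && nrow(ex)) {
    sp <- ex[, .(lo = min(start), hi = max(end)), by = .(source, transcript_id)]
    pc <- merge(pc, sp, by = c("source", "transcript_id"))
    out <- pc[cds_end < lo | cds_end >= hi]
    if (nrow(out))
      stop("cds_end outside exon span for transcript(s): ",
           paste(out$transcript_id, collapse = ", "))
  }
  setorder(tx, source, transcript_id)
  setorder(ex, source, transcript_id, exon_rank)
  structure(list(transcripts = tx[], exons = ex[]), class = "transcript_db")
}

#' @export
print.transcript_db <- function(x, ...) {
  cat(sprintf("transcript_db: %d transcripts, %d genes, %d exon records\n",
              nrow(x$transcripts),
              length(unique(x$transcripts$gene_id)),
              nrow(x$exons)))
  if (nrow(x$transcripts)) {
    tab <- table(x$transcripts$biotype)
    cat("  biotypes:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

empty_transcript_db <- function() {
  transcript_db(
    data.table(source = character(), transcript_id = character(),
               gene_id = character(), gene_symbol = character(),
               chrom = character(), strand = character(),
               biotype = character(), cds_end = integer()),
    data.table(source = character(), transcript_id = character(),
               gene_id = character(), chrom = character(),
               strand = character(), start = integer(), end = integer(),
               exon_rank = integer())
  )
}

#' Load transcript annotations from GTF and/or genePred files
#'
#' GTF files are read in the GENCODE dialect (attributes `gene_id`,
#' `transcript_id`, `transcript_type` with `transcript_biotype` accepted as
#' a fallback; feature rows `exon`, `CDS`, `stop_codon`). Transcripts
#' tagged `nonsense_mediated_decay` receive biotype `nmd`. genePred files
#' are tab-separated UCSC-style tables (name, chrom, strand, txStart,
#' txEnd, cdsStart, cdsEnd, exonCount, exonStarts, exonEnds, name2);
#' accessions starting `NR_` map to biotype `noncoding` and `NM_` to
#' `protein_coding` (the RefSeq accession-prefix reading of the two
#' transcript classes).
#'
#' Transcript identifiers are kept distinct by `(source, transcript_id)`,
#' so the same accession occurring in both sources never collides.
#'
#' @param gtf Character vector of GTF paths (or `NULL`).
#' @param genepred Character vector of genePred paths (or `NULL`).
#' @return A [transcript_db].
#' @export
load_annotations <- function(gtf = NULL, genepred = NULL) {
  parts <- list()
  for (p in gtf) parts[[length(parts) + 1L]] <- read_gtf(p)
  for (p in genepred) parts[[length(parts) + 1L]] <- read_genepred(p)
  parts <- Filter(function(x) nrow(x$transcripts) > 0L, parts)
  if (!length(parts)) return(empty_transcript_db())
  transcript_db(
    rbindlist(lapply(parts, `[[`, "transcripts"), use.names = TRUE),
    rbindlist(lapply(parts, `[[`, "exons"), use.names = TRUE)
  )
}

read_gtf <- function(path) {
  if (!file.exists(path)) stop("GTF file not found: ", path)
  if (file.size(path) == 0L)
    return(list(transcripts = data.table(), exons = data.table()))
  gr <- tryCatch(
    rtracklayer::import(path, format = "gtf"),
    error = function(e) stop("parse error in GTF file '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  df <- as.data.table(as.data.frame(gr))
  if (!nrow(df)) return(list(transcripts = data.table(), exons = data.table()))
  for (col in c("gene_id", "transcript_id"))
    if (!col %in% names(df))
      stop("GTF file '", path, "' lacks required attribute ", col)
  bt_col <- if ("transcript_type" %in% names(df)) "transcript_type"
            else if ("transcript_biotype" %in% names(df)) "transcript_biotype"
            else NA_character_
  if (!"gene_name" %in% names(df)) df[, gene_name := gene_id]
  df[, chrom := as.character(seqnames)]
  df[, strand := as.character(strand)]

  exdf <- df[type == "exon"]
  exdf <- exdf[!is.na(transcript_id)]
  if (any(!exdf$strand %in% c("+", "-")))
    stop("GTF file '", path, "' has exons with undefined strand")
  exons <- exdf[, .(source = "gencode", transcript_id, gene_id, chrom,
                    strand, start = start - 1L, end = end)]

  # stop codon last base in transcript orientation; fall back to CDS end
  stop_pos <- function(sub) {
    sub[, .(cds_end = if (strand[1] == "+") max(end) - 1L else min(start) - 1L),
        by = .(transcript_id)]
  }
  sc <- df[type == "stop_codon"]
  cd <- df[type == "CDS" & !(transcript_id %in% sc$transcript_id)]
  cds <- rbindlist(list(
    if (nrow(sc)) stop_pos(sc) else NULL,
    if (nrow(cd)) stop_pos(cd) else NULL
  ))

  tx <- exdf[, .(gene_id = gene_id[1], gene_symbol = gene_name[1],
                 chrom = chrom[1], strand = strand[1],
                 raw_biotype = if (is.na(bt_col)) NA_character_
                               else as.character(.SD[[bt_col]][1])),
             by = .(transcript_id),
             .SDcols = intersect(names(exdf), bt_col)]
  tx[, biotype := map_biotype(raw_biotype)]
  tx[, raw_biotype := NULL]
  tx[, source := "gencode"]
  tx[, cds_end := NA_integer_]
  if (nrow(cds)) tx[cds, cds_end := as.integer(i.cds_end), on = "transcript_id"]
  # transcripts declared in the file but with no exon rows are rejected
  declared <- unique(df[!is.na(transcript_id), transcript_id])
  missing <- setdiff(declared, tx$transcript_id)
  if (length(missing))
    warning("rejected ", length(missing),
            " transcript(s) without exons in '", path, "'")
  exons[, exon_rank := {
    o <- frank(start)
    if (strand[1] == "-") as.integer(.N + 1L - o) else as.integer(o)
  }, by = .(transcript_id)]
  list(transcripts = tx[, .(source, transcript_id, gene_id, gene_symbol,
                            chrom, strand, biotype, cds_end)],
       exons = exons[, .(source, transcript_id, gene_id, chrom, strand,
                         start, end, exon_rank)])
}

read_genepred <- function(path) {
  if (!file.exists(path)) stop("genePred file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines))
    return(list(transcripts = data.table(), exons = data.table()))
  tx_rows <- vector("list", length(lines))
  ex_rows <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 10L)
      stop("parse error in genePred file '", path, "', line ", i,
           ": expected >= 10 tab-separated fields, got ", length(f))
    num <- suppressWarnings(as.integer(f[c(4, 5, 6, 7, 8)]))
    if (anyNA(num))
      stop("parse error in genePred file '", path, "', line ", i,
           ": malformed coordinate field")
    name <- f[1]; chrom <- f[2]; strand <- f[3]
    if (!strand %in% c("+", "-"))
      stop("parse error in genePred file '", path, "', line ", i,
           ": invalid strand '", strand, "'")
    cds_start <- num[3]; cds_end1 <- num[4]; n_ex <- num[5]
    if (n_ex < 1L) {
      warning("rejected transcript '", name, "' with <1 exon in '",
              path, "', line ", i)
      next
    }
    starts <- suppressWarnings(as.integer(
      strsplit(sub(",$", "", f[9]), ",", fixed = TRUE)[[1]]))
    ends <- suppressWarnings(as.integer(
      strsplit(sub(",$", "", f[10]), ",", fixed = TRUE)[[1]]))
    if (anyNA(starts) || anyNA(ends) ||
        length(starts) != n_ex || length(ends) != n_ex)
      stop("parse error in genePred file '", path, "', line ", i,
           ": exonStarts/exonEnds do not match exonCount")
    name2 <- if (length(f) >= 11L && nzchar(f[11])) f[11] else name
    biotype <- if (startsWith(name, "NR_")) "noncoding"
               else if (startsWith(name, "NM_")) "protein_coding"
               else "other"
    has_cds <- cds_start != cds_end1
    cds_last <- if (!has_cds) NA_integer_
                else if (strand == "+") cds_end1 - 1L else cds_start
    if (biotype != "protein_coding") cds_last <- NA_integer_
    tx_rows[[i]] <- data.table(
      source = "refseq", transcript_id = name, gene_id = name2,
      gene_symbol = name2, chrom = chrom, strand = strand,
      biotype = biotype, cds_end = cds_last)
    rk <- if (strand == "+") seq_len(n_ex) else rev(seq_len(n_ex))
    ex_rows[[i]] <- data.table(
      source = "refseq", transcript_id = name, gene_id = name2,
      chrom = chrom, strand = strand, start = starts, end = ends,
      exon_rank = as.integer(rk))
  }
  list(transcripts = rbindlist(tx_rows), exons = rbindlist(ex_rows))
}

# One row per intron per transcript, with the flanking exon coordinates
# (lx = genomic-left exon, rx = genomic-right exon). Used by junction
# labeling and event enumeration.
transcript_introns <- function(db, min_intron_length = 0L) {
  ex <- copy(db$exons)
  if (!nrow(ex))
    return(data.table(source = character(), transcript_id = character(),
                      gene_id = character(), chrom = character(),
                      strand = character(), intron_start = integer(),
                      intron_end = integer(), lx_start = integer(),
                      lx_end = integer(), rx_start = integer(),
                      rx_end = integer()))
  setorder(ex, source, transcript_id, start)
  intr <- ex[, if (.N >= 2L) .(
    gene_id = gene_id[1], chrom = chrom[1], strand = strand[1],
    intron_start = end[-.N], intron_end = start[-1L],
    lx_start = start[-.N], lx_end = end[-.N],
    rx_start = start[-1L], rx_end = end[-1L]
  ), by = .(source, transcript_id)]
  if (!nrow(intr)) return(intr)
  intr <- intr[intron_end - intron_start >= min_intron_length]
  intr[]
}

#' Label every exon-exon junction as coding or NMD
#'
#' A junction is labeled `NMD` if and only if every transcript containing
#' it has biotype `nmd` or `noncoding`; any support from a
#' `protein_coding` or `other` transcript makes it `coding`. Junctions
#' are strand-aware: identical coordinates on opposite strands are
#' distinct keys.
#'
#' @param db A [transcript_db].
#' @param min_intron_length Introns shorter than this many bases are not
#'   considered valid junctions (default 20).
#' @return `data.table` with one row per junction: `chrom`,
#'   `intron_start`, `intron_end` (0-based half-open), `strand`, `label`
#'   (`"coding"`/`"NMD"`), and `transcripts` (supporting
#'   `source:transcript_id`, comma-separated, sorted).
#' @export
extract_junction_labels <- function(db, min_intron_length = 20L) {
  intr <- transcript_introns(db, min_intron_length)
  if (!nrow(intr))
    return(data.table(chrom = character(), intron_start = integer(),
                      intron_end = integer(), strand = character(),
                      label = character(), transcripts = character()))
  bt <- db$transcripts[, .(source, transcript_id, biotype)]
  intr <- merge(intr, bt, by = c("source", "transcript_id"))
  lab <- intr[, .(
    label = if (all(biotype %in% c("nmd", "noncoding"))) "NMD" else "coding",
    transcripts = paste(sort(unique(paste(source, transcript_id, sep = ":"))),
                        collapse = ",")
  ), by = .(chrom, intron_start, intron_end, strand)]
  setorder(lab, chrom, intron_start, intron_end, strand)
  lab[]
}

#' Evaluate the 50-nt premature termination codon rule
#'
#' For each transcript with at least two exons and an annotated stop
#' codon, computes the spliced-transcript distance from the last base of
#' the stop codon to the 3'-most exon-exon junction. The transcript is
#' predicted NMD-sensitive when the stop lies upstream of the last
#' junction by at least `min_ptc_distance` nucleotides (inclusive
#' comparison) and is not located in the last exon.
#'
#' @param db A [transcript_db].
#' @param min_ptc_distance Minimum spliced distance in nucleotides
#'   (default 50).
#' @return `data.table` with `source`, `transcript_id`, `verdict`
#'   (`nmd_predicted`, `not_nmd`, `not_applicable`) and `ptc_distance`
#'   (NA when not applicable).
#' @export
evaluate_ptc_rule <- function(db, min_ptc_distance = 50L) {
  stopifnot(min_ptc_distance >= 0L)
  tx <- db$transcripts
  if (!nrow(tx))
    return(data.table(source = character(), transcript_id = character(),
                      verdict = character(), ptc_distance = integer()))
  ex <- copy(db$exons)
  setorder(ex, source, transcript_id, exon_rank)
  res <- ex[, {
    g <- tx[.BY, cds_end, on = c("source", "transcript_id")]
    n <- .N
    if (n < 2L || is.na(g)) {
      list(verdict = "not_applicable", ptc_distance = NA_integer_)
    } else {
      idx <- which(start <= g & g < end)
      if (!length(idx))
        stop("cds_end of transcript '", .BY$transcript_id,
             "' falls outside its exons")
      w <- end - start
      if (idx == n) {
        list(verdict = "not_nmd", ptc_distance = NA_integer_)
      } else {
        offset <- if (strand[1] == "+") g - start[idx] + 1L else end[idx] - g
        p <- sum(w[seq_len(idx - 1L)]) + offset
        jpos <- sum(w[seq_len(n - 1L)])
        d <- as.integer(jpos - p)
        list(verdict = if (d >= min_ptc_distance) "nmd_predicted" else "not_nmd",
             ptc_distance = d)
      }
    }
  }, by = .(source, transcript_id)]
  res[]
}

#' Write / read a transcript database as JSON lines
#'
#' One JSON object per transcript, with exon intervals and all transcript
#' fields. Round-trips exactly through [read_transcript_db()].
#'
#' @param db A [transcript_db].
#' @param path Output file.
#' @return `path`, invisibly (writer); a [transcript_db] (reader).
#' @export
write_transcript_db <- function(db, path) {
  tx <- db$transcripts
  ex <- db$exons
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (nrow(tx)) {
    for (i in seq_len(nrow(tx))) {
      r <- tx[i]
      e <- ex[source == r$source & transcript_id == r$transcript_id][order(exon_rank)]
      obj <- list(source = r$source, transcript_id = r$transcript_id,
                  gene_id = r$gene_id, gene_symbol = r$gene_symbol,
                  chrom = r$chrom, strand = r$strand, biotype = r$biotype,
                  cds_end = r$cds_end,
                  exon_starts = e$start, exon_ends = e$end)
      writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, null = "null",
                                  na = "null", digits = NA), con)
    }
  }
  invisible(path)
}

#' @rdname write_transcript_db
#' @export
read_transcript_db <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(empty_transcript_db())
  txl <- vector("list", length(lines))
  exl <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    o <- jsonlite::fromJSON(lines[i])
    txl[[i]] <- data.table(
      source = o$source, transcript_id = o$transcript_id,
      gene_id = o$gene_id, gene_symbol = o$gene_symbol, chrom = o$chrom,
      strand = o$strand, biotype = o$biotype,
      cds_end = if (is.null(o$cds_end)) NA_integer_ else as.integer(o$cds_end))
    n <- length(o$exon_starts)
    exl[[i]] <- data.table(
      source = o$source, transcript_id = o$transcript_id,
      gene_id = o$gene_id, chrom = o$chrom, strand = o$strand,
      start = as.integer(o$exon_starts), end = as.integer(o$exon_ends),
      exon_rank = seq_len(n))
  }
  transcript_db(rbindlist(txl), rbindlist(exl))
}
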