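# Conservation analysis: partition exons into three mutually exclusive
# sets (NMD-inclusion exons, non-NMD alternatively spliced exons,
# protein-coding constitutive exons), average a per-base conservation
# score over each exon body, and summarize the fraction of exons at or
# above a conservation threshold.

#' Load a per-base conservation score track
#'
#' Accepts bedGraph (0-based half-open runs) or fixed-step wiggle input.
#' Scores must lie in `[0, 1]`; runs must not overlap within a
#' chromosome. Positions not covered by any run are "no data",
#' distinguished from score 0.
#'
#' @param path Path to the track file.
#' @param dialect `"bedgraph"` or `"fixed_wig"`.
#' @return A `conservation_track`: data.table of runs (`chrom`, `start`,
#'   `end` 0-based half-open, `score`), sorted.
#' @export
load_score_track <- function(path, dialect = c("bedgraph", "fixed_wig")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("track file not found: ", path)
  if (file.size(path) == 0L) {
    tr <- data.table(chrom = character(), start = integer(),
                     end = integer(), score = numeric())
    setattr(tr, "class", c("conservation_track", class(tr)))
    return(tr)
  }
  fmt <- if (dialect == "bedgraph") "bedGraph" else "wig"
  gr <- rtracklayer::import(path, format = fmt)
  df <- as.data.table(as.data.frame(gr))
  tr <- df[, .(chrom = as.character(seqnames), start = start - 1L,
               end = end, score = as.numeric(score))]
  if (any(tr$score < 0 | tr$score > 1))
    stop("conservation scores outside [0, 1] in '", path, "'")
  setorder(tr, chrom, start)
  bad <- tr[, any(start[-1] < end[-.N]), by = chrom][V1 == TRUE]
  if (nrow(bad))
    stop("overlapping score runs on chromosome(s): ",
         paste(bad$chrom, collapse = ", "))
  setattr(tr, "class", c("conservation_track", class(tr)))
  tr[]
}

#' Build a conservation track from in-memory runs
#'
#' @param runs `data.frame` with `chrom`, `start`, `end`, `score`.
#' @return A `conservation_track`.
#' @export
conservation_track <- function(runs) {
  tr <- as.data.table(runs)[, .(chrom, start, end, score)]
  setorder(tr, chrom, start)
  bad <- tr[, if (.N > 1L) any(start[-1] < end[-.N]) else FALSE,
            by = chrom][V1 == TRUE]
  if (nrow(bad)) stop("overlapping score runs")
  if (nrow(tr) && any(tr$score < 0 | tr$score > 1))
    stop("scores outside [0, 1]")
  setattr(tr, "class", c("conservation_track", class(tr)))
  tr[]
}

#' Write a conservation track as bedGraph
#'
#' @param track A `conservation_track`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  fwrite(as.data.table(track)[, .(chrom, start, end, score)], path,
         sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Mean conservation over genomic intervals
#'
#' Arithmetic mean of the per-base scores across each interval,
#' restricted to bases covered by the track; the covered fraction is
#' reported alongside, and the mean is `NA` when no base has data.
#'
#' @param intervals `data.frame` with `chrom`, `start`, `end` (0-based
#'   half-open).
#' @param track A `conservation_track`.
#' @return The intervals with `mean_score` and `covered_fraction`
#'   columns.
#' @export
mean_conservation <- function(intervals, track) {
  iv <- as.data.table(intervals)
  if (!nrow(iv)) {
    iv[, `:=`(mean_score = numeric(), covered_fraction = numeric())]
    return(iv[])
  }
  if (any(iv$start >= iv$end)) stop("intervals must satisfy start < end")
  tr <- as.data.table(track)
  iv[, `:=`(mean_score = NA_real_, covered_fraction = 0)]
  if (!nrow(tr)) return(iv[])
  q <- iv[, .(chrom, qs = start, qe = end - 1L, idx = .I)]
  t2 <- tr[, .(chrom, ts = start, te = end - 1L, score)]
  setkey(t2, chrom, ts, te)
  ov <- foverlaps(q, t2, by.x = c("chrom", "qs", "qe"),
                  by.y = c("chrom", "ts", "te"), nomatch = NULL)
  if (nrow(ov)) {
    ov[, olen := pmin(qe, te) - pmax(qs, ts) + 1L]
    agg <- ov[, .(covered = sum(olen), ssum = sum(score * olen)), by = idx]
    iv[agg$idx, `:=`(mean_score = agg$ssum / agg$covered,
                     covered_fraction = agg$covered / (end - start))]
  }
  iv[]
}

#' Fraction of exons at or above a conservation threshold
#'
#' Computes the mean conservation of each exon and reports the fraction
#' of exons with a defined mean that reach `threshold` (inclusive).
#'
#' @param exons `data.frame` of exon intervals (`chrom`, `start`, `end`).
#' @param track A `conservation_track`.
#' @param threshold Conservation threshold (default 0.8).
#' @return List with `fraction`, `n_conserved`, `n_defined`, `n_total`,
#'   and the per-exon `means` table.
#' @export
conserved_fraction <- function(exons, track, threshold = 0.8) {
  m <- mean_conservation(exons, track)
  defined <- !is.na(m$mean_score)
  if (!any(defined)) {
    warning("no exon has conservation data; fraction undefined")
    return(list(fraction = NA_real_, n_conserved = 0L, n_defined = 0L,
                n_total = nrow(m), means = m))
  }
  n_cons <- sum(m$mean_score[defined] >= threshold)
  list(fraction = n_cons / sum(defined), n_conserved = n_cons,
       n_defined = sum(defined), n_total = nrow(m), means = m)
}

#' Partition exons into the three conservation sets
#'
#' Builds three mutually exclusive exon sets, deduplicated by
#' `(chrom, start, end, strand)`:
#' 1. `set1` — exons whose inclusion causes NMD (alternative exons of
#'    `EI_NMD` events);
#' 2. `set2` — alternatively spliced exons that do not cause NMD
#'    (alternative exons of `cassette_exon` events), minus set 1: NMD
#'    membership wins for an exon claimed by both;
#' 3. `set3` — all remaining protein-coding exons (exons of
#'    `protein_coding` transcripts excluding sets 1 and 2).
#'
#' @param db A [transcript_db].
#' @param events Classified events from [classify_event_nmd()].
#' @return An `exon_set_partition`: list of three exon tables.
#' @export
partition_exon_sets <- function(db, events) {
  ev <- as.data.table(events)
  if (!"label" %in% names(ev))
    stop("events must be classified first (classify_event_nmd)")
  cols <- c("chrom", "start", "end", "strand")
  mk <- function(dt) unique(dt[, ..cols])[order(chrom, start, end, strand)]
  se <- ev[event_type == "SE"]
  set1 <- mk(se[label == "EI_NMD",
                .(chrom, start = alt_start, end = alt_end, strand)])
  set2 <- mk(se[label == "cassette_exon",
                .(chrom, start = alt_start, end = alt_end, strand)])
  set2 <- set2[!set1, on = cols]
  pc_tx <- db$transcripts[biotype == "protein_coding",
                          .(source, transcript_id)]
  set3 <- mk(db$exons[pc_tx, on = c("source", "transcript_id"),
                      nomatch = NULL][, .(chrom, start, end, strand)])
  set3 <- set3[!set1, on = cols][!set2, on = cols]
  structure(list(set1 = set1, set2 = set2, set3 = set3),
            class = "exon_set_partition")
}

#' @export
print.exon_set_partition <- function(x, ...) {
  cat(sprintf(paste0("exon_set_partition: %d NMD-inclusion, %d non-NMD ",
                     "alternative, %d coding-constitutive exons\n"),
              nrow(x$set1), nrow(x$set2), nrow(x$set3)))
  invisible(x)
}
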