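# Alternative-splicing event catalog: native enumeration of SE / A3 / A5 /
# RI events from the transcript database, ingest of SUPPA2-style .ioe
# files as an alternative source, and NMD classification of each event
# from the junction label table.
#
# Junction role columns (0-based half-open intron coordinates):
#   SE: j1 = inclusion_upstream, j2 = inclusion_downstream, j3 = skipping
#   A3/A5: j1 = long junction, j2 = short junction
#   RI: j1 = alternative-intron (ai) junction; parent_exons holds the host
#       exon(s), comma-separated "start-end" pairs.

.EVENT_COLS <- c("event_id", "event_type", "gene_id", "gene_symbol",
                 "chrom", "strand",
                 "j1_start", "j1_end", "j2_start", "j2_end",
                 "j3_start", "j3_end", "alt_start", "alt_end",
                 "parent_exons", "tx_alt", "tx_all")

empty_events <- function() {
  data.table(event_id = character(), event_type = character(),
             gene_id = character(), gene_symbol = character(),
             chrom = character(), strand = character(),
             j1_start = integer(), j1_end = integer(),
             j2_start = integer(), j2_end = integer(),
             j3_start = integer(), j3_end = integer(),
             alt_start = integer(), alt_end = integer(),
             parent_exons = character(), tx_alt = character(),
             tx_all = character())
}

# 1-based boundary pair "donorExonEnd-acceptorExonStart" used in event ids
# (last base of the upstream exon, first base of the downstream exon).
fmt_j <- function(s, e) sprintf("%d-%d", s, e + 1L)

make_event_id <- function(ev) {
  with(ev, switch(event_type,
    SE = sprintf("%s;SE:%s:%s:%s:%s", gene_id, chrom,
                 fmt_j(j1_start, j1_end), fmt_j(j2_start, j2_end), strand),
    A3 = sprintf("%s;A3:%s:%s:%s:%s", gene_id, chrom,
                 fmt_j(j2_start, j2_end), fmt_j(j1_start, j1_end), strand),
    A5 = sprintf("%s;A5:%s:%s:%s:%s", gene_id, chrom,
                 fmt_j(j2_start, j2_end), fmt_j(j1_start, j1_end), strand),
    RI = {
      pe <- strsplit(parent_exons, ",", fixed = TRUE)[[1]][1]
      bounds <- as.integer(strsplit(pe, "-", fixed = TRUE)[[1]])
      sprintf("%s;RI:%s:%d:%s:%d:%s", gene_id, chrom, bounds[1] + 1L,
              fmt_j(j1_start, j1_end), bounds[2], strand)
    }))
}

#' Enumerate alternative-splicing events from a transcript database
#'
#' Emits four event types, per gene, deduplicated by coordinates:
#' * `SE` (skipped exon): a transcript includes an internal exon whose two
#'   flanking junctions are matched by a single skipping junction in the
#'   gene's junction set.
#' * `A3` / `A5`: two introns share their donor (A3) or acceptor (A5)
#'   splice site but differ at the other end, and the exons adjacent to
#'   the variable end overlap.
#' * `RI` (retained intron / exitron): an intron of one transcript lies
#'   strictly inside a single exon of another transcript.
#'
#' Mutually exclusive exons and alternative first/last exons are not
#' enumerated.
#'
#' @param db A [transcript_db].
#' @param min_intron_length Introns shorter than this are ignored
#'   (default 20).
#' @return `data.table` of events with role-tagged junction coordinates
#'   (see source header for the role-column mapping) and the alternative
#'   region `alt_start`/`alt_end`.
#' @export
enumerate_events <- function(db, min_intron_length = 20L) {
  intr <- transcript_introns(db, min_intron_length)
  if (!nrow(intr)) return(empty_events())
  ex <- db$exons
  sym <- db$transcripts[, .(gene_symbol = gene_symbol[1]), by = gene_id]
  intr[, key := junction_id(chrom, intron_start, intron_end, strand)]
  intr[, tx := paste(source, transcript_id, sep = ":")]

  out <- vector("list", 0L)
  for (g in unique(intr$gene_id)) {
    gi <- intr[gene_id == g]
    gex <- ex[gene_id == g]
    # unique junction -> supporting transcripts
    jt <- gi[, .(txs = paste(sort(unique(tx)), collapse = ",")),
             by = .(chrom, strand, intron_start, intron_end, key)]
    jset <- setNames(jt$txs, jt$key)

    ## --- SE: internal exon with both flanking junctions + a skipping
    ## junction spanning the same outer boundaries
    se <- gi[, {
      n <- .N
      if (n >= 2L) {
        # consecutive intron pairs flank an included internal exon
        i <- seq_len(n - 1L)
        o <- order(intron_start)
        s1 <- intron_start[o]; e1 <- intron_end[o]
        list(up_s = s1[i], up_e = e1[i], dn_s = s1[i + 1L], dn_e = e1[i + 1L])
      }
    }, by = .(tx, chrom, strand)]
    if (nrow(se)) {
      se <- se[e1_adjacent(up_e, dn_s)]
      se[, skip_key := junction_id(chrom, up_s, dn_e, strand)]
      se <- se[skip_key %in% names(jset)]
      if (nrow(se)) {
        se <- se[, .(tx_alt = paste(sort(unique(tx)), collapse = ",")),
                 by = .(chrom, strand, up_s, up_e, dn_s, dn_e, skip_key)]
        se[, `:=`(event_type = "SE", gene_id = g,
                  j1_start = up_s, j1_end = up_e,
                  j2_start = dn_s, j2_end = dn_e,
                  j3_start = up_s, j3_end = dn_e,
                  alt_start = up_e, alt_end = dn_s,
                  parent_exons = NA_character_)]
        se[, tx_all := {
          sk <- unlist(jset[skip_key])
          paste(sort(unique(c(strsplit(tx_alt, ",")[[1]],
                              strsplit(sk, ",")[[1]]))), collapse = ",")
        }, by = seq_len(nrow(se))]
        out[[length(out) + 1L]] <-
          se[, .(event_type, gene_id, chrom, strand, j1_start, j1_end,
                 j2_start, j2_end, j3_start, j3_end, alt_start, alt_end,
                 parent_exons, tx_alt, tx_all)]
      }
    }

    ## --- A3 / A5: strand-aware donor/acceptor pairing with overlap of
    ## the exons adjacent to the variable splice site
    ctx <- unique(gi[, .(chrom, strand, intron_start, intron_end,
                         lx_start, lx_end, rx_start, rx_end)])
    if (nrow(ctx) >= 2L) {
      plus <- ctx$strand[1] == "+"
      ctx[, donor := if (plus) intron_start else intron_end]
      ctx[, acceptor := if (plus) intron_end else intron_start]
      # acceptor-side exon (downstream in transcript orientation)
      if (plus) {
        ctx[, `:=`(aex_s = rx_start, aex_e = rx_end,
                   dex_s = lx_start, dex_e = lx_end)]
      } else {
        ctx[, `:=`(aex_s = lx_start, aex_e = lx_end,
                   dex_s = rx_start, dex_e = rx_end)]
      }
      out[[length(out) + 1L]] <- alt_ss_events(ctx, g, "A3")
      out[[length(out) + 1L]] <- alt_ss_events(ctx, g, "A5")
    }

    ## --- RI: intron strictly inside an exon of another transcript
    uj <- unique(gi[, .(chrom, strand, intron_start, intron_end, key)])
    if (nrow(uj) && nrow(gex)) {
      ri <- uj[, {
        pe <- gex[start < intron_start & end > intron_end &
                    strand == .BY$strand]
        if (nrow(pe)) {
          pex <- unique(pe[, .(start, end)])[order(start)]
          list(parent_exons = paste(sprintf("%d-%d", pex$start, pex$end),
                                    collapse = ","))
        }
      }, by = .(chrom, strand, intron_start, intron_end, key)]
      if (nrow(ri)) {
        ri[, `:=`(event_type = "RI", gene_id = g,
                  j1_start = intron_start, j1_end = intron_end,
                  j2_start = NA_integer_, j2_end = NA_integer_,
                  j3_start = NA_integer_, j3_end = NA_integer_,
                  alt_start = intron_start, alt_end = intron_end,
                  tx_alt = unname(jset[key]))]
        ri[, tx_all := tx_alt]
        out[[length(out) + 1L]] <-
          ri[, .(event_type, gene_id, chrom, strand, j1_start, j1_end,
                 j2_start, j2_end, j3_start, j3_end, alt_start, alt_end,
                 parent_exons, tx_alt, tx_all)]
      }
    }
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out)) return(empty_events())
  ev <- rbindlist(out, use.names = TRUE)
  ev <- unique(ev, by = c("event_type", "chrom", "strand", "gene_id",
                          "j1_start", "j1_end", "j2_start", "j2_end",
                          "j3_start", "j3_end"))
  ev <- merge(ev, sym, by = "gene_id", all.x = TRUE)
  ev[, event_id := make_event_id(.SD), by = seq_len(nrow(ev))]
  setcolorder(ev, .EVENT_COLS)
  setorder(ev, gene_id, event_type, chrom, j1_start, j1_end)
  ev[]
}

# adjacency test kept separate so the SE candidate builder stays readable:
# the two introns must be consecutive (down intron starts at the end of
# the included exon, which starts where the up intron ends)
e1_adjacent <- function(up_e, dn_s) up_e < dn_s

alt_ss_events <- function(ctx, gene, type) {
  # A3: same donor, different acceptor; A5: same acceptor, different donor
  shared <- if (type == "A3") "donor" else "acceptor"
  vary <- if (type == "A3") "acceptor" else "donor"
  exs <- if (type == "A3") c("aex_s", "aex_e") else c("dex_s", "dex_e")
  res <- list()
  for (v in unique(ctx[[shared]])) {
    grp <- ctx[ctx[[shared]] == v]
    u <- unique(grp, by = c("intron_start", "intron_end", exs))
    if (nrow(u) < 2L) next
    for (a in seq_len(nrow(u) - 1L)) for (b in seq(a + 1L, nrow(u))) {
      if (u[[vary]][a] == u[[vary]][b]) next
      # exons adjacent to the variable splice site must overlap
      if (!(u[[exs[1]]][a] < u[[exs[2]]][b] &&
            u[[exs[1]]][b] < u[[exs[2]]][a])) next
      wa <- u$intron_end[a] - u$intron_start[a]
      wb <- u$intron_end[b] - u$intron_start[b]
      lo <- if (wa >= wb) a else b
      sh <- if (wa >= wb) b else a
      res[[length(res) + 1L]] <- data.table(
        event_type = type, gene_id = gene,
        chrom = u$chrom[1], strand = u$strand[1],
        j1_start = u$intron_start[lo], j1_end = u$intron_end[lo],
        j2_start = u$intron_start[sh], j2_end = u$intron_end[sh],
        j3_start = NA_integer_, j3_end = NA_integer_,
        alt_start = min(u[[vary]][a], u[[vary]][b]),
        alt_end = max(u[[vary]][a], u[[vary]][b]),
        parent_exons = NA_character_,
        tx_alt = NA_character_, tx_all = NA_character_)
    }
  }
  if (!length(res)) return(NULL)
  unique(rbindlist(res),
         by = c("j1_start", "j1_end", "j2_start", "j2_end"))
}

#' Classify events as NMD-inducing from junction labels
#'
#' Applies the label-based rules per event type, in this precedence:
#' * SE: skipping junction NMD -> `ES_NMD`; otherwise either inclusion
#'   junction NMD -> `EI_NMD`; otherwise `cassette_exon`. The skipping
#'   rule is checked first, so a junction set satisfying both yields
#'   `ES_NMD`.
#' * A3/A5: exactly one of long/short NMD -> `A3_NMD`/`A5_NMD`; both NMD
#'   -> `dropped_complex` (likely complex splicing, excluded downstream);
#'   neither -> `non_NMD`.
#' * RI: ai junction NMD -> `AI_NMD`, else `non_NMD`.
#'
#' @param events Events from [enumerate_events()] or [read_ioe()].
#' @param labels Junction label table from [extract_junction_labels()].
#' @return The events table with added `label` and, for A3/A5 NMD events,
#'   `nmd_role` (`"long"` or `"short"`).
#' @export
classify_event_nmd <- function(events, labels) {
  ev <- copy(as.data.table(events))
  if (!nrow(ev)) {
    ev[, `:=`(label = character(), nmd_role = character())]
    return(ev[])
  }
  lmap <- setNames(labels$label,
                   junction_id(labels$chrom, labels$intron_start,
                               labels$intron_end, labels$strand))
  get_lab <- function(s, e) {
    k <- junction_id(ev$chrom, s, e, ev$strand)
    k[is.na(s)] <- NA_character_
    unname(lmap[k])
  }
  l1 <- get_lab(ev$j1_start, ev$j1_end)
  l2 <- get_lab(ev$j2_start, ev$j2_end)
  l3 <- get_lab(ev$j3_start, ev$j3_end)
  need2 <- ev$event_type %in% c("SE", "A3", "A5")
  need3 <- ev$event_type == "SE"
  missing <- is.na(l1) | (need2 & is.na(l2)) | (need3 & is.na(l3))
  if (any(missing))
    stop("junction(s) absent from label table for event(s): ",
         paste(head(ev$event_id[missing], 5L), collapse = ", "))
  lab <- character(nrow(ev))
  role <- rep(NA_character_, nrow(ev))
  is_se <- ev$event_type == "SE"
  lab[is_se] <- ifelse(l3[is_se] == "NMD", "ES_NMD",
                ifelse(l1[is_se] == "NMD" | l2[is_se] == "NMD",
                       "EI_NMD", "cassette_exon"))
  is_ass <- ev$event_type %in% c("A3", "A5")
  both <- is_ass & l1 == "NMD" & l2 == "NMD"
  one_long <- is_ass & l1 == "NMD" & l2 != "NMD"
  one_short <- is_ass & l1 != "NMD" & l2 == "NMD"
  none <- is_ass & l1 != "NMD" & l2 != "NMD"
  lab[both] <- "dropped_complex"
  lab[one_long | one_short] <- paste0(ev$event_type[one_long | one_short], "_NMD")
  lab[none] <- "non_NMD"
  role[one_long] <- "long"
  role[one_short] <- "short"
  is_ri <- ev$event_type == "RI"
  lab[is_ri] <- ifelse(l1[is_ri] == "NMD", "AI_NMD", "non_NMD")
  ev[, `:=`(label = lab, nmd_role = role)]
  ev[]
}

#' Read alternative-splicing events from a SUPPA2-style .ioe file
#'
#' Expects the tab-separated columns `seqname`, `gene_id`, `event_id`,
#' `alternative_transcripts`, `total_transcripts`. Event coordinates are
#' decoded from the `event_id` grammar; event types other than
#' SE/A3/A5/RI are skipped with a warning. RI rows sharing the same
#' alternative-intron junction are merged, pooling their parent exons.
#'
#' @param path Path to the `.ioe` file.
#' @return `data.table` of events in the same layout as
#'   [enumerate_events()].
#' @export
read_ioe <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) && startsWith(lines[1], "seqname")) lines <- lines[-1]
  if (!length(lines)) return(empty_events())
  rows <- vector("list", length(lines))
  skipped <- character()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L)
      stop("parse error in .ioe file '", path, "', line ", i + 1L,
           ": expected >= 3 columns")
    eid <- f[3]
    parts <- strsplit(eid, ";", fixed = TRUE)[[1]]
    if (length(parts) != 2L)
      stop("parse error in .ioe file '", path, "', line ", i + 1L,
           ": malformed event_id '", eid, "'")
    gene <- parts[1]
    body <- strsplit(parts[2], ":", fixed = TRUE)[[1]]
    type <- body[1]
    if (!type %in% c("SE", "A3", "A5", "RI")) {
      skipped <- c(skipped, type)
      next
    }
    strand <- body[length(body)]
    chrom <- body[2]
    coords <- body[seq(3, length(body) - 1L)]
    parse_pair <- function(p) {
      v <- suppressWarnings(as.integer(strsplit(p, "-", fixed = TRUE)[[1]]))
      if (length(v) != 2L || anyNA(v))
        stop("parse error in .ioe file '", path, "', line ", i + 1L,
             ": malformed coordinate pair '", p, "'")
      c(v[1], v[2] - 1L)  # back to 0-based half-open intron
    }
    row <- switch(type,
      SE = {
        if (length(coords) != 2L)
          stop("parse error in .ioe file '", path, "', line ", i + 1L,
               ": SE event needs two junction pairs")
        j1 <- parse_pair(coords[1]); j2 <- parse_pair(coords[2])
        data.table(event_type = "SE", gene_id = gene, chrom = chrom,
                   strand = strand,
                   j1_start = j1[1], j1_end = j1[2],
                   j2_start = j2[1], j2_end = j2[2],
                   j3_start = j1[1], j3_end = j2[2],
                   alt_start = j1[2], alt_end = j2[1],
                   parent_exons = NA_character_)
      },
      A3 = , A5 = {
        if (length(coords) != 2L)
          stop("parse error in .ioe file '", path, "', line ", i + 1L,
               ": ", type, " event needs two junction pairs")
        ja <- parse_pair(coords[1]); jb <- parse_pair(coords[2])
        wa <- ja[2] - ja[1]; wb <- jb[2] - jb[1]
        lo <- if (wa >= wb) ja else jb
        sh <- if (wa >= wb) jb else ja
        vary <- if ((type == "A3") == (strand == "+")) 2L else 1L
        data.table(event_type = type, gene_id = gene, chrom = chrom,
                   strand = strand,
                   j1_start = lo[1], j1_end = lo[2],
                   j2_start = sh[1], j2_end = sh[2],
                   j3_start = NA_integer_, j3_end = NA_integer_,
                   alt_start = min(ja[vary], jb[vary]),
                   alt_end = max(ja[vary], jb[vary]),
                   parent_exons = NA_character_)
      },
      RI = {
        if (length(coords) != 3L)
          stop("parse error in .ioe file '", path, "', line ", i + 1L,
               ": RI event needs exon-start, junction, exon-end")
        s <- suppressWarnings(as.integer(coords[1])) - 1L
        e <- suppressWarnings(as.integer(coords[3]))
        if (is.na(s) || is.na(e))
          stop("parse error in .ioe file '", path, "', line ", i + 1L,
               ": malformed RI exon bounds")
        j <- parse_pair(coords[2])
        data.table(event_type = "RI", gene_id = gene, chrom = chrom,
                   strand = strand,
                   j1_start = j[1], j1_end = j[2],
                   j2_start = NA_integer_, j2_end = NA_integer_,
                   j3_start = NA_integer_, j3_end = NA_integer_,
                   alt_start = j[1], alt_end = j[2],
                   parent_exons = sprintf("%d-%d", s, e))
      })
    row[, `:=`(tx_alt = if (length(f) >= 4L) f[4] else NA_character_,
               tx_all = if (length(f) >= 5L) f[5] else NA_character_)]
    rows[[i]] <- row
  }
  if (length(skipped))
    warning("skipped ", length(skipped), " event(s) of unsupported type: ",
            paste(unique(skipped), collapse = ", "))
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) return(empty_events())
  ev <- rbindlist(rows, use.names = TRUE)
  # merge RI rows for the same alternative intron, pooling parent exons
  ri <- ev[event_type == "RI"]
  if (nrow(ri)) {
    ri <- ri[, {
      pe <- unique(unlist(strsplit(parent_exons, ",", fixed = TRUE)))
      ps <- as.integer(sub("-.*", "", pe))
      list(j2_start = NA_integer_, j2_end = NA_integer_,
           j3_start = NA_integer_, j3_end = NA_integer_,
           alt_start = j1_start[1], alt_end = j1_end[1],
           parent_exons = paste(pe[order(ps)], collapse = ","),
           tx_alt = paste(sort(unique(unlist(strsplit(tx_alt, ",")))),
                          collapse = ","),
           tx_all = paste(sort(unique(unlist(strsplit(tx_all, ",")))),
                          collapse = ","))
    }, by = .(event_type, gene_id, chrom, strand, j1_start, j1_end)]
    ev <- rbind(ev[event_type != "RI"], ri, use.names = TRUE, fill = TRUE)
  }
  ev <- unique(ev, by = c("event_type", "chrom", "strand", "gene_id",
                          "j1_start", "j1_end", "j2_start", "j2_end",
                          "j3_start", "j3_end"))
  ev[, gene_symbol := gene_id]
  ev[, event_id := make_event_id(.SD), by = seq_len(nrow(ev))]
  setcolorder(ev, .EVENT_COLS)
  setorder(ev, gene_id, event_type, chrom, j1_start, j1_end)
  ev[]
}

#' Write events to a SUPPA2-style .ioe file
#'
#' Inverse of [read_ioe()]. RI events are written as one row per parent
#' exon, mirroring how per-transcript event files list them.
#'
#' @param events Events table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ioe <- function(events, path) {
  ev <- as.data.table(events)
  con <- file(path, "wt")
  on.exit(close(con))
  writeLines(paste("seqname", "gene_id", "event_id",
                   "alternative_transcripts", "total_transcripts",
                   sep = "\t"), con)
  for (i in seq_len(nrow(ev))) {
    r <- ev[i]
    alt <- if (is.na(r$tx_alt)) "." else r$tx_alt
    tot <- if (is.na(r$tx_all)) "." else r$tx_all
    if (r$event_type == "RI") {
      pes <- strsplit(r$parent_exons, ",", fixed = TRUE)[[1]]
      for (pe in pes) {
        b <- as.integer(strsplit(pe, "-", fixed = TRUE)[[1]])
        eid <- sprintf("%s;RI:%s:%d:%s:%d:%s", r$gene_id, r$chrom,
                       b[1] + 1L, fmt_j(r$j1_start, r$j1_end), b[2],
                       r$strand)
        writeLines(paste(r$chrom, r$gene_id, eid, alt, tot, sep = "\t"), con)
      }
    } else {
      writeLines(paste(r$chrom, r$gene_id, r$event_id, alt, tot,
                       sep = "\t"), con)
    }
  }
  invisible(path)
}
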