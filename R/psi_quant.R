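# Percent-spliced-in (PSI) quantification from splice-junction counts:
# STAR SJ.out.tab ingest, per-event role-summed counts, the PSI
# estimators for cassette / alternative splice site / alternative intron
# events, abundance filters, and the unique-gene catalog summary.

.NMD_LABELS <- c("EI_NMD", "ES_NMD", "A3_NMD", "A5_NMD", "AI_NMD")

#' Read a STAR SJ.out.tab splice-junction count table
#'
#' Expects the 9 tab-separated STAR columns: chromosome, intron first
#' base (1-based), intron last base (1-based), strand code (0 undefined,
#' 1 `+`, 2 `-`), intron motif code, annotation flag, uniquely-mapping
#' read count, multi-mapping read count, maximum spliced overhang.
#' Coordinates are converted to the internal 0-based half-open
#' convention; quantification uses the uniquely-mapped counts (one count
#' = one uniquely mapped read pair).
#'
#' @param path Path to an SJ.out.tab-style file.
#' @param sample_id Sample identifier attached to every row.
#' @return `data.table` with columns `sample_id`, `chrom`,
#'   `intron_start`, `intron_end`, `strand` (`"*"` for undefined),
#'   `unique_reads`, `multimap_reads`, `max_overhang`.
#' @export
read_star_sj <- function(path, sample_id) {
  if (!file.exists(path)) stop("junction file not found: ", path)
  if (file.size(path) == 0L)
    return(data.table(sample_id = character(), chrom = character(),
                      intron_start = integer(), intron_end = integer(),
                      strand = character(), unique_reads = integer(),
                      multimap_reads = integer(), max_overhang = integer()))
  dt <- fread(path, header = FALSE, sep = "\t")
  if (ncol(dt) != 9L)
    stop("parse error in '", path, "': expected 9 columns, got ", ncol(dt))
  if (!all(dt$V4 %in% 0:2))
    stop("parse error in '", path, "': invalid strand code")
  if (any(dt$V7 < 0L) || any(dt$V8 < 0L))
    stop("negative junction counts in '", path, "'")
  data.table(sample_id = sample_id,
             chrom = as.character(dt$V1),
             intron_start = as.integer(dt$V2) - 1L,
             intron_end = as.integer(dt$V3),
             strand = c("*", "+", "-")[dt$V4 + 1L],
             unique_reads = as.integer(dt$V7),
             multimap_reads = as.integer(dt$V8),
             max_overhang = as.integer(dt$V9))
}

#' Write junction counts in STAR SJ.out.tab layout
#'
#' Inverse of [read_star_sj()] (motif and annotation columns are written
#' as 0 and 1).
#'
#' @param counts Junction count table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_star_sj <- function(counts, path) {
  dt <- as.data.table(counts)
  out <- data.table(dt$chrom, dt$intron_start + 1L, dt$intron_end,
                    chmatch(dt$strand, c("*", "+", "-")) - 1L,
                    0L, 1L, dt$unique_reads,
                    if ("multimap_reads" %in% names(dt)) dt$multimap_reads else 0L,
                    if ("max_overhang" %in% names(dt)) dt$max_overhang else 30L)
  fwrite(out, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Pool junction counts across samples
#'
#' @param count_list List of junction count tables.
#' @param sample_id Identifier for the pooled pseudo-sample.
#' @return A single junction count table with summed unique counts.
#' @export
pool_junction_counts <- function(count_list, sample_id = "pooled") {
  all <- rbindlist(count_list, use.names = TRUE, fill = TRUE)
  out <- all[, .(unique_reads = sum(unique_reads)),
             by = .(chrom, intron_start, intron_end, strand)]
  out[, sample_id := sample_id]
  setcolorder(out, c("sample_id", "chrom", "intron_start", "intron_end",
                     "strand", "unique_reads"))
  out[]
}

# count lookup closure over one sample's table; when allow_unstranded,
# strand-code-0 rows are matchable to a junction on either strand
make_count_lookup <- function(counts, allow_unstranded = FALSE) {
  cmap <- setNames(counts$unique_reads,
                   junction_id(counts$chrom, counts$intron_start,
                               counts$intron_end, counts$strand))
  function(chrom, s, e, strand) {
    v <- unname(cmap[junction_id(chrom, s, e, strand)])
    if (allow_unstranded) {
      alt <- unname(cmap[junction_id(chrom, s, e, "*")])
      v[is.na(v)] <- alt[is.na(v)]
    }
    v[is.na(v)] <- 0L
    as.integer(v)
  }
}

#' Aggregate junction counts per event
#'
#' Sums counts onto each event's junction roles for one sample. Skipped
#' exon events sharing the same alternatively spliced exon (and label)
#' are merged into one record whose inclusion and skipping counts are the
#' sums over the merged events' distinct junctions. For retained-intron
#' events, the host exon expression terms `sj_3p`/`sj_5p` sum all
#' observed junctions using the 3' and 5' splice sites of every parent
#' exon. Absent junctions contribute zero. Events labeled
#' `dropped_complex` and alt-splice-site or retained-intron events with
#' no NMD junction are excluded (there is no NMD-supporting role to
#' quantify).
#'
#' @param events Classified events (see [classify_event_nmd()]).
#' @param counts A single sample's junction count table.
#' @param allow_unstranded Match strand-code-0 junction rows to either
#'   strand (default `FALSE`).
#' @return `data.table` with one row per event group and the role-summed
#'   counts `sj_inc`, `sj_skip`, `sj_nmd`, `sj_coding`, `sj_ai`,
#'   `sj_3p`, `sj_5p` (NA where the role does not apply).
#' @export
aggregate_event_counts <- function(events, counts, allow_unstranded = FALSE) {
  ev <- as.data.table(events)
  if (!"label" %in% names(ev))
    stop("events must be classified first (classify_event_nmd)")
  ev <- ev[label != "dropped_complex"]
  ev <- ev[!(event_type %in% c("A3", "A5", "RI") & label == "non_NMD")]
  sid <- if (nrow(counts)) counts$sample_id[1] else NA_character_
  if (!nrow(ev)) {
    return(data.table(group_id = character(), event_type = character(),
                      label = character(), gene_id = character(),
                      gene_symbol = character(), chrom = character(),
                      strand = character(), sample_id = character(),
                      event_ids = character(), n_events = integer(),
                      sj_inc = integer(), sj_skip = integer(),
                      sj_nmd = integer(), sj_coding = integer(),
                      sj_ai = integer(), sj_3p = integer(),
                      sj_5p = integer()))
  }
  lookup <- make_count_lookup(counts, allow_unstranded)
  cdt <- as.data.table(counts)

  rows <- list()
  ## SE: merge by shared alternative exon
  se <- ev[event_type == "SE"]
  if (nrow(se)) {
    rows$se <- se[, {
      incj <- unique(rbind(data.table(s = j1_start, e = j1_end),
                           data.table(s = j2_start, e = j2_end)))
      skj <- unique(data.table(s = j3_start, e = j3_end))
      list(event_ids = paste(sort(event_id), collapse = ","),
           n_events = .N,
           gene_symbol = gene_symbol[1],
           sj_inc = sum(lookup(chrom[1], incj$s, incj$e, strand[1])),
           sj_skip = sum(lookup(chrom[1], skj$s, skj$e, strand[1])),
           sj_nmd = NA_integer_, sj_coding = NA_integer_,
           sj_ai = NA_integer_, sj_3p = NA_integer_, sj_5p = NA_integer_)
    }, by = .(gene_id, chrom, strand, alt_start, alt_end, label,
              event_type)]
    rows$se[, group_id := sprintf("%s;SEx:%s:%d-%d:%s", gene_id, chrom,
                                  alt_start + 1L, alt_end, strand)]
  }
  ## A3/A5: the NMD-role junction vs the coding one
  ass <- ev[event_type %in% c("A3", "A5")]
  if (nrow(ass)) {
    rows$ass <- ass[, {
      nmd_j <- if (nmd_role == "long") c(j1_start, j1_end) else c(j2_start, j2_end)
      cod_j <- if (nmd_role == "long") c(j2_start, j2_end) else c(j1_start, j1_end)
      list(event_ids = event_id, n_events = 1L, gene_symbol = gene_symbol,
           sj_inc = NA_integer_, sj_skip = NA_integer_,
           sj_nmd = lookup(chrom, nmd_j[1], nmd_j[2], strand),
           sj_coding = lookup(chrom, cod_j[1], cod_j[2], strand),
           sj_ai = NA_integer_, sj_3p = NA_integer_, sj_5p = NA_integer_)
    }, by = .(event_id, gene_id, chrom, strand, alt_start, alt_end,
              label, event_type)]
    rows$ass[, group_id := event_id]
    rows$ass[, event_id := NULL]
  }
  ## RI: ai junction + summed host-exon splice-site junctions
  ri <- ev[event_type == "RI"]
  if (nrow(ri)) {
    rows$ri <- ri[, {
      pe <- strsplit(parent_exons, ",", fixed = TRUE)[[1]]
      ps <- as.integer(sub("-.*", "", pe))
      pend <- as.integer(sub(".*-", "", pe))
      cc <- cdt[chrom == .BY$chrom & strand == .BY$strand]
      if (.BY$strand == "+") {
        s3 <- cc[intron_end %in% ps]    # junctions into the exon 3'ss (acceptor)
        s5 <- cc[intron_start %in% pend]  # junctions out of the exon 5'ss (donor)
      } else {
        s3 <- cc[intron_start %in% pend]
        s5 <- cc[intron_end %in% ps]
      }
      list(event_ids = event_id, n_events = 1L, gene_symbol = gene_symbol,
           sj_inc = NA_integer_, sj_skip = NA_integer_,
           sj_nmd = NA_integer_, sj_coding = NA_integer_,
           sj_ai = lookup(chrom, j1_start, j1_end, strand),
           sj_3p = sum(s3$unique_reads),
           sj_5p = sum(s5$unique_reads))
    }, by = .(event_id, gene_id, chrom, strand, alt_start, alt_end,
              label, event_type)]
    rows$ri[, group_id := event_id]
    rows$ri[, event_id := NULL]
  }
  out <- rbindlist(rows, use.names = TRUE)
  out[, sample_id := sid]
  setcolorder(out, c("group_id", "event_type", "label", "gene_id",
                     "gene_symbol", "chrom", "strand", "sample_id",
                     "event_ids", "n_events", "sj_inc", "sj_skip",
                     "sj_nmd", "sj_coding", "sj_ai", "sj_3p", "sj_5p"))
  setorder(out, gene_id, group_id)
  out[]
}

#' PSI for cassette (skipped exon) events
#'
#' Inclusion PSI is `sj_inc / (sj_inc + 2 * sj_skip)`: the inclusion
#' count sums two junctions per included molecule while the skipping
#' count comes from one, hence the factor 2. For skipping-type events
#' the reported value is the complement `1 - PSI`.
#'
#' @param sj_inc Summed inclusion-junction counts.
#' @param sj_skip Skipping-junction counts.
#' @param orientation `"EI"` for inclusion events, `"ES"` for skipping.
#' @return PSI in `[0, 1]`, `NA` when both counts are zero.
#' @export
psi_cassette <- function(sj_inc, sj_skip, orientation = c("EI", "ES")) {
  orientation <- match.arg(orientation)
  stopifnot(all(sj_inc >= 0, na.rm = TRUE), all(sj_skip >= 0, na.rm = TRUE))
  den <- sj_inc + 2 * sj_skip
  psi <- ifelse(den > 0, sj_inc / den, NA_real_)
  if (orientation == "ES") 1 - psi else psi
}

#' PSI for alternative 3'/5' splice-site events
#'
#' `sj_nmd / (sj_nmd + sj_coding)`.
#'
#' @param sj_nmd Count on the NMD-labeled junction.
#' @param sj_coding Count on the coding junction.
#' @return PSI in `[0, 1]`, `NA` when both counts are zero.
#' @export
psi_alt_ss <- function(sj_nmd, sj_coding) {
  stopifnot(all(sj_nmd >= 0, na.rm = TRUE), all(sj_coding >= 0, na.rm = TRUE))
  den <- sj_nmd + sj_coding
  ifelse(den > 0, sj_nmd / den, NA_real_)
}

#' PSI for alternative intron (exitron) events
#'
#' The host exon's expression is estimated as `(sj_3p + sj_5p) / 2`
#' (average of the junctions entering and leaving the exon); the
#' alternative-intron count is clipped to that estimate, which acts as
#' the upper limit, so the ratio lies in `[0, 1]`.
#'
#' @param sj_ai Count on the alternative-intron junction.
#' @param sj_3p,sj_5p Summed counts on the host exon's 3' and 5' splice
#'   sites.
#' @return PSI in `[0, 1]`, `NA` when the exon-expression estimate is
#'   zero.
#' @export
psi_alt_intron <- function(sj_ai, sj_3p, sj_5p) {
  stopifnot(all(sj_ai >= 0, na.rm = TRUE), all(sj_3p >= 0, na.rm = TRUE),
            all(sj_5p >= 0, na.rm = TRUE))
  expr <- (sj_3p + sj_5p) / 2
  ifelse(expr > 0, pmin(sj_ai, expr) / expr, NA_real_)
}

#' Quantify PSI for classified events against junction counts
#'
#' Runs [aggregate_event_counts()] for each sample and computes the PSI
#' appropriate to each event label, plus the count on the
#' NMD-supporting junction role(s) (`nmd_reads`): inclusion junctions
#' for EI, the skipping junction for ES, the NMD alternative-splice-site
#' junction for A3/A5, and the alternative-intron junction for AI.
#' Cassette (non-NMD) records carry the inclusion PSI and `NA`
#' `nmd_reads`.
#'
#' @param events Classified events.
#' @param counts A junction count table, or a list of them (one per
#'   sample).
#' @param allow_unstranded See [aggregate_event_counts()].
#' @return `data.table` of per-event, per-sample records with `psi` and
#'   `nmd_reads`.
#' @export
quantify_events <- function(events, counts, allow_unstranded = FALSE) {
  if (is.data.frame(counts)) counts <- list(counts)
  recs <- rbindlist(lapply(counts, function(cc)
    aggregate_event_counts(events, cc, allow_unstranded)), use.names = TRUE)
  if (!nrow(recs)) {
    recs[, `:=`(psi = numeric(), nmd_reads = integer())]
    return(recs[])
  }
  recs[, psi := NA_real_]
  recs[, nmd_reads := NA_integer_]
  recs[label %in% c("EI_NMD", "cassette_exon"),
       psi := psi_cassette(sj_inc, sj_skip, "EI")]
  recs[label == "EI_NMD", nmd_reads := sj_inc]
  recs[label == "ES_NMD", `:=`(psi = psi_cassette(sj_inc, sj_skip, "ES"),
                               nmd_reads = sj_skip)]
  recs[label %in% c("A3_NMD", "A5_NMD"),
       `:=`(psi = psi_alt_ss(sj_nmd, sj_coding), nmd_reads = sj_nmd)]
  recs[label == "AI_NMD", `:=`(psi = psi_alt_intron(sj_ai, sj_3p, sj_5p),
                               nmd_reads = sj_ai)]
  recs[]
}

#' Apply abundance filters to PSI records
#'
#' A record passes when the count on its NMD-supporting junction
#' role(s) is at least `min_junction_reads` AND its PSI is at least
#' `min_psi`; both comparisons are inclusive. With
#' `scope = "all_roles"` every junction role used by the event's PSI
#' must reach the read threshold instead. Failing records are retained
#' with `fail_reasons`; records whose PSI is undefined fail with reason
#' `zero_denominator`, and non-NMD records fail with `non_nmd_event`.
#'
#' @param records Output of [quantify_events()].
#' @param min_junction_reads Minimum junction read pairs (default 3).
#' @param min_psi Minimum PSI (default 0.03).
#' @param scope Which junction roles the read threshold applies to.
#' @return The records with `passed_filters` and `fail_reasons` columns.
#' @export
apply_filters <- function(records, min_junction_reads = 3L, min_psi = 0.03,
                          scope = c("nmd_role", "all_roles")) {
  scope <- match.arg(scope)
  stopifnot(min_junction_reads >= 0L, min_psi >= 0, min_psi <= 1)
  recs <- copy(as.data.table(records))
  if (!nrow(recs)) {
    recs[, `:=`(passed_filters = logical(), fail_reasons = character())]
    return(recs[])
  }
  role_min <- if (scope == "nmd_role") {
    as.numeric(recs$nmd_reads)
  } else {
    apply(recs[, .(sj_inc, sj_skip, sj_nmd, sj_coding, sj_ai)], 1L,
          function(r) if (all(is.na(r))) NA_real_ else min(r, na.rm = TRUE))
  }
  reasons <- vector("list", nrow(recs))
  non_nmd <- !recs$label %in% .NMD_LABELS
  undef <- is.na(recs$psi)
  low_reads <- !non_nmd & !is.na(role_min) & role_min < min_junction_reads
  low_psi <- !non_nmd & !undef & recs$psi < min_psi
  for (i in seq_len(nrow(recs))) {
    r <- character()
    if (non_nmd[i]) r <- c(r, "non_nmd_event")
    if (undef[i]) r <- c(r, "zero_denominator")
    if (low_reads[i]) r <- c(r, "low_junction_reads")
    if (low_psi[i]) r <- c(r, "low_psi")
    reasons[[i]] <- r
  }
  recs[, passed_filters := lengths(reasons) == 0L]
  recs[, fail_reasons := vapply(reasons, paste, "", collapse = ",")]
  recs[]
}

#' Summarize the unique-gene catalog of non-productive events
#'
#' An event group is catalogued when it passes filters in at least one
#' sample (`policy = "any_sample"`, the default) or in all samples; the
#' reported PSI is the maximum over passing samples. Headline counters
#' count each gene once even when it carries several event types; the
#' per-type tallies allow a gene to appear under several types.
#'
#' @param records Filtered records from [apply_filters()].
#' @param disease Optional gene-disease table from
#'   [load_gene_disease()]; adds disease flags and counts.
#' @param policy Aggregation across samples.
#' @return A `gene_catalog`: list with `events` (catalogued event
#'   groups), `genes` (one row per unique gene), and `summary`
#'   (`n_genes`, `n_disease_genes`, per-label gene tallies).
#' @export
summarize_gene_catalog <- function(records, disease = NULL,
                                   policy = c("any_sample", "all_samples")) {
  policy <- match.arg(policy)
  recs <- as.data.table(records)
  if (!"passed_filters" %in% names(recs))
    stop("records must be filtered first (apply_filters)")
  recs <- recs[label %in% .NMD_LABELS]
  n_samples <- max(1L, length(unique(recs$sample_id)))
  ev <- if (nrow(recs)) recs[, .(
    gene_symbol = gene_symbol[1],
    event_type = event_type[1], label = label[1],
    n_samples_passing = sum(passed_filters),
    psi_reported = if (any(passed_filters)) max(psi[passed_filters]) else NA_real_
  ), by = .(group_id, gene_id)] else
    data.table(group_id = character(), gene_id = character(),
               gene_symbol = character(), event_type = character(),
               label = character(), n_samples_passing = integer(),
               psi_reported = numeric())
  keep <- if (policy == "any_sample") ev$n_samples_passing >= 1L
          else ev$n_samples_passing == n_samples
  ev <- ev[keep]
  genes <- if (nrow(ev)) ev[, .(
    gene_symbol = gene_symbol[1],
    labels = paste(sort(unique(label)), collapse = ","),
    n_events = .N
  ), by = gene_id] else
    data.table(gene_id = character(), gene_symbol = character(),
               labels = character(), n_events = integer())
  by_label <- if (nrow(ev))
    ev[, .(n_genes = length(unique(gene_id))), by = label][order(label)]
  else data.table(label = character(), n_genes = integer())
  cat_obj <- structure(list(
    events = ev[order(gene_id, group_id)],
    genes = genes[order(gene_id)],
    summary = list(n_genes = nrow(genes),
                   n_disease_genes = NA_integer_,
                   genes_per_label = by_label)
  ), class = "gene_catalog")
  if (!is.null(disease)) cat_obj <- annotate_catalog(cat_obj, disease)
  cat_obj
}

#' @export
print.gene_catalog <- function(x, ...) {
  cat(sprintf("gene_catalog: %d unique genes, %d catalogued events\n",
              x$summary$n_genes, nrow(x$events)))
  if (!is.na(x$summary$n_disease_genes))
    cat(sprintf("  disease-associated genes: %d\n",
                x$summary$n_disease_genes))
  if (nrow(x$summary$genes_per_label)) {
    cat("  genes per event label:\n")
    for (i in seq_len(nrow(x$summary$genes_per_label)))
      cat(sprintf("    %-14s %d\n", x$summary$genes_per_label$label[i],
                  x$summary$genes_per_label$n_genes[i]))
  }
  invisible(x)
}
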