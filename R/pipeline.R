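# End-to-end driver: annotation -> junction labels -> event catalog ->
# per-sample PSI -> filters -> unique-gene catalog, with optional sample
# QC gating and disease annotation.

#' Run the full non-productive splicing discovery pipeline
#'
#' Chains [load_annotations()], [extract_junction_labels()],
#' [enumerate_events()], [classify_event_nmd()], [read_star_sj()],
#' [quantify_events()], [apply_filters()] and
#' [summarize_gene_catalog()]. When a QC metrics table is given,
#' failing samples are excluded before quantification; when disease and
#' gene_info tables are given, the catalog is disease-annotated.
#'
#' @param gtf,genepred Annotation file path(s); at least one required.
#' @param sj_manifest Sample manifest: a TSV path or `data.frame` with
#'   columns `sample_id`, `path` (SJ.out.tab files), and optionally
#'   `condition`.
#' @param disease,gene_info Optional disease-association and
#'   gene_info-style TSV paths (both or neither).
#' @param qc_metrics Optional QC metrics TSV path or `data.frame`; see
#'   [evaluate_samples()].
#' @param min_junction_reads,min_psi Abundance filters (defaults 3 and
#'   0.03).
#' @param min_intron_length Minimum valid intron length (default 20).
#' @param min_capture_efficiency,max_dup_diff QC thresholds.
#' @param aggregation `"any_sample"` (catalog events passing in >= 1
#'   sample, per-sample PSI) or `"pooled"` (sum counts across samples
#'   first).
#' @param allow_unstranded Match undefined-strand junction rows to
#'   either strand.
#' @return An `nmdscan_run`: list with `db`, `labels`, `events`, `psi`
#'   (filtered records), `catalog`, `qc` (when gated), and `params`.
#' @export
run_pipeline <- function(gtf = NULL, genepred = NULL, sj_manifest,
                         disease = NULL, gene_info = NULL,
                         qc_metrics = NULL,
                         min_junction_reads = 3L, min_psi = 0.03,
                         min_intron_length = 20L,
                         min_capture_efficiency = 0.70,
                         max_dup_diff = 0.10,
                         aggregation = c("any_sample", "pooled"),
                         allow_unstranded = FALSE) {
  aggregation <- match.arg(aggregation)
  if (is.null(gtf) && is.null(genepred))
    stop("at least one annotation file is required")
  man <- if (is.character(sj_manifest)) fread(sj_manifest, sep = "\t")
         else as.data.table(sj_manifest)
  if (!all(c("sample_id", "path") %in% names(man)))
    stop("manifest needs sample_id and path columns")

  qc <- NULL
  if (!is.null(qc_metrics)) {
    qm <- if (is.character(qc_metrics)) fread(qc_metrics, sep = "\t")
          else as.data.table(qc_metrics)
    qc <- filter_samples(qm, min_capture_efficiency, max_dup_diff)
    drop <- intersect(man$sample_id, qc$excluded$sample_id)
    if (length(drop))
      message("excluding ", length(drop), " sample(s) failing QC: ",
              paste(drop, collapse = ", "))
    man <- man[!sample_id %in% qc$excluded$sample_id]
    if (!nrow(man)) stop("all samples excluded by QC")
  }

  db <- load_annotations(gtf = gtf, genepred = genepred)
  labels <- extract_junction_labels(db, min_intron_length)
  events <- enumerate_events(db, min_intron_length)
  events <- classify_event_nmd(events, labels)

  counts <- lapply(seq_len(nrow(man)), function(i)
    read_star_sj(man$path[i], man$sample_id[i]))
  if (aggregation == "pooled")
    counts <- list(pool_junction_counts(counts))
  recs <- quantify_events(events, counts, allow_unstranded)
  recs <- apply_filters(recs, min_junction_reads, min_psi)

  dz <- NULL
  if (!is.null(disease) && !is.null(gene_info))
    dz <- load_gene_disease(disease, gene_info)
  catalog <- summarize_gene_catalog(recs, disease = dz)

  structure(list(db = db, labels = labels, events = events, psi = recs,
                 catalog = catalog, qc = qc,
                 params = list(min_junction_reads = min_junction_reads,
                               min_psi = min_psi,
                               min_intron_length = min_intron_length,
                               aggregation = aggregation)),
            class = "nmdscan_run")
}

#' @export
print.nmdscan_run <- function(x, ...) {
  cat("nmdscan_run\n")
  cat(sprintf("  transcripts: %d; junctions labeled: %d (%d NMD)\n",
              nrow(x$db$transcripts), nrow(x$labels),
              sum(x$labels$label == "NMD")))
  cat(sprintf("  events: %d (%s)\n", nrow(x$events),
              paste(names(table(x$events$label)), table(x$events$label),
                    sep = "=", collapse = ", ")))
  cat(sprintf("  PSI records: %d (%d passing filters)\n",
              nrow(x$psi), sum(x$psi$passed_filters)))
  print(x$catalog)
  invisible(x)
}
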