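# Sample-level quality control: exclusion logic applied to precomputed
# RNA-seq QC metrics (raw-metric computation is delegated to the usual
# QC tools; this module only consumes a metrics table).

.QC_REQUIRED <- c("sample_id", "mean_base_quality", "gc_percent",
                  "adapter_flag", "dup_rate_r1", "dup_rate_r2",
                  "uniquely_mapped_fraction", "coverage_uniformity_flag",
                  "insert_size_flag")

#' Evaluate per-sample QC metrics against exclusion thresholds
#'
#' A sample fails when its capture efficiency (fraction of reads
#' uniquely mapped to the transcriptome) is below
#' `min_capture_efficiency` (the boundary itself passes), when the
#' absolute difference of the R1 and R2 duplication rates exceeds
#' `max_dup_diff`, or when any boolean problem flag (adapters, coverage
#' uniformity, insert size) is raised. Every violated rule is reported.
#'
#' @param metrics `data.frame` with the columns listed in the package's
#'   QC metrics schema (see Details in the README).
#' @param min_capture_efficiency Minimum capture efficiency
#'   (default 0.70).
#' @param max_dup_diff Maximum absolute R1/R2 duplication-rate
#'   difference (default 0.10; the cutoff value is configurable because
#'   only the rule, not its magnitude, is standard).
#' @return The metrics table with `qc_pass` and `qc_reasons` columns.
#' @export
evaluate_samples <- function(metrics, min_capture_efficiency = 0.70,
                             max_dup_diff = 0.10) {
  m <- as.data.table(metrics)
  miss <- setdiff(.QC_REQUIRED, names(m))
  if (length(miss))
    stop("metrics table lacks required column(s): ",
         paste(miss, collapse = ", "))
  fr_cols <- c("dup_rate_r1", "dup_rate_r2", "uniquely_mapped_fraction")
  for (col in fr_cols) {
    v <- m[[col]]
    if (anyNA(v)) stop("missing values in metric '", col, "'")
    if (any(v < 0 | v > 1))
      stop("metric '", col, "' outside [0, 1]")
  }
  reasons <- vector("list", nrow(m))
  for (i in seq_len(nrow(m))) {
    r <- character()
    if (m$uniquely_mapped_fraction[i] < min_capture_efficiency)
      r <- c(r, "capture_efficiency")
    if (abs(m$dup_rate_r1[i] - m$dup_rate_r2[i]) > max_dup_diff)
      r <- c(r, "r1_r2_dup_difference")
    if (isTRUE(m$adapter_flag[i])) r <- c(r, "adapter_content")
    if (isTRUE(m$coverage_uniformity_flag[i])) r <- c(r, "coverage_uniformity")
    if (isTRUE(m$insert_size_flag[i])) r <- c(r, "insert_size")
    reasons[[i]] <- r
  }
  m[, qc_pass := lengths(reasons) == 0L]
  m[, qc_reasons := vapply(reasons, paste, "", collapse = ",")]
  m[]
}

#' Partition samples into kept and excluded sets
#'
#' @inheritParams evaluate_samples
#' @return List with `kept` and `excluded` metric tables (the excluded
#'   table carries `qc_reasons`); the two partitions are exhaustive and
#'   disjoint.
#' @export
filter_samples <- function(metrics, min_capture_efficiency = 0.70,
                           max_dup_diff = 0.10) {
  m <- as.data.table(metrics)
  if (anyDuplicated(m$sample_id))
    stop("duplicate sample_id(s): ",
         paste(unique(m$sample_id[duplicated(m$sample_id)]), collapse = ", "))
  ev <- evaluate_samples(m, min_capture_efficiency, max_dup_diff)
  list(kept = ev[qc_pass == TRUE], excluded = ev[qc_pass == FALSE])
}
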