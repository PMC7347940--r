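# Synthetic AS-NMD study generator: seeded construction of transcript
# annotations with planted non-productive events of every supported
# type, Poisson junction-count simulation under an NMD degradation
# model, and companion conservation / QC / disease fixtures with known
# ground truth.
#
# Generative model, per gene: a fraction psi of pre-mRNA molecules take
# the non-productive splicing choice; a fraction d ("NMD efficiency") of
# the resulting non-productive transcripts is degraded, so their
# steady-state survival is s = 1 - d. Cycloheximide (CHX) treatment
# blocks NMD and forces d = 0. The observable non-productive fraction is
#   f(psi, d) = psi * (1 - d) / (psi * (1 - d) + (1 - psi)),
# which equals psi under CHX. Junction counts are drawn independently
# per junction as Poisson with intensity proportional to the summed
# abundance of the isoforms carrying that junction.

#' Closed-form observable non-productive fraction
#'
#' @param psi True non-productive splicing fraction in `[0, 1]`.
#' @param d NMD efficiency (fraction of non-productive transcripts
#'   degraded) in `[0, 1]`.
#' @return `psi * (1 - d) / (psi * (1 - d) + (1 - psi))`.
#' @export
expected_nonproductive_fraction <- function(psi, d) {
  stopifnot(all(psi >= 0 & psi <= 1), all(d >= 0 & d <= 1))
  s <- 1 - d
  ifelse(psi * s + (1 - psi) > 0,
         psi * s / (psi * s + (1 - psi)), NA_real_)
}

#' Configuration for the synthetic AS-NMD study
#'
#' Defaults encode the study conditions the generator emulates: true
#' non-productive fractions spanning 0.186 to 0.89 (the observed
#' post-NMD-inhibition abundance range), per-gene NMD efficiencies
#' drawn so that the DMSO-to-CHX fold increase of the non-productive
#' fraction spans about 1.1x to 9x, and an event-type mix in which 2/3
#' of genes carry a planted NMD event (60 genes by default: 15 exon
#' inclusion, 5 exon skipping, 10 alternative 3'ss, 5 alternative 5'ss,
#' 5 exitron, and 20 genes with only a coding cassette exon).
#'
#' @param n_genes Number of genes.
#' @param event_mix Named proportions over
#'   `c("EI","ES","A3","A5","AI","none")`; normalized to sum to 1.
#' @param psi_range Range the per-gene true psi is drawn from.
#' @param fold_range Range of the CHX/DMSO fold increase used to derive
#'   per-gene NMD efficiency: given psi and fold F, `d = 1 - (1 - psi)
#'   / (F - psi)`.
#' @param depth Expected junction reads per gene (summed over its
#'   junctions).
#' @param chx Default treatment state for simulated samples (`TRUE`
#'   forces d = 0).
#' @param refseq_fraction Fraction of genes emitted as RefSeq-style
#'   (NM_/NR_ accessions, written to genePred) rather than GENCODE-style
#'   (written to GTF).
#' @param archetypes Include four fixed archetype genes (two poison
#'   exons with psi 0.30 and 0.89, one alternative 3'ss with psi 0.47
#'   and a 176-nt acceptor shift, one exitron with psi 0.20) modeled on
#'   well-characterized AS-NMD targets.
#' @param psi_values,d_values Optional explicit per-NMD-gene values
#'   overriding the random draws (recycled).
#' @param alt_ss_offset Splice-site shift in nt for A3/A5 genes.
#' @param seed Integer seed; every downstream draw is reproducible from
#'   it.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_genes = 60L,
                       event_mix = c(EI = 3, ES = 1, A3 = 2, A5 = 1,
                                     AI = 1, none = 4) / 12,
                       psi_range = c(0.186, 0.89),
                       fold_range = c(1.1, 9),
                       depth = 2000,
                       chx = FALSE,
                       refseq_fraction = 0.2,
                       archetypes = TRUE,
                       psi_values = NULL,
                       d_values = NULL,
                       alt_ss_offset = 60L,
                       seed = 1L) {
  stopifnot(n_genes >= 1L,
            all(names(event_mix) %in% c("EI", "ES", "A3", "A5", "AI", "none")),
            all(event_mix >= 0), sum(event_mix) > 0,
            all(psi_range >= 0 & psi_range <= 1),
            all(fold_range > 1), depth > 0,
            refseq_fraction >= 0, refseq_fraction <= 1)
  mix <- setNames(rep(0, 6), c("EI", "ES", "A3", "A5", "AI", "none"))
  mix[names(event_mix)] <- event_mix
  mix <- mix / sum(mix)
  if (!is.null(psi_values))
    stopifnot(all(psi_values >= 0 & psi_values < 1))
  if (!is.null(d_values))
    stopifnot(all(d_values >= 0 & d_values <= 1))
  structure(list(n_genes = as.integer(n_genes), event_mix = mix,
                 psi_range = psi_range, fold_range = fold_range,
                 depth = depth, chx = chx,
                 refseq_fraction = refseq_fraction,
                 archetypes = archetypes, psi_values = psi_values,
                 d_values = d_values,
                 alt_ss_offset = as.integer(alt_ss_offset),
                 seed = as.integer(seed)),
            class = "sim_config")
}

# largest-remainder allocation of n genes over the mix proportions
allocate_types <- function(mix, n) {
  raw <- mix * n
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    o <- order(raw - base, decreasing = TRUE)
    base[o[seq_len(rem)]] <- base[o[seq_len(rem)]] + 1
  }
  as.integer(base)
}

# Gene geometry, built in transcript-space (5'->3' left to right) and
# mirrored onto the genome for minus-strand genes. Returns local exon
# lists for the productive (P) and non-productive (N) isoforms plus the
# local stop positions and the event's alternative region.
build_gene_geometry <- function(type, alt_ss_offset = 60L) {
  widths <- as.integer(round(runif(5, 140, 240)))
  introns <- as.integer(round(runif(4, 300, 420)))
  starts <- cumsum(c(0L, head(widths, -1) + introns))
  p_ex <- data.table(start = starts, end = starts + widths)
  # productive stop: inside the last exon (never NMD-predicted)
  p_stop <- p_ex$start[5] + 60L
  alt <- c(NA_integer_, NA_integer_)
  if (type == "EI") {
    xs <- p_ex$end[2] + 100L
    xe <- xs + 90L
    n_ex <- rbind(p_ex[1:2], data.table(start = xs, end = xe), p_ex[3:5])
    n_stop <- xs + 29L
    alt <- c(xs, xe)
  } else if (type == "ES") {
    n_ex <- p_ex[c(1, 2, 4, 5)]
    n_stop <- p_ex$start[4] + 29L
    alt <- c(p_ex$start[3], p_ex$end[3])
  } else if (type == "A3") {
    ns <- p_ex$start[3] - alt_ss_offset
    n_ex <- copy(p_ex)
    n_ex$start[3] <- ns
    n_stop <- ns + 29L
    alt <- c(ns, p_ex$start[3])
  } else if (type == "A5") {
    ne <- p_ex$end[3] + alt_ss_offset
    n_ex <- copy(p_ex)
    n_ex$end[3] <- ne
    n_stop <- p_ex$end[3] + 19L
    alt <- c(p_ex$end[3], ne)
  } else if (type == "AI") {
    d <- p_ex$start[3] + 50L
    a <- p_ex$end[3] - 50L
    n_ex <- rbind(p_ex[1:2],
                  data.table(start = c(p_ex$start[3], a),
                             end = c(d, p_ex$end[3])),
                  p_ex[4:5])
    n_stop <- a + 9L
    alt <- c(d, a)
  } else if (type == "none") {
    # coding cassette exon: second isoform skips exon 3, same stop
    n_ex <- p_ex[c(1, 2, 4, 5)]
    n_stop <- p_stop
    alt <- c(p_ex$start[3], p_ex$end[3])
  } else stop("unknown gene type: ", type)
  list(p_ex = p_ex, n_ex = n_ex, p_stop = p_stop, n_stop = n_stop,
       alt = alt, span = p_ex$end[5])
}

mirror_exons <- function(ex, span, offset) {
  data.table(start = offset + span - rev(ex$end),
             end = offset + span - rev(ex$start))
}

#' Generate a synthetic transcript database with known truth
#'
#' Each gene receives a productive isoform and, according to its
#' assigned event type, a non-productive isoform whose premature stop
#' codon satisfies the 50-nt rule by construction (verified by
#' re-applying [evaluate_ptc_rule()] during generation). `none` genes
#' get a second coding isoform differing by one in-frame cassette exon,
#' so they carry an alternative-splicing event that is not
#' NMD-inducing. Genes alternate strands and are laid out on one
#' synthetic chromosome.
#'
#' @param config A [sim_config()].
#' @return An `nmd_simulation`: list with `config`, `db` (a
#'   [transcript_db]) and `truth` (per-gene data.table: event type, true
#'   psi, NMD efficiency `d`, expected CHX fold change, alternative
#'   region, source dialect).
#' @export
generate_annotation <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_genes
  counts <- allocate_types(config$event_mix, n)
  types <- rep(names(config$event_mix), counts)

  arch <- NULL
  if (config$archetypes) {
    arch <- data.table(
      symbol = c("PCCA", "SYNGAP1", "CD274", "SCN1A"),
      type = c("EI", "A3", "AI", "EI"),
      psi = c(0.30, 0.47, 0.20, 0.89),
      offset = c(config$alt_ss_offset, 176L, config$alt_ss_offset,
                 config$alt_ss_offset))
    for (tt in arch$type) {
      i <- which(types == tt)[1]
      if (is.na(i))
        stop("event mix leaves no room for the '", tt, "' archetype; ",
             "increase n_genes or disable archetypes")
      types <- types[-i]
    }
  }
  types <- c(if (!is.null(arch)) arch$type, sample(types))

  nmd_idx <- which(types != "none")
  n_nmd <- length(nmd_idx)
  psi <- rep(NA_real_, n)
  psi[nmd_idx] <- if (!is.null(config$psi_values))
    rep_len(config$psi_values, n_nmd)
  else runif(n_nmd, config$psi_range[1], config$psi_range[2])
  if (!is.null(arch)) psi[seq_len(4)] <- arch$psi
  fold <- rep(NA_real_, n)
  d <- rep(NA_real_, n)
  fold[nmd_idx] <- runif(n_nmd, config$fold_range[1], config$fold_range[2])
  d[nmd_idx] <- 1 - (1 - psi[nmd_idx]) / (fold[nmd_idx] - psi[nmd_idx])
  d[nmd_idx] <- pmin(pmax(d[nmd_idx], 0), 1)
  if (!is.null(config$d_values)) {
    d[nmd_idx] <- rep_len(config$d_values, n_nmd)
    fold[nmd_idx] <- psi[nmd_idx] /
      expected_nonproductive_fraction(psi[nmd_idx], d[nmd_idx])
  }

  is_refseq <- rep(FALSE, n)
  free <- setdiff(seq_len(n), if (!is.null(arch)) seq_len(4) else integer())
  n_rs <- round(config$refseq_fraction * length(free))
  if (n_rs > 0) is_refseq[sample(free, n_rs)] <- TRUE

  spacing <- 6000L
  txl <- list(); exl <- list(); trl <- list()
  nm_counter <- 0L
  for (g in seq_len(n)) {
    type <- types[g]
    offset <- (g - 1L) * spacing + 1000L
    strand <- if (g %% 2L == 1L) "+" else "-"
    off_arch <- if (!is.null(arch) && g <= 4L) arch$offset[g]
                else config$alt_ss_offset
    geo <- build_gene_geometry(type, off_arch)
    symbol <- if (!is.null(arch) && g <= 4L) arch$symbol[g]
              else sprintf("SYN%04d", g)
    src <- if (is_refseq[g]) "refseq" else "gencode"
    # genePred has no gene_id field distinct from name2, so RefSeq-style
    # genes use the symbol as gene_id to round-trip exactly
    gene_id <- if (is_refseq[g]) symbol else sprintf("SYNG%04d", g)
    if (is_refseq[g]) {
      nm_counter <- nm_counter + 1L
      p_id <- sprintf("NM_%06d", nm_counter)
      # the second isoform of a "none" gene is coding, hence NM_
      n_id <- if (type == "none") sprintf("NM_9%05d", nm_counter)
              else sprintf("NR_%06d", nm_counter)
    } else {
      p_id <- paste0(gene_id, ".P1")
      n_id <- paste0(gene_id, ".N1")
    }
    place <- function(ex, stop_local) {
      if (strand == "+") {
        list(ex = data.table(start = offset + ex$start,
                             end = offset + ex$end),
             stop = offset + stop_local)
      } else {
        list(ex = mirror_exons(ex, geo$span, offset),
             stop = offset + geo$span - 1L - stop_local)
      }
    }
    p <- place(geo$p_ex, geo$p_stop)
    np <- place(geo$n_ex, geo$n_stop)
    alt_g <- if (!anyNA(geo$alt)) {
      if (strand == "+") offset + geo$alt
      else c(offset + geo$span - geo$alt[2], offset + geo$span - geo$alt[1])
    } else c(NA_integer_, NA_integer_)

    np_biotype <- if (type == "none") "protein_coding"
                  else if (src == "refseq") "noncoding" else "nmd"
    np_cds <- if (type == "none") np$stop
              else if (src == "refseq") NA_integer_ else np$stop
    add_tx <- function(id, ex, cds, biotype) {
      txl[[length(txl) + 1L]] <<- data.table(
        source = src, transcript_id = id, gene_id = gene_id,
        gene_symbol = symbol, chrom = "chrS", strand = strand,
        biotype = biotype, cds_end = as.integer(cds))
      nx <- nrow(ex)
      rk <- if (strand == "+") seq_len(nx) else rev(seq_len(nx))
      exl[[length(exl) + 1L]] <<- data.table(
        source = src, transcript_id = id, gene_id = gene_id,
        chrom = "chrS", strand = strand, start = as.integer(ex$start),
        end = as.integer(ex$end), exon_rank = as.integer(rk))
    }
    add_tx(p_id, p$ex, p$stop, "protein_coding")
    add_tx(n_id, np$ex, np_cds, np_biotype)
    trl[[length(trl) + 1L]] <- data.table(
      gene_id = gene_id, gene_symbol = symbol, source = src,
      chrom = "chrS", strand = strand, event_type = type,
      psi_true = psi[g], nmd_efficiency = d[g], fold_expected = fold[g],
      alt_start = as.integer(alt_g[1]), alt_end = as.integer(alt_g[2]),
      productive_tx = p_id, nonproductive_tx = n_id)
  }
  db <- transcript_db(rbindlist(txl), rbindlist(exl))
  truth <- rbindlist(trl)

  # geometry self-check: the 50-nt rule must reproduce the intended
  # biotypes wherever a stop codon is annotated
  verdicts <- evaluate_ptc_rule(db)
  chk <- merge(db$transcripts[, .(source, transcript_id, biotype)],
               verdicts, by = c("source", "transcript_id"))
  bad <- chk[(biotype == "nmd" & verdict != "nmd_predicted") |
               (biotype == "protein_coding" & verdict == "nmd_predicted")]
  if (nrow(bad))
    stop("generation error: PTC-rule check failed for transcript(s) ",
         paste(bad$transcript_id, collapse = ", "))

  structure(list(config = config, db = db, truth = truth),
            class = "nmd_simulation")
}

#' @export
print.nmd_simulation <- function(x, ...) {
  tt <- table(x$truth$event_type)
  cat(sprintf("nmd_simulation: %d genes (%s); depth %g reads/gene\n",
              nrow(x$truth),
              paste(names(tt), tt, sep = "=", collapse = ", "),
              x$config$depth))
  invisible(x)
}

#' Simulate a junction count table from a synthetic study
#'
#' For each gene, isoform abundances are `psi * (1 - d)` for the
#' non-productive isoform (d forced to 0 under CHX) and `1 - psi` for
#' the productive one (0.5 each for `none` genes). Each junction's count
#' is Poisson with mean `depth * a_j / sum(a_j)` where `a_j` sums the
#' abundances of the isoforms carrying that junction, so the expected
#' total junction yield per gene equals `depth`.
#'
#' @param sim An `nmd_simulation`.
#' @param sample_id Sample identifier.
#' @param condition `"dmso"` (NMD active) or `"chx"` (NMD inhibited).
#' @param depth Expected junction reads per gene; defaults to the
#'   config's value.
#' @param seed Seed for this sample's draws.
#' @return A junction count table in [read_star_sj()] layout.
#' @export
simulate_counts <- function(sim, sample_id,
                            condition = if (sim$config$chx) "chx" else "dmso",
                            depth = sim$config$depth, seed = 1L) {
  stopifnot(inherits(sim, "nmd_simulation"))
  condition <- match.arg(condition, c("dmso", "chx"))
  set.seed(seed)
  intr <- transcript_introns(sim$db)
  truth <- sim$truth
  ab <- truth[, {
    s <- if (condition == "chx") 1 else 1 - nmd_efficiency
    if (event_type == "none") {
      data.table(transcript_id = c(productive_tx, nonproductive_tx),
                 abundance = c(0.5, 0.5))
    } else {
      data.table(transcript_id = c(productive_tx, nonproductive_tx),
                 abundance = c(1 - psi_true, psi_true * s))
    }
  }, by = gene_id]
  intr <- merge(intr, ab, by = c("gene_id", "transcript_id"))
  jn <- intr[, .(a = sum(abundance)),
             by = .(gene_id, chrom, strand, intron_start, intron_end)]
  jn[, lambda := depth * a / sum(a), by = gene_id]
  jn[, unique_reads := rpois(.N, lambda)]
  out <- jn[, .(sample_id = sample_id, chrom, intron_start, intron_end,
                strand, unique_reads,
                multimap_reads = 0L, max_overhang = 30L)]
  setattr(out, "condition", condition)
  setorder(out, chrom, intron_start, intron_end, strand)
  out[]
}

#' Generate random multi-isoform gene models for property testing
#'
#' Builds genes with up to `max_isoforms` transcripts derived from a
#' master exon chain by randomly skipping internal exons, shifting
#' acceptor/donor sites, and splicing introns out of exons (exitrons).
#' Transcripts with an annotated stop get their biotype from the 50-nt
#' rule; the rest are assigned `noncoding` or `other` at random.
#'
#' @param n_genes Number of genes.
#' @param max_isoforms Maximum isoforms per gene.
#' @param seed Integer seed.
#' @return A [transcript_db].
#' @export
simulate_gene_models <- function(n_genes = 50L, max_isoforms = 6L, seed = 1L) {
  set.seed(seed)
  txl <- list(); exl <- list()
  spacing <- 20000L
  for (g in seq_len(n_genes)) {
    offset <- (g - 1L) * spacing + 1000L
    strand <- if (runif(1) < 0.5) "+" else "-"
    gene_id <- sprintf("RSYN%04d", g)
    n_ex <- sample(4:7, 1)
    widths <- as.integer(round(runif(n_ex, 120, 260)))
    introns <- as.integer(round(runif(n_ex - 1L, 250, 500)))
    starts <- cumsum(c(0L, head(widths, -1) + introns))
    master <- data.table(start = offset + starts,
                         end = offset + starts + widths)
    k <- sample(seq_len(max_isoforms), 1)
    for (t in seq_len(k)) {
      ex <- copy(master)
      if (t > 1L) {
        op <- sample(c("skip", "shift_acc", "shift_don", "exitron", "keep"),
                     1, prob = c(0.3, 0.2, 0.2, 0.2, 0.1))
        if (op == "skip" && nrow(ex) >= 3L) {
          ex <- ex[-sample(2:(nrow(ex) - 1L), 1)]
        } else if (op == "shift_acc" && nrow(ex) >= 2L) {
          i <- sample(2:nrow(ex), 1)
          ex$start[i] <- ex$start[i] - sample(20:60, 1)
        } else if (op == "shift_don" && nrow(ex) >= 2L) {
          i <- sample(1:(nrow(ex) - 1L), 1)
          ex$end[i] <- ex$end[i] + sample(20:60, 1)
        } else if (op == "exitron") {
          i <- which(ex$end - ex$start >= 160L)
          if (length(i)) {
            i <- if (length(i) > 1L) sample(i, 1) else i
            d <- ex$start[i] + 50L
            a <- ex$end[i] - 50L
            ex <- rbind(ex[seq_len(i - 1L)],
                        data.table(start = c(ex$start[i], a),
                                   end = c(d, ex$end[i])),
                        if (i < nrow(ex)) ex[(i + 1L):nrow(ex)])
          }
        }
      }
      tid <- sprintf("%s.T%d", gene_id, t)
      has_cds <- runif(1) < 0.6 && nrow(ex) >= 2L
      cds <- NA_integer_
      if (has_cds) {
        i <- sample(seq_len(nrow(ex)), 1)
        w <- ex$end[i] - ex$start[i]
        cds <- ex$start[i] + sample(seq_len(w), 1) - 1L
      }
      nx <- nrow(ex)
      rk <- if (strand == "+") seq_len(nx) else rev(seq_len(nx))
      exl[[length(exl) + 1L]] <- data.table(
        source = "gencode", transcript_id = tid, gene_id = gene_id,
        chrom = "chrR", strand = strand, start = ex$start, end = ex$end,
        exon_rank = as.integer(rk))
      txl[[length(txl) + 1L]] <- data.table(
        source = "gencode", transcript_id = tid, gene_id = gene_id,
        gene_symbol = gene_id, chrom = "chrR", strand = strand,
        biotype = if (has_cds) "protein_coding"
                  else sample(c("noncoding", "other"), 1),
        cds_end = cds)
    }
  }
  db <- transcript_db(rbindlist(txl), rbindlist(exl))
  # biotype from the rule for stop-bearing transcripts
  v <- evaluate_ptc_rule(db)
  nmd_ids <- v[verdict == "nmd_predicted", .(source, transcript_id)]
  if (nrow(nmd_ids))
    db$transcripts[nmd_ids, biotype := "nmd",
                   on = c("source", "transcript_id")]
  db
}

#' Simulate per-exon conservation scores with a planted exceedance
#'
#' Exactly `round(exceedance * n)` exons are given a constant per-base
#' score at or above `threshold` (drawn uniformly in
#' `[threshold, 1]`); the rest score below it, so [conserved_fraction()]
#' recovers the planted exceedance up to rounding.
#'
#' @param exons Non-overlapping exon intervals (`chrom`, `start`,
#'   `end`).
#' @param exceedance Planted fraction of conserved exons.
#' @param threshold Conservation threshold (default 0.8).
#' @param seed Integer seed.
#' @return List with `track` (a `conservation_track`) and `truth`
#'   (exons with their drawn score and `conserved` flag).
#' @export
simulate_conservation_scores <- function(exons, exceedance = 0.16,
                                         threshold = 0.8, seed = 1L) {
  set.seed(seed)
  ex <- as.data.table(exons)[, .(chrom, start, end)]
  n <- nrow(ex)
  k <- round(exceedance * n)
  conserved <- rep(FALSE, n)
  if (k > 0) conserved[sample(n, k)] <- TRUE
  score <- numeric(n)
  score[conserved] <- runif(k, threshold, 1)
  score[!conserved] <- runif(n - k, 0.02, max(threshold - 0.02, 0.02))
  ex[, `:=`(score = score, conserved = conserved)]
  track <- conservation_track(ex[, .(chrom, start, end, score)])
  list(track = track, truth = ex[])
}

#' Simulate a sample QC metrics table with planted failures
#'
#' @param n_samples Number of samples.
#' @param n_fail_capture Samples planted below the capture-efficiency
#'   threshold.
#' @param n_fail_dup Samples planted with a large R1/R2
#'   duplication-rate difference.
#' @param min_capture_efficiency,max_dup_diff Thresholds the failures
#'   are planted against.
#' @param seed Integer seed.
#' @return List with `metrics` (schema of [evaluate_samples()]) and
#'   `truth` (`sample_id`, `intended_pass`).
#' @export
simulate_qc_metrics <- function(n_samples = 10L, n_fail_capture = 2L,
                                n_fail_dup = 1L,
                                min_capture_efficiency = 0.70,
                                max_dup_diff = 0.10, seed = 1L) {
  stopifnot(n_fail_capture + n_fail_dup <= n_samples)
  set.seed(seed)
  ids <- sprintf("S%02d", seq_len(n_samples))
  capture <- runif(n_samples, 0.75, 0.95)
  dup1 <- runif(n_samples, 0.05, 0.25)
  dup2 <- pmin(pmax(dup1 + runif(n_samples, -0.04, 0.04), 0), 1)
  fail_cap <- seq_len(n_fail_capture)
  fail_dup <- n_fail_capture + seq_len(n_fail_dup)
  capture[fail_cap] <- runif(n_fail_capture, 0.40,
                             min_capture_efficiency - 0.03)
  dup2[fail_dup] <- pmin(dup1[fail_dup] + max_dup_diff +
                           runif(n_fail_dup, 0.05, 0.2), 1)
  metrics <- data.table(
    sample_id = ids,
    mean_base_quality = round(runif(n_samples, 33, 38), 1),
    gc_percent = round(runif(n_samples, 44, 54), 1),
    adapter_flag = FALSE,
    dup_rate_r1 = round(dup1, 3), dup_rate_r2 = round(dup2, 3),
    uniquely_mapped_fraction = round(capture, 3),
    coverage_uniformity_flag = FALSE, insert_size_flag = FALSE)
  truth <- data.table(sample_id = ids,
                      intended_pass = !seq_len(n_samples) %in%
                        c(fail_cap, fail_dup))
  list(metrics = metrics, truth = truth)
}

#' Simulate gene-disease and gene_info tables with planted associations
#'
#' A subset of the simulation's NMD genes is associated with synthetic
#' disorders; one of them is reachable only through an alias (the
#' disease table lists an invented canonical symbol whose gene_info
#' synonyms include the catalog symbol), exercising alias expansion.
#'
#' @param sim An `nmd_simulation`.
#' @param fraction_associated Fraction of NMD genes to associate.
#' @param seed Integer seed.
#' @return List with `disease`, `gene_info` (data.tables matching
#'   [load_gene_disease()]'s input schemas) and `truth` (`gene_symbol`,
#'   `associated`, `via_alias`).
#' @export
simulate_disease_tables <- function(sim, fraction_associated = 0.4,
                                    seed = 1L) {
  set.seed(seed)
  nmd_genes <- sim$truth[event_type != "none", gene_symbol]
  k <- max(1L, round(fraction_associated * length(nmd_genes)))
  assoc <- sort(sample(nmd_genes, k))
  via_alias <- assoc[1]
  direct <- setdiff(assoc, via_alias)
  canon_alias <- paste0(via_alias, "CAN")
  disease <- data.table(
    symbol = c(direct, canon_alias, "DECOY1", "DECOY2"),
    disorder_id = sprintf("ORPHA:%d", 70000 + seq_len(k + 2L)),
    disorder_name = sprintf("synthetic disorder %d", seq_len(k + 2L)))
  gene_info <- data.table(
    Symbol = c(direct, canon_alias, "DECOY1", "DECOY2"),
    Synonyms = c(rep("-", length(direct)), via_alias, "-", "-"))
  truth <- data.table(
    gene_symbol = sim$truth$gene_symbol,
    associated = sim$truth$gene_symbol %in% assoc,
    via_alias = sim$truth$gene_symbol == via_alias)
  list(disease = disease, gene_info = gene_info, truth = truth)
}

#' Write a transcript database as GTF (GENCODE dialect)
#'
#' Emits exon rows plus a 3-base `stop_codon` feature for transcripts
#' with an annotated stop (the stop codon is assumed not to span a
#' junction, which the synthetic geometry guarantees).
#'
#' @param db A [transcript_db].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(db, path) {
  tx <- db$transcripts
  ex <- db$exons
  con <- file(path, "wt")
  on.exit(close(con))
  bio_str <- c(protein_coding = "protein_coding",
               nmd = "nonsense_mediated_decay",
               noncoding = "processed_transcript", other = "TEC")
  for (i in seq_len(nrow(tx))) {
    r <- tx[i]
    attr_str <- sprintf(
      'gene_id "%s"; transcript_id "%s"; gene_name "%s"; transcript_type "%s";',
      r$gene_id, r$transcript_id, r$gene_symbol, bio_str[[r$biotype]])
    e <- ex[source == r$source & transcript_id == r$transcript_id][order(start)]
    for (j in seq_len(nrow(e)))
      writeLines(paste(r$chrom, "nmdscan", "exon", e$start[j] + 1L,
                       e$end[j], ".", r$strand, ".", attr_str,
                       sep = "\t"), con)
    if (!is.na(r$cds_end)) {
      if (r$strand == "+") {
        s1 <- r$cds_end - 1L; e1 <- r$cds_end + 1L
      } else {
        s1 <- r$cds_end + 1L; e1 <- r$cds_end + 3L
      }
      writeLines(paste(r$chrom, "nmdscan", "stop_codon", s1, e1, ".",
                       r$strand, ".", attr_str, sep = "\t"), con)
    }
  }
  invisible(path)
}

#' Write a transcript database as genePred
#'
#' @param db A [transcript_db].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genepred <- function(db, path) {
  tx <- db$transcripts
  ex <- db$exons
  con <- file(path, "wt")
  on.exit(close(con))
  for (i in seq_len(nrow(tx))) {
    r <- tx[i]
    e <- ex[source == r$source & transcript_id == r$transcript_id][order(start)]
    tx_s <- min(e$start); tx_e <- max(e$end)
    if (is.na(r$cds_end)) {
      cs <- tx_s; ce <- tx_s
    } else if (r$strand == "+") {
      cs <- tx_s; ce <- r$cds_end + 1L
    } else {
      cs <- r$cds_end; ce <- tx_e
    }
    writeLines(paste(r$transcript_id, r$chrom, r$strand, tx_s, tx_e,
                     cs, ce, nrow(e),
                     paste0(paste(e$start, collapse = ","), ","),
                     paste0(paste(e$end, collapse = ","), ","),
                     r$gene_symbol, sep = "\t"), con)
  }
  invisible(path)
}

#' Write a complete synthetic fixture set to disk
#'
#' Emits everything the pipeline readers consume: GTF (GENCODE-style
#' genes), genePred (RefSeq-style genes, if any), one SJ.out.tab per
#' sample plus a sample manifest, a conservation bedGraph over the
#' partitioned exon sets with planted exceedance fractions, QC metrics,
#' disease and gene_info tables, and a `truth.json` with the generator's
#' ground truth. All files round-trip through the package readers.
#'
#' @param sim An `nmd_simulation`.
#' @param dir Output directory (created if needed).
#' @param n_replicates Samples per condition.
#' @param conditions Conditions to simulate.
#' @param exceedance Named planted conserved fractions for the three
#'   exon sets.
#' @param seed Integer seed for sample draws and companion tables.
#' @return Named list of file paths plus `manifest` (data.table) and
#'   the `sim` truth, invisibly.
#' @export
write_fixtures <- function(sim, dir, n_replicates = 2L,
                           conditions = c("dmso", "chx"),
                           exceedance = c(set1 = 0.16, set2 = 0.35,
                                          set3 = 0.90),
                           seed = sim$config$seed) {
  stopifnot(inherits(sim, "nmd_simulation"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(dir, f)
  db <- sim$db
  paths <- list()

  gc_tx <- db$transcripts[source == "gencode", .(source, transcript_id)]
  rs_tx <- db$transcripts[source == "refseq", .(source, transcript_id)]
  sub_db <- function(keys) transcript_db(
    db$transcripts[keys, on = c("source", "transcript_id")],
    db$exons[keys, on = c("source", "transcript_id")])
  if (nrow(gc_tx)) {
    write_gtf(sub_db(gc_tx), p("annotation.gtf"))
    paths$gtf <- p("annotation.gtf")
  }
  if (nrow(rs_tx)) {
    write_genepred(sub_db(rs_tx), p("annotation.genePred"))
    paths$genepred <- p("annotation.genePred")
  }

  man <- list()
  idx <- 0L
  for (cond in conditions) for (r in seq_len(n_replicates)) {
    idx <- idx + 1L
    sid <- sprintf("%s_%d", cond, r)
    cnt <- simulate_counts(sim, sid, condition = cond,
                           seed = seed + 1000L + idx)
    f <- p(sprintf("%s.SJ.out.tab", sid))
    write_star_sj(cnt, f)
    man[[idx]] <- data.table(sample_id = sid, path = f, condition = cond)
  }
  manifest <- rbindlist(man)
  fwrite(manifest, p("manifest.tsv"), sep = "\t")
  paths$manifest_path <- p("manifest.tsv")

  # conservation: planted per-set exceedance over the truth-derived sets
  set1 <- sim$truth[event_type == "EI",
                    .(chrom, start = alt_start, end = alt_end)]
  set2 <- sim$truth[event_type == "none",
                    .(chrom, start = alt_start, end = alt_end)]
  pc <- db$transcripts[biotype == "protein_coding",
                       .(source, transcript_id)]
  all_pc <- unique(db$exons[pc, on = c("source", "transcript_id")]
                   [, .(chrom, start, end)])
  set3 <- all_pc[!rbind(set1, set2), on = c("chrom", "start", "end")]
  scl <- list()
  sets <- list(set1 = set1, set2 = set2, set3 = set3)
  for (i in seq_along(sets)) {
    nm <- names(sets)[i]
    if (!nrow(sets[[nm]])) next
    scl[[nm]] <- simulate_conservation_scores(
      sets[[nm]], exceedance = exceedance[[nm]], seed = seed + 2000L + i)
  }
  track <- conservation_track(rbindlist(
    lapply(scl, function(s) s$track[, .(chrom, start, end, score)])))
  write_bedgraph(track, p("conservation.bedgraph"))
  paths$track <- p("conservation.bedgraph")

  qc <- simulate_qc_metrics(seed = seed + 3000L)
  fwrite(qc$metrics, p("qc_metrics.tsv"), sep = "\t")
  paths$qc <- p("qc_metrics.tsv")

  dz <- simulate_disease_tables(sim, seed = seed + 4000L)
  fwrite(dz$disease, p("disease.tsv"), sep = "\t")
  fwrite(dz$gene_info, p("gene_info.tsv"), sep = "\t")
  paths$disease <- p("disease.tsv")
  paths$gene_info <- p("gene_info.tsv")

  truth_out <- list(
    config = unclass(sim$config),
    genes = sim$truth,
    qc = qc$truth,
    disease = dz$truth,
    conservation = lapply(scl, function(s) s$truth))
  jsonlite::write_json(truth_out, p("truth.json"), auto_unbox = TRUE,
                       digits = NA, null = "null", na = "null")
  paths$truth <- p("truth.json")

  invisible(c(paths, list(manifest = manifest, qc_truth = qc$truth,
                          disease_truth = dz$truth,
                          conservation_truth = scl)))
}
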