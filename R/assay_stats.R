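# Downstream assay statistics: densitometry percent non-productive
# splicing, qPCR delta-delta-Ct fold changes, quadratic standard-curve
# interpolation (MSD-style protein quantification), and the
# abundance-versus-upregulation linear fit.

#' Percent non-productive splicing from band intensities
#'
#' `100 * np / (np + p)` for background-subtracted band intensities of
#' the non-productive and productive products. Scale-invariant:
#' multiplying both intensities by any positive constant leaves the
#' result unchanged.
#'
#' @param np_intensity Non-productive band intensity (>= 0).
#' @param p_intensity Productive band intensity (>= 0).
#' @return Percentage in `[0, 100]`; `NA` when both intensities are
#'   zero.
#' @export
percent_nonproductive <- function(np_intensity, p_intensity) {
  stopifnot(all(np_intensity >= 0), all(p_intensity >= 0))
  tot <- np_intensity + p_intensity
  ifelse(tot > 0, 100 * np_intensity / tot, NA_real_)
}

#' Delta-delta-Ct fold changes from qPCR triplicates
#'
#' Per sample, `dCt = mean(Ct_target) - mean(Ct_reference)` over the
#' technical replicates (arithmetic means; no outlier rejection);
#' `ddCt = dCt - mean(dCt of control samples)`; fold change
#' `= 2^-ddCt`. With a single control sample its fold change is exactly
#' 1; with several, the control ddCt values average to 0 exactly.
#'
#' @param data Long-format `data.frame` with columns `sample_id`,
#'   `group` (`"control"`/`"test"`), `assay` (`"target"`/`"reference"`),
#'   `ct` (one row per technical replicate; each sample/assay needs at
#'   least one finite Ct).
#' @return `data.table` per sample: `delta_ct`, `delta_delta_ct`,
#'   `fold_change`.
#' @export
ddct_fold_change <- function(data) {
  dt <- as.data.table(data)
  need <- c("sample_id", "group", "assay", "ct")
  if (!all(need %in% names(dt)))
    stop("data lacks required column(s): ",
         paste(setdiff(need, names(dt)), collapse = ", "))
  if (!any(dt$group == "control")) stop("no control samples present")
  means <- dt[is.finite(ct), .(mct = mean(ct)), by = .(sample_id, group, assay)]
  wide <- dcast(means, sample_id + group ~ assay, value.var = "mct")
  if (!all(c("target", "reference") %in% names(wide)) ||
      anyNA(wide$target) || anyNA(wide$reference))
    stop("every sample needs at least one finite target and reference Ct")
  wide[, delta_ct := target - reference]
  ctrl_mean <- wide[group == "control", mean(delta_ct)]
  wide[, delta_delta_ct := delta_ct - ctrl_mean]
  wide[, fold_change := 2^(-delta_delta_ct)]
  wide[, .(sample_id, group, delta_ct, delta_delta_ct, fold_change)]
}

#' Fit a quadratic standard curve
#'
#' Least-squares fit of `signal = a * conc^2 + b * conc + k` over all
#' standards (duplicates enter individually). A warning is emitted when
#' the fitted curve is not monotone across the standards' concentration
#' range, since interpolation is then ambiguous.
#'
#' @param concentration Standard concentrations (>= 3 distinct values).
#' @param signal Measured signals, same length.
#' @return An `msd_curve` object (coefficients, concentration and
#'   signal ranges, the `lm` fit).
#' @export
fit_msd_curve <- function(concentration, signal) {
  stopifnot(length(concentration) == length(signal))
  if (length(unique(concentration)) < 3L)
    stop("need at least 3 distinct standard concentrations")
  fit <- lm(signal ~ concentration + I(concentration^2))
  k <- unname(coef(fit)[1]); b <- unname(coef(fit)[2])
  a <- unname(coef(fit)[3])
  rng <- range(concentration)
  deriv <- b + 2 * a * rng
  if (prod(deriv) < 0)
    warning("fitted quadratic is not monotone over the standard range")
  structure(list(a = a, b = b, k = k, conc_range = rng,
                 signal_range = range(a * rng^2 + b * rng + k),
                 fit = fit),
            class = "msd_curve")
}

#' @export
print.msd_curve <- function(x, ...) {
  cat(sprintf("msd_curve: signal = %.4g*c^2 + %.4g*c + %.4g  (c in [%g, %g])\n",
              x$a, x$b, x$k, x$conc_range[1], x$conc_range[2]))
  invisible(x)
}

#' Interpolate concentrations from a quadratic standard curve
#'
#' Inverts the fitted quadratic for each signal. When both roots are
#' real, the root lying on the monotone branch covering the standards
#' (the side of the vertex containing the concentration range) is
#' chosen. Signals outside the standards' fitted signal range are
#' interpolated anyway but flagged as extrapolations with a warning; a
#' signal with no real root in range yields `NA`, flagged.
#'
#' @param curve An `msd_curve` from [fit_msd_curve()].
#' @param signal Signals to invert.
#' @return `data.table` with `signal`, `concentration`, `extrapolated`.
#' @export
msd_interpolate <- function(curve, signal) {
  stopifnot(inherits(curve, "msd_curve"))
  a <- curve$a; b <- curve$b; k <- curve$k
  lo <- curve$conc_range[1]; hi <- curve$conc_range[2]
  srng <- curve$signal_range
  conc <- rep(NA_real_, length(signal))
  extra <- signal < min(srng) | signal > max(srng)
  for (i in seq_along(signal)) {
    y <- signal[i]
    if (abs(a) < 1e-12) {
      if (abs(b) < 1e-12) next
      conc[i] <- (y - k) / b
      next
    }
    disc <- b^2 - 4 * a * (k - y)
    if (disc < 0) { extra[i] <- TRUE; next }
    roots <- (-b + c(-1, 1) * sqrt(disc)) / (2 * a)
    vertex <- -b / (2 * a)
    # monotone branch covering the standards
    branch <- if (lo >= vertex) roots[roots >= vertex - 1e-9]
              else if (hi <= vertex) roots[roots <= vertex + 1e-9]
              else roots
    inr <- branch[branch >= lo - 1e-9 & branch <= hi + 1e-9]
    conc[i] <- if (length(inr)) inr[which.min(abs(inr - (lo + hi) / 2))]
               else branch[which.min(pmin(abs(branch - lo), abs(branch - hi)))]
    if (!length(inr)) extra[i] <- TRUE
  }
  if (any(extra))
    warning(sum(extra), " signal(s) outside the standard range; ",
            "interpolation flagged as extrapolation")
  data.table(signal = signal, concentration = conc, extrapolated = extra)
}

#' Predict signal from a fitted standard curve
#'
#' @param curve An `msd_curve`.
#' @param concentration Concentrations.
#' @return Predicted signals.
#' @export
msd_predict <- function(curve, concentration) {
  curve$a * concentration^2 + curve$b * concentration + curve$k
}

#' Linear fit of mRNA upregulation on NMD-event abundance
#'
#' Ordinary least squares of maximal fold upregulation on
#' post-NMD-inhibition event abundance, with R-squared and the
#' two-sided p-value for the slope.
#'
#' @param abundance Post-inhibition non-productive abundances (x).
#' @param upregulation Maximal fold upregulations (y).
#' @return List with `slope`, `intercept`, `r_squared`, `p_value`,
#'   `n`, and the `lm` fit.
#' @export
abundance_upregulation_fit <- function(abundance, upregulation) {
  stopifnot(length(abundance) == length(upregulation))
  if (length(abundance) < 3L) stop("need at least 3 paired points")
  if (var(abundance) == 0) stop("abundance has zero variance; fit undefined")
  fit <- lm(upregulation ~ abundance)
  sm <- summary(fit)
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       r_squared = sm$r.squared,
       p_value = unname(sm$coefficients[2, 4]),
       n = length(abundance), fit = fit)
}
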