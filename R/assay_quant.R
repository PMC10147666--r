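#' Ct measurement (technical replicates averaged on the Ct scale)
#'
#' @param sample_id Sample identifier.
#' @param target Amplicon target label (e.g. `transgene`, `ActinB`,
#'   `host_locus`, `gAAV`).
#' @param technical_cts Non-empty numeric vector of technical-well Cts;
#'   non-finite wells (undetermined) are dropped with a warning, never
#'   imputed.
#' @return A `ct_measurement` with `mean_ct` the arithmetic mean of the
#'   retained technical Cts.
#' @export
ct_measurement <- function(sample_id, target, technical_cts) {
  technical_cts <- as.numeric(technical_cts)
  bad <- !is.finite(technical_cts)
  if (any(bad)) {
    warning(sum(bad), " undetermined technical Ct well(s) excluded for ",
            sample_id, "/", target)
    technical_cts <- technical_cts[!bad]
  }
  if (length(technical_cts) == 0)
    stop("no finite technical Cts for ", sample_id, "/", target)
  structure(list(sample_id = sample_id, target = target,
                 technical_cts = technical_cts,
                 mean_ct = mean(technical_cts)),
            class = "ct_measurement")
}

mean_ct_of <- function(x) {
  if (inherits(x, "ct_measurement")) x$mean_ct else as.numeric(x)
}

#' Delta-delta-Ct relative expression (fold change)
#'
#' Relative quantity of a target transcript normalized to a housekeeping
#' reference (e.g. beta-actin) and to a calibrator sample:
#' `2^-((Ct_target - Ct_ref)_sample - (Ct_target - Ct_ref)_calibrator)`,
#' assuming amplification base 2.
#'
#' @param target,reference `ct_measurement`s (or bare mean Cts) of the
#'   sample of interest.
#' @param target_cal,reference_cal Same for the calibrator sample.
#' @return The fold change (1.0 when sample equals calibrator).
#' @export
ddct_fold_change <- function(target, reference, target_cal, reference_cal) {
  cts <- vapply(list(target, reference, target_cal, reference_cal),
                mean_ct_of, numeric(1))
  if (any(!is.finite(cts)))
    stop("ddct_fold_change requires four finite mean Cts")
  dct_sample <- cts[1] - cts[2]
  dct_cal <- cts[3] - cts[4]
  2^(-(dct_sample - dct_cal))
}

#' Fit a qPCR standard curve from a dilution series
#'
#' Least-squares line `Ct ~ log10(copies)` over the dilution points
#' (technical Cts averaged per point first). Efficiency is
#' `10^(-1/slope) - 1`; a perfect assay (efficiency 1) has slope
#' `-log2(10) = -3.3219` cycles per decade.
#'
#' @param known_copies Numeric vector of input molecule counts (>= 3 points
#'   spanning at least 2 log10).
#' @param cts Matching vector of mean Cts (or list of `ct_measurement`s).
#' @return A `standard_curve`: slope, intercept, r_squared, efficiency.
#' @export
fit_standard_curve <- function(known_copies, cts) {
  if (is.list(cts)) cts <- vapply(cts, mean_ct_of, numeric(1))
  known_copies <- as.numeric(known_copies)
  if (any(known_copies <= 0)) stop("standard copies must be positive")
  if (length(known_copies) < 3)
    stop("need >= 3 dilution points for a standard curve")
  lx <- log10(known_copies)
  if (diff(range(lx)) < 2)
    stop("dilution series must span >= 2 log10 of input copies")
  fit <- stats::lm(cts ~ lx)
  slope <- unname(stats::coef(fit)[2])
  if (!is.finite(slope) || slope >= 0)
    stop("standard curve slope must be negative (Ct decreasing with input)")
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((cts - mean(cts))^2)
  r2 <- if (ss_tot == 0) 1 else 1 - ss_res / ss_tot
  structure(list(slope = slope,
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = r2,
                 efficiency = 10^(-1 / slope) - 1),
            class = "standard_curve")
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf(
    "<standard_curve> slope %.4f, intercept %.3f, R2 %.5f, efficiency %.1f%%\n",
    x$slope, x$intercept, x$r_squared, 100 * x$efficiency))
  invisible(x)
}

#' Absolute copy number from a Ct and a standard curve
#'
#' Inverts the curve: `copies = 10^((Ct - intercept) / slope)`.
#'
#' @param ct A `ct_measurement` or bare mean Ct (vectorized over bare Cts).
#' @param curve A `standard_curve`.
#' @return Molecule count(s).
#' @export
absolute_copies <- function(ct, curve) {
  stopifnot(inherits(curve, "standard_curve"))
  ctv <- if (inherits(ct, "ct_measurement")) ct$mean_ct else as.numeric(ct)
  10^((ctv - curve$intercept) / curve$slope)
}

#' Vector copies per cell from vector and host copy numbers
#'
#' @param gaav_copies Vector genome molecules (from the plasmid standard
#'   curve).
#' @param host_genome_copies Diploid host genome equivalents (from the
#'   genomic-DNA standard curve).
#' @return List with the inputs and `copies_per_cell`.
#' @export
copies_per_cell <- function(gaav_copies, host_genome_copies) {
  if (any(gaav_copies < 0) || any(host_genome_copies < 0))
    stop("copy numbers must be non-negative")
  if (any(host_genome_copies == 0))
    stop("copies_per_cell undefined when host genome copies are zero")
  list(gaav_copies = gaav_copies,
       host_genome_copies = host_genome_copies,
       copies_per_cell = gaav_copies / host_genome_copies)
}

#' Encapsidated (DNase-protected) fraction of vector genomes
#'
#' Ratio of vector copies surviving DNase I treatment to untreated copies
#' in the same nuclear extract; genomes still inside intact capsids are
#' protected, so the ratio proxies the un-uncoated share.
#'
#' @param copies_plus_dnase Copies measured after DNase I treatment.
#' @param copies_minus_dnase Copies in the untreated aliquot (> 0).
#' @return List with `protected` (the ratio) and `uncoated` (1 - ratio). A
#'   ratio above 1 (measurement noise) is allowed but flagged with a
#'   warning.
#' @export
encapsidated_fraction <- function(copies_plus_dnase, copies_minus_dnase) {
  if (copies_minus_dnase <= 0)
    stop("untreated copy number must be positive")
  ratio <- copies_plus_dnase / copies_minus_dnase
  if (ratio > 1)
    warning("protected fraction > 1 (", signif(ratio, 4),
            "): treated exceeds untreated, likely measurement noise")
  list(protected = ratio, uncoated = 1 - ratio)
}

#' Tissue-weight-normalized luciferase activity
#'
#' @param rlu Relative light units (vectorized; e.g. technical replicas).
#' @param tissue_mg Tissue weight in milligrams (> 0).
#' @return RLU per mg, same length as `rlu`.
#' @export
luciferase_per_weight <- function(rlu, tissue_mg) {
  if (any(tissue_mg <= 0)) stop("tissue weight must be positive")
  rlu / tissue_mg
}

#' Mean and SEM of technical replicates
#'
#' @param values Numeric vector (>= 1).
#' @return List with `mean`, `sem` (NA for a single value), `n`.
#' @export
replicate_summary <- function(values) {
  n <- length(values)
  if (n == 0) stop("no values")
  list(mean = mean(values),
       sem = if (n > 1) stats::sd(values) / sqrt(n) else NA_real_,
       n = n)
}
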