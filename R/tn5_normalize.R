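CONDITION_COLS <- c("species", "context", "capsid", "timepoint")

#' Mean Tn5 input coverage for one condition
#'
#' The second normalization step divides each Cut&Tag vector coverage by the
#' mean Tn5 input coverage of the *matched condition* — matching on
#' (species, context, capsid, timepoint), never on the profiled target: one
#' input library normalizes all marks of its condition.
#'
#' @param stats A coverage statistics table (see [coverage_stats_table()]),
#'   containing the Tn5 rows (`target == "Tn5_input"`).
#' @param condition A one-row data.frame (or list) with the condition
#'   columns `species`, `context`, `capsid`, `timepoint`.
#' @return The arithmetic mean of the matching Tn5 `raw_value`s.
#' @export
mean_tn5_coverage <- function(stats, condition) {
  stats <- as.data.table(stats)
  tn5 <- stats[stats$target == "Tn5_input", ]
  sel <- rep(TRUE, nrow(tn5))
  for (col in CONDITION_COLS)
    sel <- sel & tn5[[col]] == as.character(condition[[col]])
  tn5 <- tn5[sel, ]
  cond_str <- paste(vapply(CONDITION_COLS,
                           function(c) as.character(condition[[c]]),
                           character(1)), collapse = "/")
  if (nrow(tn5) == 0)
    stop("no Tn5 input library matches condition ", cond_str)
  m <- mean(tn5$raw_value)
  if (m <= 0)
    stop("Tn5 mean coverage is zero for condition ", cond_str,
         ": normalization undefined")
  m
}

#' Tn5-normalize a dataset of coverage statistics
#'
#' For each Cut&Tag sample, computes `normalized = raw / tn5_mean` where
#' `tn5_mean` is [mean_tn5_coverage()] of the sample's condition. Tn5 rows
#' are consumed as normalizers and excluded from the output. All statistics
#' must have been computed with the same denominator mode (and mask);
#' mixing modes is refused.
#'
#' @param stats Coverage statistics table containing both Cut&Tag and Tn5
#'   rows (columns as produced by [coverage_stats_table()]).
#' @param warn_low Warn when a condition's Tn5 mean is below this value
#'   (default 0: never).
#' @return A data.table: sample metadata columns plus `raw`, `tn5_mean`,
#'   `normalized`.
#' @export
tn5_normalize_dataset <- function(stats, warn_low = 0) {
  stats <- as.data.table(stats)
  if (length(unique(stats$denominator_mode)) > 1)
    stop("mixed denominator modes in the statistics table; ",
         "recompute all samples with one mode")
  ct <- stats[stats$target != "Tn5_input", ]
  if (nrow(ct) == 0) stop("no Cut&Tag samples to normalize")
  conds <- unique(ct[, CONDITION_COLS, with = FALSE])
  tn5_means <- vapply(seq_len(nrow(conds)), function(i)
    mean_tn5_coverage(stats, conds[i, ]), numeric(1))
  conds[, tn5_mean := tn5_means]
  if (any(tn5_means < warn_low))
    warning("Tn5 mean coverage below ", warn_low, " for ",
            sum(tn5_means < warn_low), " condition(s)")
  out <- merge(ct, conds, by = CONDITION_COLS, sort = FALSE)
  out[, `:=`(raw = raw_value, normalized = raw_value / tn5_mean)]
  keep <- c("sample_id", "target", CONDITION_COLS, "replicate",
            "raw", "tn5_mean", "normalized")
  setorder(out, target, species, context, capsid, timepoint, replicate)
  out[, keep, with = FALSE]
}
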