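#!/usr/bin/env Rscript
# Estimator calibration: how well does the Tn5-normalized, ITR-masked
# coverage statistic recover a known gene-body enrichment E injected into a
# chromatin library (matched Tn5 input, same abundance)? Reports the
# recovered ratio vs the E=1 baseline for a ladder of multipliers.

library(epivector)

build <- build_combined_reference(c(chrH = 1e6), build_vector_genome())
mask <- itr_mask(build$vector)
n_frag <- 5e5
seed <- 2026

norm_cov <- function(E) {
  profile <- if (E != 1) gene_body_profile(build$vector, E) else NULL
  ct <- simulate_chromatin_library(
    simulation_config(n_frag, 0.01, profile,
                      seed = derive_seed(seed, paste0("ct", E))),
    build, library_meta("ct", "H3K4me3", "LK03", "human"))
  tn <- simulate_tn5_library(
    simulation_config(n_frag, 0.01, seed = derive_seed(seed, paste0("tn", E))),
    build, library_meta("tn", "Tn5_input", "LK03", "human"))
  st <- coverage_stats_table(list(ct, tn), build, mask)
  st$raw_value[1] / st$raw_value[2]
}

E_grid <- c(1, 2, 4, 8)
values <- vapply(E_grid, norm_cov, numeric(1))
recovered <- values / values[1]

tab <- data.frame(E_injected = E_grid,
                  normalized_coverage = values,
                  recovered_ratio = recovered,
                  rel_error_pct = 100 * (recovered - E_grid) / E_grid)
dir.create("results", showWarnings = FALSE)
write.table(tab, "results/enrichment_recovery.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

cat("Enrichment recovery at", format(n_frag, big.mark = ","),
    "fragments/library:\n")
print(tab, row.names = FALSE, digits = 4)
cat("\nRecovered ratios sit a few percent below the injected multiplier:\n",
    "the enriched cassette saturates both the vector-assignment mass and\n",
    "the exact-coordinate deduplication on the 4-kb contig (see the\n",
    "methods vignette). Written to results/enrichment_recovery.tsv\n")
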