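# Shared fixtures: a small combined reference, track constructors, and the
# naive per-base oracle the interval-arithmetic coverage statistic is
# checked against.

toy_vector <- function(length = 4000L, itr = 145L, seed = NULL)
  build_vector_genome(length, itr, seed = seed)

toy_build <- function(host_len = 1e6, vector = toy_vector())
  build_combined_reference(c(chrH = host_len), vector)

# fragment_set from bare coordinates (vector contig unless stated)
frags <- function(start, end, strand = "+", contig = "gAAV",
                  sample_id = "s1", target = "H3K4me3") {
  n <- max(length(start), length(end))
  rec <- data.table::data.table(
    contig = rep_len(contig, n), start = as.integer(start),
    end = as.integer(end), strand = rep_len(strand, n),
    sample_id = sample_id, is_duplicate_origin = FALSE)
  structure(list(records = rec,
                 meta = library_meta(sample_id, target, "LK03", "human"),
                 dedup_applied = FALSE),
            class = "fragment_set")
}

# coverage_track from explicit runs (zero gaps allowed implicitly)
track_of <- function(start, end, value, contig = "gAAV", N = NA_integer_) {
  structure(list(contig = contig,
                 intervals = data.table::data.table(
                   start = as.integer(start), end = as.integer(end),
                   value = as.numeric(value)),
                 total_fragments_used = N),
            class = "coverage_track")
}

# brute-force per-base evaluation of the masked length-weighted statistic
naive_region_stat <- function(track, region_length, mask = NULL,
                              mode = "unmasked_length") {
  v <- numeric(region_length)
  iv <- track$intervals
  for (i in seq_len(nrow(iv)))
    if (iv$end[i] > iv$start[i])
      v[(iv$start[i] + 1):iv$end[i]] <- iv$value[i]
  keep <- rep(TRUE, region_length)
  if (!is.null(mask) && nrow(mask) > 0)
    for (i in seq_len(nrow(mask))) {
      s <- max(0L, mask$start[i]); e <- min(region_length, mask$end[i])
      if (s < e) keep[(s + 1):e] <- FALSE
    }
  D <- if (mode == "unmasked_length") sum(keep) else region_length
  sum(v[keep]) / D
}

# random piecewise-constant track + random mask on a small region
random_track_and_mask <- function(region_length = 500L, contig = "gAAV") {
  vals <- sample(c(0, 0, round(runif(3) * 20, 3)), region_length,
                 replace = TRUE)
  r <- rle(vals)
  ends <- cumsum(r$lengths)
  tr <- track_of(ends - r$lengths, ends, r$values, contig = contig)
  n_mask <- sample(0:3, 1)
  mask <- NULL
  if (n_mask > 0) {
    s <- sort(sample.int(region_length - 2L, n_mask))
    e <- pmin(region_length, s + sample.int(60, n_mask))
    mask <- interval_set(data.frame(contig = contig, start = s, end = e))
  }
  list(track = tr, mask = mask)
}

# Tn5-normalized vector coverage for one simulated Cut&Tag/Tn5 pair
simulated_normalized_coverage <- function(E, vector_fraction = 0.01,
                                          n_fragments = 2e6, seed = 11,
                                          build = NULL, mask = NULL) {
  if (is.null(build)) build <- toy_build()
  if (is.null(mask)) mask <- itr_mask(build$vector)
  profile <- if (E != 1) gene_body_profile(build$vector, E) else NULL
  ct <- simulate_chromatin_library(
    simulation_config(n_fragments, vector_fraction, profile,
                      seed = derive_seed(seed, paste0("ct", E))),
    build, library_meta(paste0("ct", E), "H3K4me3", "LK03", "human"))
  tn5 <- simulate_tn5_library(
    simulation_config(n_fragments, vector_fraction,
                      seed = derive_seed(seed, paste0("tn", E))),
    build, library_meta(paste0("tn", E), "Tn5_input", "LK03", "human"))
  st <- coverage_stats_table(list(ct, tn5), build, mask)
  st$raw_value[1] / st$raw_value[2]
}
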