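build <- toy_build()
mask <- itr_mask(build$vector)
meta_ct <- library_meta("ct1", "H3K4me3", "LK03", "human")
meta_tn <- library_meta("tn1", "Tn5_input", "LK03", "human")

test_that("library simulation is deterministic in the seed", {
  cfg <- simulation_config(n_fragments = 1000, vector_fraction = 0.3,
                           seed = 7)
  a <- simulate_chromatin_library(cfg, build, meta_ct)
  b <- simulate_chromatin_library(cfg, build, meta_ct)
  expect_identical(a$records, b$records)
  cfg2 <- simulation_config(n_fragments = 1000, vector_fraction = 0.3,
                            seed = 8)
  c <- simulate_chromatin_library(cfg2, build, meta_ct)
  expect_false(identical(a$records, c$records))
  t1 <- simulate_tn5_library(cfg, build, meta_tn)
  t2 <- simulate_tn5_library(cfg, build, meta_tn)
  expect_identical(t1$records, t2$records)
})

test_that("fragment records respect contig bounds and counts", {
  cfg <- simulation_config(n_fragments = 5000, vector_fraction = 0.5,
                           duplicate_rate = 0.2, seed = 3)
  fs <- simulate_chromatin_library(cfg, build, meta_ct)
  r <- fs$records
  expect_equal(nrow(r), 5000L)
  clen <- build$contigs$length[match(r$contig, build$contigs$name)]
  expect_true(all(r$start >= 0 & r$start < r$end & r$end <= clen))
  expect_equal(sum(r$is_duplicate_origin), 1000L)
})

test_that("vector assignment follows the configured fraction (binomial law)", {
  n <- 1e5
  cfg <- simulation_config(n_fragments = n, vector_fraction = 0.3,
                           duplicate_rate = 0, seed = 21)
  fs <- simulate_chromatin_library(cfg, build, meta_ct)
  k <- sum(fs$records$contig == "gAAV")
  sigma <- sqrt(n * 0.3 * 0.7)
  expect_lt(abs(k - n * 0.3), 3 * sigma)

  cfg0 <- simulation_config(n_fragments = 1000, vector_fraction = 0,
                            seed = 21)
  fs0 <- simulate_chromatin_library(cfg0, build, meta_ct)
  expect_equal(sum(fs0$records$contig == "gAAV"), 0L)
})

test_that("Tn5 library is flat on the vector interior (chi-square on bins)", {
  # midpoint counts per interior 100-bp bin are multinomial-uniform; edge
  # bins are excluded because fragment placement is clipped at contig ends
  cfg <- simulation_config(n_fragments = 2e5, vector_fraction = 0.5,
                           itr_multiplier = 1, duplicate_rate = 0,
                           seed = 12)
  fs <- simulate_tn5_library(cfg, build, meta_tn)
  r <- fs$records[fs$records$contig == "gAAV", ]
  mid <- (r$start + r$end) %/% 2
  interior <- mid >= 1000 & mid < 3000
  bins <- cut(mid[interior], breaks = seq(1000, 3000, by = 100))
  counts <- as.vector(table(bins))
  chi <- sum((counts - mean(counts))^2 / mean(counts))
  expect_lt(chi, qchisq(1 - 0.001, df = length(counts) - 1))
})

test_that("Tn5 simulation ignores the chromatin enrichment profile", {
  prof <- gene_body_profile(build$vector, 8)
  cfg <- simulation_config(n_fragments = 1e5, vector_fraction = 0.5,
                           enrichment_profile = prof, itr_multiplier = 1,
                           duplicate_rate = 0, seed = 5)
  ct <- simulate_chromatin_library(cfg, build, meta_ct)
  tn <- simulate_tn5_library(cfg, build, meta_tn)
  # chromatin library concentrates in the cassette relative to Tn5
  in_cassette <- function(fs) {
    r <- fs$records[fs$records$contig == "gAAV", ]
    mid <- (r$start + r$end) %/% 2
    mean(mid >= 145 & mid < 3855)
  }
  expect_gt(in_cassette(ct), in_cassette(tn) + 0.05)
  expect_error(simulate_tn5_library(cfg, build, meta_ct), "Tn5_input")
  expect_error(simulate_chromatin_library(cfg, build, meta_tn),
               "Tn5 input")
})

test_that("ITR weight multiplier produces the configured overrepresentation", {
  cfg <- simulation_config(n_fragments = 5e5, vector_fraction = 0.5,
                           itr_multiplier = 3, duplicate_rate = 0,
                           seed = 9)
  fs <- simulate_tn5_library(cfg, build, meta_tn)
  r <- fs$records[which(fs$records$contig == "gAAV"), ]
  mid <- (r$start + r$end) %/% 2
  itr <- mid < 145 | mid >= 3855
  # the multiplier scales the per-base midpoint sampling intensity; the
  # multinomial oracle predicts a 3x rate, mildly attenuated by clipping of
  # fragments at the contig ends
  rate_ratio <- (sum(itr) / 290) / (sum(!itr) / 3710)
  expect_lt(abs(rate_ratio - 3) / 3, 0.10)
  # per-base coverage keeps a clear (though smeared: 180-bp fragments vs
  # 145-bp ITRs) overrepresentation before deduplication
  fs$dedup_applied <- TRUE
  tr <- per_base_cpm_track(fs, build)
  v <- numeric(4000)
  iv <- tr$intervals
  for (i in seq_len(nrow(iv)))
    v[(iv$start[i] + 1):iv$end[i]] <- iv$value[i]
  itr_bases <- c(1:145, 3856:4000)
  expect_gt(mean(v[itr_bases]) / mean(v[-itr_bases]), 1.5)
})

test_that("empirical duplicate share and fragment length match the config", {
  cfg <- simulation_config(n_fragments = 1e5, vector_fraction = 0.1,
                           duplicate_rate = 0.1, seed = 33)
  fs <- simulate_chromatin_library(cfg, build, meta_ct)
  expect_equal(mean(fs$records$is_duplicate_origin), 0.1, tolerance = 1e-6)
  lens <- fs$records$end - fs$records$start
  # truncation to [50, 1000] shifts the lognormal mean slightly; 3 sigma of
  # the empirical mean at n = 1e5 is well under 1 bp
  expect_equal(mean(lens), 180, tolerance = 0.02)
  expect_true(all(lens >= 50 & lens <= 1000))
})

test_that("profile all-zero on the vector is refused when fragments go there", {
  prof <- data.frame(start = 0, end = 4000, multiplier = 0)
  cfg <- simulation_config(n_fragments = 100, vector_fraction = 0.5,
                           enrichment_profile = prof, itr_multiplier = 0,
                           seed = 1)
  expect_error(simulate_chromatin_library(cfg, build, meta_ct), "all-zero")
})

test_that("qPCR plate follows the amplification model exactly when noiseless", {
  p <- simulate_qpcr_plate(c(a = 1e6), efficiency = 1, ct_at_1e6 = 20,
                           noise_sd = 0)
  expect_equal(p$ct, c(20, 20))
  p2 <- simulate_qpcr_plate(c(a = 1e6, b = 5e5), efficiency = 1,
                            ct_at_1e6 = 20, noise_sd = 0)
  expect_equal(mean(p2$ct[p2$sample == "b"]) -
                 mean(p2$ct[p2$sample == "a"]), 1.0)
  # 10-fold dilution spacing at efficiency 0.93 is log(10)/log(1.93)
  p3 <- simulate_qpcr_plate(c(a = 1e6, b = 1e5), efficiency = 0.93,
                            noise_sd = 0)
  expect_equal(mean(p3$ct[p3$sample == "b"]) -
                 mean(p3$ct[p3$sample == "a"]),
               log(10) / log(1.93), tolerance = 1e-12)
  expect_error(simulate_qpcr_plate(c(a = 0)), "positive")
  expect_error(simulate_qpcr_plate(c(a = 10), efficiency = 1.5),
               "efficiency")
  pA <- simulate_qpcr_plate(c(a = 1e4), noise_sd = 0.3, seed = 4)
  pB <- simulate_qpcr_plate(c(a = 1e4), noise_sd = 0.3, seed = 4)
  expect_identical(pA, pB)
})

test_that("fragments round-trip through BED", {
  fs <- simulate_chromatin_library(
    simulation_config(500, 0.4, duplicate_rate = 0.1, seed = 2),
    build, meta_ct)
  path <- withr::local_tempfile(fileext = ".bed")
  write_fragments(fs, path, "BED", build = build)
  back <- read_fragments(path, "BED")
  key <- function(r) sort(paste(r$contig, r$start, r$end, r$strand))
  expect_identical(key(back$records), key(fs$records))
  expect_equal(nrow(back$records), nrow(fs$records))
})

test_that("fragments round-trip through paired-end SAM with a valid header", {
  fs <- frags(start = c(10, 100, 3900), end = c(200, 130, 4000),
              strand = c("+", "-", "+"))
  path <- withr::local_tempfile(fileext = ".sam")
  write_fragments(fs, path, "SAM", build = build, read_length = 75)
  lines <- readLines(path)
  sq <- lines[startsWith(lines, "@SQ")]
  expect_equal(sq, c("@SQ\tSN:chrH\tLN:1000000", "@SQ\tSN:gAAV\tLN:4000"))
  body <- lines[!startsWith(lines, "@")]
  expect_equal(length(body), 6L)  # one pair per fragment
  # fragment [100,130) is shorter than 2x75: mates overlap, reads are 30 bp
  short <- strsplit(body[3], "\t")[[1]]
  expect_equal(short[6], "30M")
  back <- read_fragments(path, "SAM")
  key <- function(r) sort(paste(r$contig, r$start, r$end, r$strand))
  expect_identical(key(back$records), key(fs$records))
})

test_that("out-of-bounds fragments are refused on write", {
  fs <- frags(start = 3990, end = 4100)
  expect_error(write_fragments(fs, tempfile(), "BED", build = build),
               "bounds")
})
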