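CHROMATIN_TARGETS <- c("H3K4me3", "H3K27ac", "H3K9me3", "H3K27me3",
                       "H2A", "H3", "H4", "PolII")
ALL_TARGETS <- c(CHROMATIN_TARGETS, "Tn5_input")
CAPSIDS <- c("LK03", "DJ", "AM", "other")
SPECIES <- c("human", "mouse")
CONTEXTS <- c("cell_line", "liver")

#' Library metadata for one sequencing library
#'
#' @param sample_id Unique sample identifier.
#' @param target Profiled target: a histone mark, core histone, `PolII`, or
#'   `Tn5_input` for the input (abundance-only) library.
#' @param capsid,species,context,timepoint Condition fields (controlled
#'   vocabularies: capsid in LK03/DJ/AM/other, species human/mouse, context
#'   cell_line/liver).
#' @param replicate Biological replicate number (>= 1).
#' @return A `library_meta` list.
#' @export
library_meta <- function(sample_id, target, capsid, species,
                         context = "cell_line", timepoint = "day3",
                         replicate = 1L) {
  target <- match.arg(target, ALL_TARGETS)
  capsid <- match.arg(capsid, CAPSIDS)
  species <- match.arg(species, SPECIES)
  context <- match.arg(context, CONTEXTS)
  structure(list(sample_id = as.character(sample_id), target = target,
                 capsid = capsid, species = species, context = context,
                 timepoint = as.character(timepoint),
                 replicate = as.integer(replicate)),
            class = "library_meta")
}

condition_key <- function(meta) {
  paste(meta$species, meta$context, meta$capsid, meta$timepoint, sep = "|")
}

#' Simulation configuration for one fragment library
#'
#' Fragments (paired-end sequenced inserts) are the simulation unit; a
#' library is a set of placed fragments on the combined host+vector
#' reference. `vector_fraction` is the expected share of fragments
#' originating from the vector contig *under a uniform enrichment profile*;
#' a non-uniform profile increases or decreases the vector's sampling mass
#' and the effective vector share scales accordingly (more marked chromatin
#' on the episome captures more fragments). ITR intervals get an additional
#' weight multiplier, emulating the systematic ITR overrepresentation seen
#' in all libraries.
#'
#' @param n_fragments Total fragments to emit (including duplicates).
#' @param vector_fraction Expected vector share at uniform profile, in
#'   `[0, 1]`.
#' @param enrichment_profile Optional data.frame `(start, end, multiplier)`
#'   of piecewise-constant per-base sampling weight multipliers over vector
#'   coordinates (0-based half-open); bases not covered have multiplier 1.
#'   `NULL` means uniform.
#' @param itr_multiplier Extra weight multiplier over the ITR intervals
#'   (default 5).
#' @param duplicate_rate Share of emitted records that are exact copies of
#'   earlier records (PCR duplicates), in `[0, 1)`.
#' @param fragment_length `c(mean, sd)` in bp of the insert-size
#'   distribution, a lognormal truncated to `[50, 1000]` bp (nucleosomal
#'   scale; default mean 180, sd 50).
#' @param read_length Read length of the paired-end view (default 75).
#' @param seed Integer seed; the library is fully reproducible from it.
#' @return A `sim_config` list.
#' @export
simulation_config <- function(n_fragments = 2e6, vector_fraction = 0.01,
                              enrichment_profile = NULL, itr_multiplier = 5,
                              duplicate_rate = 0.1,
                              fragment_length = c(mean = 180, sd = 50),
                              read_length = 75L, seed = 1L) {
  if (vector_fraction < 0 || vector_fraction > 1)
    stop("vector_fraction must be in [0, 1]")
  if (duplicate_rate < 0 || duplicate_rate >= 1)
    stop("duplicate_rate must be in [0, 1)")
  if (itr_multiplier < 0) stop("itr_multiplier must be >= 0")
  if (!is.null(enrichment_profile)) {
    enrichment_profile <- as.data.table(enrichment_profile)
    stopifnot(all(c("start", "end", "multiplier") %in%
                    names(enrichment_profile)))
    if (any(!is.finite(enrichment_profile$multiplier)) ||
        any(enrichment_profile$multiplier < 0))
      stop("profile multipliers must be finite and >= 0")
  }
  structure(list(n_fragments = as.numeric(n_fragments),
                 vector_fraction = vector_fraction,
                 enrichment_profile = enrichment_profile,
                 itr_multiplier = itr_multiplier,
                 duplicate_rate = duplicate_rate,
                 fragment_length = fragment_length,
                 read_length = as.integer(read_length),
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Enrichment profile covering the cassette between the ITRs
#'
#' Convenience profile: one multiplier over the whole expression cassette
#' (everything between `ITR_left` and `ITR_right`), the "gene body" of the
#' episome. This is the knob used to inject known mark enrichment into
#' simulated chromatin libraries.
#'
#' @param vector A `vector_genome`.
#' @param multiplier Per-base weight multiplier (>= 0).
#' @return A data.frame usable as `enrichment_profile`.
#' @export
gene_body_profile <- function(vector, multiplier) {
  left <- vg_feature(vector, "ITR_left")
  right <- vg_feature(vector, "ITR_right")
  data.frame(start = left$end, end = right$start, multiplier = multiplier)
}

# Per-base sampling weight over the vector contig.
vector_weights <- function(config, vector, uniform_profile = FALSE) {
  w <- rep(1, vector$length)
  if (!uniform_profile && !is.null(config$enrichment_profile)) {
    for (i in seq_len(nrow(config$enrichment_profile))) {
      s <- config$enrichment_profile$start[i]
      e <- config$enrichment_profile$end[i]
      if (s < 0 || e > vector$length || s >= e)
        stop("enrichment profile interval [", s, ",", e,
             ") outside vector bounds")
      w[(s + 1):e] <- w[(s + 1):e] * config$enrichment_profile$multiplier[i]
    }
  }
  for (lab in c("ITR_left", "ITR_right")) {
    f <- vg_feature(vector, lab)
    if (!is.null(f)) w[(f$start + 1):f$end] <- w[(f$start + 1):f$end] *
        config$itr_multiplier
  }
  w
}

rtrunc_lognormal <- function(n, mean, sd, lo = 50, hi = 1000) {
  sdlog <- sqrt(log(1 + (sd / mean)^2))
  meanlog <- log(mean) - sdlog^2 / 2
  p <- runif(n, stats::plnorm(lo, meanlog, sdlog),
             stats::plnorm(hi, meanlog, sdlog))
  pmin(hi, pmax(lo, round(stats::qlnorm(p, meanlog, sdlog))))
}

simulate_fragments <- function(config, build, meta, uniform_profile) {
  stopifnot(inherits(config, "sim_config"), inherits(build, "genome_build"))
  set.seed(config$seed)
  vec <- build$vector
  host <- build$contigs[!build$contigs$is_vector, ]
  w <- vector_weights(config, vec, uniform_profile = uniform_profile)
  mass <- sum(w)
  f <- config$vector_fraction
  if (f > 0 && mass == 0)
    stop("enrichment profile is all-zero on the vector while vector_fraction > 0")
  # Reference mass at uniform profile (same ITR multiplier); the host weight
  # constant is calibrated so that a uniform profile yields exactly
  # vector_fraction, and enrichment scales the vector share with its mass.
  cfg_u <- config
  cfg_u$enrichment_profile <- NULL
  mass0 <- sum(vector_weights(cfg_u, vec, uniform_profile = TRUE))
  if (nrow(host) == 0) {
    p_vec <- 1
  } else if (f == 0) {
    p_vec <- 0
  } else if (f == 1) {
    p_vec <- 1
  } else {
    host_mass <- mass0 * (1 - f) / f
    p_vec <- mass / (mass + host_mass)
  }
  n_total <- as.integer(round(config$n_fragments))
  n_dup <- as.integer(round(config$duplicate_rate * n_total))
  n_new <- n_total - n_dup

  lens <- as.integer(rtrunc_lognormal(n_new, config$fragment_length[[1]],
                                      config$fragment_length[[2]]))
  on_vec <- runif(n_new) < p_vec
  nv <- sum(on_vec)
  nh <- n_new - nv
  contig <- character(n_new)
  mid0 <- integer(n_new)
  clen <- integer(n_new)
  if (nv > 0) {
    contig[on_vec] <- vec$name
    mid0[on_vec] <- sample.int(vec$length, nv, replace = TRUE, prob = w) - 1L
    clen[on_vec] <- as.integer(vec$length)
  }
  if (nh > 0) {
    hi <- if (nrow(host) == 1L) rep(1L, nh)
          else sample.int(nrow(host), nh, replace = TRUE, prob = host$length)
    contig[!on_vec] <- host$name[hi]
    hl <- as.integer(host$length[hi])
    mid0[!on_vec] <- as.integer(floor(runif(nh) * hl))
    clen[!on_vec] <- hl
  }
  lens <- pmin(lens, clen)
  start <- pmax(0L, pmin(mid0 - lens %/% 2L, clen - lens))
  strand <- c("+", "-")[1L + (runif(n_new) < 0.5)]
  dup_flag <- logical(n_new)
  if (n_dup > 0) {
    idx <- sample.int(n_new, n_dup, replace = TRUE)
    contig <- c(contig, contig[idx])
    start <- c(start, start[idx])
    lens <- c(lens, lens[idx])
    strand <- c(strand, strand[idx])
    dup_flag <- c(dup_flag, rep(TRUE, n_dup))
  }
  rec <- data.table(contig = contig, start = start, end = start + lens,
                    strand = strand, sample_id = meta$sample_id,
                    is_duplicate_origin = dup_flag)
  structure(list(records = rec, meta = meta, dedup_applied = FALSE),
            class = "fragment_set")
}

#' Simulate a Cut&Tag chromatin fragment library
#'
#' Emits exactly `n_fragments` placed fragments on the combined reference:
#' fragments are assigned to the vector contig with probability derived from
#' `vector_fraction` and the vector's enrichment mass (see
#' [simulation_config()]); vector fragment midpoints are drawn proportional
#' to `enrichment_profile` x `itr_multiplier`, host fragment midpoints
#' uniformly; a `duplicate_rate` share of the output are exact copies of
#' earlier records (PCR duplicates). Fully reproducible from `config$seed`.
#'
#' @param config A [simulation_config()].
#' @param build A `genome_build`.
#' @param meta A [library_meta()] with a chromatin target (not `Tn5_input`).
#' @return A `fragment_set`.
#' @export
simulate_chromatin_library <- function(config, build, meta) {
  stopifnot(inherits(meta, "library_meta"))
  if (meta$target == "Tn5_input")
    stop("use simulate_tn5_library() for Tn5 input libraries")
  simulate_fragments(config, build, meta, uniform_profile = FALSE)
}

#' Simulate a Tn5 input (normalizer) fragment library
#'
#' Identical to [simulate_chromatin_library()] but the enrichment profile is
#' forced uniform: the Tn5 library of bulk genomic DNA carries abundance
#' information only, like a ChIP input. The ITR weight multiplier still
#' applies (ITR overrepresentation is seen in all libraries, input
#' included).
#'
#' @inheritParams simulate_chromatin_library
#' @param meta A [library_meta()] with target `Tn5_input`.
#' @return A `fragment_set`.
#' @export
simulate_tn5_library <- function(config, build, meta) {
  stopifnot(inherits(meta, "library_meta"))
  if (meta$target != "Tn5_input")
    stop("simulate_tn5_library() requires target Tn5_input")
  simulate_fragments(config, build, meta, uniform_profile = TRUE)
}

#' @export
print.fragment_set <- function(x, ...) {
  cat("<fragment_set> ", x$meta$sample_id, ": ", nrow(x$records),
      " fragments", if (x$dedup_applied) " (deduplicated)" else "",
      "\n", sep = "")
  invisible(x)
}

#' Simulate a qPCR plate from known molecule counts
#'
#' Ct model: `Ct = ct_at_1e6 - log(copies / 1e6) / log(1 + efficiency) +
#' Normal(0, noise_sd)`, with `n_technical` wells per reaction. With
#' efficiency 1 a halving of input copies raises Ct by exactly one cycle; a
#' 10-fold dilution is spaced by `log(10) / log(1 + efficiency)` cycles.
#'
#' @param true_copies Named (or unnamed) vector of per-reaction molecule
#'   counts; names become sample ids.
#' @param efficiency Amplification efficiency in (0, 1].
#' @param ct_at_1e6 Ct at one million input copies (curve anchor).
#' @param noise_sd Gaussian Ct noise, cycles.
#' @param n_technical Technical replicate wells per reaction (default 2, as
#'   reactions are commonly run in duplicate).
#' @param seed Optional integer seed.
#' @return A data.table with columns `sample`, `true_copies`, `well`, `ct`.
#' @export
simulate_qpcr_plate <- function(true_copies, efficiency = 0.95,
                                ct_at_1e6 = 15, noise_sd = 0.2,
                                n_technical = 2L, seed = NULL) {
  if (efficiency <= 0 || efficiency > 1)
    stop("efficiency must be in (0, 1]")
  if (any(true_copies <= 0))
    stop("true_copies must be positive")
  if (!is.null(seed)) set.seed(as.integer(seed))
  ids <- names(true_copies)
  if (is.null(ids)) ids <- paste0("S", seq_along(true_copies))
  n <- length(true_copies) * n_technical
  plate <- data.table(
    sample = rep(ids, each = n_technical),
    true_copies = rep(as.numeric(true_copies), each = n_technical),
    well = rep(seq_len(n_technical), times = length(true_copies))
  )
  plate[, ct := ct_at_1e6 - log(true_copies / 1e6) / log(1 + efficiency) +
          rnorm(n, 0, noise_sd)]
  plate[]
}

#' Write a fragment set to BED or SAM
#'
#' BED emits one 6-column line per fragment (contig, start, end,
#' name=sample_id, score=0, strand). SAM emits a valid paired-end record
#' pair per fragment: reads of `read_length` bp (shorter when the fragment
#' is shorter) anchored at the two fragment ends, header taken from the
#' genome build in contig order. Both formats are re-readable to an equal
#' fragment multiset; the simulator-only duplicate-origin flag is not
#' round-tripped.
#'
#' @param fragments A `fragment_set`.
#' @param path Output file path.
#' @param format `"BED"` or `"SAM"`.
#' @param build Required for SAM: the `genome_build` providing the header.
#' @param read_length Read length for the SAM paired-end view.
#' @return Invisibly, `path`.
#' @export
write_fragments <- function(fragments, path, format = c("BED", "SAM"),
                            build = NULL, read_length = 75L) {
  format <- match.arg(format)
  stopifnot(inherits(fragments, "fragment_set"))
  r <- fragments$records
  if (!is.null(build)) {
    clen <- build$contigs$length[match(r$contig, build$contigs$name)]
    if (anyNA(clen) || any(r$start < 0) || any(r$end > clen))
      stop("fragment outside contig bounds; refusing to write")
  }
  if (format == "BED") {
    write_bed(data.table(contig = r$contig, start = r$start, end = r$end,
                         name = r$sample_id, score = 0L, strand = r$strand),
              path)
  } else {
    if (is.null(build)) stop("SAM output requires the genome build")
    write_fragments_sam(r, path, build, read_length)
  }
  invisible(path)
}

write_fragments_sam <- function(r, path, build, read_length) {
  header <- c("@HD\tVN:1.6\tSO:unknown",
              sprintf("@SQ\tSN:%s\tLN:%d", build$contigs$name,
                      as.integer(build$contigs$length)))
  n <- nrow(r)
  if (n == 0) { writeLines(header, path); return(invisible(path)) }
  len <- r$end - r$start
  rlen <- pmin(as.integer(read_length), len)
  qname <- sprintf("%s:frag%07d", r$sample_id, seq_len(n))
  pos_left <- r$start + 1L            # 1-based leftmost
  pos_right <- r$end - rlen + 1L
  fwd <- r$strand == "+"
  # read1 carries the fragment strand: forward read1 at the left end for
  # "+", reverse read1 at the right end for "-".
  flag1 <- ifelse(fwd, 99L, 83L)
  flag2 <- ifelse(fwd, 147L, 163L)
  pos1 <- ifelse(fwd, pos_left, pos_right)
  pos2 <- ifelse(fwd, pos_right, pos_left)
  tlen1 <- ifelse(fwd, len, -len)
  cigar <- sprintf("%dM", rlen)
  seqs <- vapply(rlen, function(k) strrep("N", k), character(1))
  l1 <- sprintf("%s\t%d\t%s\t%d\t60\t%s\t=\t%d\t%d\t%s\t*",
                qname, flag1, r$contig, pos1, cigar, pos2, tlen1, seqs)
  l2 <- sprintf("%s\t%d\t%s\t%d\t60\t%s\t=\t%d\t%d\t%s\t*",
                qname, flag2, r$contig, pos2, cigar, pos1, -tlen1, seqs)
  out <- character(2L * n)
  out[seq(1L, 2L * n, by = 2L)] <- l1
  out[seq(2L, 2L * n, by = 2L)] <- l2
  writeLines(c(header, out), path)
  invisible(path)
}

#' Read fragments back from BED or SAM
#'
#' @param path File written by [write_fragments()].
#' @param format `"BED"` or `"SAM"`.
#' @param meta Optional [library_meta()] to attach; when `NULL`, a minimal
#'   metadata stub is built from the sample ids found in the file.
#' @return A `fragment_set` (with `is_duplicate_origin` unset).
#' @export
read_fragments <- function(path, format = c("BED", "SAM"), meta = NULL) {
  format <- match.arg(format)
  if (format == "BED") {
    bed <- read_bed(path)
    rec <- data.table(contig = bed$contig, start = bed$start, end = bed$end,
                      strand = bed$strand, sample_id = bed$name,
                      is_duplicate_origin = FALSE)
  } else {
    lines <- readLines(path)
    lines <- lines[!startsWith(lines, "@")]
    if (length(lines) == 0) {
      rec <- data.table(contig = character(), start = integer(),
                        end = integer(), strand = character(),
                        sample_id = character(),
                        is_duplicate_origin = logical())
    } else {
      f <- strsplit(lines, "\t", fixed = TRUE)
      flag <- vapply(f, function(x) as.integer(x[2]), integer(1))
      first <- bitwAnd(flag, 64L) > 0L
      f <- f[first]; flag <- flag[first]
      qn <- vapply(f, `[`, character(1), 1)
      pos <- vapply(f, function(x) as.integer(x[4]), integer(1))
      pnext <- vapply(f, function(x) as.integer(x[8]), integer(1))
      tlen <- vapply(f, function(x) as.integer(x[9]), integer(1))
      start <- pmin(pos, pnext) - 1L
      rec <- data.table(
        contig = vapply(f, `[`, character(1), 3),
        start = start, end = start + abs(tlen),
        strand = ifelse(bitwAnd(flag, 16L) > 0L, "-", "+"),
        sample_id = sub(":frag[0-9]+$", "", qn),
        is_duplicate_origin = FALSE)
    }
  }
  if (is.null(meta)) {
    sid <- if (nrow(rec) > 0) rec$sample_id[1] else "unknown"
    meta <- library_meta(sid, "H3K4me3", "other", "human")
  }
  structure(list(records = rec, meta = meta, dedup_applied = FALSE),
            class = "fragment_set")
}
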