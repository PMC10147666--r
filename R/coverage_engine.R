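#' Remove PCR duplicates from a fragment set
#'
#' Collapses records identical in (contig, start, end, strand) to a single
#' retained record, keeping the first in input order — the fragment-level
#' analogue of marking duplicates on aligned pairs. Idempotent by
#' construction; the fragment set is flagged so CPM normalization can insist
#' on deduplicated input.
#'
#' @param fragments A `fragment_set`; if already deduplicated the call is a
#'   no-op (idempotent).
#' @param quiet Suppress the removal-count message.
#' @return The deduplicated `fragment_set`.
#' @export
deduplicate <- function(fragments, quiet = TRUE) {
  stopifnot(inherits(fragments, "fragment_set"))
  if (isTRUE(fragments$dedup_applied))
    return(fragments)
  r <- fragments$records
  keep <- !fragment_duplicates(r)
  out <- fragments
  out$records <- r[which(keep)]
  out$dedup_applied <- TRUE
  if (!quiet)
    message(sprintf("deduplicate: %s: removed %d of %d fragments",
                    fragments$meta$sample_id, sum(!keep), length(keep)))
  out
}

# Duplicate flags by (contig, start, end, strand), first occurrence kept.
# Encodes each fragment as one double for speed; falls back to column-wise
# dedup if the encoding would lose integer precision.
fragment_duplicates <- function(r) {
  n <- nrow(r)
  if (n == 0) return(logical(0))
  ci <- match(r$contig, unique(r$contig))
  len <- r$end - r$start
  B <- 2 * (max(len) + 1)
  key <- r$start * B + len * 2 + (r$strand == "+")
  key <- key + ci * (max(key) + 1)
  if (max(key) < 2^53) return(duplicated(key))
  duplicated(r, by = c("contig", "start", "end", "strand"))
}

#' Per-base CPM coverage track for one contig
#'
#' Coverage at base `b` is the number of deduplicated fragments overlapping
#' `b` on the requested contig, scaled to counts per million by
#' `1e6 / N` where `N` is the total deduplicated fragment count of the
#' library across *all* contigs (genome-wide CPM semantics, matching
#' bin-size-1 CPM-normalized coverage tracks). Emitted as merged
#' constant-value intervals spanning the whole contig (zero runs included).
#'
#' @param fragments A deduplicated `fragment_set`.
#' @param build The `genome_build` the fragments were placed on.
#' @param contig Contig to compute the track for (default: the vector).
#' @return A `coverage_track`: list with `contig`, `intervals` (data.table
#'   start/end/value, 0-based half-open, adjacent equal values merged) and
#'   `total_fragments_used` (the CPM denominator `N`).
#' @export
per_base_cpm_track <- function(fragments, build,
                               contig = build$vector$name) {
  stopifnot(inherits(fragments, "fragment_set"))
  if (!isTRUE(fragments$dedup_applied))
    stop("per_base_cpm_track requires deduplicated fragments; call deduplicate() first")
  N <- nrow(fragments$records)
  if (N == 0) stop("empty library: CPM normalization undefined (N = 0)")
  L <- as.integer(contig_length(build, contig))
  sel <- which(fragments$records$contig == contig)
  r <- fragments$records[sel, ]
  cpm_track_from_records(r, L, N, contig)
}

# Track construction from an already-deduplicated, contig-restricted record
# subset, with the library-wide CPM denominator N supplied explicitly.
cpm_track_from_records <- function(r, L, N, contig) {
  if (nrow(r) == 0) {
    iv <- data.table(start = 0L, end = L, value = 0)
  } else {
    cov <- IRanges::coverage(IRanges::IRanges(start = r$start + 1L,
                                              end = r$end), width = L)
    rl <- S4Vectors::runLength(cov)
    ends <- cumsum(rl)
    iv <- data.table(start = as.integer(ends - rl),
                     end = as.integer(ends),
                     value = as.numeric(S4Vectors::runValue(cov)) * 1e6 / N)
  }
  structure(list(contig = contig, intervals = iv,
                 total_fragments_used = N),
            class = "coverage_track")
}

#' @export
print.coverage_track <- function(x, ...) {
  cat("<coverage_track> ", x$contig, ": ", nrow(x$intervals),
      " runs, N = ", x$total_fragments_used, "\n", sep = "")
  invisible(x)
}

#' Write a coverage track as bedGraph
#'
#' Standard 4-column bedGraph, 0-based half-open; zero-value runs are
#' omitted on write (and reconstructed as zeros on read, so write-then-read
#' is the identity up to the representation of zero runs). Values are
#' printed with full double precision so the coverage statistic round-trips
#' exactly.
#'
#' @param track A `coverage_track`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_bedgraph <- function(track, path) {
  stopifnot(inherits(track, "coverage_track"))
  iv <- track$intervals[track$intervals$value != 0, ]
  writeLines(sprintf("%s\t%d\t%d\t%.17g", track$contig, iv$start, iv$end,
                     iv$value), path)
  invisible(path)
}

#' Read a bedGraph file into a coverage track
#'
#' Expects a single-contig 4-column bedGraph with sorted, non-overlapping
#' intervals; gaps are implicit zeros. Malformed lines raise a parse error
#' naming the line number.
#'
#' @param path bedGraph file path.
#' @param contig_length Optional contig length; when given, a trailing zero
#'   run is appended so the track spans the whole contig.
#' @return A `coverage_track` (`total_fragments_used` is `NA`: the CPM
#'   denominator is not stored in bedGraph).
#' @export
read_bedgraph <- function(path, contig_length = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  n <- length(lines)
  contig <- character(n); start <- integer(n); end <- integer(n)
  value <- numeric(n)
  for (i in seq_len(n)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) != 4)
      stop("bedGraph parse error at line ", i, ": expected 4 columns, got ",
           length(f))
    s <- suppressWarnings(as.integer(f[2]))
    e <- suppressWarnings(as.integer(f[3]))
    v <- suppressWarnings(as.numeric(f[4]))
    if (is.na(s) || is.na(e) || is.na(v) || s >= e)
      stop("bedGraph parse error at line ", i, ": invalid interval or value")
    contig[i] <- f[1]; start[i] <- s; end[i] <- e; value[i] <- v
  }
  if (n > 0) {
    if (length(unique(contig)) != 1)
      stop("bedGraph parse error: expected a single contig, found ",
           length(unique(contig)))
    if (any(start[-1] < end[-n]))
      stop("bedGraph parse error at line ",
           which(start[-1] < end[-n])[1] + 1L,
           ": intervals overlap or are unsorted")
  }
  iv <- fill_zero_runs(data.table(start = start, end = end, value = value),
                       contig_length)
  structure(list(contig = if (n > 0) contig[1] else NA_character_,
                 intervals = iv, total_fragments_used = NA_integer_),
            class = "coverage_track")
}

fill_zero_runs <- function(iv, contig_length = NULL) {
  if (nrow(iv) == 0) {
    if (!is.null(contig_length))
      return(data.table(start = 0L, end = as.integer(contig_length),
                        value = 0))
    return(iv)
  }
  ext <- if (is.null(contig_length)) max(iv$end) else as.integer(contig_length)
  bounds <- c(0L, iv$end)
  gaps <- data.table(start = c(0L, iv$end),
                     end = c(iv$start, ext))
  gaps <- gaps[gaps$start < gaps$end]
  gaps[, value := 0]
  out <- rbindlist(list(iv, gaps))
  setorder(out, start)
  out
}

#' Length-weighted, ITR-masked vector coverage statistic
#'
#' The scalar coverage of a region: the sum over track runs, outside the
#' mask, of `value x run_length`, divided by a denominator `D`. With
#' `denominator_mode = "unmasked_length"` (default), `D` is the unmasked
#' region length; with `"full_gAAV_size"`, `D` is the full region length.
#' Both interpret "normalized count times interval length summed over the
#' region, over the region size", with ITR intervals removed from the
#' calculation; runs partially overlapping the mask are split exactly at
#' mask boundaries. Bases beyond the track extent count as zero.
#'
#' @param track A `coverage_track`.
#' @param region_length Region (vector genome) length in bp; must be >= the
#'   track extent.
#' @param mask An `interval_set` on the track's contig (or `NULL` / empty).
#' @param denominator_mode `"unmasked_length"` or `"full_gAAV_size"`.
#' @param sample_id Optional sample id carried into the result.
#' @return A `coverage_stat`: list with `sample_id`, `region`, `raw_value`,
#'   `masked_length`, `denominator_mode`.
#' @export
region_coverage_stat <- function(track, region_length, mask = NULL,
                                 denominator_mode = c("unmasked_length",
                                                      "full_gAAV_size"),
                                 sample_id = NA_character_) {
  denominator_mode <- match.arg(denominator_mode)
  stopifnot(inherits(track, "coverage_track"))
  iv <- track$intervals
  if (nrow(iv) > 0 && max(iv$end) > region_length)
    stop("region_length (", region_length,
         ") smaller than track extent (", max(iv$end), ")")
  masked_len <- 0L
  eff_w <- iv$end - iv$start
  if (!is.null(mask) && nrow(mask) > 0) {
    m <- mask[mask$contig == track$contig, ]
    if (nrow(m) < nrow(mask) && nrow(m) == 0 && nrow(mask) > 0)
      stop("mask contig does not match track contig '", track$contig, "'")
    if (nrow(m) > 0) {
      mc <- data.table(start = pmax(m$start, 0L),
                       end = pmin(m$end, as.integer(region_length)))
      mc <- mc[mc$start < mc$end]
      masked_len <- sum(mc$end - mc$start)
      if (nrow(iv) > 0 && nrow(mc) > 0) {
        ir <- IRanges::IRanges(start = iv$start + 1L, end = iv$end)
        mr <- IRanges::IRanges(start = mc$start + 1L, end = mc$end)
        ov <- IRanges::findOverlaps(ir, mr)
        if (length(ov) > 0) {
          w_ov <- IRanges::width(IRanges::pintersect(
            ir[S4Vectors::queryHits(ov)], mr[S4Vectors::subjectHits(ov)]))
          masked_in <- tapply(w_ov, S4Vectors::queryHits(ov), sum)
          idx <- as.integer(names(masked_in))
          eff_w[idx] <- eff_w[idx] - as.integer(masked_in)
        }
      }
    }
  }
  D <- if (denominator_mode == "unmasked_length")
    region_length - masked_len else region_length
  if (D <= 0) stop("coverage statistic denominator is zero")
  raw <- sum(iv$value * eff_w) / D
  structure(list(sample_id = sample_id, region = track$contig,
                 raw_value = raw, masked_length = as.integer(masked_len),
                 denominator_mode = denominator_mode),
            class = "coverage_stat")
}

#' @export
print.coverage_stat <- function(x, ...) {
  cat(sprintf("<coverage_stat> %s on %s: %.6g (%s, %d bp masked)\n",
              x$sample_id, x$region, x$raw_value, x$denominator_mode,
              x$masked_length))
  invisible(x)
}

#' Per-sample coverage statistics for a set of libraries
#'
#' Convenience wrapper running dedup -> CPM track -> masked coverage
#' statistic for each fragment set, on the vector contig.
#'
#' @param fragment_sets List of `fragment_set` objects (not yet
#'   deduplicated).
#' @param build The `genome_build`.
#' @param mask The ITR `interval_set`.
#' @param denominator_mode Passed to [region_coverage_stat()].
#' @param track_dir Optional directory; when given, each sample's vector
#'   bedGraph track is written there.
#' @return A data.table: sample_id, target, capsid, species, context,
#'   timepoint, replicate, n_fragments, n_dedup, raw_value,
#'   denominator_mode.
#' @export
coverage_stats_table <- function(fragment_sets, build, mask,
                                 denominator_mode = "unmasked_length",
                                 track_dir = NULL) {
  contig <- build$vector$name
  L <- as.integer(build$vector$length)
  rows <- lapply(fragment_sets, function(fs) {
    n0 <- nrow(fs$records)
    # same computation as deduplicate() + per_base_cpm_track(), but only the
    # vector-contig subset is materialized (the dedup count N is library-wide)
    dup <- fragment_duplicates(fs$records)
    N <- sum(!dup)
    if (N == 0) stop("empty library ", fs$meta$sample_id)
    sel <- which(!dup & fs$records$contig == contig)
    tr <- cpm_track_from_records(fs$records[sel], L, N, contig)
    if (!is.null(track_dir))
      write_bedgraph(tr, file.path(track_dir,
                                   paste0(fs$meta$sample_id, ".bedgraph")))
    st <- region_coverage_stat(tr, L, mask, denominator_mode,
                               sample_id = fs$meta$sample_id)
    m <- fs$meta
    data.table(sample_id = m$sample_id, target = m$target,
               capsid = m$capsid, species = m$species, context = m$context,
               timepoint = m$timepoint, replicate = m$replicate,
               n_fragments = n0, n_dedup = N,
               raw_value = st$raw_value,
               denominator_mode = denominator_mode)
  })
  rbindlist(rows)
}
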