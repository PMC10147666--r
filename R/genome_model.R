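#' @importFrom data.table data.table as.data.table setorder setnames
#'   rbindlist fread set CJ :=
#' @importFrom stats var quantile fivenum pt pf rnorm runif
#' @importFrom utils write.table read.table packageVersion
NULL

# All coordinates in this package are 0-based half-open (BED/bedGraph
# convention); an interval [start, end) has length end - start.

VECTOR_FEATURE_LABELS <- c("ITR_left", "promoter", "transgene",
                           "regulatory", "polyA", "ITR_right")

#' Construct an annotated AAV vector genome (ITR-to-ITR cassette)
#'
#' Builds the model of the recombinant vector genome as it appears on the
#' combined reference: the expression cassette flanked by two inverted
#' terminal repeats (ITRs), with the genome defined from ITR to ITR so that
#' `ITR_left` starts at 0 and `ITR_right` ends at `length`.
#'
#' @param length Total vector genome length in bp (ITR to ITR).
#' @param itr_length Length of each ITR in bp (default 145, the canonical
#'   AAV2 ITR length).
#' @param feature_layout Named numeric vector of inner feature lengths, in
#'   order, using labels from `promoter`, `transgene`, `regulatory`,
#'   `polyA`. Must sum to `length - 2 * itr_length`. When `NULL`, a default
#'   CAG-luciferase-like layout is derived proportionally.
#' @param name Contig name for the vector (default `"gAAV"`).
#' @param seed Optional integer; when given, a reproducible random
#'   nucleotide sequence of length `length` is attached.
#' @return An object of class `vector_genome` with fields `name`, `length`,
#'   `features` (data.table of label/start/end, 0-based half-open) and
#'   `sequence` (or `NULL`).
#' @export
build_vector_genome <- function(length = 4000L, itr_length = 145L,
                                feature_layout = NULL, name = "gAAV",
                                seed = NULL) {
  length <- as.integer(length)
  itr_length <- as.integer(itr_length)
  if (itr_length < 1L)
    stop("itr_length must be >= 1")
  inner <- length - 2L * itr_length
  if (inner < 0L)
    stop("vector length too short for two ITRs of ", itr_length, " bp")
  if (is.null(feature_layout)) {
    # proportional CAG-promoter / luciferase-CDS / WPRE-like / polyA split
    prop <- c(promoter = 0.16, transgene = 0.65, regulatory = 0.07,
              polyA = 0.12)
    feature_layout <- floor(prop * inner)
    feature_layout["transgene"] <- feature_layout["transgene"] +
      inner - sum(feature_layout)
  }
  if (sum(feature_layout) != inner)
    stop("feature layout lengths (", sum(feature_layout),
         ") inconsistent with total length: need ", inner,
         " bp between the ITRs")
  bad <- setdiff(names(feature_layout), VECTOR_FEATURE_LABELS)
  if (length(bad) > 0)
    stop("unknown feature labels: ", paste(bad, collapse = ", "))
  labels <- c("ITR_left", names(feature_layout), "ITR_right")
  lens <- c(itr_length, as.integer(feature_layout), itr_length)
  ends <- cumsum(lens)
  features <- data.table(label = labels,
                         start = as.integer(ends - lens),
                         end = as.integer(ends))
  sequence <- NULL
  if (!is.null(seed)) {
    sequence <- random_dna(length, seed)
  }
  structure(list(name = name, length = length, features = features,
                 sequence = sequence),
            class = "vector_genome")
}

random_dna <- function(n, seed) {
  set.seed(as.integer(seed))
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

vg_feature <- function(vector, lab) {
  sel <- which(vector$features$label == lab)
  if (length(sel) == 0) return(NULL)
  vector$features[sel, ]
}

#' @export
print.vector_genome <- function(x, ...) {
  cat("<vector_genome> ", x$name, ": ", x$length, " bp, ",
      nrow(x$features), " features",
      if (!is.null(x$sequence)) ", with sequence" else "", "\n", sep = "")
  print(x$features)
  invisible(x)
}

#' Combine host contigs with the vector genome into one reference
#'
#' Appends the vector genome as the last contig of the reference, flagged as
#' the vector, mirroring the alignment setup in which the host genome build
#' is merged with the vector genome sequence.
#'
#' @param host_contigs A data.frame with columns `name` and `length`, or a
#'   named numeric vector of contig lengths. May be empty (vector-only
#'   reference, useful for vector-focused tests).
#' @param vector A `vector_genome`.
#' @return An object of class `genome_build` with fields `contigs`
#'   (data.table: name, length, is_vector) and `vector`.
#' @export
build_combined_reference <- function(host_contigs, vector) {
  stopifnot(inherits(vector, "vector_genome"))
  if (is.numeric(host_contigs)) {
    host_contigs <- data.table(name = names(host_contigs),
                               length = as.numeric(host_contigs))
  }
  host_contigs <- as.data.table(host_contigs)
  if (nrow(host_contigs) > 0) {
    if (anyDuplicated(host_contigs$name))
      stop("duplicate host contig names")
    if (vector$name %in% host_contigs$name)
      stop("host contig name collides with vector contig '",
           vector$name, "'")
    if (any(host_contigs$length <= 0))
      stop("host contig lengths must be positive")
  }
  contigs <- rbind(
    data.table(name = as.character(host_contigs$name),
               length = as.numeric(host_contigs$length),
               is_vector = FALSE),
    data.table(name = vector$name, length = as.numeric(vector$length),
               is_vector = TRUE)
  )
  structure(list(contigs = contigs, vector = vector),
            class = "genome_build")
}

#' @export
print.genome_build <- function(x, ...) {
  cat("<genome_build> ", nrow(x$contigs), " contigs, vector = ",
      x$vector$name, " (", x$vector$length, " bp)\n", sep = "")
  print(x$contigs)
  invisible(x)
}

contig_length <- function(build, contig) {
  i <- match(contig, build$contigs$name)
  if (is.na(i)) stop("unknown contig: ", contig)
  build$contigs$length[i]
}

#' Canonical sorted/merged interval set
#'
#' Intervals are 0-based half-open; overlapping or abutting intervals on the
#' same contig are merged, and the result is sorted by (contig, start).
#'
#' @param intervals data.frame with columns `contig`, `start`, `end`.
#' @return An `interval_set` (a data.table with the invariant enforced).
#' @export
interval_set <- function(intervals = data.frame(contig = character(),
                                                start = integer(),
                                                end = integer())) {
  iv <- as.data.table(intervals)[, c("contig", "start", "end")]
  iv[, `:=`(contig = as.character(contig), start = as.integer(start),
            end = as.integer(end))]
  if (nrow(iv) > 0) {
    if (any(iv$start >= iv$end))
      stop("interval_set requires start < end for every interval")
    merged <- iv[, {
      ir <- IRanges::reduce(IRanges::IRanges(start = start + 1L, end = end))
      list(start = IRanges::start(ir) - 1L, end = IRanges::end(ir))
    }, by = contig]
    setorder(merged, contig, start)
    iv <- merged
  }
  structure(iv, class = c("interval_set", class(iv)))
}

#' Total length covered by an interval set
#'
#' @param mask An `interval_set`.
#' @param contig Optional contig to restrict to.
#' @return Total covered bases (intervals are disjoint by construction).
#' @export
interval_set_total_length <- function(mask, contig = NULL) {
  if (nrow(mask) == 0) return(0L)
  m <- if (is.null(contig)) mask else mask[mask$contig == contig, ]
  sum(m$end - m$start)
}

#' Extract the ITR mask of a vector genome
#'
#' Returns the two ITR intervals as an [interval_set()] on the vector
#' contig. ITR coverage is systematically overrepresented in both Cut&Tag
#' and Tn5 libraries, so these intervals are excluded from the vector
#' coverage statistic.
#'
#' @param vector A `vector_genome` with both `ITR_left` and `ITR_right`
#'   features.
#' @return An `interval_set` containing exactly the two ITR intervals.
#' @export
itr_mask <- function(vector) {
  stopifnot(inherits(vector, "vector_genome"))
  left <- vg_feature(vector, "ITR_left")
  right <- vg_feature(vector, "ITR_right")
  if (is.null(left) || is.null(right))
    stop("vector genome is missing an ITR feature (need ITR_left and ITR_right)")
  interval_set(data.frame(contig = vector$name,
                          start = c(left$start, right$start),
                          end = c(left$end, right$end)))
}

#' Write reference files for a combined genome build
#'
#' Writes, under `dir`: `reference.fa` (all contigs; synthetic sequence is
#' generated for contigs without one, seeded), `contigs.tsv` (name, length,
#' is_vector), `vector_features.bed` and `itr_mask.bed` (0-based half-open
#' BED). [read_reference()] restores the `genome_build` and mask losslessly
#' (sequence identity holds for the vector contig when it carries one).
#'
#' @param build A `genome_build`.
#' @param mask An `interval_set` (typically [itr_mask()] of the vector).
#' @param dir Output directory (created if needed).
#' @param seed Seed for synthetic host sequence generation.
#' @param fasta_width Line width for FASTA output.
#' @return Invisibly, the named vector of file paths written.
#' @export
serialize_reference <- function(build, mask, dir, seed = 1L,
                                fasta_width = 60L) {
  stopifnot(inherits(build, "genome_build"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(fasta = file.path(dir, "reference.fa"),
             contigs = file.path(dir, "contigs.tsv"),
             features = file.path(dir, "vector_features.bed"),
             mask = file.path(dir, "itr_mask.bed"))
  seqs <- vapply(seq_len(nrow(build$contigs)), function(i) {
    name <- build$contigs$name[i]
    if (build$contigs$is_vector[i] && !is.null(build$vector$sequence))
      build$vector$sequence
    else
      random_dna(build$contigs$length[i],
                 derive_seed(seed, paste0("refseq:", name)))
  }, character(1))
  names(seqs) <- build$contigs$name
  dna <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(dna, paths[["fasta"]], width = fasta_width)
  write.table(build$contigs, paths[["contigs"]], sep = "\t",
              quote = FALSE, row.names = FALSE)
  write_bed(data.table(contig = build$vector$name,
                       start = build$vector$features$start,
                       end = build$vector$features$end,
                       name = build$vector$features$label),
            paths[["features"]])
  write_bed(data.table(contig = mask$contig, start = mask$start,
                       end = mask$end, name = "ITR"), paths[["mask"]])
  invisible(paths)
}

#' Read back a serialized reference
#'
#' @param dir Directory written by [serialize_reference()].
#' @return A list with elements `build` (a `genome_build`) and `mask` (an
#'   `interval_set`).
#' @export
read_reference <- function(dir) {
  contigs <- as.data.table(read.table(file.path(dir, "contigs.tsv"),
                                      header = TRUE, sep = "\t",
                                      colClasses = c("character", "numeric",
                                                     "logical")))
  feats <- read_bed(file.path(dir, "vector_features.bed"))
  dna <- Biostrings::readDNAStringSet(file.path(dir, "reference.fa"))
  vec_row <- which(contigs$is_vector)
  if (length(vec_row) != 1L) stop("contigs.tsv must flag exactly one vector contig")
  vname <- contigs$name[vec_row]
  vector <- structure(list(
    name = vname,
    length = as.integer(contigs$length[vec_row]),
    features = data.table(label = feats$name, start = feats$start,
                          end = feats$end),
    sequence = as.character(dna[[match(vname, names(dna))]])
  ), class = "vector_genome")
  build <- build_combined_reference(contigs[!contigs$is_vector,
                                            c("name", "length")], vector)
  mask_bed <- read_bed(file.path(dir, "itr_mask.bed"))
  mask <- interval_set(mask_bed[, c("contig", "start", "end")])
  list(build = build, mask = mask)
}

write_bed <- function(df, path) {
  df <- as.data.table(df)
  stopifnot(all(c("contig", "start", "end") %in% names(df)))
  cols <- list(df$contig, as.integer(df$start), as.integer(df$end))
  if (!is.null(df$name)) {
    cols <- c(cols, list(df$name))
    if (!is.null(df$score) || !is.null(df$strand)) {
      score <- if (is.null(df$score)) rep(0L, nrow(df)) else df$score
      strand <- if (is.null(df$strand)) rep(".", nrow(df)) else df$strand
      cols <- c(cols, list(score, strand))
    }
  }
  lines <- do.call(paste, c(cols, sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

read_bed <- function(path) {
  if (file.size(path) == 0)
    return(data.table(contig = character(), start = integer(),
                      end = integer(), name = character(),
                      score = integer(), strand = character()))
  bed <- fread(path, header = FALSE, sep = "\t")
  nm <- c("contig", "start", "end", "name", "score", "strand")
  setnames(bed, nm[seq_len(ncol(bed))])
  bed[, `:=`(contig = as.character(contig), start = as.integer(start),
             end = as.integer(end))]
  bed
}

#' Derive a reproducible sub-stream seed from a global seed and a key
#'
#' Deterministic string hash folded with the global seed, kept below 2^31 so
#' it is a valid R integer seed. Used so that every simulated library gets
#' its own stable random stream: adding a library to a study does not
#' perturb any other library's data.
#'
#' @param seed Integer global seed.
#' @param key Character key (e.g. a sample identifier).
#' @return A non-negative integer seed.
#' @export
derive_seed <- function(seed, key) {
  m <- 2147483647
  h <- as.numeric(seed) %% m
  for (ch in utf8ToInt(as.character(key)))
    h <- (h * 31 + ch) %% m
  as.integer(h)
}
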