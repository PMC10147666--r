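#' Build a study roster of libraries to simulate
#'
#' One row per library. Chromatin targets get `n_replicates` rows per
#' condition; every condition additionally gets one Tn5 input library
#' (shared by all targets of that condition, like a ChIP input).
#'
#' Abundance variability is injected on two levels, both lognormal jitters
#' of the vector fraction: a *condition-level* jitter shared by every
#' library of the condition including its Tn5 input (each capsid/species/
#' timepoint combination transduces to its own episome abundance; the Tn5
#' input is made from bulk nuclei of the same condition pool, so it tracks
#' that abundance — this is exactly what the Tn5 ratio normalization
#' cancels), and a *replicate-level* jitter on each chromatin library only
#' (well-to-well biological variation, which survives normalization and is
#' what the replicate statistics see).
#'
#' @param conditions data.frame with columns `capsid`, `species`, `context`,
#'   `timepoint`, and optionally per-condition `vector_fraction` and
#'   `gene_body_multiplier` (enrichment ground truth; default 1).
#' @param targets Chromatin targets to profile per condition.
#' @param n_replicates Biological replicates per (condition, target).
#' @param n_fragments Fragments per chromatin library.
#' @param tn5_depth_factor Depth multiplier for the Tn5 input libraries
#'   (default 7.5: input libraries are sequenced several-fold deeper than
#'   the chromatin libraries, which keeps the per-condition normalizer
#'   noise small).
#' @param vector_fraction Default vector fraction at uniform profile.
#' @param biological_cv Lognormal sd of the per-replicate vector-fraction
#'   jitter on chromatin libraries (0 disables it).
#' @param condition_cv Lognormal sd of the condition-level abundance jitter
#'   shared by all libraries of a condition (0 disables it).
#' @param duplicate_rate,itr_multiplier Passed to [simulation_config()].
#' @param seed Global seed; per-replicate jitter and per-library streams are
#'   derived from it with [derive_seed()].
#' @return A data.table roster, one row per library, with all simulation
#'   parameters resolved.
#' @export
study_roster <- function(conditions, targets = "H3K4me3",
                         n_replicates = 3L, n_fragments = 5e5,
                         tn5_depth_factor = 7.5,
                         vector_fraction = 0.01, biological_cv = 0.15,
                         condition_cv = 0.3,
                         duplicate_rate = 0.1, itr_multiplier = 5,
                         seed = 1L) {
  conditions <- as.data.table(conditions)
  stopifnot(all(c("capsid", "species", "context", "timepoint") %in%
                  names(conditions)))
  if (is.null(conditions$vector_fraction))
    set(conditions, j = "vector_fraction", value = vector_fraction)
  if (is.null(conditions$gene_body_multiplier))
    set(conditions, j = "gene_body_multiplier", value = 1)
  rows <- list()
  for (i in seq_len(nrow(conditions))) {
    cn <- conditions[i, ]
    ckey <- paste(cn$species, cn$context, cn$capsid, cn$timepoint, sep = "_")
    vf_cond <- cn$vector_fraction
    if (condition_cv > 0) {
      set.seed(derive_seed(seed, paste0("cond:", ckey)))
      vf_cond <- vf_cond * exp(rnorm(1, 0, condition_cv))
    }
    for (tg in c(targets, "Tn5_input")) {
      nrep <- if (tg == "Tn5_input") 1L else as.integer(n_replicates)
      for (r in seq_len(nrep)) {
        sid <- paste(ckey, tg, paste0("rep", r), sep = "_")
        # replicate-level jitter on chromatin libraries only: the Tn5 input
        # measures the condition pool itself
        vf <- vf_cond
        if (biological_cv > 0 && tg != "Tn5_input") {
          set.seed(derive_seed(seed, paste0("biorep:", sid)))
          vf <- vf * exp(rnorm(1, 0, biological_cv))
        }
        rows[[length(rows) + 1L]] <- data.table(
          sample_id = sid, target = tg, capsid = cn$capsid,
          species = cn$species, context = cn$context,
          timepoint = cn$timepoint, replicate = r,
          n_fragments = as.numeric(n_fragments) *
            (if (tg == "Tn5_input") tn5_depth_factor else 1),
          vector_fraction = min(vf, 1),
          gene_body_multiplier = cn$gene_body_multiplier,
          itr_multiplier = itr_multiplier, duplicate_rate = duplicate_rate,
          lib_seed = derive_seed(seed, paste0("lib:", sid)))
      }
    }
  }
  rbindlist(rows)
}

#' Simulate every library of a roster and compute coverage statistics
#'
#' Runs the core per-library chain — simulate, deduplicate, per-base CPM
#' track on the vector contig, ITR-masked coverage statistic — and the
#' dataset-level Tn5 normalization.
#'
#' @param roster A [study_roster()].
#' @param build A `genome_build`.
#' @param mask The ITR `interval_set`.
#' @param denominator_mode Passed to [region_coverage_stat()].
#' @param track_dir Optional directory for per-sample bedGraph tracks.
#' @return List: `stats` (per-sample coverage statistics), `norm`
#'   (Tn5-normalized table).
#' @export
compute_study <- function(roster, build, mask,
                          denominator_mode = "unmasked_length",
                          track_dir = NULL) {
  fsets <- lapply(seq_len(nrow(roster)), function(i)
    simulate_roster_row(roster[i, ], build))
  stats <- coverage_stats_table(fsets, build, mask, denominator_mode,
                                track_dir = track_dir)
  list(stats = stats, norm = tn5_normalize_dataset(stats))
}

# Simulate one roster row (shared by compute_study and fragment export).
simulate_roster_row <- function(row, build) {
  meta <- library_meta(row$sample_id, row$target, row$capsid, row$species,
                       row$context, row$timepoint, row$replicate)
  gbm <- row$gene_body_multiplier %||% 1
  profile <- if (gbm != 1) gene_body_profile(build$vector, gbm) else NULL
  cfg <- simulation_config(n_fragments = row$n_fragments,
                           vector_fraction = row$vector_fraction,
                           enrichment_profile = profile,
                           itr_multiplier = row$itr_multiplier %||% 5,
                           duplicate_rate = row$duplicate_rate %||% 0.1,
                           seed = row$lib_seed)
  if (row$target == "Tn5_input") simulate_tn5_library(cfg, build, meta)
  else simulate_chromatin_library(cfg, build, meta)
}

#' Group comparisons over a Tn5-normalized table
#'
#' The reporting layer run by the pipeline: per target, pairwise Welch t
#' tests between all conditions with >= 2 replicates each, plus a two-way
#' capsid x species ANOVA when both factors vary (one-way across the
#' varying factor otherwise, when it has >= 3 levels or the Welch pair
#' list is empty).
#'
#' @param norm Output of [tn5_normalize_dataset()] (or a data.frame with
#'   columns target, capsid, species, context, timepoint, normalized).
#' @return A data.table: target, test, comparison, statistic, df1, df2,
#'   p_value, stars.
#' @export
compare_stage <- function(norm) {
  norm <- as.data.table(norm)
  norm[, cond := paste(capsid, species, context, timepoint, sep = "/")]
  out <- list()
  for (tg in unique(norm$target)) {
    d <- norm[norm$target == tg, ]
    conds <- unique(d$cond)
    if (length(conds) >= 2) {
      prs <- utils::combn(sort(conds), 2, simplify = FALSE)
      for (pr in prs) {
        a <- d$normalized[d$cond == pr[1]]
        b <- d$normalized[d$cond == pr[2]]
        if (length(a) >= 2 && length(b) >= 2) {
          tr <- welch_t(a, b)
          out[[length(out) + 1L]] <- data.table(
            target = tg, test = "welch_t",
            comparison = paste(pr, collapse = " vs "),
            statistic = tr$statistic, df1 = tr$df, df2 = NA_real_,
            p_value = tr$p_value, stars = tr$stars)
        }
      }
    }
    two_way <- length(unique(d$capsid)) >= 2 && length(unique(d$species)) >= 2
    if (two_way) {
      trs <- anova_twoway(d$normalized, d$capsid, d$species,
                          names = c("capsid", "species"))
      for (tr in trs)
        out[[length(out) + 1L]] <- data.table(
          target = tg, test = "anova_2way", comparison = tr$term,
          statistic = tr$statistic, df1 = tr$df[1], df2 = tr$df[2],
          p_value = tr$p_value, stars = tr$stars)
    } else {
      for (fac in c("capsid", "species", "timepoint")) {
        if (length(unique(d[[fac]])) >= 3) {
          tr <- anova_oneway(d$normalized, d[[fac]])
          out[[length(out) + 1L]] <- data.table(
            target = tg, test = "anova_1way", comparison = fac,
            statistic = tr$statistic, df1 = tr$df[1], df2 = tr$df[2],
            p_value = tr$p_value, stars = tr$stars)
        }
      }
    }
  }
  if (length(out) == 0)
    return(data.table(target = character(), test = character(),
                      comparison = character(), statistic = numeric(),
                      df1 = numeric(), df2 = numeric(),
                      p_value = numeric(), stars = character()))
  rbindlist(out)
}

#' Validate a pipeline configuration
#'
#' Checks performed before any compute: roster columns present, sample ids
#' unique, every chromatin condition has a Tn5 input library, and a seed is
#' set. Violations are reported together, naming offending conditions.
#'
#' @param config A pipeline configuration list (see [run_pipeline()]).
#' @return Invisibly `TRUE`; stops with a message otherwise.
#' @export
validate_pipeline_config <- function(config) {
  problems <- character()
  if (is.null(config$seed)) problems <- c(problems, "no global seed set")
  roster <- as.data.table(config$roster)
  need <- c("sample_id", "target", "capsid", "species", "context",
            "timepoint", "replicate", "n_fragments", "vector_fraction",
            "lib_seed")
  miss <- setdiff(need, names(roster))
  if (length(miss) > 0)
    problems <- c(problems,
                  paste("roster missing columns:", paste(miss, collapse = ", ")))
  if (length(problems) == 0) {
    if (anyDuplicated(roster$sample_id))
      problems <- c(problems, "duplicate sample ids in roster")
    ckey <- function(d) paste(d$species, d$context, d$capsid, d$timepoint,
                              sep = "/")
    ct <- roster[roster$target != "Tn5_input", ]
    tn5 <- roster[roster$target == "Tn5_input", ]
    orphan <- setdiff(unique(ckey(ct)), unique(ckey(tn5)))
    if (length(orphan) > 0)
      problems <- c(problems,
                    paste("conditions without a Tn5 input library:",
                          paste(orphan, collapse = "; ")))
  }
  if (length(problems) > 0)
    stop("invalid pipeline config:\n  - ",
         paste(problems, collapse = "\n  - "))
  invisible(TRUE)
}

#' Run the full pipeline from one configuration
#'
#' Stages: validate -> build + serialize reference -> simulate libraries ->
#' deduplicate -> per-base CPM tracks (vector contig bedGraphs) ->
#' ITR-masked coverage statistics -> Tn5 normalization -> group statistics.
#' Re-running with the same config reproduces every numeric output
#' byte-identically.
#'
#' @param config List with elements: `roster` (a [study_roster()]),
#'   `seed` (integer), and optionally `reference` (list: `vector_length`,
#'   `itr_length`, `host` named lengths, `vector_name`) and
#'   `denominator_mode`.
#' @param out_dir Output directory; layout: `reference/`, `tracks/`,
#'   `stats.tsv`, `norm.tsv`, `tests.tsv`, `run_log.txt`. `NULL` computes
#'   in memory only.
#' @param keep_fragments Also write per-library fragment BED files under
#'   `fragments/` (off by default; large).
#' @return List: `build`, `mask`, `stats`, `norm`, `tests`.
#' @export
run_pipeline <- function(config, out_dir = NULL, keep_fragments = FALSE) {
  validate_pipeline_config(config)
  ref <- config$reference
  if (is.null(ref)) ref <- list()
  vector_length <- ref$vector_length %||% 4000L
  itr_length <- ref$itr_length %||% 145L
  host <- ref$host %||% c(chrH = 1e6)
  vname <- ref$vector_name %||% "gAAV"
  mode <- config$denominator_mode %||% "unmasked_length"

  vec <- build_vector_genome(vector_length, itr_length, name = vname,
                             seed = derive_seed(config$seed, "vectorseq"))
  build <- build_combined_reference(host, vec)
  mask <- itr_mask(vec)

  track_dir <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    serialize_reference(build, mask, file.path(out_dir, "reference"),
                        seed = config$seed)
    track_dir <- file.path(out_dir, "tracks")
    dir.create(track_dir, showWarnings = FALSE)
  }
  roster <- as.data.table(config$roster)
  res <- compute_study(roster, build, mask, denominator_mode = mode,
                       track_dir = track_dir)
  tests <- compare_stage(res$norm)

  if (!is.null(out_dir)) {
    if (keep_fragments) {
      fdir <- file.path(out_dir, "fragments")
      dir.create(fdir, showWarnings = FALSE)
      for (i in seq_len(nrow(roster))) {
        fs <- simulate_roster_row(roster[i, ], build)
        write_fragments(fs,
                        file.path(fdir, paste0(roster$sample_id[i], ".bed")),
                        "BED", build = build)
      }
    }
    write_tsv(res$stats, file.path(out_dir, "stats.tsv"))
    write_tsv(res$norm, file.path(out_dir, "norm.tsv"))
    write_tsv(tests, file.path(out_dir, "tests.tsv"))
    log_lines <- c(
      sprintf("epivector %s", as.character(packageVersion("epivector"))),
      sprintf("seed: %d", config$seed),
      sprintf("denominator_mode: %s", mode),
      sprintf("libraries: %d", nrow(roster)),
      sprintf("fragments simulated: %.0f", sum(res$stats$n_fragments)),
      sprintf("fragments after dedup: %.0f", sum(res$stats$n_dedup)),
      "tn5 normalization denominators:",
      {
        tn5 <- unique(res$norm[, c("species", "context", "capsid",
                                   "timepoint", "tn5_mean")])
        sprintf("  %s/%s/%s/%s: %.6g", tn5$species, tn5$context,
                tn5$capsid, tn5$timepoint, tn5$tn5_mean)
      })
    writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  }
  list(build = build, mask = mask, stats = res$stats, norm = res$norm,
       tests = tests)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

write_tsv <- function(d, path) {
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a pipeline configuration from YAML
#'
#' The YAML mirrors the [run_pipeline()] config: a `reference` block, a
#' `seed`, a `denominator_mode`, and either an explicit `roster` (list of
#' library rows) or a `study` block (conditions/targets/replicates) expanded
#' with [study_roster()].
#'
#' @param path YAML file path.
#' @return A config list ready for [run_pipeline()].
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$roster) && !is.null(y$study)) {
    s <- y$study
    y$roster <- study_roster(
      conditions = rbindlist(lapply(s$conditions, as.data.table),
                             fill = TRUE),
      targets = s$targets %||% "H3K4me3",
      n_replicates = s$n_replicates %||% 3L,
      n_fragments = s$n_fragments %||% 5e5,
      vector_fraction = s$vector_fraction %||% 0.01,
      biological_cv = s$biological_cv %||% 0.15,
      seed = y$seed %||% 1L)
  } else if (!is.null(y$roster)) {
    y$roster <- rbindlist(lapply(y$roster, as.data.table), fill = TRUE)
  }
  y
}

#' Preset study scenarios with known ground truth
#'
#' Generates a condition grid emulating the study designs, runs the
#' pipeline, and returns the report bundle together with the injected
#' ground truth.
#'
#' * `fig2_like` — cell lines, capsid x species grid at one timepoint.
#'   Active-mark enrichment is depleted for LK03-delivered genomes in mouse
#'   cells (gene-body multiplier 1) and high for LK03-human and DJ in both
#'   species (multiplier `effect_size`, default 8).
#' * `fig3_like` — mouse liver, day 3, capsids LK03 / DJ / AM, one-way
#'   comparison across capsids (ground truth multipliers 1 / 6 / 3).
#' * `fig4_like` — mouse liver, LK03, day 3 vs day 15: late timepoint has
#'   10-fold fewer vector copies (vector fraction / 10 in both the Cut&Tag
#'   and Tn5 libraries) but stronger per-copy chromatinization (multiplier
#'   `effect_size`), so normalized coverage rises while the copy proxy
#'   falls.
#'
#' @param preset One of `"fig2_like"`, `"fig3_like"`, `"fig4_like"`.
#' @param n_fragments Fragments per library.
#' @param n_replicates Biological replicates per (condition, target).
#' @param seed Global seed.
#' @param effect_size Ground-truth enrichment multiplier for the enriched
#'   conditions (default 8).
#' @param capsids Optional subset of the preset's capsids.
#' @param targets Chromatin targets (default `"H3K4me3"`).
#' @param null_scenario If `TRUE`, all enrichment multipliers are set equal
#'   (to 1): no condition differs and no comparison should be called.
#' @param out_dir Optional output directory (passed to [run_pipeline()]).
#' @return The [run_pipeline()] bundle plus `conditions` (with ground
#'   truth) and `preset`.
#' @export
scenario_study <- function(preset = c("fig2_like", "fig3_like", "fig4_like"),
                           n_fragments = 5e5, n_replicates = 3L, seed = 1L,
                           effect_size = 8, capsids = NULL,
                           targets = "H3K4me3", null_scenario = FALSE,
                           out_dir = NULL) {
  preset <- match.arg(preset)
  if (preset == "fig2_like") {
    conds <- CJ(capsid = capsids %||% c("LK03", "DJ"),
                species = c("human", "mouse"))
    conds[, `:=`(context = "cell_line", timepoint = "day3")]
    # LK03-delivered genomes lack the active mark in mouse cells only
    conds[, gene_body_multiplier :=
            ifelse(capsid == "LK03" & species == "mouse", 1, effect_size)]
    conds[, vector_fraction := 0.01]
  } else if (preset == "fig3_like") {
    conds <- data.table(capsid = capsids %||% c("LK03", "DJ", "AM"),
                        species = "mouse", context = "liver",
                        timepoint = "day3")
    truth <- c(LK03 = 1, DJ = 6, AM = 3)
    conds[, gene_body_multiplier := truth[capsid]]
    conds[, vector_fraction := 0.01]
  } else {
    conds <- data.table(capsid = capsids %||% "LK03", species = "mouse",
                        context = "liver",
                        timepoint = rep(c("day3", "day15"),
                                        each = length(capsids %||% "LK03")))
    conds[, gene_body_multiplier :=
            ifelse(timepoint == "day15", effect_size, 1)]
    # late timepoint: 10-fold fewer nuclear vector genomes
    conds[, vector_fraction := ifelse(timepoint == "day15", 0.001, 0.01)]
  }
  if (null_scenario) conds[, gene_body_multiplier := 1]
  roster <- study_roster(conds, targets = targets,
                         n_replicates = n_replicates,
                         n_fragments = n_fragments, seed = seed)
  config <- list(roster = roster, seed = seed)
  res <- run_pipeline(config, out_dir = out_dir)
  res$conditions <- conds
  res$preset <- preset
  res
}
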