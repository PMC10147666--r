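---
title: "Quantifying histone-mark enrichment on episomal AAV genomes: models and design choices"
author: "epivector"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying histone-mark enrichment on episomal AAV genomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The measurement problem

An rAAV vector genome is a ~4 kb single-stranded DNA cassette flanked by
two ~145 bp inverted terminal repeats (ITRs); in the nucleus it converts to
a double-stranded, chromatinized episome. Cut&Tag libraries from
transduced cells are aligned to the host genome build merged with the
vector sequence (the `gAAV` contig, defined ITR to ITR), so the vector is
just one more — very small, often highly covered — contig. Comparing mark
enrichment on the episome across conditions requires two normalizations:

1. **Within-library**: per-base coverage in counts per million (CPM),
   making tracks comparable across sequencing depths.
2. **Across conditions**: vector abundance (episome copy number per
   nucleus) varies strongly between capsids, species and timepoints. A Tn5
   input library — tagmented bulk genomic DNA from the same condition's
   nuclei, the Cut&Tag analogue of ChIP input — carries that abundance
   signal without antibody selection, so dividing by its mean vector
   coverage converts coverage into a per-copy modification density.

## The coverage statistic

All coordinates in the package are 0-based half-open; an interval
`[start, end)` has length `end - start`. The formula "sum of normalized
count times (end − start position + 1) over gAAV size" that defines the
scalar coverage is the length-weighted sum of bedGraph run values over the
region; the `+1` belongs to 1-based inclusive display coordinates, and is
exactly the run length in half-open coordinates. For a track with runs
$(s_i, e_i, c_i)$ and an ITR mask $M$:

$$ C \;=\; \frac{\sum_i c_i \, \big| [s_i,e_i) \setminus M \big|}{D} $$

Runs partially overlapping the mask are split exactly at mask boundaries.
Two denominators are defensible and both are implemented behind
`denominator_mode`: the unmasked cassette length (default) and the full
vector length (`full_gAAV_size`). The ITRs are excluded because their
coverage is overrepresented in every library type (plausibly ssDNA/hairpin
recognition); with the default vector layout the mask removes 290 of
4000 bp. Bases absent from a bedGraph are zeros, and the statistic counts
them as such.

PCR duplicates — records identical in (contig, start, end, strand) — are
removed before CPM scaling, keeping the first record in input order, and
the CPM denominator $N$ is the deduplicated fragment count across **all**
contigs, matching genome-wide CPM semantics of standard coverage tools.
Coverage counts fragments, not reads: a fragment overlapping a base
contributes one.

## Tn5 ratio normalization

`tn5_normalize_dataset()` divides each Cut&Tag coverage by the arithmetic
mean of the Tn5 input coverages of the *matched condition*, where the
match key is (species, context, capsid, timepoint) — never the antibody
target: one input normalizes all marks of its condition. A missing or
zero-mean Tn5 match is a hard error, and mixing denominator modes within
one dataset is refused. The resulting ratio is exactly scale invariant
(multiplying all CPM values by any constant cancels) and cancels vector
abundance: in simulation, a 10-fold change of vector fraction applied to
both the Cut&Tag and the Tn5 library moves the normalized value by well
under 10% at 2e6 fragments.

## The generative model behind the simulator

The simulator emits *fragments* (paired-end inserts), not reads; the 2x75
paired-end view is derived when writing SAM. Key parameters, with
defaults:

* `n_fragments` (2e6, scaled down in tests): records per library,
  emulating the >2M-read depth of typical Cut&Tag libraries. Study rosters
  simulate Tn5 inputs 7.5x deeper (inputs are sequenced to much greater
  depth than the chromatin libraries, >15M vs >2M in the emulated design).
* `vector_fraction` (0.01 in study presets): expected share of fragments
  from the vector contig *at a uniform enrichment profile*. A 4 kb episome
  at tens to hundreds of copies against a mammalian genome makes a
  low-single-percent share realistic.
* `enrichment_profile`: piecewise-constant per-base weight multipliers on
  the vector. Crucially, enrichment changes the vector's total sampling
  mass: the host weight is calibrated so a uniform profile yields exactly
  `vector_fraction`, and a profile that multiplies the cassette weight by
  E pulls proportionally more fragments to the vector. This is what makes
  per-copy enrichment recoverable as a ratio of normalized coverages —
  with a fixed vector share, redistributing fragments within the cassette
  would leave the masked mean unchanged and no normalization could recover
  E.
* `itr_multiplier` (5): extra weight on the ITR intervals in *all*
  libraries, Tn5 included, emulating the universal ITR overrepresentation.
* `duplicate_rate` (0.1): share of emitted records that are exact copies
  of earlier records, appended after the first pass so the ground truth is
  exact.
* `fragment_length`: lognormal with mean 180, sd 50, truncated to
  [50, 1000] bp — nucleosomal scale; sampled by inverse-CDF so truncation
  is exact.
* Fragment placement: midpoints are drawn per-base proportional to the
  weight vector (uniform on host contigs), then extended symmetrically and
  clipped to contig bounds.

Study rosters add two levels of abundance variability, both lognormal
jitters of the vector fraction: a **condition-level** jitter (sd 0.3)
shared by every library of a condition *including its Tn5 input* — each
capsid/species/timepoint transduces to its own episome abundance, and the
input library made from the same nuclei pool tracks it (this component is
cancelled by normalization, and every study run exercises that
cancellation) — and a **replicate-level** jitter (sd 0.15) on chromatin
libraries only, representing well-to-well biological variation. The
replicate-level component is what survives normalization and what the
replicate statistics estimate. Making the Tn5 abundance independent of its
condition would instead inject between-group noise invisible to
within-group variance and miscalibrate every test — it would also
contradict the reason the input library exists.

Deterministic reproducibility: every library's stream seed is derived from
the global seed and the sample id by a stable string hash
(`derive_seed()`, result < 2^31), so adding a library to a roster never
perturbs any other library's data, and re-running a pipeline reproduces
all tables byte-identically.

### What the simulator does not emulate

No sequence content, GC or Tn5 insertion-site bias, no adapter artifacts,
no mapping ambiguity or mismapping between host and vector (fragments are
born mapped), no host chromatin structure (host coverage is uniform), no
concatemeric or circular episome forms, and enrichment magnitudes are free
parameters rather than estimates of the underlying biology. Tests passing
on these libraries validate the *quantification machinery* — they say
nothing about antibody specificity or mapping artifacts in real data.

## Attenuation of recovered enrichment

Two saturation effects make the recovered enrichment ratio sit a few
percent below the injected multiplier E, visibly so at E = 8:

1. **Mass saturation**: the effective vector share is
   $M/(M + k)$ with $M$ the vector mass and $k$ the calibrated host mass;
   it grows sublinearly in E. At `vector_fraction` 0.01 this costs ~5% at
   E = 8 (it would cost ~20% at 0.05 — one reason the presets use 0.01).
2. **Dedup saturation**: exact-coordinate deduplication on a 4 kb contig
   begins to remove coincidental collisions once per-base fragment
   redundancy is high; the enriched cassette is denser and loses more.
   At 2e6 fragments this costs a further few percent.

Both effects are properties of the measurement process being modeled (a
real pipeline running MarkDuplicates on a tiny dense contig behaves the
same way), so they are documented rather than corrected. The recovery
checks assert the normalized ratio within ±15% of E for E in {2, 8} at
2e6 fragments; measured values are ≈1.86–1.96 and ≈6.9–7.1.

For the same reason the ITR weight multiplier is verified on fragment
*midpoint intensity* (the quantity it actually scales, with an exact
multinomial oracle): 180 bp fragments smear the 145 bp ITR weight into the
flanks, so the per-base *coverage* ratio is attenuated below the
multiplier even before deduplication, and collapses under dedup at extreme
density.

## qPCR and assay models

A reaction with input `copies` and amplification efficiency `eff` has

$$ Ct = Ct_{10^6} - \frac{\log(copies/10^6)}{\log(1 + eff)} + \varepsilon $$

so a 10-fold dilution is spaced by $\log 10 / \log(1+eff)$ cycles
(3.32 at 100% efficiency, 3.50 at 93%). `fit_standard_curve()` is the
least-squares line of mean Ct on log10(copies) over ≥3 dilutions spanning
≥2 decades; efficiency is $10^{-1/slope} - 1$ and `absolute_copies()`
inverts the line. Technical wells are averaged on the Ct scale before any
transformation (standard practice); sub-threshold "undetermined" wells are
excluded with a warning, never imputed. ΔΔCt uses amplification base 2
(plain ΔΔCt; efficiency-corrected variants are out of scope). The
DNase-protection ratio may exceed 1 under measurement noise; it is
reported with a warning rather than clamped. Copy-per-cell uses
diploid-genome equivalents from the host genomic-DNA standard curve.

## Reporting layer conventions

* Boxplot hinges are Tukey hinges (`fivenum`); whiskers extend to the most
  extreme point within 1.5 x IQR of the hinge; points beyond are outliers.
  For 1:7 the hinges are 2.5 and 5.5 (hinge depth 2.5). A
  linear-interpolation (type-7 quantile) convention is available behind
  `quartile = "linear"`.
* Welch t uses the Welch–Satterthwaite df; groups with zero pooled
  variance are an error.
* Two-way ANOVA uses Type II sums of squares via model comparison —
  replicate counts vary across the condition grid, and Type II tests each
  main effect adjusted for the other without making main effects depend on
  the interaction coding. In a saturated noise-free layout a term with
  zero incremental SS reports F = 0, p = 1; a constant response reports
  p = 1 for every term.
* Significance stars: `*` < 0.05, `**` < 0.01, `***` < 0.001; all
  p-values are reported per comparison with no multiple-testing
  correction beyond that.

## Problem sizes

Calibration checks (enrichment recovery, abundance cancellation) run at
2e6 fragments per library; the cell-line study preset runs at 5e5 with 3
replicates per condition; null-calibration sweeps (200 seeded runs of the
equal-enrichment preset) run at 1e5 per library, since the false-call rate
of a replicate-level test does not depend on sequencing depth once
counting noise is far below replicate variability. Measured on these
sizes: Welch type-I error ≈ 0.037–0.05 at nominal 0.05, directional
false-call rate ≈ 0.01–0.02, injected 8-fold depletion recovered at
p < 0.01 with 3 replicates.

## Known limitations

The vector layout is a synthetic stand-in (the default 4000 bp /
145 bp ITR cassette), not a reconstruction of any specific plasmid;
species identity is metadata, not sequence. The coverage engine targets
the single vector contig plus small control loci, not genome-wide
analysis; there is no peak calling and no bigWig output. SAM output is a
minimal valid paired-end view intended for interchange, not a full
aligner emulation.
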