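---
title: "Classifying bacterial isolates from MALDI-TOF protein mass fingerprints"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying bacterial isolates from MALDI-TOF protein mass fingerprints}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Whole-cell MALDI-TOF mass spectrometry records the abundant proteins
(largely ribosomal) of a bacterial isolate as a fingerprint of
(m/z, intensity) peaks in the 2–20 kDa range. Because ribosomal protein
masses are conserved within species and diverge between them, these
fingerprints can classify isolates much faster than marker-gene
sequencing. `msfinger` implements the full analysis chain for such data:
spectral preprocessing, composite correlation index (CCI) relatedness
matrices, Bray–Curtis ordination, a single-linkage dendrogram of the
profiles, a neighbor-joining (NJ) 16S rRNA phylogeny, and a concordance
report that asks whether the fingerprint dendrogram groups species the
way the sequence phylogeny does.

```{r}
library(msfinger)
```

## Preprocessing model

Exported peak lists are resampled onto a fixed 1 Da grid from 2000 to
20000 Da (18001 points), so that any two spectra are comparable
point-wise. Each grid point takes the maximum intensity of the raw peaks
rounding to it (preserving apex heights); m/z values are rounded half-up
to one decimal on input, and intensities at colliding m/z are summed so
total ion signal is conserved.

Two transforms follow:

* **log10 conversion** — `I -> log10(1 + I)`. The offset pins empty
  baseline at exactly zero while compressing the dynamic range, so large
  intensity differences are narrowed and small reproducible differences
  survive. The raw-vs-log choice matters because un-transformed spectra
  are dominated by a handful of tall peaks.
* **sliding-window noise filter** — a 100 Da window slides across the
  grid in 1 Da steps; within each window the top
  `ceiling(0.2 * w)` intensities (w = window width in points, so 20 of
  100 by default) are marked as signal. Under the default *union* rule a
  grid point survives if any covering window marks it; the alternative
  *per_window* rule lets each window zero its span in sequence
  (last-writer wins) and is provided for sensitivity analysis. The union
  default was chosen because it can never delete a locally maximal peak,
  which a last-writer scheme can. Ties at the cutoff are broken by higher
  intensity, then lower m/z, so results are bit-reproducible. The final
  window start is clamped so trailing grid points are always covered.

Because the log is strictly increasing it does not change within-window
rankings, so the *support* retained by the filter is identical whether
the log is applied before or after denoising; only the surviving values
differ. Both orders are available (`preprocess_pipeline(order=)`); the
default applies the log first.

The window kernel is implemented in C++ (`src/denoise.cpp`): with 18001
grid points and ~17.9 thousand overlapping windows per spectrum, a
compiled kernel keeps multi-hundred-spectrum studies interactive. The
test suite checks it exactly against a naive window-by-window re-ranking
oracle written in R.

## The composite correlation index

The CCI of two preprocessed spectra splits the grid into `n_intervals`
equal-width mass blocks (default 10), computes the Pearson correlation
within each block, and averages the block correlations. Splitting first
rewards agreement across the whole mass range rather than letting one
crowded region dominate; `n_intervals = 1` recovers plain Pearson
correlation, so both readings of a "composite" index are available.
Blocks where either spectrum has zero variance (empty mass ranges after
denoising) carry no information and are excluded from the mean rather
than scored zero; a pair with no informative block at all is an error.
Negative composites are clamped to 0 by default so the index lives on
the same [0, 1] relatedness scale as published CCI heatmaps.

Replicate-level matrices can be averaged to strain level
(`aggregate_to_strains()`: strain-pair value = mean over cross-replicate
pairs), which is what the dendrogram stage consumes.

## Ordination, clustering, phylogeny

* **PCoA** (`pcoa()`): Gower double-centering of `-d²/2` and
  eigendecomposition. Bray–Curtis distances are generally non-Euclidean,
  so negative eigenvalues can occur; they are dropped and reported
  (count and most negative value) rather than corrected, keeping the
  retained coordinates interpretable. Axis signs are fixed by making
  each axis's largest-magnitude coordinate positive so outputs are
  reproducible run to run. `cluster_recovery_score()` quantifies visual
  separation by k-medoids on the leading axes scored with the adjusted
  Rand index.
* **Single-linkage dendrogram** (`linkage_single()`): merges the two
  clusters at minimum nearest-member distance; tie pairs are resolved by
  the lexicographically smallest pair of representative labels, so the
  merge order is deterministic. The default input is `1 - CCI` at strain
  level, which keeps the similarity matrices and the dendrogram on one
  scale; Bray–Curtis input is available. Trees serialise to Newick with
  branch length = parent height − child height.
* **NJ phylogeny** (`neighbor_joining()`): the Saitou–Nei Q-criterion
  agglomeration, written out in full rather than delegated, with
  deterministic tie-breaks and negative branch estimates clamped to zero
  (logged in an attribute). NJ is exact on additive matrices, and the
  tests exploit that: trees drawn at random generate additive distances,
  and the reconstruction must match topology (Robinson–Foulds 0) and
  branch lengths to 1e-9. Distances come from closed forms (p, JC69,
  K2P) with pairwise deletion of gaps/ambiguities. Bootstrap supports
  resample alignment columns with replacement and report the fraction of
  replicate trees containing each original bipartition; the convention
  of 1000 replicates is the default, while tests and the bundled runs
  use fewer for speed.

## Concordance between dendrogram and phylogeny

The question "do the two trees group species the same way?" is
operationalised through *spanning clades*: for each species, take the
smallest clade containing all its strains, and record which species have
at least one strain inside it (the co-group set). A species is
consistently grouped when its co-group set is identical in both trees;
the grouping similarity is the fraction of consistent species. This
criterion needs no arbitrary cut heights, reproduces the intuitive
cases (cleanly monophyletic species are consistent; two species whose
strains interleave list each other), and is symmetric in the two trees.
A cut-based alternative (`grouping_similarity_cut()`) compares flat
partitions instead and is provided as a sensitivity check, since
published analyses sometimes group by an explicit distance threshold.
Dendrograms are rooted by construction; NJ trees are midpoint-rooted
before clade extraction. The Sankey edge table is the contingency table
of the two partitions, suitable for any plotting tool.

## What the synthetic generator emulates

Real studies of this kind rarely deposit raw spectra, so the package
ships a generator whose outputs have the statistical structure the
analysis assumes, with known truth:

* a genus → species → strain hierarchy (default preset: 4 genera,
  species split 7/5/5/5 = 22, strains 3 per species for 17 species and
  2 for the remaining 5 = 61, with 3 replicates per strain);
* *genus-conserved* peaks shared by all species of a genus, drawn
  disjointly across genera so no peak is shared between genera, plus
  fresh *species-specific* peaks (defaults 8 and 12 — a realistic
  fingerprint of ~20 true peaks in 2–20 kDa);
* strain-level log-normal intensity multipliers fixed per strain, so
  replicates of one strain differ mainly in relative intensity —
  intra-strain similarity exceeds intra-genus, which exceeds
  inter-genus, the ordering real CCI matrices show;
* per-replicate measurement noise: log-normal intensity scatter
  (sd 0.25 on the log scale), 5% peak dropout, ±0.3 Da m/z jitter, and
  a sparse low-intensity noise baseline (0.005 peaks/Da, i.e. ~90
  points);
* 16S-like sequences evolved under Jukes–Cantor along the same species
  tree (within-genus branches ~0.02 substitutions/site, between-genus
  backbone 5× deeper, strain branches 0.002, 1200 sites), with no
  indels so the output is aligned by construction.

What it does **not** emulate: ionisation physics, isotopic envelopes,
detector saturation, mass-dependent resolution, peak-shape effects,
chimeric sequences, indel evolution or rate heterogeneity. Passing the
recovery tests therefore shows the *analysis chain* is correct and
well-conditioned under the assumed structure — not that any particular
real instrument or taxon set will separate equally cleanly.

All generator randomness derives from one seed; spectra and sequences
draw from offset substreams (`seed + 1`, `seed + 2`) so each stage can
be regenerated independently.

## Numerical and design choices

* m/z "one decimal place" rounding is half-up (3005.45 → 3005.5), not
  banker's rounding.
* keep count per window is `ceiling(keep_fraction * w)`, which equals
  the conventional 20-of-100 at the defaults and generalises to other
  window sizes.
* `pcoa()` treats eigenvalues within `1e-9` of the largest magnitude as
  zero.
* NJ Q-ties and linkage ties are label-lexicographic; all stochastic
  steps (generator, bootstrap, k-medoids) take explicit seeds.
* Degenerate inputs fail loudly: empty spectra, all-zero spectra (named
  in the Bray–Curtis error), saturated sequence pairs (p ≥ 3/4 under
  JC69, named), leaf/manifest mismatches (listed).

## Worked example

A small fully synthetic study, end to end:

```{r}
cfg <- default_run_config(out_dir = tempfile("run"), seed = 1)
cfg$sim <- list(n_genera = 2, species_per_genus = 2,
                strains_per_species = 2, replicates = 2, seq_length = 600)
cfg$cluster$k <- 2
cfg$phylo$bootstrap_reps <- 25
res <- run_end_to_end(cfg)
res$report
round(cci_level_means(res$cci, res$set$manifest), 3)
```

The report lists each species' co-group set under both trees and the
grouping-similarity fraction; the tier means show the expected
intra-strain > intra-genus > inter-genus ordering.

## Problem sizes and limitations

The bundled tests and the acceptance script run the default 61-strain
preset (183 spectra on the 18001-point grid) for the similarity-ordering
checks, single-replicate 61-strain runs for the end-to-end concordance
checks, 100 random 5–10 taxon additive matrices for NJ exactness, and
10000-site alignments for the substitution-model check — sizes chosen so
a complete validation runs on a laptop in a few minutes while still
exercising the full study geometry.

Known limitations: the CCI interval count behind published heatmaps is
vendor-specific and not recoverable from typical methods sections — the
default of 10 equal-width intervals is documented and configurable, and
`n_intervals = 1` gives the plain-Pearson reading; "single-cluster"
dendrograms from cloud platforms are interpreted as single linkage;
the maximum-composite-likelihood distance of MEGA is deliberately out of
scope (JC69/K2P are the supported models, and on synthetic data the
recovered topology is insensitive to the model choice — asserted in the
test suite, not assumed).
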