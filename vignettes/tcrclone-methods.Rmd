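---
title: "Methods: clonal analysis of TCRβ repertoires across tissues and memory subsets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: clonal analysis of TCRβ repertoires}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tcrclone)
library(dplyr)
```

## Scope

`tcrclone` analyses bulk TCRβ rearrangement data downstream of read
preprocessing and V/J annotation: its inputs are AIRR-style rearrangement
tables (one row per unique sequence with a V call, J call, CDR3
amino-acid junction, productivity flag and copy count) plus a sample
sheet placing each sequencing library at its (donor, age, lineage,
subset, tissue, replicate) coordinates. Everything upstream — sorting,
PCR, sequencing, quality filtering, annotation — is out of scope; the
package consumes annotated output and emits the statistics and data
tables behind repertoire figures: clonal expansion summaries, TRBV usage
matrices, overlap heatmaps, distance hierarchies and clone tracks.

## Clone definition and abundance filters

A clone is the set of sequences sharing an identical TRBV gene, TRBJ
gene and CDR3 amino-acid sequence. `assemble_clones()` sums copy counts
within each key and discards clones seen fewer than `min_copies = 2`
times — a guard against spurious "clones" created by PCR/sequencing
errors, which typically appear as one-copy, one-edit variants of an
abundant clone. Gene calls are keyed at gene level (allele suffixes
stripped) because the multiplexed genomic-DNA amplification that
produces such libraries does not resolve alleles reliably; allele-level
keying is available via `granularity = "allele"` in
`read_rearrangements()`.

The copy-number cutoff used before usage and overlap analyses
(`copy_cutoff_filter()`) removes clones strictly below half the sample's
mean copy number (total copies / unique clones). Two numerical choices
are fixed and tested: the threshold is computed **once** from the
pre-filter table (iterating would shift the mean after each pass and has
no principled stopping point), and ties at exactly half the mean
survive, reading "below" strictly. The two-copy rule is applied per
sequencing library by default; pooling copies per donor before
thresholding is possible by concatenating records under one `sample_id`
upstream of `assemble_clones()` — the per-library default matches the
fact that every downstream statistic operates on replicate-level tables.

## Clonality

For clone frequencies $p(x)$ over $L$ unique clones,

$$\mathrm{clonality} = 1 - \frac{-\sum_x p(x)\log_2 p(x)}{\log_2 L},$$

i.e. one minus normalized Shannon entropy: 0 for a uniform repertoire,
1 for a monoclonal one. For $L = 1$ the ratio is 0/0 and clonality is
defined as 1 — a monoclonal sample is maximally clonal. Clonality is
scale-invariant in the counts and strictly increases when copy mass
moves from a smaller to a larger clone; merging two clones always
lowers the raw entropy, though not necessarily clonality (the
normalizer $\log_2 L$ shrinks too). These properties are exercised in
the test suite.
Entropy is in bits (base 2); the symmetrized Kullback–Leibler divergence
below deliberately uses natural log — the two conventions are kept
exactly as the statistics are conventionally printed.

`clonality_age_regression()` fits ordinary least squares of clonality on
donor age per lineage × subset, pooling tissues, with each sample one
point (the scatter-plot reading: no donor weighting); groups with fewer
than 3 points or constant age are skipped rather than fitted.

## TRBV usage

`trbv_usage()` counts each unique clone once after the copy cutoff and
reports per-sample percentages; `usage_matrix()` assembles the genes ×
samples matrix (absent genes at 0%) that heatmaps and PCA consume. The
"centered and scaled" variant standardizes each **gene** across samples
— the only reading under which samples remain comparable — using the
sample-SD (n−1) convention; zero-variance genes map to z = 0 rather than
NaN. Hierarchical clustering and PCA of this matrix are delegated to
`stats::hclust` (complete linkage) and standard PCA routines; the
package guarantees the matrix, not the plot.

## Cosine overlap

Samples are compared as clone-frequency vectors over the union of clone
keys with cosine similarity, after applying the copy cutoff to each
replicate table independently. `sample_pair_cosine()` reports the mean
of the four replicate cross-pairs (A1B1, A1B2, A2B1, A2B2); with a
missing replicate it degrades to the available pairs and records how
many were used. For compiled group summaries
(`compile_group_overlap()`), sample pairs are classified as same subset
/ two sites, different subsets / one site, or different subsets /
different sites, and pooled across donors at pair level by default
(donor-level averaging via `pool_level = "donor"`). The optional
between-subject normalization is within-donor centering with grand-mean
restoration (value − donor mean + grand mean, per lineage) — a standard
within-subject SE correction for repeated measures; raw means are always
reported alongside.

## CDR3 sequence distances and the stratum hierarchy

The sequence-level analyses ask whether clone *sequences* (not clone
identities) track tissue or subset. Clones shared between any two
samples are removed (`remove_overlapping_clones()`), non-productive
rearrangements are excluded (assemble with `productive_only = TRUE`),
and a fixed-size random sample of clones per library is drawn
(`draw_distance_sample()`, default 500 per sample, seeded and
order-invariant via canonical key sorting so results are
machine-independent).

Distances: Levenshtein (`cdr3_levenshtein()`, unit-cost edit distance
via `utils::adist`, verified in the tests against an independent
dynamic-programming oracle), Hamming (`cdr3_hamming()`; undefined for
unequal lengths, such pairs are skipped by default with a
length-penalty variant available), and the symmetrized Kullback–Leibler
divergence between per-sample TRBV compositions
(`kl_divergence_sym()`, natural log, pseudocount 1 added to every gene
of the cohort-wide support so zero counts never produce infinities).

`distance_hierarchy()` classifies every sample pair by the *finest*
metadata level at which the two samples differ — replicate, subset,
tissue, lineage, donor — which partitions the pair set. Clone-pair
distances are averaged **within each sample pair first**, then sample
pairs are averaged within a stratum, so unequal sampling depth cannot
dominate a stratum mean. Neighboring strata are compared with two-sided
unpaired Student's t tests (pooled variance; Welch via `welch = TRUE`).
`embedding_input()` produces the symmetric clone × clone Levenshtein
matrix with tissue/subset labels that an external tSNE/UMAP consumes;
the embedding itself is out of scope.

## Clone tracking

`top_clones()` ranks a donor-lineage's clones by copies summed over all
sites, subsets and replicates; `track_clone()` aggregates one clone's
copies per site and splits each site's copies into subset fractions —
the data behind line-circle clone-tracking plots. Replicates are summed
by default (presence and size should reflect the library, not the
replicate split); `replicates = "first"` restricts to replicate 1.
Copies are reported both raw and as a fraction of the site's total
repertoire. No "enrichment" call is made per site: no quantitative
criterion is defined for one, so the package emits the underlying
numbers only.

## The synthetic cohort generator

`simulate_cohort()` exists so that every stage is exercisable, with
known ground truth, without any external download. Its defaults are
fixed study conditions, not tuning knobs:

* **Cohort**: 3 donors aged 33/48/61 (mirroring the handful of deeply
  sampled organ donors such analyses profile per-donor, with ages
  spanning the adult decades such cohorts cover), 5 sites (Bld, BM,
  Spl, LN, Lung), the six sorted lineage × subset combinations (CD4:
  TCM/TEM/TRM; CD8: TEM/TRM/TEMRA), 2 replicates per sample drawn as
  independent multinomials of 5000 cells from one clone pool.
* **Clone sizes**: per subset, a geometric "head" of expanded clones
  holding `head_mass` of the repertoire plus a uniform diverse tail.
  Defaults (TEMRA: mass 0.90, decay 0.08; TEM: 0.65/0.03; TRM:
  0.60/0.03; TCM: 0.25/0.01; tails 1200–8000 clones, TCM largest)
  produce the clonality ordering TEMRA > TEM ≈ TRM > TCM with TCM the
  most diverse — chosen once from the qualitative ordering such
  repertoires show, and held fixed.
* **Sharing**: each clone has a home tissue and joins each other tissue
  with per-subset probability (TEMRA 0.70, TEM 0.45, TRM 0.15, TCM
  0.08): circulating subsets disseminate, resident ones do not.
  Expanded clones also appear in a sibling subset with probability 0.2
  at reduced weight, so clone tracks have multi-subset wedges.
* **Sequence structure**: CDR3s are `C` + random amino acids + `F` with
  one shared length distribution (11–17, mode 14) for *all* groups, so
  distance effects can never be length artifacts. Hierarchical
  composition biases give the distance analyses a known signal: a
  donor-preferred and a donor × lineage-preferred 5-letter alphabet
  tilt the letter distribution, and each lineage × tissue carries a
  3-letter motif written at positions 5–7 of a clone's CDR3 with
  probability `imprint_strength` (default 0.6; 0 disables tissue
  imprinting for type-I-error controls). Motifs are keyed by lineage ×
  tissue so that cross-lineage pairs never share a motif and the donor
  > lineage > tissue ordering of mean distances can emerge.
* **Noise**: 4% of clones are flagged non-productive; each library adds
  `Binomial(depth, 0.005)` error reads — single-copy records whose CDR3
  is a one-edit perturbation of a frequency-sampled parent clone — whose
  keys are recorded in the ground truth so the two-copy rule's rescue
  rate is measurable.

What the generator does **not** emulate: V(D)J recombination mechanics
(no D segments, no nucleotide junctions), thymic or antigen selection,
power-law clone-size tails, length–motif interactions, or realistic
sequencing error profiles (only the spurious-singleton mode is
modelled). Passing recovery tests therefore demonstrates that the
pipeline's statistics respond correctly to the phenomena they claim to
measure — not that real repertoires look like these simulations.

## Problem sizes and numerical choices

The package's own analyses and checks run at desk scale: the default
cohort (180 libraries, ~200k records) is simulated in seconds; distance
hierarchies are computed from 60–100 drawn clones per sample (the
function default of 500 matches the scale such studies use on real
data), which puts the full 16k-sample-pair Levenshtein hierarchy at
about a minute of CPU. Determinism everywhere comes from explicit seeds
plus canonical ordering before any sampling step; no statistic depends
on row order. Degenerate inputs are defined, not crashed on: empty clone
tables propagate as empty results with warnings, monoclonal samples
have clonality 1, zero-variance genes z-score to 0, single-value groups
report SEM as `NA`, and zero frequency vectors are a hard error for
cosine similarity.

## A worked mini-pipeline

```{r pipeline, eval = FALSE}
coh <- simulate_cohort(cohort_config(), seed = 1)
clones <- assemble_clones(coh$rearrangements)

# diversity
sample_clonality(clones) |>
  inner_join(coh$samples, by = "sample_id") |>
  group_by(lineage, subset) |>
  summarise(clonality = mean(clonality), .groups = "drop")

# overlap within one donor
pw <- pairwise_overlap(clones, coh$samples)
overlap_matrix(pw, donor = "S324", lineage = "CD8")

# sequence distance hierarchy
priv <- remove_overlapping_clones(clones)
ds <- draw_distance_sample(priv, n = 100, seed = 1)
distance_hierarchy(ds, coh$samples, metric = "levenshtein")$strata
```

## Known limitations

* The generator's clone-size law is geometric-plus-uniform; real
  repertoires are heavier-tailed, so absolute clonality values are not
  comparable to real data — only orderings and recoveries are claimed.
* Hamming distances silently reduce to the equal-length subset of clone
  pairs under the default skip policy; with heterogeneous length
  distributions the retained subset may be small.
* `remove_overlapping_clones()` removes clones shared by *any* two
  samples, including replicates of the same library; deeply sequenced,
  highly clonal samples can retain few private clones, and the drawn
  distance samples flag this (`undersampled` attribute) rather than
  erroring.
* The between-subject normalization of compiled overlaps is one
  reasonable reading of a within-subject correction; raw values are
  always emitted so the choice is inspectable.
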