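# tcrclone

Downstream analysis of bulk T cell receptor β (TCRβ) repertoires across
tissues and memory T cell subsets, for immunologists working with
AIRR-format rearrangement tables (V/J gene calls, CDR3 amino-acid
junction, productivity, copy count) plus a sample sheet of
(donor, age, lineage CD4/CD8, subset TCM/TEM/TRM/TEMRA, tissue,
replicate) coordinates.

The package implements the statistics such studies hinge on:

* **Clone assembly** — a clone is a unique (TRBV, TRBJ, CDR3aa) key,
  required to be seen ≥ 2 times (`assemble_clones()`), with a
  50%-of-mean copy-number cutoff for abundance-weighted analyses
  (`copy_cutoff_filter()`).
* **Clonality** — one minus normalized Shannon entropy,
  `1 − H(p)/log2(L)`: 0 = maximally diverse, 1 = monoclonal
  (`clonality()`, `sample_clonality()`), plus top-clone rank-band
  summaries (`top_clone_proportions()`) and per-subset regression of
  clonality on donor age (`clonality_age_regression()`).
* **TRBV usage** — percentage of unique clones per gene after the copy
  cutoff, as tidy tables and genes × samples (z-scaled) matrices for
  heatmaps/PCA (`trbv_usage()`, `usage_matrix()`), with CD4-vs-CD8
  per-gene t tests (`lineage_usage_comparison()`).
* **Overlap** — cosine similarity between clone-frequency vectors,
  averaged over the four replicate cross-pairs per sample pair
  (`sample_pair_cosine()`, `pairwise_overlap()`, `overlap_matrix()`),
  compiled across donors by same-subset / cross-subset / same-site /
  cross-site design (`compile_group_overlap()`).
* **Sequence distance hierarchy** — after removing clones shared between
  samples and drawing a fixed number of clones per library, mean CDR3
  Levenshtein (or Hamming) distances and symmetrized TRBV
  Kullback–Leibler divergences (pseudocount 1, natural log) between all
  sample pairs, stratified by the finest metadata level at which each
  pair differs: replicate < subset < tissue < lineage < donor
  (`distance_hierarchy()`, `embedding_input()` for tSNE-ready matrices).
* **Clone tracking** — per-clone copies per tissue site with subset
  wedge fractions, the data behind line-circle tracking plots
  (`top_clones()`, `track_clone()`, `track_top_clones()`).
* **Synthetic cohorts** — `simulate_cohort()` generates AIRR-style
  multi-donor, multi-tissue repertoires with known ground truth
  (per-subset clone-size laws, per-subset tissue sharing,
  lineage-biased TRBV usage, tissue CDR3 motifs, replicate pairs from a
  common pool, spurious-singleton sequencing errors), so the whole
  pipeline is testable without any external data.

See `vignettes/tcrclone-methods.Rmd` for the models, conventions and
design choices.

## Worked example

```r
library(tcrclone)
library(dplyr)

coh <- simulate_cohort(cohort_config(), seed = 1)   # 3 donors, 5 tissues
clones <- assemble_clones(coh$rearrangements)        # two-copy rule

sample_clonality(clones) |>
  inner_join(coh$samples, by = "sample_id") |>
  group_by(lineage, subset) |>
  summarise(clonality = mean(clonality), .groups = "drop")
```

```
# A tibble: 6 × 3
  lineage subset clonality
  <chr>   <chr>      <dbl>
1 CD4     TCM       0.0669
2 CD4     TEM       0.199
3 CD4     TRM       0.218
4 CD8     TEM       0.197
5 CD8     TEMRA     0.304
6 CD8     TRM       0.225
```

Clonality is a property of the subset: TEMRA ≫ TEM ≈ TRM ≫ TCM, the
ordering the generator encodes and the estimator recovers from sampled
libraries.

```r
priv <- remove_overlapping_clones(clones)            # private clones only
ds <- draw_distance_sample(priv, n = 60, seed = 1)   # seeded subsample
distance_hierarchy(ds, coh$samples, metric = "levenshtein")$strata
```

```
# A tibble: 5 × 5
  stratum    mean      se n_pairs  p_vs_next
  <fct>     <dbl>   <dbl>   <int>      <dbl>
1 replicate  10.8 0.0312       90  2.70e-  2
2 subset     10.9 0.0128      360  2.03e-123
3 tissue     11.1 0.00376    2160  0
4 lineage    11.4 0.00311    2700  3.73e- 10
5 donor      11.4 0.00210   10800 NA
```

Mean CDR3 edit distance rises with each metadata level: replicates of
one library are most alike, then subsets within a tissue, tissues
within a lineage, lineages within a donor, and finally different
donors — the repertoire-similarity hierarchy, driven here by the
generator's tissue motifs and donor/lineage composition biases.

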