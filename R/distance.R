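#' Remove clones shared between samples
#'
#' Any clone key observed in more than one sample is removed from all
#' samples, leaving each sample's private clones only — the input the
#' CDR3 sequence analyses require so that shared clones cannot make two
#' samples trivially similar.
#'
#' @param clones Clone table (>= 2 samples).
#' @return Filtered clone table; the number of removed rows is attached
#'   as attribute `n_removed`. Samples emptied entirely trigger a
#'   warning.
#' @export
remove_overlapping_clones <- function(clones) {
  check_clone_table(clones)
  key <- clone_key(clones$v_call, clones$j_call, clones$cdr3_aa)
  n_samples_per_key <- rowsum(
    as.integer(!duplicated(paste(key, clones$sample_id))), key)
  shared <- rownames(n_samples_per_key)[n_samples_per_key[, 1] > 1]
  out <- clones[!key %in% shared, , drop = FALSE]
  emptied <- setdiff(unique(clones$sample_id), unique(out$sample_id))
  if (length(emptied) > 0) {
    warn(sprintf("%d sample(s) lost all clones to overlap removal",
                 length(emptied)))
  }
  out <- renormalize(out)
  attr(out, "n_removed") <- nrow(clones) - nrow(out)
  out
}

#' Draw a seeded random subset of clones per sample
#'
#' Samples up to `n` clones per sample uniformly without replacement.
#' Clones are put in canonical (key) order before drawing, so the result
#' depends only on the clone set and the seed, not on row order. Samples
#' with fewer than `n` clones contribute all their clones and are
#' flagged.
#'
#' @param clones Clone table.
#' @param n Clones per sample (default 500).
#' @param seed Integer seed.
#' @return Clone table of drawn clones with attribute `undersampled`
#'   (named logical per sample).
#' @export
draw_distance_sample <- function(clones, n = 500, seed = 1) {
  check_clone_table(clones)
  clones <- dplyr::arrange(clones, .data$sample_id, .data$v_call,
                           .data$j_call, .data$cdr3_aa)
  ids <- sort(unique(clones$sample_id))
  undersampled <- setNames(logical(length(ids)), ids)
  picks <- withr::with_seed(as.integer(seed), {
    lapply(ids, function(id) {
      rows <- which(clones$sample_id == id)
      k <- min(n, length(rows))
      sort(sample(rows, k))
    })
  })
  for (i in seq_along(ids)) {
    undersampled[ids[i]] <- length(picks[[i]]) < n
  }
  out <- clones[unlist(picks), , drop = FALSE]
  attr(out, "undersampled") <- undersampled
  out
}

#' Levenshtein edit distance between CDR3 amino-acid sequences
#'
#' Unit-cost insertions, deletions and substitutions. Returns the full
#' cross matrix for vector inputs, a scalar for two single strings.
#'
#' @param a,b Character vectors.
#' @return Integer matrix `length(a)` x `length(b)` (scalar if both are
#'   single strings).
#' @export
cdr3_levenshtein <- function(a, b) {
  m <- adist(a, b)
  storage.mode(m) <- "integer"
  if (length(a) == 1 && length(b) == 1) m[1, 1] else m
}

#' Hamming distance between CDR3 amino-acid sequences
#'
#' Counts mismatching positions. Hamming distance is undefined for
#' strings of unequal length; such pairs are skipped (`NA`) by default,
#' or given the Hamming distance over the common prefix plus the length
#' difference under `unequal = "penalty"`.
#'
#' @param a,b Character vectors.
#' @param unequal `"skip"` (default) or `"penalty"`.
#' @return Integer matrix (scalar for two single strings), `NA` where a
#'   pair was skipped.
#' @export
cdr3_hamming <- function(a, b, unequal = c("skip", "penalty")) {
  unequal <- match.arg(unequal)
  sa <- strsplit(a, ""); sb <- strsplit(b, "")
  na_ <- nchar(a); nb <- nchar(b)
  m <- matrix(NA_integer_, length(a), length(b))
  for (i in seq_along(a)) {
    for (j in seq_along(b)) {
      if (na_[i] == nb[j]) {
        m[i, j] <- sum(sa[[i]] != sb[[j]])
      } else if (unequal == "penalty") {
        k <- min(na_[i], nb[j])
        m[i, j] <- sum(sa[[i]][seq_len(k)] != sb[[j]][seq_len(k)]) +
          abs(na_[i] - nb[j])
      }
    }
  }
  if (length(a) == 1 && length(b) == 1) m[1, 1] else m
}

#' Symmetrized Kullback-Leibler divergence between TRBV compositions
#'
#' Computes `D(p_i || p_j) + D(p_j || p_i)` (natural log) between the
#' TRBV gene compositions of two clone sets. A pseudocount is added to
#' every gene of the support in both samples before normalizing to
#' frequencies, so zero counts never produce infinities.
#'
#' @param counts_i,counts_j Named numeric vectors of per-gene clone
#'   counts.
#' @param pseudocount Added to each gene's count (default 1).
#' @param support Optional character vector fixing the gene support
#'   (e.g. the union over a whole cohort); defaults to the union of the
#'   two names.
#' @return Non-negative divergence; 0 iff the smoothed frequencies are
#'   equal.
#' @export
kl_divergence_sym <- function(counts_i, counts_j, pseudocount = 1,
                              support = NULL) {
  support <- support %||% union(names(counts_i), names(counts_j))
  grab <- function(x) {
    v <- setNames(numeric(length(support)), support)
    v[intersect(names(x), support)] <- x[intersect(names(x), support)]
    v + pseudocount
  }
  ci <- grab(counts_i); cj <- grab(counts_j)
  pi_ <- ci / sum(ci); pj <- cj / sum(cj)
  sum(pi_ * log(pi_ / pj) + pj * log(pj / pi_))
}

vgene_counts <- function(tbl) {
  tab <- table(tbl$v_call)
  setNames(as.numeric(tab), names(tab))
}

## finest metadata level at which two samples differ
classify_stratum <- function(a, b) {
  dplyr::case_when(
    a$donor_id != b$donor_id ~ "donor",
    a$lineage != b$lineage ~ "lineage",
    a$tissue != b$tissue ~ "tissue",
    a$subset != b$subset ~ "subset",
    a$replicate != b$replicate ~ "replicate",
    TRUE ~ NA_character_
  )
}

.strata_levels <- c("replicate", "subset", "tissue", "lineage", "donor")

#' Distance hierarchy over metadata strata
#'
#' Classifies every sample pair by the finest metadata level at which the
#' two samples differ (replicate < subset < tissue < lineage < donor) and
#' summarizes a per-pair distance within each stratum. For the sequence
#' metrics the per-pair distance is the mean cross-clone CDR3 distance
#' (each pair aggregated before stratum averaging, so unequal clone
#' sampling cannot dominate); for `"kl"` it is the symmetrized TRBV KL
#' divergence of the two clone sets over the cohort-wide gene support.
#' Neighboring strata are compared with two-sided unpaired t tests
#' (Student's pooled variance; Welch by option).
#'
#' @param dsamples Clone table of drawn distance samples (see
#'   [remove_overlapping_clones()] and [draw_distance_sample()]).
#' @param samples Sample sheet.
#' @param metric `"levenshtein"`, `"hamming"` or `"kl"`.
#' @param pseudocount For `"kl"`.
#' @param welch Use Welch's t test for neighbor comparisons.
#' @return List with `pairs` (one row per sample pair: ids, stratum,
#'   distance) and `strata` (per stratum: `mean`, `se`, `n_pairs`,
#'   `p_vs_next` comparing the stratum to the next coarser one).
#' @export
distance_hierarchy <- function(dsamples, samples,
                               metric = c("levenshtein", "hamming", "kl"),
                               pseudocount = 1, welch = FALSE) {
  metric <- match.arg(metric)
  check_clone_table(dsamples)
  tabs <- split(dsamples, dsamples$sample_id)
  ids <- names(tabs)
  meta <- samples[match(ids, samples$sample_id), ]
  if (anyNA(meta$sample_id)) abort("dsamples contain unknown sample ids")
  if (length(ids) < 2) abort("need at least two samples")
  support <- sort(unique(dsamples$v_call))
  counts <- if (metric == "kl") lapply(tabs, vgene_counts)
  pair_dist <- function(i, j) {
    A <- tabs[[i]]; B <- tabs[[j]]
    switch(metric,
      levenshtein = mean(adist(A$cdr3_aa, B$cdr3_aa)),
      hamming = {
        d <- cdr3_hamming(A$cdr3_aa, B$cdr3_aa)
        if (all(is.na(d))) NA_real_ else mean(d, na.rm = TRUE)
      },
      kl = kl_divergence_sym(counts[[i]], counts[[j]], pseudocount,
                             support = support)
    )
  }
  idx <- combn(length(ids), 2)
  pairs <- tibble::tibble(
    sample_a = ids[idx[1, ]], sample_b = ids[idx[2, ]],
    stratum = vapply(seq_len(ncol(idx)), function(k) {
      classify_stratum(meta[idx[1, k], ], meta[idx[2, k], ])
    }, character(1)),
    distance = vapply(seq_len(ncol(idx)), function(k) {
      pair_dist(idx[1, k], idx[2, k])
    }, numeric(1))
  )
  pairs$stratum <- factor(pairs$stratum, levels = .strata_levels)
  ok <- !is.na(pairs$distance)
  strata <- pairs[ok, ] |>
    dplyr::group_by(.data$stratum) |>
    dplyr::summarise(
      mean = mean(.data$distance),
      se = if (dplyr::n() > 1) sd(.data$distance) / sqrt(dplyr::n())
           else NA_real_,
      n_pairs = dplyr::n(), .groups = "drop"
    ) |>
    dplyr::arrange(.data$stratum)
  strata$p_vs_next <- NA_real_
  present <- as.character(strata$stratum)
  for (k in seq_len(nrow(strata) - 1)) {
    x <- pairs$distance[ok & pairs$stratum == present[k]]
    y <- pairs$distance[ok & pairs$stratum == present[k + 1]]
    if (length(x) > 1 && length(y) > 1) {
      strata$p_vs_next[k] <- t.test(x, y, var.equal = !welch)$p.value
    }
  }
  list(pairs = pairs, strata = strata)
}

#' Clone-by-clone distance matrix for a 2-D embedding
#'
#' Pools the drawn clones of the given samples, takes a seeded random
#' subset of `n` clones, and returns the symmetric CDR3 Levenshtein
#' matrix together with per-clone tissue and subset labels — the input an
#' external tSNE/UMAP embedding consumes.
#'
#' @param dsamples Clone table of drawn distance samples.
#' @param samples Sample sheet.
#' @param n Total clones to embed (default 250).
#' @param seed Integer seed.
#' @return List with `distances` (n x n integer matrix, zero diagonal)
#'   and `labels` (tibble: `clone`, `sample_id`, `tissue`, `subset`,
#'   aligned 1:1 with matrix rows).
#' @export
embedding_input <- function(dsamples, samples, n = 250, seed = 1) {
  check_clone_table(dsamples)
  pool <- dplyr::arrange(dsamples, .data$sample_id, .data$v_call,
                         .data$j_call, .data$cdr3_aa)
  k <- min(n, nrow(pool))
  rows <- withr::with_seed(as.integer(seed), sort(sample(nrow(pool), k)))
  pool <- pool[rows, , drop = FALSE]
  m <- adist(pool$cdr3_aa, pool$cdr3_aa)
  storage.mode(m) <- "integer"
  labels <- pool |>
    dplyr::transmute(
      clone = clone_key(.data$v_call, .data$j_call, .data$cdr3_aa),
      sample_id = .data$sample_id) |>
    dplyr::left_join(samples[, c("sample_id", "tissue", "subset")],
                     by = "sample_id")
  list(distances = m, labels = labels)
}
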