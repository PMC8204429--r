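#' Cosine similarity between two clone-frequency vectors
#'
#' Vectors are named by clone key and aligned over the union of keys;
#' absent clones count 0. The statistic is scale-invariant, 1 for
#' identical repertoires and 0 for disjoint ones.
#'
#' @param a,b Named non-negative numeric vectors (clone key -> frequency
#'   or copies).
#' @return Cosine similarity in \[0, 1\].
#' @export
cosine_similarity <- function(a, b) {
  if (is.null(names(a)) || is.null(names(b))) {
    abort("vectors must be named by clone key")
  }
  if (any(a < 0) || any(b < 0)) abort("frequencies must be non-negative")
  keys <- union(names(a), names(b))
  x <- setNames(numeric(length(keys)), keys); x[names(a)] <- a
  y <- setNames(numeric(length(keys)), keys); y[names(b)] <- b
  nx <- sqrt(sum(x^2)); ny <- sqrt(sum(y^2))
  if (nx == 0 || ny == 0) abort("zero vector has no cosine similarity")
  sum(x * y) / (nx * ny)
}

freq_vector <- function(tbl) {
  setNames(tbl$frequency, clone_key(tbl$v_call, tbl$j_call, tbl$cdr3_aa))
}

#' Replicate-averaged cosine similarity between two samples
#'
#' Each sample is represented by its sequencing replicates; the reported
#' value is the mean cosine over all replicate cross-pairs (four when
#' both samples have two replicates). The 50%-of-mean copy cutoff is
#' applied to each replicate table independently before computing
#' frequencies. Missing replicates degrade gracefully: the mean is taken
#' over the available pairs and their number recorded.
#'
#' @param reps_a,reps_b Lists of clone tables, one per replicate.
#' @param apply_cutoff Apply [copy_cutoff_filter()] per replicate.
#' @param fraction Cutoff fraction.
#' @return Mean cosine with attribute `n_replicate_pairs`.
#' @export
sample_pair_cosine <- function(reps_a, reps_b, apply_cutoff = TRUE,
                               fraction = 0.5) {
  prep <- function(reps) {
    if (!is.list(reps) || length(reps) == 0) abort("no replicate tables")
    lapply(reps, function(tbl) {
      check_clone_table(tbl)
      if (apply_cutoff) tbl <- copy_cutoff_filter(tbl, fraction)
      freq_vector(tbl)
    })
  }
  va <- prep(reps_a); vb <- prep(reps_b)
  if (length(va) < 2 || length(vb) < 2) {
    warn("fewer than two replicates on one side; averaging available pairs")
  }
  vals <- as.vector(outer(seq_along(va), seq_along(vb),
                          Vectorize(function(i, j)
                            cosine_similarity(va[[i]], vb[[j]]))))
  out <- mean(vals)
  attr(out, "n_replicate_pairs") <- length(vals)
  out
}

#' All pairwise replicate-averaged overlaps within donor and lineage
#'
#' For every donor-lineage, computes [sample_pair_cosine()] between every
#' pair of subset-by-tissue cell populations.
#'
#' @param clones Clone table covering all replicates (multi-sample).
#' @param samples Sample sheet.
#' @param apply_cutoff,fraction Passed to [sample_pair_cosine()].
#' @return Tibble `donor_id`, `lineage`, `subset_a`, `tissue_a`,
#'   `subset_b`, `tissue_b`, `cosine_mean`, `n_replicate_pairs`.
#' @export
pairwise_overlap <- function(clones, samples, apply_cutoff = TRUE,
                             fraction = 0.5) {
  check_clone_table(clones)
  split_tables <- split(clones, clones$sample_id)
  units <- samples |>
    dplyr::distinct(.data$donor_id, .data$lineage, .data$subset,
                    .data$tissue)
  get_reps <- function(donor, lineage, subset, tissue) {
    ids <- samples$sample_id[samples$donor_id == donor &
                             samples$lineage == lineage &
                             samples$subset == subset &
                             samples$tissue == tissue]
    ids <- ids[order(samples$replicate[match(ids, samples$sample_id)])]
    tabs <- split_tables[intersect(ids, names(split_tables))]
    unname(tabs)
  }
  out <- list()
  for (dl in split(units, paste(units$donor_id, units$lineage))) {
    if (nrow(dl) < 2) next
    idx <- combn(nrow(dl), 2)
    for (k in seq_len(ncol(idx))) {
      a <- dl[idx[1, k], ]; b <- dl[idx[2, k], ]
      ra <- get_reps(a$donor_id, a$lineage, a$subset, a$tissue)
      rb <- get_reps(b$donor_id, b$lineage, b$subset, b$tissue)
      if (length(ra) == 0 || length(rb) == 0) next
      cm <- suppressWarnings(
        sample_pair_cosine(ra, rb, apply_cutoff, fraction))
      out[[length(out) + 1]] <- tibble::tibble(
        donor_id = a$donor_id, lineage = a$lineage,
        subset_a = a$subset, tissue_a = a$tissue,
        subset_b = b$subset, tissue_b = b$tissue,
        cosine_mean = as.numeric(cm),
        n_replicate_pairs = attr(cm, "n_replicate_pairs")
      )
    }
  }
  dplyr::bind_rows(out)
}

#' Per-donor overlap matrix
#'
#' Arranges the pairwise overlaps of one donor and lineage into a
#' symmetric matrix over subset-by-tissue populations (unit diagonal),
#' with a complete-linkage leaf ordering attached for heatmap plotting.
#'
#' @param pairwise Output of [pairwise_overlap()] (any donors).
#' @param donor,lineage Which block to extract.
#' @return Symmetric numeric matrix with attribute `hclust_order`.
#' @export
overlap_matrix <- function(pairwise, donor, lineage) {
  pw <- pairwise[pairwise$donor_id == donor & pairwise$lineage == lineage, ]
  labs <- sort(unique(c(paste(pw$subset_a, pw$tissue_a, sep = "."),
                        paste(pw$subset_b, pw$tissue_b, sep = "."))))
  if (length(labs) < 2) abort("need at least two populations")
  m <- matrix(NA_real_, length(labs), length(labs),
              dimnames = list(labs, labs))
  diag(m) <- 1
  la <- paste(pw$subset_a, pw$tissue_a, sep = ".")
  lb <- paste(pw$subset_b, pw$tissue_b, sep = ".")
  for (k in seq_len(nrow(pw))) {
    m[la[k], lb[k]] <- m[lb[k], la[k]] <- pw$cosine_mean[k]
  }
  if (!anyNA(m)) {
    attr(m, "hclust_order") <- hclust(as.dist(1 - m),
                                      method = "complete")$order
  }
  m
}

classify_pair_design <- function(subset_a, tissue_a, subset_b, tissue_b) {
  dplyr::case_when(
    subset_a == subset_b & tissue_a != tissue_b ~ "same_subset_between_sites",
    subset_a != subset_b & tissue_a == tissue_b ~ "cross_subset_within_site",
    subset_a != subset_b & tissue_a != tissue_b ~ "cross_subset_between_sites",
    TRUE ~ NA_character_
  )
}

#' Compile group-level overlap summaries across donors
#'
#' Classifies every sample pair as same-subset-between-sites (labelled by
#' the subset), cross-subset-within-site, or cross-subset-between-sites
#' (labelled by the subset pair), then reports the mean and SEM per
#' lineage and group. Optionally the values are normalized for
#' between-subject variability first (within-donor centering with
#' grand-mean restoration, per lineage); the raw mean is then reported
#' alongside.
#'
#' @param pairwise Output of [pairwise_overlap()].
#' @param normalize Apply the within-donor normalization before SEM.
#' @param pool_level `"pair"` pools all pairs across donors; `"donor"`
#'   first averages within donor, then across donors.
#' @return Tibble `lineage`, `design`, `label`, `mean`, `sem`, `n` (and
#'   `mean_raw` when `normalize = TRUE`). Groups with a single value get
#'   `sem = NA`.
#' @export
compile_group_overlap <- function(pairwise, normalize = FALSE,
                                  pool_level = c("pair", "donor")) {
  pool_level <- match.arg(pool_level)
  pw <- pairwise |>
    dplyr::mutate(
      design = classify_pair_design(.data$subset_a, .data$tissue_a,
                                    .data$subset_b, .data$tissue_b),
      label = dplyr::if_else(
        .data$subset_a == .data$subset_b, .data$subset_a,
        paste(pmin(.data$subset_a, .data$subset_b),
              pmax(.data$subset_a, .data$subset_b), sep = "-"))
    ) |>
    dplyr::filter(!is.na(.data$design))
  pw$value <- pw$cosine_mean
  if (normalize) {
    pw <- pw |>
      dplyr::group_by(.data$lineage) |>
      dplyr::mutate(grand = mean(.data$value)) |>
      dplyr::group_by(.data$lineage, .data$donor_id) |>
      dplyr::mutate(value = .data$value - mean(.data$value) +
                      .data$grand[1]) |>
      dplyr::ungroup()
  }
  if (pool_level == "donor") {
    pw <- pw |>
      dplyr::group_by(.data$lineage, .data$design, .data$label,
                      .data$donor_id) |>
      dplyr::summarise(value = mean(.data$value),
                       cosine_mean = mean(.data$cosine_mean),
                       .groups = "drop")
  }
  pw |>
    dplyr::group_by(.data$lineage, .data$design, .data$label) |>
    dplyr::summarise(
      mean = mean(.data$value),
      mean_raw = mean(.data$cosine_mean),
      sem = if (dplyr::n() > 1) sd(.data$value) / sqrt(dplyr::n())
            else NA_real_,
      n = dplyr::n(), .groups = "drop"
    ) |>
    (\(d) if (normalize) d else dplyr::select(d, -"mean_raw"))()
}
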