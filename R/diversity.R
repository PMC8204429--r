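#' Clonality of a set of clone copy counts
#'
#' Clonality is one minus the Shannon entropy of the clone frequency
#' distribution normalized by its maximum, `log2(L)` for `L` unique
#' clones: 0 for a uniform (maximally diverse) repertoire, 1 for a
#' monoclonal one. A monoclonal sample (`L = 1`) makes the ratio 0/0 and
#' is defined as clonality 1.
#'
#' @param counts Positive copy counts, one per clone.
#' @return List with `clonality`, `entropy_bits` and `n_clones`.
#' @export
clonality <- function(counts) {
  counts <- as.numeric(counts)
  if (length(counts) == 0) abort("no clones")
  if (any(!is.finite(counts)) || any(counts <= 0)) {
    abort("counts must be positive and finite")
  }
  p <- counts / sum(counts)
  h <- -sum(p * log2(p))
  L <- length(counts)
  cl <- if (L == 1) 1 else 1 - h / log2(L)
  list(clonality = min(max(cl, 0), 1), entropy_bits = h, n_clones = L)
}

#' Per-sample clonality
#'
#' @param clones Clone table (multi-sample).
#' @return Tibble with one row per sample: `sample_id`, `n_clones`,
#'   `entropy_bits`, `clonality`.
#' @export
sample_clonality <- function(clones) {
  check_clone_table(clones)
  clones |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(
      n_clones = dplyr::n(),
      entropy_bits = clonality(.data$copies)$entropy_bits,
      clonality = clonality(.data$copies)$clonality,
      .groups = "drop"
    )
}

band_labels <- function(edges) {
  edges <- sort(unique(as.integer(edges)))
  lo <- c(1L, edges + 1L)
  hi <- c(edges, NA)
  ifelse(is.na(hi), paste0(">", edges[length(edges)]),
         ifelse(lo == 1L, paste0("top ", hi), paste0(lo, "-", hi)))
}

#' Fraction of copies held by rank bands of clones
#'
#' Clones are ranked by descending copy count (ties broken by CDR3 then
#' V/J for reproducibility) and the copy mass falling in each rank band
#' is reported, e.g. the default bands top 10 / 11-100 / 101-1000 / >1000.
#'
#' @param counts Copy counts.
#' @param edges Upper rank edges of the bands.
#' @param tiebreak Optional character vector (e.g. CDR3 sequences) used to
#'   order tied counts deterministically.
#' @return Tibble `band` (ordered factor), `fraction`; fractions sum to 1.
#' @export
top_n_fraction <- function(counts, edges = c(10, 100, 1000),
                           tiebreak = NULL) {
  if (length(counts) == 0) abort("no clones")
  edges <- sort(unique(as.integer(edges)))
  ord <- if (is.null(tiebreak)) order(-counts) else order(-counts, tiebreak)
  counts <- counts[ord]
  labs <- band_labels(edges)
  band <- cut(seq_along(counts), breaks = c(0, edges, Inf), labels = labs)
  fr <- tapply(counts, band, sum, default = 0) / sum(counts)
  tibble::tibble(band = factor(labs, levels = labs),
                 fraction = as.numeric(fr[labs]))
}

#' Per-sample clonal-expansion summary
#'
#' @param clones Clone table (multi-sample).
#' @param edges Rank band edges, see [top_n_fraction()].
#' @return Tibble `sample_id`, `band`, `fraction`.
#' @export
top_clone_proportions <- function(clones, edges = c(10, 100, 1000)) {
  check_clone_table(clones)
  clones |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::reframe(top_n_fraction(.data$copies, edges,
                                  tiebreak = .data$cdr3_aa))
}

#' Regression of clonality on donor age
#'
#' Fits an ordinary least-squares regression of clonality on age within
#' each lineage-by-subset group, pooling tissue sites, and reports the
#' slope with a two-sided p-value for slope = 0. Groups with fewer than
#' `min_n` samples or no age variation are skipped with a warning.
#'
#' @param clonality_df Output of [sample_clonality()].
#' @param samples Sample sheet with `sample_id`, `age`, `lineage`,
#'   `subset`.
#' @param min_n Minimum samples per group (default 3).
#' @return Tibble with one row per lineage-subset group: `slope`,
#'   `intercept`, `slope_se`, `p_value`, `n`.
#' @export
clonality_age_regression <- function(clonality_df, samples, min_n = 3) {
  df <- dplyr::inner_join(
    clonality_df,
    samples[, c("sample_id", "age", "lineage", "subset")],
    by = "sample_id"
  )
  fit_one <- function(d) {
    if (nrow(d) < min_n || length(unique(d$age)) < 2) {
      warn(sprintf("skipping group %s %s: too few samples or constant age",
                   d$lineage[1], d$subset[1]))
      return(NULL)
    }
    fit <- lm(clonality ~ age, data = d)
    sm <- summary(fit)
    cf <- sm$coefficients
    slope <- cf["age", "Estimate"]
    p <- cf["age", "Pr(>|t|)"]
    # (near-)zero residual variance, e.g. constant clonality: the t ratio
    # is numerical noise, so report the degenerate fit honestly
    if (!is.finite(p) || sm$sigma < 1e-10 * max(1, abs(mean(d$clonality)))) {
      p <- if (abs(slope) < 1e-10) 1 else 0
    }
    tibble::tibble(
      lineage = d$lineage[1], subset = d$subset[1],
      slope = slope, intercept = cf["(Intercept)", "Estimate"],
      slope_se = cf["age", "Std. Error"], p_value = p,
      n = nrow(d)
    )
  }
  df |>
    dplyr::group_split(.data$lineage, .data$subset) |>
    purrr::map(fit_one) |>
    purrr::compact() |>
    dplyr::bind_rows()
}
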