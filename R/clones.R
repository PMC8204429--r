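#' Remove non-productive rearrangements
#'
#' @param records Rearrangement tibble with a logical `productive` column.
#' @return Records with only productive rows; the number removed is
#'   attached as attribute `n_removed`.
#' @export
remove_nonproductive <- function(records) {
  if (!"productive" %in% names(records)) {
    abort("`records` has no `productive` column")
  }
  keep <- records$productive %in% TRUE
  n_removed <- sum(!keep)
  out <- records[keep, , drop = FALSE]
  if (nrow(out) == 0 && n_removed > 0) {
    warn("all records were non-productive; returning an empty table")
  }
  attr(out, "n_removed") <- n_removed
  out
}

#' Collapse rearrangements into clones
#'
#' A clone is the set of sequences sharing the same TRBV gene, TRBJ gene
#' and CDR3 amino-acid sequence. Copy counts are summed within each clone
#' and clones detected fewer than `min_copies` times are discarded — the
#' default of 2 suppresses spurious clones created by sequencing error.
#' Frequencies are computed over the retained copies of each sample.
#'
#' @param records Rearrangement tibble (one or more samples; a
#'   `sample_id` column splits the table, otherwise all records are
#'   treated as one sample called `"sample"`).
#' @param min_copies Minimum total copies for a clone to be kept.
#' @param productive_only Drop non-productive records before grouping.
#' @return A clone table: `sample_id`, `v_call`, `j_call`, `cdr3_aa`,
#'   `copies`, `frequency`, ordered by descending copies within sample.
#' @export
assemble_clones <- function(records, min_copies = 2, productive_only = TRUE) {
  if (min_copies < 1) abort("min_copies must be >= 1")
  if (nrow(records) == 0) return(empty_clone_table())
  if (!"sample_id" %in% names(records)) records$sample_id <- "sample"
  if (productive_only) {
    records <- suppressWarnings(remove_nonproductive(records))
  }
  if (nrow(records) == 0) return(empty_clone_table())
  out <- records |>
    dplyr::group_by(.data$sample_id, .data$v_call, .data$j_call,
                    .data$cdr3_aa) |>
    dplyr::summarise(copies = as.integer(sum(.data$duplicate_count)),
                     .groups = "drop") |>
    dplyr::filter(.data$copies >= min_copies)
  if (nrow(out) == 0) {
    warn("all clones fell below min_copies; returning an empty table")
    return(empty_clone_table())
  }
  out |>
    renormalize() |>
    dplyr::arrange(.data$sample_id, dplyr::desc(.data$copies),
                   .data$v_call, .data$j_call, .data$cdr3_aa)
}

#' Copy-number cutoff filter
#'
#' Removes, per sample, clones whose copy number is strictly below
#' `fraction` of the sample's mean copy number (total copies divided by
#' the number of unique clones). The threshold is computed once on the
#' input table — it is not recomputed after removal — and ties at exactly
#' the threshold survive. Frequencies are renormalized over survivors.
#'
#' @param clones Clone table.
#' @param fraction Fraction of the mean copy number used as threshold
#'   (default 0.5, i.e. a 50%-of-mean cutoff).
#' @return Filtered, renormalized clone table.
#' @export
copy_cutoff_filter <- function(clones, fraction = 0.5) {
  check_clone_table(clones)
  if (fraction <= 0 || fraction > 1) abort("fraction must be in (0, 1]")
  if (nrow(clones) == 0) return(clones)
  clones |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::filter(.data$copies >= fraction * mean(.data$copies)) |>
    dplyr::ungroup() |>
    renormalize()
}
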