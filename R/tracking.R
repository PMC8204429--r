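#' Top clones of a donor and lineage
#'
#' Ranks clones by total copies summed over all of the donor's samples
#' (subsets, tissues and replicates) for one lineage, with deterministic
#' tie-breaking by clone key.
#'
#' @param clones Clone table (multi-sample).
#' @param samples Sample sheet.
#' @param donor,lineage Donor id and lineage to rank.
#' @param n Number of clones to return (default 500; all if fewer).
#' @return Tibble `v_call`, `j_call`, `cdr3_aa`, `total_copies`, ranked.
#' @export
top_clones <- function(clones, samples, donor, lineage, n = 500) {
  check_clone_table(clones)
  ids <- samples$sample_id[samples$donor_id == donor &
                           samples$lineage == lineage]
  clones |>
    dplyr::filter(.data$sample_id %in% ids) |>
    dplyr::group_by(.data$v_call, .data$j_call, .data$cdr3_aa) |>
    dplyr::summarise(total_copies = sum(.data$copies), .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$total_copies), .data$v_call,
                   .data$j_call, .data$cdr3_aa) |>
    head(n)
}

#' Track one clone across tissue sites and subsets
#'
#' Aggregates a clone's copies per tissue site (summing subsets and,
#' by default, replicates) and reports the fraction of each site's copies
#' contributed by each memory subset — the data behind line-circle
#' clone-tracking plots. Copies are also expressed relative to the
#' site's total repertoire size so circle areas can be scaled either way.
#'
#' @param clones Clone table (multi-sample).
#' @param samples Sample sheet.
#' @param donor,lineage Donor id and lineage.
#' @param v_call,j_call,cdr3_aa The clone key.
#' @param replicates `"sum"` pools replicates (default); `"first"`
#'   restricts to replicate 1.
#' @return Tibble `tissue`, `subset`, `copies`, `site_copies`,
#'   `subset_fraction`, `site_total_copies`, `repertoire_fraction`. Empty
#'   (with a message) when the clone is absent from the donor.
#' @export
track_clone <- function(clones, samples, donor, lineage,
                        v_call, j_call, cdr3_aa,
                        replicates = c("sum", "first")) {
  replicates <- match.arg(replicates)
  check_clone_table(clones)
  meta <- samples[samples$donor_id == donor & samples$lineage == lineage, ]
  if (replicates == "first") meta <- meta[meta$replicate == 1, ]
  df <- clones |>
    dplyr::inner_join(meta[, c("sample_id", "tissue", "subset")],
                      by = "sample_id")
  site_totals <- df |>
    dplyr::group_by(.data$tissue) |>
    dplyr::summarise(site_total_copies = sum(.data$copies),
                     .groups = "drop")
  hit <- df[df$v_call == v_call & df$j_call == j_call &
            df$cdr3_aa == cdr3_aa, ]
  if (nrow(hit) == 0) {
    message(sprintf("clone %s absent from donor %s (%s)",
                    clone_key(v_call, j_call, cdr3_aa), donor, lineage))
    return(tibble::tibble(
      tissue = character(), subset = character(), copies = integer(),
      site_copies = integer(), subset_fraction = double(),
      site_total_copies = integer(), repertoire_fraction = double()))
  }
  hit |>
    dplyr::group_by(.data$tissue, .data$subset) |>
    dplyr::summarise(copies = sum(.data$copies), .groups = "drop") |>
    dplyr::group_by(.data$tissue) |>
    dplyr::mutate(site_copies = sum(.data$copies),
                  subset_fraction = .data$copies / .data$site_copies) |>
    dplyr::ungroup() |>
    dplyr::left_join(site_totals, by = "tissue") |>
    dplyr::mutate(repertoire_fraction = .data$site_copies /
                    .data$site_total_copies) |>
    dplyr::arrange(.data$tissue, .data$subset)
}

#' Track the top clones of a donor and lineage
#'
#' Convenience wrapper combining [top_clones()] and [track_clone()] into
#' one long table for plotting layers.
#'
#' @inheritParams track_clone
#' @param n Number of top clones to track.
#' @return Long tibble with a `clone` key column followed by the
#'   [track_clone()] columns.
#' @export
track_top_clones <- function(clones, samples, donor, lineage, n = 500,
                             replicates = c("sum", "first")) {
  replicates <- match.arg(replicates)
  top <- top_clones(clones, samples, donor, lineage, n)
  purrr::pmap(top[, c("v_call", "j_call", "cdr3_aa")], function(...) {
    key <- list(...)
    tr <- track_clone(clones, samples, donor, lineage,
                      key$v_call, key$j_call, key$cdr3_aa,
                      replicates = replicates)
    tr$clone <- clone_key(key$v_call, key$j_call, key$cdr3_aa)
    dplyr::relocate(tr, "clone")
  }) |>
    dplyr::bind_rows()
}
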