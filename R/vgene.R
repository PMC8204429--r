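#' TRBV usage of a clone table
#'
#' Counts each unique clone once and reports, per sample, the percentage
#' of clones carrying each TRBV gene. By default the 50%-of-mean copy
#' cutoff ([copy_cutoff_filter()]) is applied first so that low-copy
#' clones do not dominate the gene counts.
#'
#' @param clones Clone table (multi-sample).
#' @param apply_cutoff Apply [copy_cutoff_filter()] before counting.
#' @param fraction Cutoff fraction passed to [copy_cutoff_filter()].
#' @return Tibble `sample_id`, `v_call`, `n_clones`, `percent`; percents
#'   sum to 100 within a sample.
#' @export
trbv_usage <- function(clones, apply_cutoff = TRUE, fraction = 0.5) {
  check_clone_table(clones)
  if (nrow(clones) == 0) {
    warn("empty clone table; returning empty usage")
    return(tibble::tibble(sample_id = character(), v_call = character(),
                          n_clones = integer(), percent = double()))
  }
  if (apply_cutoff) clones <- copy_cutoff_filter(clones, fraction)
  clones |>
    dplyr::count(.data$sample_id, .data$v_call, name = "n_clones") |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::mutate(percent = 100 * .data$n_clones / sum(.data$n_clones)) |>
    dplyr::ungroup()
}

#' Genes-by-samples usage matrix
#'
#' Builds the TRBV usage matrix underlying heatmaps and PCA: rows are
#' genes (the union over samples, absent genes at 0%), columns are
#' samples. With `scale = TRUE` each gene row is standardized across
#' samples to a z-score (sample SD, n-1 convention); zero-variance rows
#' map to 0 rather than NaN.
#'
#' @param usage Long usage tibble from [trbv_usage()].
#' @param scale Standardize each gene across samples.
#' @return Numeric matrix genes x samples.
#' @export
usage_matrix <- function(usage, scale = FALSE) {
  wide <- usage |>
    dplyr::select("sample_id", "v_call", "percent") |>
    tidyr::pivot_wider(names_from = "sample_id", values_from = "percent",
                       values_fill = 0)
  m <- as.matrix(wide[, -1, drop = FALSE])
  rownames(m) <- wide$v_call
  m <- m[order(rownames(m)), , drop = FALSE]
  if (scale) {
    mu <- rowMeans(m)
    s <- apply(m, 1, sd)
    m <- (m - mu) / ifelse(s > 0, s, 1)  # zero-variance rows become 0
  }
  m
}

#' Compare per-gene TRBV usage between CD4 and CD8 lineages
#'
#' For each gene, compares usage percentages between the two lineages
#' with a two-sided Student's t test (Welch by option). Samples missing a
#' gene contribute 0%. Raw p-values are reported; an adjusted column is
#' available via `p_adjust_method`.
#'
#' @param usage Long usage tibble from [trbv_usage()].
#' @param samples Sample sheet with `sample_id` and `lineage`.
#' @param p_adjust_method Method for [stats::p.adjust()] (default "none",
#'   matching raw-star reporting; "BH" recommended for screening).
#' @param welch Use Welch's unequal-variance t test.
#' @param min_per_group Minimum samples per lineage (default 2); genes
#'   observed in fewer are skipped.
#' @return Tibble per gene: lineage means and SEs, `n_cd4`, `n_cd8`,
#'   `p_value`, `p_adjusted`.
#' @export
lineage_usage_comparison <- function(usage, samples,
                                     p_adjust_method = "none",
                                     welch = FALSE, min_per_group = 2) {
  df <- usage |>
    dplyr::select("sample_id", "v_call", "percent") |>
    tidyr::complete(.data$sample_id, .data$v_call,
                    fill = list(percent = 0)) |>
    dplyr::inner_join(samples[, c("sample_id", "lineage")], by = "sample_id")
  sem <- function(x) sd(x) / sqrt(length(x))
  res <- df |>
    dplyr::group_split(.data$v_call) |>
    purrr::map(function(d) {
      a <- d$percent[d$lineage == "CD4"]
      b <- d$percent[d$lineage == "CD8"]
      if (length(a) < min_per_group || length(b) < min_per_group) {
        return(NULL)
      }
      p <- tryCatch(
        t.test(a, b, var.equal = !welch)$p.value,
        error = function(e) NA_real_  # zero variance in both groups
      )
      tibble::tibble(
        v_call = d$v_call[1],
        mean_cd4 = mean(a), se_cd4 = sem(a), n_cd4 = length(a),
        mean_cd8 = mean(b), se_cd8 = sem(b), n_cd8 = length(b),
        p_value = p
      )
    }) |>
    purrr::compact() |>
    dplyr::bind_rows()
  if (nrow(res) == 0) {
    return(tibble::tibble(
      v_call = character(), mean_cd4 = double(), se_cd4 = double(),
      n_cd4 = integer(), mean_cd8 = double(), se_cd8 = double(),
      n_cd8 = integer(), p_value = double(), p_adjusted = double()))
  }
  res$p_adjusted <- p.adjust(res$p_value, method = p_adjust_method)
  res
}
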