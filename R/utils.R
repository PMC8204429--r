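#' Build the clone key used throughout the package
#'
#' Clones are defined by identical TRBV gene, TRBJ gene and CDR3 amino-acid
#' sequence; the key is their concatenation and is used for frequency
#' vectors, overlap removal and tracking.
#'
#' @param v_call,j_call,cdr3_aa Character vectors of equal length.
#' @return Character vector of keys.
#' @export
clone_key <- function(v_call, j_call, cdr3_aa) {
  paste(v_call, j_call, cdr3_aa, sep = "|")
}

#' Normalize a V/J gene call
#'
#' Keeps the first gene of a comma-separated ambiguous call and, at gene
#' granularity, strips the IMGT allele suffix (`*NN`).
#'
#' @param x Character vector of gene calls.
#' @param granularity `"gene"` (default) strips allele suffixes;
#'   `"allele"` keeps them.
#' @return Normalized character vector.
#' @export
normalize_gene_call <- function(x, granularity = c("gene", "allele")) {
  granularity <- match.arg(granularity)
  x <- trimws(sub(",.*$", "", x))
  if (granularity == "gene") x <- sub("\\*.*$", "", x)
  x
}

## columns every clone table carries
.clone_cols <- c("sample_id", "v_call", "j_call", "cdr3_aa",
                 "copies", "frequency")

empty_clone_table <- function() {
  tibble::tibble(
    sample_id = character(), v_call = character(), j_call = character(),
    cdr3_aa = character(), copies = integer(), frequency = double()
  )
}

check_clone_table <- function(clones, arg = "clones") {
  missing <- setdiff(.clone_cols, names(clones))
  if (length(missing) > 0) {
    abort(sprintf("`%s` is missing clone-table column(s): %s",
                  arg, paste(missing, collapse = ", ")))
  }
  invisible(clones)
}

## frequency renormalization within sample
renormalize <- function(clones) {
  dplyr::mutate(
    dplyr::group_by(clones, .data$sample_id),
    frequency = .data$copies / sum(.data$copies)
  ) |> dplyr::ungroup()
}
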