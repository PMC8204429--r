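#' Default AIRR column dialect
#'
#' Maps the fields the package needs onto candidate column names in a
#' rearrangement TSV. The defaults cover the AIRR standard names
#' (`junction_aa`) plus common ImmuneDB-flavoured exports (`cdr3_aa`,
#' `copy_number`). Supply a modified list to [read_rearrangements()] for
#' other dialects.
#'
#' @return Named list mapping field -> candidate column names (first match
#'   wins).
#' @export
airr_dialect <- function() {
  list(
    sequence_id     = c("sequence_id", "seq_id"),
    v_call          = c("v_call", "v_gene"),
    j_call          = c("j_call", "j_gene"),
    cdr3_aa         = c("junction_aa", "cdr3_aa"),
    productive      = c("productive", "functional"),
    duplicate_count = c("duplicate_count", "copy_number", "copies")
  )
}

parse_productive <- function(x) {
  lx <- tolower(trimws(as.character(x)))
  out <- rep(NA, length(x))
  out[lx %in% c("t", "true", "1", "yes", "y")] <- TRUE
  out[lx %in% c("f", "false", "0", "no", "n")] <- FALSE
  out
}

#' Read an AIRR rearrangement table
#'
#' Reads a tab-separated rearrangement file, resolves columns through a
#' dialect table, normalizes gene calls (first gene of an ambiguous call;
#' allele suffix stripped at gene granularity) and parses copy counts.
#' Rows with an unparseable copy count or productivity flag are skipped
#' with a warning; the skip count is attached as attribute `n_skipped` so
#' that rows in = records out + skips.
#'
#' @param path Path to a rearrangement TSV.
#' @param dialect Column-name mapping, see [airr_dialect()].
#' @param granularity Gene-call granularity, `"gene"` or `"allele"`.
#' @return A tibble with columns `sequence_id`, `v_call`, `j_call`,
#'   `cdr3_aa`, `productive`, `duplicate_count` (plus `sample_id` if the
#'   file carries one), with attribute `n_skipped`.
#' @export
read_rearrangements <- function(path, dialect = airr_dialect(),
                                granularity = c("gene", "allele")) {
  granularity <- match.arg(granularity)
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  resolve <- function(field, required = TRUE) {
    hit <- intersect(dialect[[field]], names(raw))
    if (length(hit) == 0) {
      if (required) {
        abort(sprintf(
          "mandatory column for field '%s' not found (looked for: %s)",
          field, paste(dialect[[field]], collapse = ", ")))
      }
      return(NULL)
    }
    hit[[1]]
  }
  for (f in c("v_call", "j_call", "cdr3_aa", "productive",
              "duplicate_count")) resolve(f)
  if (nrow(raw) == 0) {
    warn(sprintf("no data rows in %s", path))
    out <- tibble::tibble(
      sequence_id = character(), v_call = character(),
      j_call = character(), cdr3_aa = character(),
      productive = logical(), duplicate_count = integer()
    )
    attr(out, "n_skipped") <- 0L
    return(out)
  }
  seq_col <- resolve("sequence_id", required = FALSE)
  out <- tibble::tibble(
    sequence_id = if (is.null(seq_col)) sprintf("row%06d", seq_len(nrow(raw)))
                  else raw[[seq_col]],
    v_call = normalize_gene_call(raw[[resolve("v_call")]], granularity),
    j_call = normalize_gene_call(raw[[resolve("j_call")]], granularity),
    cdr3_aa = toupper(trimws(dplyr::coalesce(raw[[resolve("cdr3_aa")]], ""))),
    productive = parse_productive(raw[[resolve("productive")]]),
    duplicate_count = suppressWarnings(
      as.integer(raw[[resolve("duplicate_count")]]))
  )
  if ("sample_id" %in% names(raw)) out$sample_id <- raw[["sample_id"]]
  bad <- is.na(out$duplicate_count) | out$duplicate_count < 1L |
    is.na(out$productive) | is.na(out$v_call) | out$v_call == ""
  if (any(bad)) {
    warn(sprintf("skipped %d unparseable row(s) in %s", sum(bad), path))
    out <- out[!bad, , drop = FALSE]
  }
  attr(out, "n_skipped") <- sum(bad)
  out
}

#' Read and validate a sample sheet
#'
#' The sample sheet assigns each sequencing library its coordinates:
#' donor, age, lineage (CD4/CD8), memory subset (TCM/TEM/TRM/TEMRA),
#' tissue and replicate. Coordinates must be unique; unknown lineage or
#' subset tokens are hard errors. The lineage-subset combinations that are
#' not sorted in practice (CD4 TEMRA, CD8 TCM) raise a warning only.
#'
#' @param path Path to a TSV (or CSV, by extension) sample sheet with
#'   columns `donor_id`, `age`, `lineage`, `subset`, `tissue`,
#'   `replicate`; `sample_id` is constructed when absent.
#' @return A validated tibble of sample metadata.
#' @export
read_sample_sheet <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  reader <- if (grepl("\\.csv$", path, ignore.case = TRUE))
    readr::read_csv else readr::read_tsv
  raw <- reader(path, col_types = readr::cols(.default = "c"),
                progress = FALSE)
  validate_sample_sheet(raw)
}

#' Validate sample metadata
#'
#' @param sheet Data frame of sample metadata (see [read_sample_sheet()]).
#' @return A validated tibble with typed columns.
#' @export
validate_sample_sheet <- function(sheet) {
  required <- c("donor_id", "age", "lineage", "subset", "tissue", "replicate")
  missing <- setdiff(required, names(sheet))
  if (length(missing) > 0) {
    abort(sprintf("sample sheet is missing column(s): %s",
                  paste(missing, collapse = ", ")))
  }
  out <- tibble::tibble(
    donor_id = as.character(sheet$donor_id),
    age = suppressWarnings(as.integer(sheet$age)),
    lineage = as.character(sheet$lineage),
    subset = as.character(sheet$subset),
    tissue = as.character(sheet$tissue),
    replicate = suppressWarnings(as.integer(sheet$replicate))
  )
  if (any(!out$lineage %in% .lineages)) {
    abort(sprintf("unknown lineage token(s): %s (accepted: %s)",
                  paste(unique(setdiff(out$lineage, .lineages)), collapse = ", "),
                  paste(.lineages, collapse = ", ")))
  }
  if (any(!out$subset %in% .subsets)) {
    abort(sprintf("unknown subset token(s): %s (accepted: %s)",
                  paste(unique(setdiff(out$subset, .subsets)), collapse = ", "),
                  paste(.subsets, collapse = ", ")))
  }
  if (any(is.na(out$tissue) | out$tissue == "")) abort("empty tissue label")
  if (any(is.na(out$replicate) | out$replicate < 1L)) {
    abort("replicate must be an integer >= 1")
  }
  if (any(is.na(out$age))) abort("age must be an integer")
  key <- paste(out$donor_id, out$lineage, out$subset, out$tissue,
               out$replicate)
  if (anyDuplicated(key) > 0) {
    abort(sprintf("duplicate sample coordinates: %s",
                  paste(unique(key[duplicated(key)]), collapse = "; ")))
  }
  odd <- (out$lineage == "CD4" & out$subset == "TEMRA") |
         (out$lineage == "CD8" & out$subset == "TCM")
  if (any(odd)) {
    warn(sprintf("%d sample(s) carry a lineage-subset combination not sorted in practice (CD4 TEMRA / CD8 TCM)",
                 sum(odd)))
  }
  out$sample_id <- if ("sample_id" %in% names(sheet)) {
    as.character(sheet$sample_id)
  } else {
    paste(out$donor_id, out$lineage, out$subset, out$tissue,
          out$replicate, sep = "_")
  }
  if (anyDuplicated(out$sample_id) > 0) abort("duplicate sample_id values")
  dplyr::relocate(out, "sample_id")
}

#' Write a clone table to TSV
#'
#' @param clones Clone table (see [assemble_clones()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @seealso [read_clone_table()] for the lossless inverse.
#' @export
write_clone_table <- function(clones, path) {
  check_clone_table(clones)
  readr::write_tsv(clones[, .clone_cols], path, progress = FALSE)
  invisible(path)
}

#' Read a clone table written by [write_clone_table()]
#'
#' @param path Path to the TSV.
#' @return Clone table tibble.
#' @export
read_clone_table <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  readr::read_tsv(
    path, progress = FALSE,
    col_types = readr::cols(
      sample_id = "c", v_call = "c", j_call = "c", cdr3_aa = "c",
      copies = "i", frequency = "d"
    )
  )
}
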