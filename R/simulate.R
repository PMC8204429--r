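#' Configuration for the synthetic cohort generator
#'
#' Defines a multi-donor, multi-tissue, multi-subset TCR-beta cohort.
#' Defaults describe three deeply sampled organ donors with five sites
#' (blood, bone marrow, spleen, lung-draining lymph node, lung), the six
#' sorted lineage-subset combinations (CD4: TCM/TEM/TRM; CD8:
#' TEM/TRM/TEMRA) and two sequencing replicates per sample drawn from a
#' common cell pool.
#'
#' Clone sizes per subset follow a geometric "head" of expanded clones
#' holding `head_mass` of the repertoire plus a uniform diverse tail;
#' the defaults produce the clonality ordering TEMRA > TEM ~ TRM > TCM.
#' `share` is the per-subset probability that a clone is also present in
#' each non-home tissue, highest for circulating TEMRA/TEM and low for
#' resident TRM and TCM. CDR3 sequences carry donor- and lineage-level
#' amino-acid composition biases and a per-lineage-tissue 3-letter motif
#' applied with probability `imprint_strength`, giving the sequence
#' analyses a known donor > lineage > tissue signal; one shared length
#' distribution is used throughout so distances are never length
#' artifacts. A per-read error process emits corrupted singletons at
#' `error_rate`.
#'
#' @param donors Tibble with `donor_id` and `age` (years).
#' @param tissues Character vector of tissue site labels.
#' @param replicates Sequencing replicates per sample.
#' @param depth Cells sampled per library.
#' @param subsets Tibble with per-subset `q` (geometric decay of the
#'   expanded head), `head_mass`, `share`, `n_head`, `n_tail`.
#' @param cross_subset_rate Probability an expanded clone also appears in
#'   a sibling subset (at `cross_subset_scale` times its weight).
#' @param cross_subset_scale See `cross_subset_rate`.
#' @param error_rate Per-read probability of a corrupted singleton.
#' @param nonproductive_rate Fraction of non-productive clones.
#' @param imprint_strength Probability a clone carries its home tissue's
#'   CDR3 motif (0 disables tissue imprinting).
#' @param donor_alpha_weight,lineage_alpha_weight Mixture weights of the
#'   donor-/lineage-preferred amino-acid alphabets in CDR3 generation.
#' @param cdr3_lengths,cdr3_length_probs Shared CDR3 length distribution.
#' @param usage_noise_sd Log-normal SD of per-donor TRBV usage noise.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(
    donors = tibble::tibble(donor_id = c("S324", "S383", "S466"),
                            age = c(33L, 48L, 61L)),
    tissues = .default_tissues,
    replicates = 2L,
    depth = 5000L,
    subsets = tibble::tibble(
      subset    = c("TCM", "TEM", "TRM", "TEMRA"),
      q         = c(0.010, 0.030, 0.030, 0.080),
      head_mass = c(0.25, 0.65, 0.60, 0.90),
      share     = c(0.08, 0.45, 0.15, 0.70),
      n_head    = c(200L, 200L, 200L, 200L),
      n_tail    = c(8000L, 2500L, 4000L, 1200L)
    ),
    cross_subset_rate = 0.2,
    cross_subset_scale = 0.3,
    error_rate = 0.005,
    nonproductive_rate = 0.04,
    imprint_strength = 0.6,
    donor_alpha_weight = 0.25,
    lineage_alpha_weight = 0.2,
    cdr3_lengths = 11:17,
    cdr3_length_probs = c(0.05, 0.125, 0.2, 0.25, 0.2, 0.125, 0.05),
    usage_noise_sd = 0.2) {
  cfg <- list(
    donors = donors, tissues = tissues, replicates = as.integer(replicates),
    depth = as.integer(depth), subsets = subsets,
    cross_subset_rate = cross_subset_rate,
    cross_subset_scale = cross_subset_scale,
    error_rate = error_rate, nonproductive_rate = nonproductive_rate,
    imprint_strength = imprint_strength,
    donor_alpha_weight = donor_alpha_weight,
    lineage_alpha_weight = lineage_alpha_weight,
    cdr3_lengths = as.integer(cdr3_lengths),
    cdr3_length_probs = cdr3_length_probs / sum(cdr3_length_probs),
    usage_noise_sd = usage_noise_sd,
    v_genes = c("TRBV2", "TRBV4-1", "TRBV5-1", "TRBV6-1", "TRBV6-4",
                "TRBV7-2", "TRBV7-9", "TRBV9", "TRBV10-3", "TRBV11-2",
                "TRBV12-3", "TRBV18", "TRBV19", "TRBV20-1", "TRBV24-1",
                "TRBV25-1", "TRBV27", "TRBV28", "TRBV29-1", "TRBV30"),
    j_genes = c(paste0("TRBJ1-", 1:6), paste0("TRBJ2-", 1:7)),
    # genes preferentially used by each lineage (usage-bias analogue)
    lineage_boost = list(CD4 = c("TRBV5-1", "TRBV18", "TRBV6-4"),
                         CD8 = c("TRBV12-3", "TRBV27", "TRBV30")),
    boost_factor = 2.2
  )
  validate_cohort_config(cfg)
  cfg
}

validate_cohort_config <- function(cfg) {
  probs <- c(cfg$subsets$share, cfg$cross_subset_rate, cfg$error_rate,
             cfg$nonproductive_rate, cfg$imprint_strength,
             cfg$donor_alpha_weight, cfg$lineage_alpha_weight)
  if (any(probs < 0 | probs > 1)) abort("probabilities must be in [0, 1]")
  if (any(cfg$subsets$q <= 0 | cfg$subsets$q >= 1)) {
    abort("geometric decay q must be in (0, 1)")
  }
  if (any(cfg$subsets$n_head < 1 | cfg$subsets$n_tail < 1)) {
    abort("infeasible config: each subset needs head and tail clones")
  }
  if (nrow(cfg$donors) < 1 || cfg$depth < 1 || cfg$replicates < 1) {
    abort("infeasible config: need donors, depth >= 1, replicates >= 1")
  }
  if (length(cfg$cdr3_lengths) != length(cfg$cdr3_length_probs)) {
    abort("cdr3_lengths and cdr3_length_probs differ in length")
  }
  if (min(cfg$cdr3_lengths) < 4) abort("CDR3 lengths must be >= 4")
  invisible(cfg)
}

## random CDR3s: C + biased inner letters + F
gen_cdr3 <- function(lens, d_alpha, l_alpha, ad, al) {
  n <- length(lens)
  inner_len <- lens - 2L
  tot <- sum(inner_len)
  comp <- sample.int(3L, tot, replace = TRUE, prob = c(ad, al, 1 - ad - al))
  letters_out <- character(tot)
  letters_out[comp == 1L] <- sample(d_alpha, sum(comp == 1L), replace = TRUE)
  letters_out[comp == 2L] <- sample(l_alpha, sum(comp == 2L), replace = TRUE)
  letters_out[comp == 3L] <- sample(.aa20, sum(comp == 3L), replace = TRUE)
  inner <- vapply(split(letters_out, rep(seq_len(n), inner_len)),
                  paste0, character(1), collapse = "")
  paste0("C", inner, "F")
}

## one random substitution inside the CDR3 (error-read model)
perturb_cdr3 <- function(x) {
  vapply(x, function(s) {
    len <- nchar(s)
    pos <- sample(2:(len - 1), 1)
    old <- substr(s, pos, pos)
    new <- sample(setdiff(.aa20, old), 1)
    paste0(substr(s, 1, pos - 1), new, substr(s, pos + 1, len))
  }, character(1), USE.NAMES = FALSE)
}

#' Generate a synthetic multi-tissue TCR-beta cohort
#'
#' Simulates, deterministically for a given seed, AIRR-style
#' rearrangement records for every donor, lineage, subset, tissue and
#' replicate of the configuration, together with the ground truth needed
#' for parameter-recovery tests: the underlying clone universe with
#' per-tissue presence and true weights, per-sample true clonality, and
#' the keys of every injected error singleton.
#'
#' @param config A [cohort_config()].
#' @param seed Integer seed; identical seeds give identical cohorts.
#' @return A list of class `tcr_cohort`: `rearrangements` (records for
#'   all samples, with `sample_id`), `samples` (sheet), and `truth`
#'   (`sample_truth`, `universe`, `error_keys`, `motifs`, `config`,
#'   `seed`).
#' @export
simulate_cohort <- function(config = cohort_config(), seed = 1) {
  validate_cohort_config(config)
  withr::with_seed(as.integer(seed), simulate_cohort_impl(config, seed))
}

simulate_cohort_impl <- function(cfg, seed) {
  tissues <- cfg$tissues
  pres_cols <- paste0("in_", tissues)

  sheet <- purrr::map_dfr(seq_len(nrow(cfg$donors)), function(di) {
    purrr::map_dfr(.lineages, function(lin) {
      tidyr::expand_grid(
        donor_id = cfg$donors$donor_id[di], age = cfg$donors$age[di],
        lineage = lin, subset = .lineage_subsets[[lin]],
        tissue = tissues, replicate = seq_len(cfg$replicates)
      )
    })
  })
  sheet$sample_id <- paste(sheet$donor_id, sheet$lineage, sheet$subset,
                           sheet$tissue, sheet$replicate, sep = "_")
  sheet <- validate_sample_sheet(sheet)

  motifs <- tidyr::expand_grid(lineage = .lineages, tissue = tissues)
  motifs$motif <- vapply(seq_len(nrow(motifs)), function(i) {
    paste0(sample(.aa20, 3), collapse = "")
  }, character(1))

  donor_alpha <- lapply(setNames(cfg$donors$donor_id, cfg$donors$donor_id),
                        function(d) sample(.aa20, 5))

  base_w <- setNames(0.95^seq_along(cfg$v_genes), cfg$v_genes)

  universes <- list(); records <- list(); truths <- list(); errkeys <- list()

  for (di in seq_len(nrow(cfg$donors))) {
    donor <- cfg$donors$donor_id[di]
    for (lin in .lineages) {
      lin_alpha <- sample(.aa20, 5)
      w <- base_w
      w[cfg$lineage_boost[[lin]]] <- w[cfg$lineage_boost[[lin]]] *
        cfg$boost_factor
      w <- w * exp(rnorm(length(w), 0, cfg$usage_noise_sd))
      w <- w / sum(w)

      uni <- purrr::map_dfr(.lineage_subsets[[lin]], function(ss) {
        par <- cfg$subsets[cfg$subsets$subset == ss, ]
        n <- par$n_head + par$n_tail
        lens <- sample(cfg$cdr3_lengths, n, replace = TRUE,
                       prob = cfg$cdr3_length_probs)
        cdr3 <- gen_cdr3(lens, donor_alpha[[donor]], lin_alpha,
                         cfg$donor_alpha_weight, cfg$lineage_alpha_weight)
        home <- sample(tissues, n, replace = TRUE)
        imp <- runif(n) < cfg$imprint_strength & lens >= 9
        if (any(imp)) {
          mot <- motifs$motif[match(paste(lin, home), paste(motifs$lineage,
                                                            motifs$tissue))]
          imprinted <- cdr3[imp]
          substr(imprinted, 5, 7) <- mot[imp]
          cdr3[imp] <- imprinted
        }
        head_w <- (1 - par$q)^(seq_len(par$n_head) - 1)
        head_w <- par$head_mass * head_w / sum(head_w)
        u <- tibble::tibble(
          donor_id = donor, lineage = lin, subset = ss,
          v_call = sample(cfg$v_genes, n, replace = TRUE, prob = w),
          j_call = sample(cfg$j_genes, n, replace = TRUE),
          cdr3_aa = cdr3, home_tissue = home,
          is_head = c(rep(TRUE, par$n_head), rep(FALSE, par$n_tail)),
          productive = runif(n) >= cfg$nonproductive_rate,
          weight = c(head_w, rep((1 - par$head_mass) / par$n_tail,
                                 par$n_tail))
        )
        pres <- matrix(FALSE, n, length(tissues),
                       dimnames = list(NULL, pres_cols))
        for (t in seq_along(tissues)) {
          pres[, t] <- home == tissues[t] |
            runif(n) < par$share
        }
        dplyr::bind_cols(u, tibble::as_tibble(pres))
      })

      # expanded clones occasionally seen in a sibling subset too
      sibs <- .lineage_subsets[[lin]]
      extra <- uni |>
        dplyr::filter(.data$is_head) |>
        dplyr::filter(runif(dplyr::n()) < cfg$cross_subset_rate)
      if (nrow(extra) > 0) {
        extra$subset <- vapply(extra$subset, function(s) {
          sample(setdiff(sibs, s), 1)
        }, character(1))
        extra$weight <- extra$weight * cfg$cross_subset_scale
        uni <- dplyr::bind_rows(uni, extra)
      }
      universes[[paste(donor, lin)]] <- uni

      for (ss in .lineage_subsets[[lin]]) {
        for (tis in tissues) {
          pool <- uni[uni$subset == ss & uni[[paste0("in_", tis)]] &
                        uni$weight > 0, ]
          if (nrow(pool) == 0) abort("infeasible config: empty clone pool")
          freq <- pool$weight / sum(pool$weight)
          prod_freq <- freq[pool$productive]
          truth_cl <- clonality(prod_freq / sum(prod_freq))
          for (rep_i in seq_len(cfg$replicates)) {
            sid <- paste(donor, lin, ss, tis, rep_i, sep = "_")
            counts <- as.vector(rmultinom(1, cfg$depth, freq))
            det <- counts > 0
            rec <- tibble::tibble(
              sample_id = sid,
              sequence_id = sprintf("%s_seq%05d", sid, seq_len(sum(det))),
              v_call = paste0(pool$v_call[det], "*01"),
              j_call = paste0(pool$j_call[det], "*01"),
              cdr3_aa = pool$cdr3_aa[det],
              productive = pool$productive[det],
              duplicate_count = counts[det]
            )
            n_err <- rbinom(1, cfg$depth, cfg$error_rate)
            if (n_err > 0) {
              parents <- sample(nrow(pool), n_err, replace = TRUE,
                                prob = freq)
              err <- tibble::tibble(
                sample_id = sid,
                sequence_id = sprintf("%s_err%05d", sid, seq_len(n_err)),
                v_call = paste0(pool$v_call[parents], "*01"),
                j_call = paste0(pool$j_call[parents], "*01"),
                cdr3_aa = perturb_cdr3(pool$cdr3_aa[parents]),
                productive = TRUE,
                duplicate_count = 1L
              )
              rec <- dplyr::bind_rows(rec, err)
              errkeys[[length(errkeys) + 1]] <- tibble::tibble(
                sample_id = sid, v_call = pool$v_call[parents],
                j_call = pool$j_call[parents], cdr3_aa = err$cdr3_aa
              )
            }
            records[[length(records) + 1]] <- rec
            if (rep_i == 1) {
              truths[[length(truths) + 1]] <- tibble::tibble(
                donor_id = donor, lineage = lin, subset = ss, tissue = tis,
                n_clones_true = nrow(pool),
                true_clonality = truth_cl$clonality,
                true_top10_mass = sum(sort(freq, decreasing = TRUE)[
                  seq_len(min(10, length(freq)))])
              )
            }
          }
        }
      }
    }
  }

  sample_truth <- dplyr::bind_rows(truths)
  sample_truth <- purrr::map_dfr(seq_len(cfg$replicates), function(r) {
    dplyr::mutate(sample_truth, replicate = r)
  })
  sample_truth$sample_id <- paste(sample_truth$donor_id,
                                  sample_truth$lineage,
                                  sample_truth$subset, sample_truth$tissue,
                                  sample_truth$replicate, sep = "_")

  structure(list(
    rearrangements = dplyr::bind_rows(records),
    samples = sheet,
    truth = list(
      sample_truth = dplyr::relocate(sample_truth, "sample_id"),
      universe = dplyr::bind_rows(universes),
      error_keys = dplyr::bind_rows(errkeys),
      motifs = motifs,
      config = cfg,
      seed = seed
    )
  ), class = "tcr_cohort")
}

#' Machine-readable ground truth of a synthetic cohort
#'
#' @param cohort A `tcr_cohort` from [simulate_cohort()].
#' @return List with `sample_truth` (per-sample true clonality and
#'   top-10 mass), `sharing` (per donor/lineage/subset tissue-pair true
#'   cosine similarity and shared-clone fraction of the underlying
#'   pools) and `imprint` (the lineage-tissue motif table).
#' @export
ground_truth_report <- function(cohort) {
  stopifnot(inherits(cohort, "tcr_cohort"))
  uni <- cohort$truth$universe
  tissues <- cohort$truth$config$tissues
  sharing <- list()
  uni <- uni[uni$weight > 0, ]
  for (g in split(uni, paste(uni$donor_id, uni$lineage, uni$subset))) {
    if (nrow(g) == 0) next
    key <- clone_key(g$v_call, g$j_call, g$cdr3_aa)
    for (k in seq_len(length(tissues) - 1)) {
      for (l in (k + 1):length(tissues)) {
        ina <- g[[paste0("in_", tissues[k])]]
        inb <- g[[paste0("in_", tissues[l])]]
        if (!any(ina) || !any(inb)) next
        va <- setNames(g$weight[ina] / sum(g$weight[ina]), key[ina])
        vb <- setNames(g$weight[inb] / sum(g$weight[inb]), key[inb])
        sharing[[length(sharing) + 1]] <- tibble::tibble(
          donor_id = g$donor_id[1], lineage = g$lineage[1],
          subset = g$subset[1], tissue_a = tissues[k],
          tissue_b = tissues[l],
          true_cosine = cosine_similarity(va, vb),
          shared_fraction = sum(ina & inb) / sum(ina | inb)
        )
      }
    }
  }
  list(sample_truth = cohort$truth$sample_truth,
       sharing = dplyr::bind_rows(sharing),
       imprint = cohort$truth$motifs)
}

#' Write a synthetic cohort to AIRR-style files
#'
#' Emits one rearrangement TSV per sample (AIRR column names, including
#' `junction_aa`), a `sample_sheet.tsv`, and the ground truth under
#' `truth/`. Output is byte-identical for identical cohorts.
#'
#' @param cohort A `tcr_cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "tcr_cohort"))
  dir.create(file.path(dir, "truth"), recursive = TRUE, showWarnings = FALSE)
  for (sid in unique(cohort$rearrangements$sample_id)) {
    rec <- cohort$rearrangements[cohort$rearrangements$sample_id == sid, ]
    out <- tibble::tibble(
      sequence_id = rec$sequence_id, v_call = rec$v_call,
      j_call = rec$j_call, junction_aa = rec$cdr3_aa,
      productive = rec$productive, duplicate_count = rec$duplicate_count
    )
    readr::write_tsv(out, file.path(dir, paste0(sid, ".tsv")),
                     progress = FALSE)
  }
  readr::write_tsv(cohort$samples, file.path(dir, "sample_sheet.tsv"),
                   progress = FALSE)
  readr::write_tsv(cohort$truth$sample_truth,
                   file.path(dir, "truth", "sample_truth.tsv"),
                   progress = FALSE)
  readr::write_tsv(cohort$truth$error_keys,
                   file.path(dir, "truth", "error_keys.tsv"),
                   progress = FALSE)
  readr::write_tsv(cohort$truth$motifs,
                   file.path(dir, "truth", "motifs.tsv"), progress = FALSE)
  invisible(dir)
}
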