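test_that("overlap removal keeps only sample-private clones", {
  a <- dplyr::bind_rows(
    clone_tbl(3, sample_id = "A", v = "TRBV1", cdr3 = "CASSAF"),
    clone_tbl(2, sample_id = "A", v = "TRBV2", cdr3 = "CASSBF"))
  b <- clone_tbl(5, sample_id = "B", v = "TRBV1", cdr3 = "CASSAF")
  expect_warning(out <- remove_overlapping_clones(dplyr::bind_rows(a, b)),
                 "lost all clones")
  expect_equal(out$sample_id, "A")
  expect_equal(out$cdr3_aa, "CASSBF")
  expect_equal(attr(out, "n_removed"), 2L)

  disjoint <- dplyr::bind_rows(
    clone_tbl(3, sample_id = "A", v = "TRBV1", cdr3 = "CASSAF"),
    clone_tbl(2, sample_id = "B", v = "TRBV2", cdr3 = "CASSBF"))
  expect_equal(nrow(remove_overlapping_clones(disjoint)), 2)

  same <- dplyr::bind_rows(
    clone_tbl(3, sample_id = "A", v = "TRBV1", cdr3 = "CASSAF"),
    clone_tbl(3, sample_id = "B", v = "TRBV1", cdr3 = "CASSAF"))
  expect_warning(gone <- remove_overlapping_clones(same), "lost all")
  expect_equal(nrow(gone), 0)
})

test_that("distance sampling is seeded, order-invariant and flags shortfalls", {
  withr::with_seed(4, {
    tbl <- tibble::tibble(
      sample_id = "S", v_call = sample(paste0("TRBV", 1:9), 200, TRUE),
      j_call = "TRBJ1-1",
      cdr3_aa = replicate(200, paste0(
        c("C", sample(c("A", "S", "G", "L"), 8, TRUE), "F"), collapse = "")),
      copies = 2L, frequency = 1 / 200
    )
  })
  tbl <- dplyr::distinct(tbl, v_call, cdr3_aa, .keep_all = TRUE)
  d1 <- draw_distance_sample(tbl, n = 20, seed = 99)
  d2 <- draw_distance_sample(tbl, n = 20, seed = 99)
  expect_equal(as.data.frame(d1), as.data.frame(d2))
  shuffled <- tbl[rev(seq_len(nrow(tbl))), ]
  d3 <- draw_distance_sample(shuffled, n = 20, seed = 99)
  expect_equal(as.data.frame(d3), as.data.frame(d1))
  expect_false(attr(d1, "undersampled")[["S"]])
  d4 <- draw_distance_sample(tbl, n = 10000, seed = 1)
  expect_true(attr(d4, "undersampled")[["S"]])
  expect_equal(nrow(d4), nrow(tbl))
})

test_that("Levenshtein distance agrees with the DP oracle and is a metric", {
  expect_equal(cdr3_levenshtein("CASSLG", "CASSLG"), 0L)
  expect_equal(cdr3_levenshtein("CASSL", "CASS"), 1L)
  expect_equal(cdr3_levenshtein("kitten", "sitting"), dp_levenshtein("kitten", "sitting"))
  expect_equal(cdr3_levenshtein("kitten", "sitting"), 3L)

  withr::with_seed(8, {
    s <- random_strings(60, max_len = 8)
    for (i in 1:150) {
      pair <- sample(s, 2)
      expect_equal(cdr3_levenshtein(pair[1], pair[2]),
                   dp_levenshtein(pair[1], pair[2]))
    }
    for (i in 1:50) {
      tri <- sample(s, 3)
      dxy <- cdr3_levenshtein(tri[1], tri[2])
      dyz <- cdr3_levenshtein(tri[2], tri[3])
      dxz <- cdr3_levenshtein(tri[1], tri[3])
      expect_lte(dxz, dxy + dyz)
      expect_equal(dxy, cdr3_levenshtein(tri[2], tri[1]))
    }
  })
})

test_that("Hamming distance counts mismatches and skips unequal lengths", {
  expect_equal(cdr3_hamming("CASS", "CASS"), 0L)
  expect_equal(cdr3_hamming("CASS", "CAST"), 1L)
  expect_true(is.na(cdr3_hamming("CAS", "CASS")))
  expect_equal(cdr3_hamming("CAS", "CASS", unequal = "penalty"), 1L)
  m <- cdr3_hamming(c("CASS", "CAS"), c("CASS", "CATT"))
  expect_equal(m[1, ], c(0L, 2L))
  expect_true(all(is.na(m[2, ])))
})

test_that("symmetrized KL divergence matches hand arithmetic and is a pre-metric", {
  x <- c(A = 3, B = 0)
  y <- c(A = 0, B = 3)
  expect_equal(kl_divergence_sym(x, y), 1.6635532333, tolerance = 1e-9)
  expect_equal(kl_divergence_sym(x, x), 0)
  withr::with_seed(14, {
    for (i in 1:20) {
      genes <- paste0("TRBV", 1:8)
      a <- setNames(rpois(8, 5), genes)
      b <- setNames(rpois(8, 5), genes)
      expect_equal(kl_divergence_sym(a, b), kl_divergence_sym(b, a))
      expect_gte(kl_divergence_sym(a, b), 0)
      # invariant to relabelling both samples the same way
      perm <- sample(genes)
      expect_equal(kl_divergence_sym(setNames(a[perm], genes),
                                     setNames(b[perm], genes)),
                   kl_divergence_sym(a, b))
    }
  })
})

test_that("stratum classification partitions all sample pairs", {
  coh <- small_cohort()
  priv <- suppressWarnings(remove_overlapping_clones(coh$clones))
  ds <- draw_distance_sample(priv, n = 25, seed = 6)
  h <- distance_hierarchy(ds, coh$samples, metric = "kl")
  n_samples <- length(unique(ds$sample_id))
  expect_equal(sum(h$strata$n_pairs), choose(n_samples, 2))
  expect_true(all(!is.na(h$pairs$stratum)))
  expect_true(all(h$pairs$distance >= 0))
})

test_that("hierarchy on identical CDR3 sets gives zero distances", {
  tbl <- dplyr::bind_rows(lapply(c("X_CD4_TEM_Spl_1", "X_CD4_TEM_Spl_2"),
    function(s) clone_tbl(c(2, 2), sample_id = s,
                          v = c("TRBV1", "TRBV2"),
                          cdr3 = c("CASSAF", "CASSAF"))))
  samples <- validate_sample_sheet(tibble::tibble(
    sample_id = unique(tbl$sample_id), donor_id = "X", age = 40,
    lineage = "CD4", subset = "TEM", tissue = "Spl", replicate = 1:2))
  h <- distance_hierarchy(tbl, samples, metric = "levenshtein")
  expect_equal(as.character(h$strata$stratum), "replicate")
  expect_equal(h$strata$mean, 0)
})

test_that("embedding input is a symmetric labelled distance matrix", {
  coh <- small_cohort()
  priv <- suppressWarnings(remove_overlapping_clones(coh$clones))
  sm <- coh$samples
  donor_ids <- sm$sample_id[sm$donor_id == "D1" & sm$lineage == "CD8"]
  ds <- draw_distance_sample(priv[priv$sample_id %in% donor_ids, ],
                             n = 30, seed = 2)
  emb <- embedding_input(ds, sm, n = 40, seed = 3)
  expect_true(isSymmetric(emb$distances))
  expect_equal(unname(diag(emb$distances)), rep(0L, nrow(emb$distances)))
  expect_equal(nrow(emb$labels), nrow(emb$distances))
  expect_true(all(emb$labels$tissue %in% sm$tissue))
  emb2 <- embedding_input(ds, sm, n = 40, seed = 3)
  expect_identical(emb$distances, emb2$distances)
})
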