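test_that("cosine similarity matches hand computations and its invariances", {
  a <- c(c1 = 0.4, c2 = 0.6)
  expect_equal(cosine_similarity(a, a), 1)
  expect_equal(cosine_similarity(c(c1 = 1), c(c2 = 0.5, c3 = 0.5)), 0)
  expect_equal(cosine_similarity(c(c1 = 1), c(c1 = 0.5, c2 = 0.5)),
               0.7071067812, tolerance = 1e-9)
  withr::with_seed(2, {
    for (i in 1:10) {
      x <- setNames(runif(6), paste0("k", 1:6))
      y <- setNames(runif(6), paste0("k", 3:8))
      expect_equal(cosine_similarity(x, y), cosine_similarity(y, x))
      expect_equal(cosine_similarity(x, y), cosine_similarity(x * 3, y / 7))
    }
  })
  expect_error(cosine_similarity(c(c1 = 0), c(c1 = 1)), "zero vector")
  expect_error(cosine_similarity(1, c(c1 = 1)), "named")
})

test_that("replicate-averaged sample overlap is the mean of the cross pairs", {
  r1 <- clone_tbl(c(6, 4))
  same <- sample_pair_cosine(list(r1, r1), list(r1, r1),
                             apply_cutoff = FALSE)
  expect_equal(as.numeric(same), 1)
  expect_equal(attr(same, "n_replicate_pairs"), 4L)

  other <- clone_tbl(c(3, 3), v = c("TRBVX", "TRBVY"),
                     cdr3 = c("CASSXF", "CASSYF"))
  expect_equal(as.numeric(
    sample_pair_cosine(list(r1, r1), list(other, other),
                       apply_cutoff = FALSE)), 0)

  # A1=B1={c1}, A2=B2={c2}: pairs (1,0,0,1) -> mean 0.5
  c1 <- clone_tbl(5, v = "TRBV1", cdr3 = "CASSAF")
  c2 <- clone_tbl(5, v = "TRBV2", cdr3 = "CASSBF")
  expect_equal(as.numeric(
    sample_pair_cosine(list(c1, c2), list(c1, c2), apply_cutoff = FALSE)),
    0.5)

  # a missing replicate degrades to the available pairs with a warning
  expect_warning(
    one <- sample_pair_cosine(list(r1), list(r1, r1), apply_cutoff = FALSE),
    "fewer than two replicates")
  expect_equal(attr(one, "n_replicate_pairs"), 2L)
})

test_that("overlap matrices are symmetric, unit-diagonal and order-stable", {
  coh <- small_cohort()
  cl <- coh$clones
  sm <- coh$samples
  keep <- sm$sample_id[sm$donor_id == "D1" & sm$lineage == "CD8"]
  pw <- pairwise_overlap(cl[cl$sample_id %in% keep, ],
                         sm[sm$sample_id %in% keep, ])
  m <- overlap_matrix(pw, "D1", "CD8")
  expect_true(isSymmetric(unname(m), tol = 1e-12))
  expect_equal(unname(diag(m)), rep(1, nrow(m)))
  expect_true(all(m >= 0 & m <= 1 + 1e-12))

  # permuting input rows leaves the pairwise values unchanged
  shuf <- cl[cl$sample_id %in% keep, ]
  shuf <- shuf[rev(seq_len(nrow(shuf))), ]
  pw2 <- pairwise_overlap(shuf, sm[sm$sample_id %in% keep, ])
  m2 <- overlap_matrix(pw2, "D1", "CD8")
  expect_equal(m2[rownames(m), colnames(m)], m[rownames(m), colnames(m)],
               tolerance = 1e-12)
})

test_that("group compilation classifies designs and averages with SEM", {
  pw <- tibble::tibble(
    donor_id = c("D1", "D2", "D1"), lineage = "CD8",
    subset_a = c("TEM", "TEM", "TEM"), tissue_a = c("Bld", "Bld", "Spl"),
    subset_b = c("TEM", "TEM", "TRM"), tissue_b = c("Spl", "Spl", "Spl"),
    cosine_mean = c(0.4, 0.6, 0.2), n_replicate_pairs = 4L
  )
  grp <- compile_group_overlap(pw)
  same <- grp[grp$design == "same_subset_between_sites", ]
  expect_equal(same$label, "TEM")
  expect_equal(same$mean, 0.5)
  expect_equal(same$sem, 0.1)
  expect_equal(same$n, 2L)
  within <- grp[grp$design == "cross_subset_within_site", ]
  expect_equal(within$label, "TEM-TRM")
  expect_true(is.na(within$sem))   # single pair: SEM undefined

  # normalization recenters within donor but keeps the raw mean alongside
  norm <- compile_group_overlap(pw, normalize = TRUE)
  expect_true("mean_raw" %in% names(norm))
  expect_equal(norm$mean_raw[norm$design == "same_subset_between_sites"],
               0.5)
})

test_that("replicates from one pool overlap more than different subsets", {
  coh <- small_cohort()
  cl <- coh$clones
  sm <- coh$samples
  tabs <- split(cl, cl$sample_id)
  id <- function(d, l, s, t, r) paste(d, l, s, t, r, sep = "_")
  rep_cos <- sample_pair_cosine(list(tabs[[id("D1", "CD8", "TEM", "Spl", 1)]]),
                                list(tabs[[id("D1", "CD8", "TEM", "Spl", 2)]])) |>
    suppressWarnings()
  cross <- sample_pair_cosine(list(tabs[[id("D1", "CD8", "TEM", "Spl", 1)]]),
                              list(tabs[[id("D1", "CD8", "TRM", "Spl", 1)]])) |>
    suppressWarnings()
  expect_gt(as.numeric(rep_cos), as.numeric(cross))
})
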