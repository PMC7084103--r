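make_proteome <- function(n = 40, seed = 41) {
  generate_proteome(proteome_spec(n_genes = n, seed = seed))
}

test_that("batch scans equal per-protein profile correlations", {
  prot <- make_proteome(15)
  set.seed(42)
  s <- aa_scale(rnorm(20), name = "probe")
  scan <- scan_proteome(prot$cds, s, "+1")
  for (id in sample(names(scan$R), 5)) {
    wt <- wildtype_translate(prot$cds[[id]])
    sh <- frameshift_translate(prot$cds[[id]], "+1")
    r <- profile_correlation(build_profile(wt, s), build_profile(sh, s),
                             offset = frameshift_offset())
    expect_equal(unname(scan$R[id]), r, tolerance = 1e-10)
  }
  # permuting the input leaves per-protein values unchanged
  scan_rev <- scan_proteome(rev(prot$cds), s, "+1")
  expect_equal(scan_rev$R[names(scan$R)], scan$R, tolerance = 1e-12)
  expect_equal(scan$median_R, median(scan$R))
  expect_equal(scan$n_proteins + nrow(scan$skipped), length(prot$cds))
})

test_that("degenerate scales skip every protein with a reason", {
  prot <- make_proteome(8)
  scan <- scan_proteome(prot$cds, aa_scale(rep(1, 20), name = "flat"), "+1")
  expect_equal(scan$n_proteins, 0)
  expect_true(all(scan$skipped$reason == "undefined_correlation"))
  expect_equal(nrow(scan$skipped), 8)
})

test_that("short proteins are filtered by min_len and counted", {
  cds <- c(long = random_cds(60), short = random_cds(5))
  set.seed(43)
  scan <- scan_proteome(cds, aa_scale(rnorm(20)), "+1", min_len = 21)
  expect_identical(names(scan$R), "long")
  expect_identical(scan$skipped$id, "short")
  expect_identical(scan$skipped$reason, "too_short")
})

test_that("an optimized scale scores above random scales proteome-wide", {
  prot <- make_proteome(60, seed = 44)
  opt <- optimize_scale(pairs_p1, n_starts = 30, seed = 45)
  scan <- scan_proteome(prot$cds, opt$scale, "+1")
  expect_gt(scan$median_R, 0)
  set.seed(46)
  null_medians <- replicate(100, {
    scan_proteome(prot$cds, aa_scale(rnorm(20)), "+1")$median_R
  })
  expect_gt(scan$median_R, quantile(null_medians, 0.95))
})

test_that("per-scale proteome p-values are monotone in median R", {
  prot <- make_proteome(30, seed = 47)
  opt <- optimize_scale(pairs_p1, n_starts = 20, seed = 48)
  lib <- generate_scale_library(
    scale_library_spec(n_categories = 3, scales_per_category = 8, seed = 49),
    pairs_p1, optimal = opt)
  res <- proteome_scale_pvalues(prot$cds, lib, "+1", n_null = 120, seed = 50)
  expect_equal(nrow(res), 24)
  ord <- order(res$median_R)
  expect_true(all(diff(res$p[ord]) <= 1e-12))
  null <- attr(res, "null")
  expect_lt(abs(null$mu), 0.1)
  # planted stable scales get systematically lower p
  expect_lt(median(res$p[res$category == "stable"]),
            median(res$p[res$category != "stable"]))
})

test_that("mRNA-side profiles are identical across frame comparisons", {
  prot <- make_proteome(6, seed = 51)
  # identity check: a protein profile built from the purine density itself
  cds1 <- prot$cds[[1]]
  mrna <- purine_density_profile(cds1)
  expect_equal(profile_correlation(mrna, mrna), 1, tolerance = 1e-12)
  # the mRNA profile does not depend on the protein frame compared against
  for (id in names(prot$cds)) {
    expect_identical(purine_density_profile(prot$cds[[id]])$values,
                     purine_density_profile(prot$cds[[id]])$values)
  }
  set.seed(52)
  gua <- aa_scale(rnorm(20), name = "gua_affinity", category = "nuc")
  r_wt <- mrna_protein_matching(prot$cds, gua, "wt")
  r_p1 <- mrna_protein_matching(prot$cds, gua, "+1")
  expect_true(all(is.finite(r_wt)))
  expect_true(all(abs(r_wt) <= 1) && all(abs(r_p1) <= 1))
  # negating the affinity scale flips every correlation
  r_neg <- mrna_protein_matching(prot$cds, invert_scale(gua), "wt")
  expect_equal(r_neg, -r_wt, tolerance = 1e-12)
})

test_that("ortholog stability correlation handles pairing and nulls", {
  prot <- make_proteome(60, seed = 53)
  opt <- optimize_scale(pairs_p1, n_starts = 20, seed = 54)
  scan <- scan_proteome(prot$cds, opt$scale, "+1")
  ids <- names(scan$R)
  # a proteome paired with itself gives R = 1
  self <- ortholog_stability_correlation(scan, scan,
                                         data.frame(a = ids, b = ids))
  expect_equal(self$R, 1, tolerance = 1e-12)
  expect_equal(self$n_used, length(ids))
  # randomly permuted pairing decorrelates
  set.seed(55)
  perm <- ortholog_stability_correlation(scan, scan,
                                         data.frame(a = ids, b = sample(ids)))
  expect_lt(abs(perm$R), 3 / sqrt(perm$n_used))
  # missing ids are dropped and counted
  pairs_df <- data.frame(a = c(ids[1:5], "absent"), b = c(ids[1:5], ids[6]))
  res <- ortholog_stability_correlation(scan, scan, pairs_df)
  expect_equal(res$n_used, 5)
  expect_equal(res$n_dropped, 1)
  expect_error(ortholog_stability_correlation(scan, scan,
                                              data.frame(a = "x", b = "y")),
               "fewer than 3")
})

test_that("stability ranking is deterministic with lexicographic ties", {
  R <- setNames(c(0.9, 0.5, 0.5, 0.1), c("d", "b", "a", "c"))
  scan <- structure(list(R = R, n_proteins = 4, frame = "+1",
                         scale_name = "toy",
                         skipped = data.frame(id = character(0),
                                              reason = character(0))),
                    class = "proteome_scan")
  rk <- stability_ranking(scan, quantile = 0.5)
  expect_identical(rk$ranked$id, c("d", "a", "b", "c"))
  expect_identical(rk$top, c("d", "a"))
  # quantile 0.75 on 100 proteins keeps 25 ids
  set.seed(56)
  scan2 <- structure(list(R = setNames(runif(100), sprintf("p%03d", 1:100)),
                          n_proteins = 100, frame = "+1", scale_name = "toy",
                          skipped = data.frame()),
                     class = "proteome_scan")
  rk2 <- stability_ranking(scan2, 0.75)
  expect_length(rk2$top, 25)
  expect_gte(min(scan2$R[rk2$top]), max(scan2$R[setdiff(names(scan2$R), rk2$top)]))
})
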