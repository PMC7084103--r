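test_that("scale construction validates and orders values", {
  s <- aa_scale(1:20, name = "toy", category = "hydro")
  expect_s3_class(s, "aa_scale")
  expect_identical(names(scale_values(s)),
                   strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]])
  # named input in scrambled order is reordered canonically
  v <- setNames(1:20, sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]))
  expect_identical(names(scale_values(aa_scale(v))), sort(names(v)))
  expect_error(aa_scale(1:19), "20 values")
  expect_error(aa_scale(c(1:19, NA)), "non-finite")
  expect_true(is_degenerate(aa_scale(rep(3, 20))))
  expect_false(is_degenerate(s))
})

test_that("normalization gives zero mean, unit norm, and is idempotent", {
  set.seed(1)
  s <- aa_scale(rnorm(20, 5, 3))
  n1 <- normalize_scale(s)
  expect_equal(mean(as.numeric(n1)), 0, tolerance = 1e-12)
  expect_equal(sum(as.numeric(n1)^2), 1, tolerance = 1e-12)
  expect_equal(as.numeric(normalize_scale(n1)), as.numeric(n1),
               tolerance = 1e-12)
  # frameshift R is invariant under affine maps with positive slope
  r0 <- ugc_correlation(s, pairs_p1)
  expect_equal(ugc_correlation(n1, pairs_p1), r0, tolerance = 1e-12)
  shifted <- aa_scale(2.5 * as.numeric(s) + 7)
  expect_equal(ugc_correlation(shifted, pairs_p1), r0, tolerance = 1e-12)
  expect_error(normalize_scale(aa_scale(rep(1, 20))), "zero-variance")
})

test_that("inversion negates values, preserves category and correlation", {
  set.seed(2)
  s <- aa_scale(rnorm(20), category = "hydro")
  inv <- invert_scale(s)
  expect_equal(as.numeric(inv), -as.numeric(s))
  expect_identical(scale_category(inv), "hydro")
  expect_equal(as.numeric(invert_scale(inv)), as.numeric(s))
  expect_equal(ugc_correlation(inv, pairs_p1),
               ugc_correlation(s, pairs_p1), tolerance = 1e-12)
})

test_that("the built-in charge scale follows the integer convention", {
  ch <- scale_values(builtin_charge_scale())
  expect_equal(unname(ch["D"]), -1)
  expect_equal(unname(ch["E"]), -1)
  expect_equal(unname(ch["K"]), 1)
  expect_equal(unname(ch["R"]), 1)
  expect_equal(unname(ch["H"]), 0)
  expect_equal(sum(ch[c("D", "E", "K", "R")]), 0)
  expect_equal(sum(ch != 0), 4)
})

aaindex_fixture <- function(path, with_na = FALSE) {
  entry <- function(acc, vals) {
    c(paste("H", acc),
      "D toy scale for testing",
      "R LIT:0000",
      "I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V",
      paste(" ", paste(vals[1:10], collapse = "   ")),
      paste(" ", paste(vals[11:20], collapse = "   ")),
      "//")
  }
  set.seed(99)
  lines <- c(entry("TEST001", round(rnorm(20), 3)),
             entry("TEST002", round(runif(20, -2, 5), 3)),
             entry("TEST003", 1:20))
  if (with_na) {
    lines <- c(lines, entry("TESTNA1", c(round(rnorm(19), 3), "NA")))
  }
  writeLines(lines, path)
  path
}

test_that("the AAindex reader parses entries and skips NA records", {
  path <- withr::local_tempfile(fileext = ".txt")
  aaindex_fixture(path)
  lib <- read_aaindex(path)
  expect_length(lib, 3)
  expect_identical(names(lib), c("TEST001", "TEST002", "TEST003"))
  # I-record rows are in AAindex order (A R N D C Q E G H I / L K M F P S T W Y V)
  v <- scale_values(lib$TEST003)
  expect_equal(unname(v["A"]), 1)
  expect_equal(unname(v["I"]), 10)
  expect_equal(unname(v["L"]), 11)
  expect_equal(unname(v["V"]), 20)
  # NA entry is skipped with a warning and shrinks the library by one
  path2 <- withr::local_tempfile(fileext = ".txt")
  aaindex_fixture(path2, with_na = TRUE)
  expect_warning(lib2 <- read_aaindex(path2), "TESTNA1")
  expect_length(lib2, 3)
  # category mapping
  lib3 <- read_aaindex(path, categories = c(TEST001 = "hydro"))
  expect_identical(scale_category(lib3$TEST001), "hydro")
  expect_identical(scale_category(lib3$TEST002), "other")
})

test_that("malformed AAindex entries are rejected by accession", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("H BADENTRY", "D broken", "I A/L",
               " 1 2 3", " 4 5 6", "//"), path)
  expect_error(read_aaindex(path), "BADENTRY")
})

test_that("AAindex and TSV round trips are lossless", {
  set.seed(7)
  lib <- scale_library(lapply(1:4, function(i) {
    aa_scale(rnorm(20), name = paste0("RT", i),
             category = c("hydro", "beta", "nuc", "other")[i])
  }))
  p1 <- withr::local_tempfile(fileext = ".txt")
  write_aaindex(lib, p1)
  back <- read_aaindex(p1)
  expect_identical(names(back), names(lib))
  for (nm in names(lib)) {
    expect_equal(scale_values(back[[nm]]), scale_values(lib[[nm]]),
                 tolerance = 1e-15)
  }
  p2 <- withr::local_tempfile(fileext = ".tsv")
  write_scales_tsv(lib, p2)
  back2 <- read_scales_tsv(p2)
  expect_identical(names(back2), names(lib))
  for (nm in names(lib)) {
    expect_equal(scale_values(back2[[nm]]), scale_values(lib[[nm]]),
                 tolerance = 1e-15)
    expect_identical(scale_category(back2[[nm]]), scale_category(lib[[nm]]))
  }
})
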