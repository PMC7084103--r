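test_that("windowed profiles match the per-position loop oracle", {
  set.seed(31)
  s <- aa_scale(rnorm(20))
  vals <- scale_values(s)
  for (k in 1:5) {
    chars <- sample(c(names(vals), "*"), 40, replace = TRUE,
                    prob = c(rep(1, 20), 2))
    aa <- paste(chars, collapse = "")
    for (w in c(1, 5, 21)) {
      prof <- build_profile(aa, s, window = w)
      expect_equal(prof$values, oracle_window_profile(chars, vals, w),
                   tolerance = 1e-12)
      expect_identical(prof$mask, chars == "*")
    }
  }
})

test_that("profile edge cases: constant sequence, unit window, stop rule", {
  s <- aa_scale(1:20)
  vals <- scale_values(s)
  # constant sequence -> constant profile at the residue's value
  prof <- build_profile(strrep("A", 30), s)
  expect_true(all(prof$values == vals["A"]))
  # window 1 equals the raw per-residue values
  aa <- "ACDEFGHIKLMNPQRSTVWY"
  prof1 <- build_profile(aa, s, window = 1)
  expect_equal(prof1$values, unname(vals[strsplit(aa, "")[[1]]]))
  # 25-residue toy with one internal stop: the center value averages the
  # 20 non-stop residues of its 21-window
  chars <- c(rep("A", 12), "*", rep("C", 12))
  prof2 <- build_profile(paste(chars, collapse = ""), s, window = 21)
  center <- 13
  expect_true(is.na(prof2$values[center]))
  # the position just left of the stop averages its 21-window minus the stop
  p <- center - 1
  winp <- chars[(p - 10):(p + 10)]
  expect_equal(prof2$values[p], mean(vals[winp[winp != "*"]]),
               tolerance = 1e-12)
  expect_error(build_profile("MASG", s, window = 4), "odd")
  expect_error(build_profile("MXSG", s), "absent")
})

test_that("profiles commute with affine scale transforms", {
  set.seed(32)
  s <- aa_scale(rnorm(20))
  aa <- paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], 60,
                     replace = TRUE), collapse = "")
  p0 <- build_profile(aa, s)
  p1 <- build_profile(aa, aa_scale(3 * as.numeric(s) - 2))
  expect_equal(p1$values, 3 * p0$values - 2, tolerance = 1e-12)
})

test_that("profile correlation matches the oracle after identical masking", {
  set.seed(33)
  s <- aa_scale(rnorm(20))
  cds <- random_cds(80)
  wt <- wildtype_translate(cds)
  sh <- frameshift_translate(cds, "+1")
  pw <- build_profile(wt, s)
  ps <- build_profile(sh, s)
  r <- profile_correlation(pw, ps, offset = frameshift_offset())
  # oracle: flat vectors, explicit masking and alignment
  shc <- strsplit(sh, "")[[1]]
  iq <- seq_along(shc); ip <- iq + 1
  keep <- ip <= nchar(wt) & shc != "*" & !is.na(ps$values[iq])
  expect_equal(r, oracle_pearson(pw$values[ip[keep]], ps$values[iq[keep]]),
               tolerance = 1e-12)
  # self-correlation and anti-correlation
  expect_equal(profile_correlation(pw, pw), 1, tolerance = 1e-12)
  neg <- pw; neg$values <- -neg$values
  expect_equal(profile_correlation(pw, neg), -1, tolerance = 1e-12)
  # symmetry at fixed alignment
  expect_equal(profile_correlation(pw, ps, 0), profile_correlation(ps, pw, 0),
               tolerance = 1e-12)
  expect_error(profile_correlation(pw, ps, offset = 1e4), "aligned")
})

test_that("purine-density profiles follow the codon purine fraction", {
  expect_true(all(purine_density_profile(strrep("A", 30))$values == 1))
  expect_true(all(purine_density_profile(strrep("C", 30))$values == 0))
  # toy: hand-computed codon fractions then window average
  cds <- "ATGCCCAGGTTT"  # fractions: ATG 2/3, CCC 0, AGG 1, TTT 0
  prof <- purine_density_profile(cds, window = 3)
  frac <- c(2 / 3, 0, 1, 0)
  expected <- c(mean(frac[1:2]), mean(frac[1:3]), mean(frac[2:4]),
                mean(frac[3:4]))
  expect_equal(prof$values, expected, tolerance = 1e-12)
  expect_error(purine_density_profile("AN"), "non-canonical")
})

test_that("net charge and charge profiles follow the integer convention", {
  expect_equal(net_charge("DEKR"), 0)
  expect_equal(net_charge("KKKK"), 4)
  expect_equal(net_charge("DD*E"), -3)
  expect_equal(net_charge("GGGG"), 0)
  prof <- charge_density_profile("KKDD", window = 1)
  expect_equal(prof$values, c(1, 1, -1, -1))
})

test_that("charge-inverting codons produce anticorrelated net charge", {
  # GAA encodes Glu (-1) while its +1 frame reads AAG = Lys (+1), so genes
  # built from GAA blocks plus neutral GGG padding invert their net charge
  # under a +1 frameshift
  set.seed(35)
  n_gaa <- sample(5:40, 25, replace = TRUE)
  wt_charge <- numeric(25); p1_charge <- numeric(25)
  for (g in seq_along(n_gaa)) {
    cds <- paste(c("ATG", rep("GAA", n_gaa[g]), rep("GGG", 45 - n_gaa[g]),
                   "TAA"), collapse = "")
    wt_charge[g] <- net_charge(wildtype_translate(cds))
    p1_charge[g] <- net_charge(frameshift_translate(cds, "+1"))
  }
  expect_lt(cor(wt_charge, p1_charge), -0.9)
})

test_that("disorder stability reports R, means and threshold agreement", {
  x <- c(0.1, 0.2, 0.8, 0.9, 0.3, 0.6)
  res <- disorder_stability(x, x, offset = 0)
  expect_equal(res$R, 1)
  expect_equal(res$agreement, 1)
  expect_equal(res$mean_wt, mean(x))
  # anti-aligned around the cutoff -> zero agreement
  res2 <- disorder_stability(x, 1 - x, offset = 0)
  expect_equal(res2$agreement, 0)
  # agreement matches a direct thresholded comparison oracle with offset
  set.seed(34)
  a <- runif(50); b <- runif(40)
  res3 <- disorder_stability(a, b, cutoff = 0.5, offset = 1)
  oracle <- mean((a[2:41] >= 0.5) == (b >= 0.5))
  expect_equal(res3$agreement, oracle, tolerance = 1e-12)
  expect_equal(res3$R, oracle_pearson(a[2:41], b), tolerance = 1e-12)
})

test_that("disorder profiles round-trip through TSV", {
  profs <- list(p1 = c(0.1, 0.5, 0.9), p2 = c(0.3, 0.4))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_disorder_tsv(profs, path)
  back <- read_disorder_tsv(path)
  expect_equal(back[order(names(back))], profs[order(names(profs))],
               tolerance = 1e-12)
})
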