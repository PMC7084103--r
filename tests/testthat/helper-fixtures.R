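# shared fixtures, built once per test run

the_code <- standard_code()
pairs_p1 <- enumerate_frameshift_pairs(the_code, "+1")
pairs_m1 <- enumerate_frameshift_pairs(the_code, "-1")

# independent textbook Pearson correlation on flat vectors (oracle; kept
# deliberately naive and separate from the package's implementations)
oracle_pearson <- function(x, y) {
  n <- length(x)
  sum((x - sum(x) / n) * (y - sum(y) / n)) /
    sqrt(sum((x - sum(x) / n)^2) * sum((y - sum(y) / n)^2))
}

# oracle windowed average with stop exclusion: direct per-position loop
oracle_window_profile <- function(chars, values_by_aa, window) {
  h <- (window - 1) / 2
  n <- length(chars)
  out <- rep(NA_real_, n)
  for (p in seq_len(n)) {
    if (chars[p] == "*") next
    win <- chars[max(1, p - h):min(n, p + h)]
    win <- win[win != "*"]
    out[p] <- mean(values_by_aa[win])
  }
  out
}

# random valid CDS (no internal stops) for property-style tests
random_cds <- function(n_codons, code = the_code) {
  sense <- names(code$codon_to_aa)[code$codon_to_aa != "*"]
  paste(c(sample(sense, n_codons, replace = TRUE), "TAA"), collapse = "")
}
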