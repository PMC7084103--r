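# centered moving average with truncated edges; masked positions contribute
# nothing and shrink the effective window. values at masked positions are NA.
window_mean <- function(vals, mask, window) {
  if (window < 1 || window %% 2 == 0) stop("window must be odd and >= 1")
  n <- length(vals)
  h <- (window - 1L) %/% 2L
  v0 <- ifelse(mask, 0, vals)
  cs <- cumsum(v0)
  cn <- cumsum(!mask)
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  sums <- cs[hi] - c(0, cs)[lo]
  cnts <- cn[hi] - c(0, cn)[lo]
  out <- ifelse(cnts > 0, sums / cnts, NA_real_)
  out[mask] <- NA_real_
  out
}

#' Windowed property profile of a protein sequence
#'
#' Replaces each residue by its scale value and smooths with a centered
#' moving average (default 21 residues). Near the termini the window is
#' truncated to the available residues, so the profile has one entry per
#' residue and stays index-aligned with the sequence. Stop sentinels
#' (`"*"`, arising in frameshifted variants) are excluded from every
#' window average — they contribute nothing and reduce the effective
#' window size — and carry no profile value themselves.
#'
#' @param aa Amino-acid string, possibly with `"*"` sentinels.
#' @param scale An `aa_scale`.
#' @param window Odd window length in residues (default 21).
#' @param id Optional sequence identifier stored on the profile.
#' @return A `property_profile`: list with `values` (numeric, `NA` at
#'   masked positions), `mask` (logical, `TRUE` at stop positions),
#'   `window`, `scale_name`, `id`.
#' @export
build_profile <- function(aa, scale, window = 21, id = NULL) {
  if (nchar(aa) < 1) stop("empty sequence")
  chars <- strsplit(aa, "", fixed = TRUE)[[1]]
  mask <- chars == "*"
  bad <- setdiff(unique(chars[!mask]), AA_ORDER)
  if (length(bad) > 0) {
    stop("residue(s) absent from scale: ", paste(bad, collapse = ", "))
  }
  v <- as.numeric(scale)[match(chars, AA_ORDER)]
  structure(list(values = window_mean(v, mask, window),
                 mask = mask,
                 window = as.integer(window),
                 scale_name = scale_name(scale),
                 id = id),
            class = "property_profile")
}

#' @export
print.property_profile <- function(x, ...) {
  cat(sprintf("<property_profile%s> scale %s, %d positions (%d masked), window %d\n",
              if (!is.null(x$id)) paste0(" ", x$id) else "",
              x$scale_name, length(x$values), sum(x$mask), x$window))
  invisible(x)
}

# aligned, mutually unmasked value pairs of two profiles: q position i is
# compared with p position i + offset
aligned_values <- function(p, q, offset) {
  iq <- seq_along(q$values)
  ip <- iq + offset
  keep <- ip >= 1 & ip <= length(p$values)
  iq <- iq[keep]; ip <- ip[keep]
  ok <- !p$mask[ip] & !q$mask[iq] &
    !is.na(p$values[ip]) & !is.na(q$values[iq])
  list(p = p$values[ip[ok]], q = q$values[iq[ok]])
}

#' Pearson correlation of two property profiles
#'
#' Correlates aligned profile values, comparing position `i` of `q` with
#' position `i + offset` of `p`; pairs in which either position is masked
#' are dropped. For wild-type versus frameshifted comparisons use
#' `offset = frameshift_offset()`.
#'
#' @param p,q `property_profile` objects.
#' @param offset Integer alignment offset (default 0).
#' @return Pearson R.
#' @export
profile_correlation <- function(p, q, offset = 0L) {
  al <- aligned_values(p, q, offset)
  if (length(al$p) < 3) stop("fewer than 3 aligned unmasked positions")
  if (stats::sd(al$p) == 0 || stats::sd(al$q) == 0) {
    stop("zero variance in aligned profile values")
  }
  stats::cor(al$p, al$q)
}

#' Purine-density profile of an mRNA coding sequence
#'
#' Per-codon purine fraction (count of A/G among the three bases divided
#' by 3) smoothed with the same centered-window rule as protein profiles.
#' One value per codon, so the profile aligns index-wise with the profile
#' of the encoded protein; the mRNA profile is by construction unaffected
#' by a frameshift of the *protein*, which is what makes mRNA-protein
#' profile matching comparable across frames.
#'
#' @param cds Nucleotide string (length >= 3; trailing incomplete codon
#'   dropped).
#' @param window Odd window length in codons (default 21, i.e. 63 nt).
#' @param id Optional identifier.
#' @return A `property_profile` over codons (no masked positions).
#' @export
purine_density_profile <- function(cds, window = 21, id = NULL) {
  nt <- normalize_nt(cds)
  chars <- strsplit(nt, "", fixed = TRUE)[[1]]
  bad <- setdiff(unique(chars), DNA_BASES)
  if (length(bad) > 0) {
    stop("non-canonical nucleotide(s): ", paste(bad, collapse = ", "))
  }
  n_codon <- length(chars) %/% 3L
  if (n_codon < 1) stop("sequence shorter than one codon")
  pur <- chars %in% c("A", "G")
  frac <- (pur[seq(1, 3 * n_codon, by = 3)] +
           pur[seq(2, 3 * n_codon, by = 3)] +
           pur[seq(3, 3 * n_codon, by = 3)]) / 3
  structure(list(values = window_mean(frac, rep(FALSE, n_codon), window),
                 mask = rep(FALSE, n_codon),
                 window = as.integer(window),
                 scale_name = "purine_density",
                 id = id),
            class = "property_profile")
}

#' Net charge of a protein sequence
#'
#' Sum of per-residue charge values; stop sentinels contribute 0.
#'
#' @param aa Amino-acid string.
#' @param charge_scale An `aa_scale`; defaults to [builtin_charge_scale()].
#' @return Numeric net charge.
#' @export
net_charge <- function(aa, charge_scale = builtin_charge_scale()) {
  chars <- strsplit(aa, "", fixed = TRUE)[[1]]
  chars <- chars[chars != "*"]
  if (length(chars) == 0) return(0)
  sum(as.numeric(charge_scale)[match(chars, AA_ORDER)])
}

#' Charge-density profile
#'
#' Windowed profile of per-residue charge, see [build_profile()].
#'
#' @inheritParams net_charge
#' @param window Odd window length (default 21).
#' @param id Optional identifier.
#' @export
charge_density_profile <- function(aa, charge_scale = builtin_charge_scale(),
                                   window = 21, id = NULL) {
  build_profile(aa, charge_scale, window = window, id = id)
}

#' Frameshift stability of externally supplied disorder profiles
#'
#' Compares per-residue intrinsic-disorder values (computed by an external
#' predictor such as IUPred; values in `[0, 1]`) between a wild-type
#' protein and its frameshifted variant. No stop-exclusion masking is
#' applied to disorder profiles. Reports the Pearson correlation of the
#' aligned profiles, the per-sequence means, and the fraction of aligned
#' positions whose structured/unstructured classification (below/above
#' `cutoff`) agrees.
#'
#' @param wt_values Numeric per-residue disorder values of the wild type.
#' @param shifted_values Numeric per-residue values of the variant.
#' @param cutoff Classification threshold (default 0.5).
#' @param offset Alignment offset; default [frameshift_offset()].
#' @return List with `R`, `mean_wt`, `mean_shifted`, `agreement`,
#'   `n_aligned`.
#' @export
disorder_stability <- function(wt_values, shifted_values, cutoff = 0.5,
                               offset = frameshift_offset()) {
  iq <- seq_along(shifted_values)
  ip <- iq + offset
  keep <- ip >= 1 & ip <= length(wt_values)
  if (sum(keep) < 3) stop("fewer than 3 aligned positions")
  a <- wt_values[ip[keep]]
  b <- shifted_values[iq[keep]]
  R <- if (stats::sd(a) == 0 || stats::sd(b) == 0) NA_real_ else stats::cor(a, b)
  list(R = R,
       mean_wt = mean(wt_values),
       mean_shifted = mean(shifted_values),
       agreement = mean((a >= cutoff) == (b >= cutoff)),
       n_aligned = sum(keep))
}

#' Read / write per-residue disorder profiles as TSV
#'
#' Three columns: `id`, `position` (1-based), `value`.
#'
#' @param path File path.
#' @return `read_disorder_tsv` returns a named list of numeric vectors.
#' @export
read_disorder_tsv <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  split_vals <- split(tab[, c("position", "value")], tab$id)
  lapply(split_vals, function(d) d$value[order(d$position)])
}

#' @rdname read_disorder_tsv
#' @param profiles Named list of numeric vectors.
#' @export
write_disorder_tsv <- function(profiles, path) {
  tab <- do.call(rbind, lapply(names(profiles), function(id) {
    data.frame(id = id, position = seq_along(profiles[[id]]),
               value = profiles[[id]], stringsAsFactors = FALSE)
  }))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
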