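# per-position window weight matrix (L x 20): row p gives, for each amino
# acid, its fraction among the non-masked residues of the window around p
window_weight_matrix <- function(aa_idx, mask, window) {
  L <- length(aa_idx)
  h <- (window - 1L) %/% 2L
  ind <- matrix(0, L, 20L)
  keep <- !mask & !is.na(aa_idx)
  ind[cbind(which(keep), aa_idx[keep])] <- 1
  cs <- apply(ind, 2, cumsum)
  lo <- pmax(seq_len(L) - h, 1L)
  hi <- pmin(seq_len(L) + h, L)
  counts <- cs[hi, , drop = FALSE] - rbind(0, cs)[lo, , drop = FALSE]
  tot <- rowSums(counts)
  counts / ifelse(tot > 0, tot, 1)
}

# Precomputed linear machinery for proteome scans. Windowed profile values
# are linear in the 20 scale values, so each protein contributes two
# weight-matrix blocks (wild-type side and shifted side) over its aligned,
# unmasked positions; scanning K scales is then two matrix products.
build_scan_design <- function(cds_set, frame, code = standard_code(),
                              window = 21, min_len = 21,
                              offset = frameshift_offset()) {
  if (length(cds_set) == 0) stop("empty coding-sequence set")
  ids <- names(cds_set)
  if (is.null(ids)) stop("coding sequences must be named")
  blocks_wt <- vector("list", length(cds_set))
  blocks_sh <- vector("list", length(cds_set))
  kept_ids <- character(0)
  group <- integer(0)
  skipped <- data.frame(id = character(0), reason = character(0),
                        stringsAsFactors = FALSE)
  gi <- 0L
  for (k in seq_along(cds_set)) {
    id <- ids[k]
    wt <- tryCatch(wildtype_translate(cds_set[[k]], code = code),
                   error = function(e) NULL)
    if (is.null(wt) || nchar(wt) < min_len) {
      skipped <- rbind(skipped, data.frame(id = id, reason = "too_short"))
      next
    }
    sh <- tryCatch(frameshift_translate(cds_set[[k]], frame, code = code),
                   error = function(e) NULL)
    if (is.null(sh)) {
      skipped <- rbind(skipped, data.frame(id = id, reason = "shift_failed"))
      next
    }
    wt_chars <- strsplit(wt, "", fixed = TRUE)[[1]]
    sh_chars <- strsplit(sh, "", fixed = TRUE)[[1]]
    sh_mask <- sh_chars == "*"
    iq <- seq_along(sh_chars)
    ip <- iq + offset
    keep <- ip >= 1 & ip <= length(wt_chars) & !sh_mask
    if (sum(keep) < 3) {
      skipped <- rbind(skipped,
                       data.frame(id = id, reason = "insufficient_overlap"))
      next
    }
    Wwt <- window_weight_matrix(match(wt_chars, AA_ORDER),
                                rep(FALSE, length(wt_chars)), window)
    Wsh <- window_weight_matrix(match(sh_chars, AA_ORDER), sh_mask, window)
    gi <- gi + 1L
    kept_ids <- c(kept_ids, id)
    blocks_wt[[k]] <- Wwt[ip[keep], , drop = FALSE]
    blocks_sh[[k]] <- Wsh[iq[keep], , drop = FALSE]
    group <- c(group, rep(gi, sum(keep)))
  }
  structure(list(W_wt = do.call(rbind, blocks_wt),
                 W_sh = do.call(rbind, blocks_sh),
                 group = group, ids = kept_ids, skipped = skipped,
                 frame = frame, window = as.integer(window),
                 min_len = min_len, offset = offset,
                 n_input = length(cds_set)),
            class = "scan_design")
}

# per-protein Pearson R for K scales at once; V is a 20 x K value matrix.
# Returns an n_protein x K matrix (NaN where the correlation is undefined).
design_correlations <- function(design, V) {
  X <- design$W_wt %*% V
  Y <- design$W_sh %*% V
  g <- design$group
  n <- as.vector(rowsum(rep(1, length(g)), g))
  Sx <- rowsum(X, g); Sy <- rowsum(Y, g)
  Sxx <- rowsum(X * X, g); Syy <- rowsum(Y * Y, g)
  Sxy <- rowsum(X * Y, g)
  num <- Sxy - Sx * Sy / n
  den <- sqrt(pmax(Sxx - Sx^2 / n, 0) * pmax(Syy - Sy^2 / n, 0))
  out <- num / den
  out[den == 0] <- NaN
  rownames(out) <- design$ids
  out
}

#' Proteome-wide frameshift stability of one scale
#'
#' For every coding sequence: translate the wild type and the frameshifted
#' variant, build windowed property profiles of both, and correlate them
#' at the standard registration ([frameshift_offset()]). Proteins shorter
#' than `min_len`, with insufficient aligned overlap, or with an undefined
#' correlation are skipped and counted.
#'
#' @param cds_set Named character vector of validated coding sequences.
#' @param scale An `aa_scale`.
#' @param frame `"+1"` or `"-1"`.
#' @param code A `genetic_code`.
#' @param window Odd profile window (default 21 residues).
#' @param min_len Minimum wild-type length in residues (default 21, one
#'   full window).
#' @param offset Alignment offset (default [frameshift_offset()]).
#' @return A `proteome_scan`: list with `scale_name`, `frame`, `R` (named
#'   per-protein Pearson R), `median_R`, `n_proteins`, `skipped` (data
#'   frame of id/reason).
#' @export
scan_proteome <- function(cds_set, scale, frame = c("+1", "-1"),
                          code = standard_code(), window = 21, min_len = 21,
                          offset = frameshift_offset()) {
  frame <- match.arg(frame)
  design <- build_scan_design(cds_set, frame, code, window, min_len, offset)
  scan_design_scale(design, scale)
}

# scan a prebuilt design with one scale
scan_design_scale <- function(design, scale) {
  r <- design_correlations(design, matrix(as.numeric(scale), 20, 1))[, 1]
  bad <- !is.finite(r)
  skipped <- design$skipped
  if (any(bad)) {
    skipped <- rbind(skipped,
                     data.frame(id = names(r)[bad],
                                reason = "undefined_correlation",
                                stringsAsFactors = FALSE))
  }
  r <- r[!bad]
  structure(list(scale_name = scale_name(scale), frame = design$frame,
                 R = r,
                 median_R = if (length(r)) stats::median(r) else NA_real_,
                 n_proteins = length(r), skipped = skipped,
                 n_input = design$n_input),
            class = "proteome_scan")
}

#' @export
print.proteome_scan <- function(x, ...) {
  cat(sprintf("<proteome_scan> scale %s, frame %s: %d proteins, median R = %.3f (%d skipped)\n",
              x$scale_name, x$frame, x$n_proteins, x$median_R,
              nrow(x$skipped)))
  invisible(x)
}

#' Per-scale median stability and p-values over a proteome
#'
#' Computes the median per-protein frameshift correlation for every scale
#' in a library, and a p-value for each against the proteome-level
#' random-scale null: the same scan is run for `n_null` scales with
#' i.i.d. standard-normal values, the resulting medians are fitted with a
#' Gaussian, and upper-tail p-values are reported.
#'
#' @inheritParams scan_proteome
#' @param lib A `scale_library`.
#' @param n_null Number of random scales for the null (the reference
#'   analysis uses 1e5; a few hundred already give a stable Gaussian fit).
#' @param seed Optional integer seed for the null draws.
#' @param chunk Scales per matrix-product chunk (memory knob).
#' @return Data frame `name`, `category`, `median_R`, `p`, with the fitted
#'   null as attribute `"null"` and the design skip table as `"skipped"`.
#' @export
proteome_scale_pvalues <- function(cds_set, lib, frame = c("+1", "-1"),
                                   code = standard_code(), window = 21,
                                   min_len = 21,
                                   offset = frameshift_offset(),
                                   n_null = 1e5, seed = NULL, chunk = 100L) {
  frame <- match.arg(frame)
  design <- build_scan_design(cds_set, frame, code, window, min_len, offset)
  degen <- vapply(lib, is_degenerate, logical(1))
  if (any(degen)) {
    warning("dropping ", sum(degen), " degenerate scale(s)")
    lib <- lib[!degen]
  }
  med <- chunked_median_R(design, t(library_matrix(lib)), chunk)
  if (!is.null(seed)) set.seed(seed)
  null_med <- numeric(n_null)
  done <- 0L
  while (done < n_null) {
    k <- min(chunk, n_null - done)
    null_med[done + seq_len(k)] <-
      chunked_median_R(design, matrix(stats::rnorm(20 * k), 20, k), chunk)
    done <- done + k
  }
  null <- structure(list(mu = mean(null_med), sigma = stats::sd(null_med),
                         n_samples = as.integer(n_null), seed = seed,
                         empirical = NULL),
                    class = "null_distribution")
  out <- data.frame(name = names(lib),
                    category = unname(library_categories(lib)),
                    median_R = unname(med),
                    p = unname(p_value(med, null)),
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "null") <- null
  attr(out, "skipped") <- design$skipped
  out
}

chunked_median_R <- function(design, V, chunk) {
  K <- ncol(V)
  out <- numeric(K)
  done <- 0L
  while (done < K) {
    k <- min(chunk, K - done)
    r <- design_correlations(design, V[, done + seq_len(k), drop = FALSE])
    out[done + seq_len(k)] <-
      apply(r, 2, function(col) stats::median(col[is.finite(col)]))
    done <- done + k
  }
  out
}

#' mRNA purine-density versus protein nucleobase-affinity matching
#'
#' For each gene, correlates the purine-density profile of the wild-type
#' mRNA with the nucleobase-affinity profile of the encoded protein —
#' wild-type, +1- or -1-frameshifted. The mRNA-side profile is identical
#' across the three comparisons (frameshifts do not change the mRNA).
#' With conventionally signed affinity scales (lower = higher affinity),
#' matching appears as negative Pearson R.
#'
#' @inheritParams scan_proteome
#' @param affinity_scale An `aa_scale` (e.g. a guanine-affinity scale).
#' @param frame `"wt"`, `"+1"` or `"-1"`.
#' @return Named numeric vector of per-gene Pearson R values; genes whose
#'   correlation is undefined are dropped.
#' @export
mrna_protein_matching <- function(cds_set, affinity_scale,
                                  frame = c("wt", "+1", "-1"),
                                  code = standard_code(), window = 21,
                                  min_len = 21,
                                  offset = frameshift_offset()) {
  frame <- match.arg(frame)
  out <- numeric(0)
  for (id in names(cds_set)) {
    cds <- cds_set[[id]]
    r <- tryCatch({
      mrna <- purine_density_profile(cds, window = window, id = id)
      prot <- if (frame == "wt") {
        wildtype_translate(cds, code = code)
      } else {
        frameshift_translate(cds, frame, code = code)
      }
      if (nchar(prot) < min_len && frame == "wt") stop("too short")
      pp <- build_profile(prot, affinity_scale, window = window, id = id)
      profile_correlation(mrna, pp,
                          offset = if (frame == "wt") 0L else offset)
    }, error = function(e) NA_real_)
    if (is.finite(r)) out[id] <- r
  }
  out
}

#' Cross-proteome correlation of frameshift stability
#'
#' Given per-protein stability values from two proteome scans and a table
#' of ortholog id pairs, correlates the stability of orthologous proteins.
#' High values mean frameshift stability is itself conserved between the
#' two species.
#'
#' @param scan_a,scan_b `proteome_scan` objects.
#' @param pairs Two-column data frame (ids in `scan_a`, ids in `scan_b`).
#' @return List with `R`, `n_used`, `n_dropped`.
#' @export
ortholog_stability_correlation <- function(scan_a, scan_b, pairs) {
  a <- scan_a$R[as.character(pairs[[1]])]
  b <- scan_b$R[as.character(pairs[[2]])]
  ok <- is.finite(a) & is.finite(b)
  if (sum(ok) < 3) stop("fewer than 3 ortholog pairs with values in both scans")
  list(R = stats::cor(a[ok], b[ok]),
       n_used = sum(ok), n_dropped = sum(!ok))
}

#' Rank proteins by frameshift stability
#'
#' Sorts proteins by their per-protein Pearson R (descending, ties broken
#' by id so the ranking is deterministic) and extracts the top-quantile
#' subset, e.g. for export to external GO-enrichment tools.
#'
#' @param scan A `proteome_scan`.
#' @param quantile Lower bound of the retained top fraction (default 0.75,
#'   i.e. the top quartile).
#' @return List with `ranked` (data frame `id`, `R` in rank order) and
#'   `top` (character vector of top-subset ids).
#' @export
stability_ranking <- function(scan, quantile = 0.75) {
  if (scan$n_proteins == 0) stop("empty scan")
  ids <- names(scan$R)
  ord <- order(-scan$R, ids)
  ranked <- data.frame(id = ids[ord], R = unname(scan$R[ord]),
                       stringsAsFactors = FALSE)
  n_top <- ceiling(nrow(ranked) * (1 - quantile))
  list(ranked = ranked, top = ranked$id[seq_len(n_top)])
}
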