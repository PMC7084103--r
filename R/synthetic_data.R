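#' Specification of a synthetic proteome
#'
#' Defines the generative conditions for a synthetic set of coding
#' sequences used to exercise the pipeline without downloads: gene count,
#' a log-normal protein length distribution (median ~375 residues, a
#' typical proteome-like value), a GC-content target, and a codon-usage
#' table (default uniform over the 61 sense codons).
#'
#' @param n_genes Number of genes (default 500).
#' @param length_meanlog,length_sdlog Log-normal parameters of protein
#'   length in residues (defaults `log(375)` and 0.35).
#' @param gc Target GC content of the coding sequences in `(0, 1)`, or
#'   `NULL` to leave the usage table untilted.
#' @param codon_usage Optional named numeric vector of relative codon
#'   frequencies; stop codons are ignored. Default uniform.
#' @param seed Integer seed (default 1).
#' @return A `proteome_spec` list.
#' @export
proteome_spec <- function(n_genes = 500, length_meanlog = log(375),
                          length_sdlog = 0.35, gc = NULL,
                          codon_usage = NULL, seed = 1) {
  stopifnot(n_genes >= 1, length_sdlog > 0)
  if (!is.null(gc) && (gc <= 0 || gc >= 1)) stop("gc must be in (0, 1)")
  structure(list(n_genes = as.integer(n_genes),
                 length_meanlog = length_meanlog,
                 length_sdlog = length_sdlog,
                 gc = gc, codon_usage = codon_usage,
                 seed = as.integer(seed)),
            class = "proteome_spec")
}

# exponentially tilt codon probabilities so the expected GC fraction hits
# the target: w_c \propto u_c * exp(theta * gc_count_c)
tilt_codon_usage <- function(usage, gc_target) {
  gc_count <- vapply(names(usage), function(cd) {
    sum(strsplit(cd, "", fixed = TRUE)[[1]] %in% c("G", "C"))
  }, numeric(1))
  gc_of <- function(theta) {
    w <- usage * exp(theta * gc_count)
    sum(w * gc_count) / (3 * sum(w)) - gc_target
  }
  sol <- tryCatch(stats::uniroot(gc_of, c(-60, 60), tol = 1e-12),
                  error = function(e) {
                    stop("infeasible GC target ", gc_target,
                         " for the given codon-usage table")
                  })
  w <- usage * exp(sol$root * gc_count)
  w / sum(w)
}

#' Generate a synthetic proteome
#'
#' Draws protein lengths from the spec's log-normal, then samples sense
#' codons independently from the (GC-tilted) usage table; the first codon
#' is ATG and a stop codon terminates each gene, so wild-type proteins
#' contain no internal stop. The generator is fully seeded.
#'
#' @param spec A [proteome_spec()].
#' @param code A `genetic_code`.
#' @return List with `cds` (named nucleotide vector), `protein` (named
#'   wild-type amino-acid vector), and `spec`.
#' @export
generate_proteome <- function(spec, code = standard_code()) {
  set.seed(spec$seed)
  sense <- names(code$codon_to_aa)[code$codon_to_aa != "*"]
  stops <- stop_codons(code)
  usage <- spec$codon_usage
  if (is.null(usage)) {
    usage <- stats::setNames(rep(1, length(sense)), sense)
  }
  usage <- usage[names(usage) %in% sense]
  if (length(usage) == 0) stop("codon-usage table has no sense codons")
  usage <- usage / sum(usage)
  if (!is.null(spec$gc)) usage <- tilt_codon_usage(usage, spec$gc)
  lens <- pmax(3L, as.integer(round(stats::rlnorm(spec$n_genes,
                                                  spec$length_meanlog,
                                                  spec$length_sdlog))))
  ids <- sprintf("SYN%04d", seq_len(spec$n_genes))
  cds <- character(spec$n_genes)
  for (g in seq_len(spec$n_genes)) {
    body <- sample(names(usage), lens[g] - 1L, replace = TRUE, prob = usage)
    cds[g] <- paste(c("ATG", body, sample(stops, 1L)), collapse = "")
  }
  names(cds) <- ids
  protein <- vapply(cds, wildtype_translate, character(1), code = code)
  list(cds = cds, protein = protein, spec = spec)
}

#' Specification of a synthetic scale library
#'
#' Emulates the category/cluster structure of a real property-scale
#' library: categories of mutually correlated scales (like the
#' hydrophobicity cluster) plus categories planted as frameshift-stable,
#' constructed by perturbing an optimally frameshift-stable scale with
#' Gaussian noise so their code-level R sits between the optimum and 0.
#'
#' @param n_categories Total number of categories (default 5).
#' @param scales_per_category Scales in each category (default 20).
#' @param rho Within-category correlation of the non-planted categories,
#'   in `[0, 1)` (default 0.5).
#' @param n_stable Number of planted frameshift-stable categories
#'   (default 1; must be < `n_categories`).
#' @param stable_noise_sd Standard deviation of the perturbation added to
#'   the (unit-norm) optimized scale (default 0.1; the optimized scale's
#'   values have root-mean-square 1/sqrt(20) ~ 0.22).
#' @param seed Integer seed (default 1).
#' @return A `scale_library_spec` list.
#' @export
scale_library_spec <- function(n_categories = 5, scales_per_category = 20,
                               rho = 0.5, n_stable = 1,
                               stable_noise_sd = 0.1, seed = 1) {
  stopifnot(n_categories >= 2, scales_per_category >= 1,
            rho >= 0, rho < 1, n_stable >= 0, n_stable < n_categories,
            stable_noise_sd > 0)
  structure(list(n_categories = as.integer(n_categories),
                 scales_per_category = as.integer(scales_per_category),
                 rho = rho, n_stable = as.integer(n_stable),
                 stable_noise_sd = stable_noise_sd,
                 seed = as.integer(seed)),
            class = "scale_library_spec")
}

#' Generate a synthetic scale library
#'
#' Planted stable categories (`"stable"`, `"stable2"`, ...) are the
#' optimized frameshift-stable scale for `pairs` plus i.i.d. Gaussian
#' noise; background categories (`"bg1"`, `"bg2"`, ...) are equicorrelated
#' Gaussian draws with within-category correlation `rho`.
#'
#' @param spec A [scale_library_spec()].
#' @param pairs A `frameshift_pairs` object (used to derive the optimized
#'   scale the stable categories are built from).
#' @param optimal An optional precomputed result of [optimize_scale()] on
#'   `pairs`; computed internally (50 starts) when `NULL`.
#' @return A `scale_library`.
#' @export
generate_scale_library <- function(spec, pairs, optimal = NULL) {
  set.seed(spec$seed)
  if (is.null(optimal) && spec$n_stable > 0) {
    optimal <- optimize_scale(pairs, n_starts = 50)
  }
  scales <- list()
  idx <- 0L
  for (cc in seq_len(spec$n_categories)) {
    stable <- cc <= spec$n_stable
    cat_name <- if (stable) {
      if (cc == 1) "stable" else paste0("stable", cc)
    } else {
      paste0("bg", cc - spec$n_stable)
    }
    z_cat <- stats::rnorm(20)
    for (s in seq_len(spec$scales_per_category)) {
      idx <- idx + 1L
      v <- if (stable) {
        as.numeric(optimal$scale) + stats::rnorm(20, sd = spec$stable_noise_sd)
      } else {
        sqrt(spec$rho) * z_cat + sqrt(1 - spec$rho) * stats::rnorm(20)
      }
      scales[[idx]] <- aa_scale(v, name = sprintf("SYN_%s_%02d", cat_name, s),
                                category = cat_name)
    }
  }
  scale_library(scales, provenance = "synthetic")
}

#' Generate synthetic per-residue disorder profiles
#'
#' Stand-in for the output of an external disorder predictor: smoothed
#' Gaussian noise passed through a logistic squash, giving values in
#' `(0, 1)` with tunable autocorrelation.
#'
#' @param proteins Named character vector of amino-acid sequences.
#' @param smoothness Moving-average window of the underlying noise
#'   (higher = smoother profiles; default 11).
#' @param seed Integer seed.
#' @return Named list of numeric per-residue vectors in `(0, 1)`.
#' @export
generate_disorder_profiles <- function(proteins, smoothness = 11, seed = 1) {
  if (length(proteins) == 0) stop("no proteins supplied")
  set.seed(seed)
  w <- max(1L, as.integer(smoothness))
  if (w %% 2 == 0) w <- w + 1L
  out <- lapply(proteins, function(aa) {
    L <- nchar(aa)
    z <- stats::rnorm(L + w - 1L)
    sm <- window_mean(z, rep(FALSE, length(z)), w)
    sm <- sm[(w - 1L) %/% 2L + seq_len(L)]
    stats::plogis(sm * sqrt(w) * 1.5)
  })
  names(out) <- names(proteins)
  out
}
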