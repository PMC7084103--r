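# accumulate y into a length-20 vector by amino-acid index
acc20 <- function(y, idx) {
  out <- numeric(20)
  tmp <- rowsum(y, idx)
  out[as.integer(rownames(tmp))] <- tmp
  out
}

# frameshift-stability objective and its analytic gradient over the 20 free
# scale values; returns closures used by optim()
stability_objective <- function(pairs) {
  idx <- pair_indices(pairs)
  oi <- idx$original; si <- idx$shifted
  w <- idx$weight / sum(idx$weight)
  fn <- function(x) {
    a <- x[oi]; b <- x[si]
    at <- a - sum(w * a); bt <- b - sum(w * b)
    saa <- sum(w * at^2); sbb <- sum(w * bt^2)
    if (saa <= 0 || sbb <= 0) return(0)
    -sum(w * at * bt) / sqrt(saa * sbb)
  }
  gr <- function(x) {
    a <- x[oi]; b <- x[si]
    at <- a - sum(w * a); bt <- b - sum(w * b)
    saa <- sum(w * at^2); sbb <- sum(w * bt^2)
    if (saa <= 0 || sbb <= 0) return(numeric(20))
    sab <- sum(w * at * bt)
    r <- sab / sqrt(saa * sbb)
    d_sab <- acc20(w * bt, oi) + acc20(w * at, si)
    d_saa <- acc20(w * at, oi)
    d_sbb <- acc20(w * bt, si)
    -(d_sab - r * (sqrt(sbb / saa) * d_saa + sqrt(saa / sbb) * d_sbb)) /
      sqrt(saa * sbb)
  }
  list(fn = fn, gr = gr)
}

# BFGS run followed by a polishing restart from the found point: the
# objective is very flat along the optimal manifold, and the restart pulls
# near-converged solutions tightly onto it
local_maximum <- function(obj, x0, tol) {
  res <- stats::optim(x0, obj$fn, obj$gr, method = "BFGS",
                      control = list(maxit = 1000, reltol = tol))
  stats::optim(res$par, obj$fn, obj$gr, method = "BFGS",
               control = list(maxit = 1000, reltol = 1e-14))
}

#' Derive a scale computationally optimized for frameshift stability
#'
#' Maximizes the frameshift Pearson correlation ([ugc_correlation()]) over
#' all real-valued 20-amino-acid scales by multi-start local optimization
#' (BFGS with analytic gradient; starts drawn i.i.d. standard normal).
#' Because Pearson R is invariant under positive affine maps of the scale,
#' the returned solution is normalized to zero mean and unit norm.
#'
#' For the standard code the attainable optimum is around 0.56, well above
#' the ~0.4 reached by the best experimentally derived scales.
#'
#' @param pairs A `frameshift_pairs` object.
#' @param n_starts Number of independent random starts (>= 1; 100 is ample
#'   for the standard code — almost every start reaches the optimum).
#' @param seed Optional integer seed.
#' @param tol Convergence tolerance on the objective.
#' @return List with `scale` (normalized `aa_scale`), `R` (best objective),
#'   and `start_R` (objective attained from each start).
#' @export
optimize_scale <- function(pairs, n_starts = 100, seed = NULL, tol = 1e-10) {
  if (n_starts < 1) stop("n_starts must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  obj <- stability_objective(pairs)
  best <- NULL
  best_val <- Inf
  start_R <- numeric(n_starts)
  for (k in seq_len(n_starts)) {
    res <- local_maximum(obj, stats::rnorm(20), tol)
    start_R[k] <- -res$value
    if (res$value < best_val) {
      best_val <- res$value
      best <- res$par
    }
  }
  s <- normalize_scale(aa_scale(best, name = "optimal_frameshift",
                                category = "other"))
  list(scale = s, R = -best_val, start_R = start_R)
}

#' Collect a set of optimally frameshift-stable scales
#'
#' Runs independent single-start optimizations and retains every solution
#' whose objective is within `retain_tol` of the best found. The solutions
#' are not a single point: they form a continuum which, after
#' normalization, is essentially two-dimensional (see [fit_pca()]). By
#' default the set is closed under sign inversion (if a scale is optimal
#' so is its negation), which centers it exactly at the origin.
#'
#' @param pairs A `frameshift_pairs` object.
#' @param n_solutions Number of independent optimizations (>= 10).
#' @param seed Optional integer seed.
#' @param retain_tol Keep solutions with R within this distance of the
#'   maximum (default 0.01).
#' @param include_negations Append the negation of every retained solution
#'   (default `TRUE`).
#' @return An `optimal_scale_set`: list with `scales` (matrix, one row per
#'   solution, columns the 20 amino acids, each row zero-mean unit-norm),
#'   `R` (objective per row), `R_best`, `retain_tol`, `seed`.
#' @export
collect_optimal_set <- function(pairs, n_solutions = 100, seed = NULL,
                                retain_tol = 0.01, include_negations = TRUE) {
  if (n_solutions < 10) stop("n_solutions must be >= 10")
  if (!is.null(seed)) set.seed(seed)
  obj <- stability_objective(pairs)
  sols <- matrix(NA_real_, n_solutions, 20L)
  vals <- numeric(n_solutions)
  for (k in seq_len(n_solutions)) {
    res <- local_maximum(obj, stats::rnorm(20), 1e-12)
    v <- res$par - mean(res$par)
    nv <- sqrt(sum(v^2))
    if (nv == 0) next
    sols[k, ] <- v / nv
    vals[k] <- -res$value
  }
  ok <- is.finite(vals) & !is.na(sols[, 1])
  sols <- sols[ok, , drop = FALSE]
  vals <- vals[ok]
  best <- max(vals)
  keep <- vals >= best - retain_tol
  sols <- sols[keep, , drop = FALSE]
  vals <- vals[keep]
  if (include_negations) {
    sols <- rbind(sols, -sols)
    vals <- c(vals, vals)
  }
  colnames(sols) <- AA_ORDER
  structure(list(scales = sols, R = vals, R_best = best,
                 retain_tol = retain_tol, seed = seed),
            class = "optimal_scale_set")
}

#' @export
print.optimal_scale_set <- function(x, ...) {
  cat(sprintf("<optimal_scale_set> %d solutions, best R = %.4f (tol %.3g)\n",
              nrow(x$scales), x$R_best, x$retain_tol))
  invisible(x)
}

#' Principal-component geometry of the optimal-scale set
#'
#' PCA of the normalized optimal solutions. For the standard code the
#' first two components capture essentially all of the variance: the
#' optimal scales lie on a circle in the (PC1, PC2) plane. The loadings
#' give the contribution of each amino acid to the two components.
#'
#' @param set An `optimal_scale_set` with >= 10 solutions.
#' @param n_components Number of components to retain (default 2).
#' @return A `scale_space_pca`: list with `rotation` (20 x k loadings),
#'   `center`, `explained_variance_ratio` (all 20 components).
#' @export
fit_pca <- function(set, n_components = 2) {
  if (nrow(set$scales) < 10) stop("need >= 10 solutions for a stable PCA")
  if (n_components > min(dim(set$scales))) {
    stop("more components requested than the solution set supports")
  }
  pc <- stats::prcomp(set$scales, center = TRUE, scale. = FALSE)
  evr <- pc$sdev^2 / sum(pc$sdev^2)
  structure(list(rotation = pc$rotation[, seq_len(n_components), drop = FALSE],
                 center = pc$center,
                 explained_variance_ratio = evr),
            class = "scale_space_pca")
}

#' @export
print.scale_space_pca <- function(x, ...) {
  k <- ncol(x$rotation)
  cat(sprintf("<scale_space_pca> %d components; explained variance: %s\n",
              k, paste(sprintf("%.3f", x$explained_variance_ratio[seq_len(k)]),
                       collapse = ", ")))
  invisible(x)
}

#' Project a scale into the optimal-scale PCA space
#'
#' Normalizes the scale (zero mean, unit norm) and projects it onto the
#' retained components. Members of the optimal set land on the unit circle;
#' experimentally derived frameshift-stable scales (hydrophobicity above
#' all) cluster near that circle, and inverting a scale maps its projection
#' to the antipode.
#'
#' @param s An `aa_scale` (non-degenerate).
#' @param pca A `scale_space_pca`.
#' @return Named numeric vector of projected coordinates (`PC1`, `PC2`, ...).
#' @export
project_scale <- function(s, pca) {
  v <- as.numeric(normalize_scale(s))
  drop(crossprod(pca$rotation, v - pca$center))
}

#' Project every scale of a library
#'
#' @param lib A `scale_library`.
#' @param pca A `scale_space_pca`.
#' @return Data frame: `name`, `category`, one column per component, and
#'   `radius` (Euclidean norm of the projection).
#' @export
project_library <- function(lib, pca) {
  coords <- t(vapply(lib, project_scale, numeric(ncol(pca$rotation)),
                     pca = pca))
  data.frame(name = names(lib),
             category = unname(library_categories(lib)),
             coords,
             radius = sqrt(rowSums(coords^2)),
             stringsAsFactors = FALSE, row.names = NULL)
}
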