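#' Full eigendecomposition of a symmetric dFC slice
#'
#' Spectrum sorted descending by eigenvalue; the decomposition satisfies
#' `V %*% diag(lambda) %*% t(V) = dfc_slice` to numerical precision.
#'
#' @param dfc_slice symmetric N x N numeric matrix (asymmetry beyond `tol`
#'   is an error).
#' @param tol symmetry tolerance, default `1e-10` relative to the largest
#'   absolute entry.
#' @return List with `values` (descending eigenvalues) and `vectors`
#'   (orthonormal columns).
#' @export
eigendecompose <- function(dfc_slice, tol = 1e-10) {
  dfc_slice <- as.matrix(dfc_slice)
  if (nrow(dfc_slice) != ncol(dfc_slice))
    stop("dfc slice must be square", call. = FALSE)
  asym <- max(abs(dfc_slice - t(dfc_slice)))
  scale <- max(abs(dfc_slice), 1e-300)
  if (asym > tol * max(1, scale))
    stop(sprintf("matrix asymmetric beyond tolerance (max |A - t(A)| = %.3g)",
                 asym), call. = FALSE)
  e <- eigen((dfc_slice + t(dfc_slice)) / 2, symmetric = TRUE)
  list(values = e$values, vectors = e$vectors)
}

#' Dominant k-dimensional subspace of a dFC slice
#'
#' Takes the `k` leading eigenvectors of a symmetric connectivity slice as a
#' reduced representation `D_t` of the dominant dFC pattern. With the default
#' `scaling = "sqrt_eigenvalue"` each column is scaled by
#' \eqn{\sqrt{|\lambda_i|}}, so `components %*% t(components)` is the best
#' rank-k reconstruction of the slice (up to eigenvalue signs); with
#' `scaling = "unit"` the columns are the orthonormal eigenvectors
#' themselves. Either choice spans the same subspace, which is all the
#' principal-angle metric sees.
#'
#' The default `k = 3` follows the observation that for phase-coherence dFC
#' the three leading eigenvectors always capture at least 99% of the total
#' variance (a phase-coherence slice has rank at most 2, so this holds
#' exactly up to floating point).
#'
#' Eigenvector sign is fixed so each column's largest-magnitude entry is
#' positive, making runs reproducible; sign does not affect principal
#' angles.
#'
#' @param dfc_slice symmetric N x N matrix.
#' @param k number of leading components, default 3.
#' @param scaling `"sqrt_eigenvalue"` (default) or `"unit"`.
#' @param sign_convention `"max_abs_positive"` (default) or `"none"`.
#' @return An object of class `"dominant_subspace"`: list with `components`
#'   (N x k), `eigenvalues_k`, `variance_fraction`
#'   (\eqn{\sum_{i\le k}|\lambda_i| / \sum_i |\lambda_i|}), `k`, `timepoint`
#'   (NA unless set by [subspace_trajectory()]), `null_flags` (logical, TRUE
#'   for columns with \eqn{|\lambda| < 10^{-12}\lambda_1} that are numerically
#'   null and must be regularized downstream).
#' @export
dominant_subspace <- function(dfc_slice, k = 3,
                              scaling = c("sqrt_eigenvalue", "unit"),
                              sign_convention = c("max_abs_positive", "none")) {
  scaling <- match.arg(scaling)
  sign_convention <- match.arg(sign_convention)
  e <- eigendecompose(dfc_slice)
  N <- length(e$values)
  if (k < 1 || k > N)
    stop(sprintf("k must be in [1, %d]", N), call. = FALSE)
  lam <- e$values[seq_len(k)]
  V <- e$vectors[, seq_len(k), drop = FALSE]
  if (sign_convention == "max_abs_positive") {
    for (i in seq_len(k)) {
      j <- which.max(abs(V[, i]))
      if (V[j, i] < 0) V[, i] <- -V[, i]
    }
  }
  if (scaling == "sqrt_eigenvalue")
    V <- V * rep(sqrt(abs(lam)), each = N)
  vf <- sum(abs(lam)) / sum(abs(e$values))
  structure(
    list(components = V, eigenvalues_k = lam, variance_fraction = vf,
         k = as.integer(k), timepoint = NA_integer_,
         null_flags = abs(lam) < 1e-12 * max(abs(e$values[1]), 1e-300),
         scaling = scaling),
    class = "dominant_subspace")
}

#' @export
print.dominant_subspace <- function(x, ...) {
  cat(sprintf(
    "<dominant_subspace> N = %d, k = %d, variance fraction = %.6f%s\n",
    nrow(x$components), x$k, x$variance_fraction,
    if (any(x$null_flags)) sprintf(" (%d numerically null column(s))",
                                   sum(x$null_flags)) else ""))
  invisible(x)
}

#' Dominant-subspace trajectory of a dFC tensor
#'
#' Applies [dominant_subspace()] to every timepoint slice, returning one
#' reduced pattern `D_t` per timepoint plus per-timepoint variance fractions
#' for QC.
#'
#' @param dfc a `"dfc_tensor"` from [phase_coherence_dfc()] or
#'   [sliding_window_dfc()].
#' @param k,scaling,sign_convention passed to [dominant_subspace()].
#' @return An object of class `"subspace_trajectory"`: list with `subspaces`
#'   (list of `"dominant_subspace"`, `timepoint` set), `variance_fractions`
#'   (numeric vector), `k`, `n_regions`, `region_labels`.
#' @export
subspace_trajectory <- function(dfc, k = 3,
                                scaling = c("sqrt_eigenvalue", "unit"),
                                sign_convention = c("max_abs_positive", "none")) {
  stopifnot(inherits(dfc, "dfc_tensor"))
  scaling <- match.arg(scaling)
  sign_convention <- match.arg(sign_convention)
  TT <- dim(dfc$values)[3]
  subs <- vector("list", TT)
  for (t in seq_len(TT)) {
    s <- dominant_subspace(dfc$values[, , t], k = k, scaling = scaling,
                           sign_convention = sign_convention)
    s$timepoint <- t
    subs[[t]] <- s
  }
  structure(
    list(subspaces = subs,
         variance_fractions = vapply(subs, `[[`, numeric(1),
                                     "variance_fraction"),
         k = as.integer(k), n_regions = dim(dfc$values)[1],
         region_labels = dfc$region_labels),
    class = "subspace_trajectory")
}

#' @export
print.subspace_trajectory <- function(x, ...) {
  cat(sprintf(
    "<subspace_trajectory> %d timepoints, N = %d, k = %d, min variance fraction = %.6f\n",
    length(x$subspaces), x$n_regions, x$k, min(x$variance_fractions)))
  invisible(x)
}

#' @export
length.subspace_trajectory <- function(x) length(x$subspaces)
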