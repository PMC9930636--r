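#' Principal angle(s) between two dominant dFC subspaces
#'
#' Both component matrices are orthonormalized by SVD; directions whose
#' singular value falls below `rank_tol` times the largest are treated as
#' numerically null and dropped (with the default `sqrt_eigenvalue` scaling
#' this discards the near-zero third eigendirection of an exactly rank-2
#' phase-coherence slice rather than comparing numerical noise). The
#' principal angles are the arccosines of the singular values of the
#' cross-Gram matrix of the two orthonormal bases, clipped to `[0, 1]`, and
#' range from 0 (identical spans) to \eqn{\pi/2} (orthogonal spans).
#'
#' "The" principal angle reported in the stability matrix is the LARGEST
#' one, matching the angle-between-subspaces convention whose value spans
#' the full \eqn{(0, \pi/2]} range.
#'
#' @param Da,Db `"dominant_subspace"` objects or plain N x k matrices with
#'   the same N.
#' @param which `"largest"` (default), `"smallest"` or `"all"`.
#' @param rank_tol relative singular-value cutoff for the orthonormalization
#'   (default `1e-6`).
#' @return A scalar angle in radians, or a descending vector of all angles
#'   for `which = "all"`.
#' @examples
#' A <- diag(6)[, 1:2]
#' B <- diag(6)[, 3:4]
#' principal_angle(A, B)  # pi / 2
#' @export
principal_angle <- function(Da, Db, which = c("largest", "smallest", "all"),
                            rank_tol = 1e-6) {
  which <- match.arg(which)
  Qa <- orthonormal_basis(subspace_components(Da), rank_tol)
  Qb <- orthonormal_basis(subspace_components(Db), rank_tol)
  if (nrow(Qa) != nrow(Qb))
    stop("subspaces live in different ambient dimensions", call. = FALSE)
  ang <- principal_angles_from_bases(Qa, Qb)
  switch(which,
         largest = ang[1],
         smallest = ang[length(ang)],
         all = ang)
}

# Angles between orthonormal bases, descending. acos of the cross-Gram
# singular values loses half the working precision near zero, so small
# angles are recomputed from the sine form (SVD of Qb - Qa Qa' Qb).
principal_angles_from_bases <- function(Qa, Qb) {
  G <- crossprod(Qa, Qb)
  sv <- pmin(pmax(svd(G, nu = 0, nv = 0)$d, -1), 1)
  ang <- sort(acos(sv), decreasing = TRUE)
  if (ncol(Qa) == ncol(Qb) && any(ang < pi / 4)) {
    S <- svd(Qb - Qa %*% G, nu = 0, nv = 0)$d
    ang_sin <- sort(asin(pmin(pmax(S, 0), 1)), decreasing = TRUE)
    small <- ang < pi / 4
    ang[small] <- ang_sin[small]
  }
  ang
}

subspace_components <- function(x) {
  if (inherits(x, "dominant_subspace")) x$components else as.matrix(x)
}

orthonormal_basis <- function(M, rank_tol = 1e-6) {
  s <- svd(M)
  if (s$d[1] <= 0 || !is.finite(s$d[1]))
    stop("degenerate subspace: all columns numerically zero", call. = FALSE)
  keep <- s$d > rank_tol * s$d[1]
  if (!any(keep))
    stop("degenerate subspace: all columns numerically zero", call. = FALSE)
  s$u[, keep, drop = FALSE]
}

#' Principal-angle temporal stability matrix
#'
#' The (t_x, t_y) entry is the (largest) principal angle between the dominant
#' dFC subspaces at timepoints t_x and t_y. Low angles over extended blocks
#' of time indicate a stable dominant connectivity configuration; values
#' range from 0 to \eqn{\pi/2}.
#'
#' @param trajectory a `"subspace_trajectory"`.
#' @param rank_tol passed to [principal_angle()].
#' @return A `"stability_matrix"`: list with `values` (T' x T' symmetric,
#'   zero diagonal), `metric = "angle"`, `theoretical_range = c(0, pi/2)`.
#' @export
angle_stability_matrix <- function(trajectory, rank_tol = 1e-6) {
  stopifnot(inherits(trajectory, "subspace_trajectory"))
  TT <- length(trajectory$subspaces)
  if (TT < 2) stop("need at least 2 subspaces", call. = FALSE)
  Q <- lapply(trajectory$subspaces, function(s)
    orthonormal_basis(s$components, rank_tol))
  M <- matrix(0, TT, TT)
  for (a in seq_len(TT - 1)) {
    Qa <- Q[[a]]
    for (b in (a + 1):TT) {
      sv <- svd(crossprod(Qa, Q[[b]]), nu = 0, nv = 0)$d
      M[a, b] <- M[b, a] <- acos(min(pmin(pmax(sv, -1), 1)))
    }
  }
  stability_matrix(M, metric = "angle")
}

stability_matrix <- function(values, metric = c("angle", "mahalanobis"),
                             mode = NULL) {
  metric <- match.arg(metric)
  structure(
    list(values = values, metric = metric, mode = mode,
         theoretical_range = if (metric == "angle") c(0, pi / 2)
                             else c(0, Inf)),
    class = "stability_matrix")
}

#' @export
print.stability_matrix <- function(x, ...) {
  cat(sprintf("<stability_matrix> metric = %s%s, %d x %d, range [%.4g, %.4g]\n",
              x$metric, if (!is.null(x$mode)) paste0("/", x$mode) else "",
              nrow(x$values), ncol(x$values), min(x$values), max(x$values)))
  invisible(x)
}

#' @export
dim.stability_matrix <- function(x) dim(x$values)

#' Per-region Mahalanobis stability profile between two subspaces
#'
#' Treats the N rows of each N x k component matrix as N points in k-space.
#' The covariance `C` is estimated from the mean-centred rows of `Da` and
#' regularized as \eqn{C + \epsilon\,\mathrm{tr}(C)/k\, I} (mandatory:
#' phase-coherence slices are rank-2, so the k = 3 component direction is
#' numerically null and `C` would otherwise be singular).
#'
#' Two reading of the distance are supported:
#' \describe{
#'   \item{`rowpair` (default)}{\eqn{M_p = \sqrt{(d_p^a - d_p^b)^T C^{-1}
#'     (d_p^a - d_p^b)}} — the literal matched-row difference form.}
#'   \item{`distribution`}{\eqn{M_p = \sqrt{(d_p^b - \mu_a)^T C^{-1}
#'     (d_p^b - \mu_a)}} — each region of `Db` (point P) measured against
#'     the point cloud of `Da` (distribution D).}
#' }
#'
#' @param Da,Db `"dominant_subspace"` objects or N x k matrices.
#' @param mode `"rowpair"` (default) or `"distribution"`.
#' @param epsilon_scale regularization \eqn{\epsilon}, default `1e-8`.
#' @return A `"stability_profile"`: list with `per_roi_distance` (length N,
#'   nonnegative), `mode`, `timepoint_pair`.
#' @export
mahalanobis_profile <- function(Da, Db, mode = c("rowpair", "distribution"),
                                epsilon_scale = 1e-8) {
  mode <- match.arg(mode)
  A <- subspace_components(Da)
  B <- subspace_components(Db)
  if (!all(dim(A) == dim(B)))
    stop("subspaces must share N and k", call. = FALSE)
  k <- ncol(A)
  mu <- colMeans(A)
  Ac <- sweep(A, 2, mu)
  C <- crossprod(Ac) / (nrow(A) - 1)
  C <- C + diag(epsilon_scale * sum(diag(C)) / k, k)
  Ci <- tryCatch(solve(C), error = function(e) NULL)
  if (is.null(Ci) || !all(is.finite(Ci)))
    stop("covariance singular even after regularization (identical rows?)",
         call. = FALSE)
  D <- if (mode == "rowpair") A - B else sweep(B, 2, mu)
  d2 <- rowSums((D %*% Ci) * D)
  tp <- c(subspace_timepoint(Da), subspace_timepoint(Db))
  structure(
    list(per_roi_distance = sqrt(pmax(d2, 0)), mode = mode,
         timepoint_pair = tp),
    class = "stability_profile")
}

subspace_timepoint <- function(x) {
  if (inherits(x, "dominant_subspace")) x$timepoint else NA_integer_
}

#' @export
print.stability_profile <- function(x, ...) {
  cat(sprintf(
    "<stability_profile> mode = %s, %d regions, mean distance = %.4g\n",
    x$mode, length(x$per_roi_distance), mean(x$per_roi_distance)))
  invisible(x)
}

#' Mahalanobis temporal stability matrix
#'
#' The (t_x, t_y) entry is the per-region Mahalanobis distance of
#' [mahalanobis_profile()] averaged across all brain parcels. The raw
#' definition is asymmetric (the covariance comes from the first subspace),
#' so the matrix is symmetrized as `(M(a,b) + M(b,a)) / 2`; the diagonal is
#' exactly zero in `rowpair` mode.
#'
#' @param trajectory a `"subspace_trajectory"`.
#' @param mode,epsilon_scale passed to [mahalanobis_profile()].
#' @return A `"stability_matrix"` with `metric = "mahalanobis"`.
#' @export
mahalanobis_stability_matrix <- function(trajectory,
                                         mode = c("rowpair", "distribution"),
                                         epsilon_scale = 1e-8) {
  stopifnot(inherits(trajectory, "subspace_trajectory"))
  mode <- match.arg(mode)
  subs <- trajectory$subspaces
  TT <- length(subs)
  if (TT < 2) stop("need at least 2 subspaces", call. = FALSE)
  k <- trajectory$k
  comp <- lapply(subs, `[[`, "components")
  mus <- lapply(comp, colMeans)
  Cinv <- vector("list", TT)
  for (t in seq_len(TT)) {
    Ac <- sweep(comp[[t]], 2, mus[[t]])
    C <- crossprod(Ac) / (nrow(Ac) - 1)
    C <- C + diag(epsilon_scale * sum(diag(C)) / k, k)
    Cinv[[t]] <- solve(C)
  }
  raw <- matrix(0, TT, TT)
  for (a in seq_len(TT)) {
    Ci <- Cinv[[a]]
    for (b in seq_len(TT)) {
      if (a == b && mode == "rowpair") next
      D <- if (mode == "rowpair") comp[[a]] - comp[[b]]
           else sweep(comp[[b]], 2, mus[[a]])
      raw[a, b] <- mean(sqrt(pmax(rowSums((D %*% Ci) * D), 0)))
    }
  }
  stability_matrix((raw + t(raw)) / 2, metric = "mahalanobis", mode = mode)
}

#' Short- and long-range spatial stability profiles
#'
#' Convenience extraction of the per-region Mahalanobis profiles for one
#' nearby and one distant timepoint pair, the empirical probes of short-
#' versus long-range temporal stability (defaults: t = 15 vs 20, i.e. 5
#' samples apart, and t = 15 vs 150, 135 samples apart).
#'
#' @param trajectory a `"subspace_trajectory"`.
#' @param near_pair,far_pair length-2 vectors of 1-based timepoints.
#' @param mode,epsilon_scale passed to [mahalanobis_profile()].
#' @return List with elements `near` and `far`, each a
#'   `"stability_profile"`.
#' @export
short_long_range_profiles <- function(trajectory, near_pair = c(15, 20),
                                      far_pair = c(15, 150),
                                      mode = c("rowpair", "distribution"),
                                      epsilon_scale = 1e-8) {
  stopifnot(inherits(trajectory, "subspace_trajectory"))
  mode <- match.arg(mode)
  TT <- length(trajectory$subspaces)
  for (p in list(near_pair, far_pair))
    if (any(p < 1 | p > TT))
      stop(sprintf("timepoint pair (%d, %d) outside [1, %d]",
                   p[1], p[2], TT), call. = FALSE)
  prof <- function(p) mahalanobis_profile(trajectory$subspaces[[p[1]]],
                                          trajectory$subspaces[[p[2]]],
                                          mode = mode,
                                          epsilon_scale = epsilon_scale)
  list(near = prof(near_pair), far = prof(far_pair))
}
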