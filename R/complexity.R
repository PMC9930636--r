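#' Histogram entropy of a temporal stability matrix
#'
#' All entries of the matrix (diagonal included) are mapped to `[0, 1]`,
#' binned into `bins` equal-width bins, and the Shannon entropy
#' \eqn{E = -\sum_b p_b \log_2 p_b} of the normalized counts is returned
#' (base 2, 256 bins by default, mirroring the unit-range image-histogram
#' convention). Higher entropy means a richer mix of distance values, i.e.
#' a less uniformly stable time-by-time structure.
#'
#' Range mapping: angle matrices use the fixed theoretical range
#' \eqn{[0, \pi/2]} by default (comparable across subjects); Mahalanobis
#' matrices, which have no finite theoretical bound, use their own min-max
#' by default. Both policies are selectable.
#'
#' @param mat a `"stability_matrix"` or a plain finite numeric matrix.
#' @param bins number of histogram bins, default 256.
#' @param range_policy `"auto"` (default: `fixed_theoretical` for angle,
#'   `minmax` otherwise), `"fixed_theoretical"` or `"minmax"`.
#' @return An `"entropy_result"`: list with `E` (bits), `p` (normalized
#'   counts, length `bins`), `bins`, `range_policy`.
#' @examples
#' m <- matrix(runif(100, 0, pi / 2), 10)
#' stability_entropy(stability_matrix_from_values(m, "angle"))$E
#' @export
stability_entropy <- function(mat, bins = 256,
                              range_policy = c("auto", "fixed_theoretical",
                                               "minmax")) {
  range_policy <- match.arg(range_policy)
  metric <- if (inherits(mat, "stability_matrix")) mat$metric else NULL
  theo <- if (inherits(mat, "stability_matrix")) mat$theoretical_range
          else NULL
  x <- if (inherits(mat, "stability_matrix")) mat$values else as.matrix(mat)
  if (!all(is.finite(x)))
    stop("stability matrix has non-finite entries", call. = FALSE)
  if (range_policy == "auto")
    range_policy <- if (identical(metric, "angle")) "fixed_theoretical"
                    else "minmax"
  if (range_policy == "fixed_theoretical") {
    if (is.null(theo) || !is.finite(theo[2]))
      stop("no finite theoretical range for this matrix; use 'minmax'",
           call. = FALSE)
    lo <- theo[1]; hi <- theo[2]
  } else {
    lo <- min(x); hi <- max(x)
  }
  v <- as.vector(x)
  if (hi <= lo) {
    # constant matrix: single occupied bin, entropy 0
    warning("degenerate value range; entropy is 0", call. = FALSE)
    p <- numeric(bins); p[1] <- 1
    return(structure(list(E = 0, p = p, bins = as.integer(bins),
                          range_policy = range_policy),
                     class = "entropy_result"))
  }
  u <- (v - lo) / (hi - lo)
  u <- pmin(pmax(u, 0), 1)
  idx <- pmin(floor(u * bins) + 1L, bins)   # value 1 falls in last bin
  counts <- tabulate(idx, nbins = bins)
  p <- counts / sum(counts)
  nz <- p[p > 0]
  structure(list(E = -sum(nz * log2(nz)), p = p, bins = as.integer(bins),
                 range_policy = range_policy),
            class = "entropy_result")
}

#' @export
print.entropy_result <- function(x, ...) {
  cat(sprintf("<entropy_result> E = %.4f bits (%d bins, %s range)\n",
              x$E, x$bins, x$range_policy))
  invisible(x)
}

#' Wrap a plain matrix as a stability matrix
#'
#' Utility for matrices read back from disk (metric tag is not stored in the
#' CSV payload).
#'
#' @param values numeric matrix.
#' @param metric `"angle"` or `"mahalanobis"`.
#' @param mode optional Mahalanobis mode tag.
#' @return A `"stability_matrix"`.
#' @export
stability_matrix_from_values <- function(values,
                                         metric = c("angle", "mahalanobis"),
                                         mode = NULL) {
  stability_matrix(as.matrix(values), metric = match.arg(metric), mode = mode)
}

#' Frobenius distance between two temporal stability matrices
#'
#' \eqn{\|x_F\| = \sqrt{\sum_{ij} |a_{ij} - b_{ij}|^2}} over the full
#' matrices. Stability matrices from runs of different length (e.g. rest
#' with T = 261 versus movie with T = 193) are first truncated to their
#' common leading `T_min` x `T_min` block; the truncation size is recorded.
#' Comparing an angle matrix with a Mahalanobis matrix is refused.
#'
#' @param A,B `"stability_matrix"` objects with the same metric.
#' @return A `"frobenius_result"`: list with `x_F`, `shapes_compared`,
#'   `truncated_to`.
#' @export
frobenius_distance <- function(A, B) {
  stopifnot(inherits(A, "stability_matrix"), inherits(B, "stability_matrix"))
  if (!identical(A$metric, B$metric))
    stop(sprintf("metric mismatch: '%s' vs '%s'", A$metric, B$metric),
         call. = FALSE)
  Ta <- nrow(A$values); Tb <- nrow(B$values)
  Tmin <- min(Ta, Tb)
  a <- A$values[seq_len(Tmin), seq_len(Tmin), drop = FALSE]
  b <- B$values[seq_len(Tmin), seq_len(Tmin), drop = FALSE]
  structure(list(x_F = sqrt(sum((a - b)^2)),
                 shapes_compared = c(Ta, Tb),
                 truncated_to = as.integer(Tmin)),
            class = "frobenius_result")
}

#' @export
print.frobenius_result <- function(x, ...) {
  cat(sprintf("<frobenius_result> ||x_F|| = %.6g (%d x %d vs %d x %d, truncated to %d)\n",
              x$x_F, x$shapes_compared[1], x$shapes_compared[1],
              x$shapes_compared[2], x$shapes_compared[2], x$truncated_to))
  invisible(x)
}
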