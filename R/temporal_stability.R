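#' Temporal stability analysis of one parcellated BOLD run
#'
#' The package's one-call front end: from a regions-by-time BOLD matrix it
#' (1) computes instantaneous phases via the analytic signal (or Gaussian
#' windowed correlations), (2) forms the dFC tensor, (3) reduces each
#' timepoint to its dominant k-dimensional eigen-subspace, (4) assembles the
#' time-by-time stability matrix under the chosen metric, and (5) summarizes
#' it with histogram entropy and the lag-`lag` stability time course.
#'
#' @param x a [bold_ts()] object, or a plain regions-by-time numeric matrix
#'   (then `tr_seconds` is required).
#' @param tr_seconds sampling interval when `x` is a bare matrix.
#' @param estimator `"phase_coherence"` (default) or `"sliding_window"`.
#' @param window_length window size for the sliding-window estimator.
#' @param k subspace dimension, default 3.
#' @param metric `"angle"` (default) or `"mahalanobis"`.
#' @param mode Mahalanobis mode, `"rowpair"` (default) or `"distribution"`.
#' @param lag offset of the stability time course, default 1.
#' @param bins,range_policy entropy histogram settings
#'   (see [stability_entropy()]).
#' @param detrend,bandpass phase-extraction settings (see [hilbert_phase()]).
#' @return An object of class `"temporal_stability"`: list with
#'   `stability` (the `"stability_matrix"`), `entropy` (an
#'   `"entropy_result"`), `timecourse` (a `"stability_timecourse"`),
#'   `trajectory` (the `"subspace_trajectory"`), `metric`, `estimator`,
#'   `k`, `subject_id`, `condition`.
#' @examples
#' g <- generate_regime_bold(regime_spec(2, dwell_mean = 25), N = 12,
#'                           T_len = 100, seed = 1)
#' fit <- temporal_stability(g$ts)
#' fit
#' summary(fit)
#' @export
temporal_stability <- function(x, tr_seconds = NULL,
                               estimator = c("phase_coherence",
                                             "sliding_window"),
                               window_length = 20, k = 3,
                               metric = c("angle", "mahalanobis"),
                               mode = c("rowpair", "distribution"),
                               lag = 1, bins = 256, range_policy = "auto",
                               detrend = TRUE, bandpass = NULL) {
  estimator <- match.arg(estimator)
  metric <- match.arg(metric)
  mode <- match.arg(mode)
  if (!inherits(x, "bold_ts")) {
    if (is.null(tr_seconds))
      stop("tr_seconds is required when x is a bare matrix", call. = FALSE)
    x <- bold_ts(x, tr_seconds = tr_seconds)
  }
  dfc <- if (estimator == "phase_coherence")
           phase_coherence_dfc(hilbert_phase(x, detrend = detrend,
                                             bandpass = bandpass))
         else sliding_window_dfc(x, window_length)
  traj <- subspace_trajectory(dfc, k = k)
  sm <- if (metric == "angle") angle_stability_matrix(traj)
        else mahalanobis_stability_matrix(traj, mode = mode)
  structure(
    list(stability = sm,
         entropy = stability_entropy(sm, bins = bins,
                                     range_policy = range_policy),
         timecourse = stability_timecourse(sm, lag = lag),
         trajectory = traj, metric = metric, estimator = estimator,
         k = as.integer(k), subject_id = x$subject_id,
         condition = x$condition),
    class = "temporal_stability")
}

#' @export
print.temporal_stability <- function(x, ...) {
  TT <- nrow(x$stability$values)
  cat(sprintf("Temporal stability of dFC subspaces (%s, %s)\n",
              x$estimator, x$metric))
  cat(sprintf("  subject %s [%s]: %d timepoints, N = %d, k = %d\n",
              x$subject_id, x$condition, TT, x$trajectory$n_regions, x$k))
  cat(sprintf("  min variance fraction at k: %.6f\n",
              min(x$trajectory$variance_fractions)))
  cat(sprintf("  entropy: %.4f bits (%d bins)\n", x$entropy$E,
              x$entropy$bins))
  invisible(x)
}

#' @export
summary.temporal_stability <- function(object, ...) {
  v <- object$stability$values
  off <- v[lower.tri(v)]
  out <- list(
    metric = object$metric, estimator = object$estimator, k = object$k,
    n_timepoints = nrow(v), n_regions = object$trajectory$n_regions,
    entropy_bits = object$entropy$E,
    min_variance_fraction = min(object$trajectory$variance_fractions),
    distance_quartiles = stats::quantile(off, c(0, .25, .5, .75, 1)),
    timecourse_mean = mean(object$timecourse$values),
    timecourse_sd = stats::sd(object$timecourse$values))
  class(out) <- "summary.temporal_stability"
  out
}

#' @export
print.summary.temporal_stability <- function(x, ...) {
  cat(sprintf("Temporal stability summary (%s / %s, k = %d)\n",
              x$estimator, x$metric, x$k))
  cat(sprintf("  %d regions, %d timepoints\n", x$n_regions, x$n_timepoints))
  cat(sprintf("  entropy: %.4f bits; min variance fraction: %.6f\n",
              x$entropy_bits, x$min_variance_fraction))
  cat("  off-diagonal distance quartiles:\n")
  print(signif(x$distance_quartiles, 4))
  cat(sprintf("  lag-%d time course: mean %.4g, sd %.4g\n",
              1, x$timecourse_mean, x$timecourse_sd))
  invisible(x)
}

#' @export
plot.temporal_stability <- function(x, ...) {
  v <- x$stability$values
  TT <- nrow(v)
  graphics::image(seq_len(TT), seq_len(TT), v,
                  xlab = expression(t[x]), ylab = expression(t[y]),
                  main = sprintf("%s stability matrix", x$metric),
                  useRaster = TRUE, ...)
  invisible(x)
}
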