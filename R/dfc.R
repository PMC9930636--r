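#' Instantaneous phase of parcellated BOLD via the analytic signal
#'
#' Each region's series is optionally mean-removed (default) and band-pass
#' filtered, then extended to its analytic signal
#' \eqn{z(t) = s(t) + j\,HT[s(t)]} using the discrete Fourier construction
#' (negative frequencies zeroed, positive doubled). The instantaneous phase
#' is the angle of \eqn{z(t)}, in \eqn{(-\pi, \pi]}.
#'
#' The band-pass, when requested, is a zero-phase (forward-backward) cascade
#' of order-2 Butterworth high- and low-pass sections. It is OFF by default:
#' phase coherence is well defined on the raw mean-removed series, and
#' narrowband filtering is left as an explicit analysis choice.
#'
#' @param ts a [bold_ts()] object.
#' @param detrend remove each region's temporal mean before the transform
#'   (default `TRUE`; the arctangent phase presumes a zero-mean oscillation).
#' @param bandpass optional `c(low_hz, high_hz)`; both edges must lie strictly
#'   inside `(0, Nyquist)` where Nyquist = `1 / (2 * tr_seconds)`.
#' @return An object of class `"phase_series"`: list with `phases` (N x T
#'   matrix of radians in \eqn{(-\pi, \pi]}), `tr_seconds`, `region_labels`,
#'   `source_condition`, `subject_id`.
#' @examples
#' ts <- bold_ts(rbind(cos(2 * pi * 0.05 * (0:99) * 2),
#'                     sin(2 * pi * 0.05 * (0:99) * 2)), tr_seconds = 2)
#' ph <- hilbert_phase(ts)
#' range(ph$phases)
#' @export
hilbert_phase <- function(ts, detrend = TRUE, bandpass = NULL) {
  stopifnot(inherits(ts, "bold_ts"))
  x <- ts$values
  if (detrend) x <- x - rowMeans(x)
  if (!is.null(bandpass)) {
    nyq <- 1 / (2 * ts$tr_seconds)
    if (length(bandpass) != 2 || bandpass[1] <= 0 || bandpass[2] >= nyq ||
        bandpass[1] >= bandpass[2])
      stop(sprintf(
        "bandpass edges must satisfy 0 < low < high < Nyquist (%.4g Hz)", nyq),
        call. = FALSE)
    fs <- 1 / ts$tr_seconds
    x <- t(apply(x, 1, butter_bandpass, low = bandpass[1],
                 high = bandpass[2], fs = fs))
  }
  v <- apply(x, 1, stats::var)
  if (any(v <= 0 | !is.finite(v))) {
    bad <- which(v <= 0 | !is.finite(v))[1]
    stop(sprintf("region '%s' has zero variance; phase undefined",
                 ts$region_labels[bad]), call. = FALSE)
  }
  z <- t(apply(x, 1, analytic_signal))
  dimnames(z) <- NULL
  structure(
    list(phases = Arg(z), tr_seconds = ts$tr_seconds,
         region_labels = ts$region_labels, subject_id = ts$subject_id,
         source_condition = ts$condition),
    class = "phase_series")
}

#' @export
print.phase_series <- function(x, ...) {
  cat(sprintf("<phase_series> %d regions x %d timepoints\n",
              nrow(x$phases), ncol(x$phases)))
  invisible(x)
}

# Discrete analytic signal: zero negative-frequency bins, double positive.
analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

# Order-2 Butterworth band-pass as a zero-phase HP+LP biquad cascade.
butter_bandpass <- function(x, low, high, fs) {
  x <- filtfilt_biquad(biquad_coef("high", low, fs), x)
  filtfilt_biquad(biquad_coef("low", high, fs), x)
}

# RBJ biquad coefficients, Q = 1/sqrt(2) (maximally flat order-2 section).
biquad_coef <- function(type, fc, fs) {
  w0 <- 2 * pi * fc / fs
  alpha <- sin(w0) / sqrt(2)
  cw <- cos(w0)
  if (type == "low") {
    b <- c((1 - cw) / 2, 1 - cw, (1 - cw) / 2)
  } else {
    b <- c((1 + cw) / 2, -(1 + cw), (1 + cw) / 2)
  }
  a <- c(1 + alpha, -2 * cw, 1 - alpha)
  list(b = b / a[1], a = a / a[1])
}

biquad_filter <- function(cf, x) {
  n <- length(x)
  y <- numeric(n)
  x1 <- 0; x2 <- 0; y1 <- 0; y2 <- 0
  b <- cf$b; a <- cf$a
  for (i in seq_len(n)) {
    y[i] <- b[1] * x[i] + b[2] * x1 + b[3] * x2 - a[2] * y1 - a[3] * y2
    x2 <- x1; x1 <- x[i]
    y2 <- y1; y1 <- y[i]
  }
  y
}

# Forward-backward filtering with reflected padding to tame edge transients.
filtfilt_biquad <- function(cf, x) {
  n <- length(x)
  pad <- min(3 * 10, n - 1)
  xp <- c(2 * x[1] - rev(x[2:(pad + 1)]), x,
          2 * x[n] - rev(x[(n - pad):(n - 1)]))
  y <- biquad_filter(cf, xp)
  y <- rev(biquad_filter(cf, rev(y)))
  y[(pad + 1):(pad + n)]
}

#' Instantaneous phase-coherence dFC tensor
#'
#' For each timepoint `t`, the connectivity between regions `n` and `p` is
#' \eqn{\mathrm{dFC}(n,p,t) = \cos(\theta(n,t) - \theta(p,t))}: 1 when the
#' regions' BOLD phases are synchronized, 0 when orthogonal, -1 in antiphase.
#' Every slice is symmetric with a unit diagonal, and — because
#' \eqn{\cos(\theta_n-\theta_p) = c c^T + s s^T} with
#' \eqn{c = \cos\theta(\cdot,t)}, \eqn{s = \sin\theta(\cdot,t)} — has rank
#' at most 2, which is why 3 leading eigenvectors always capture at least
#' 99% of its variance.
#'
#' @param phases a `"phase_series"` from [hilbert_phase()].
#' @return An object of class `"dfc_tensor"`: list with `values`
#'   (N x N x T array), `estimator = "phase_coherence"`,
#'   `window_length = NULL`, `region_labels`, `tr_seconds`.
#' @export
phase_coherence_dfc <- function(phases) {
  stopifnot(inherits(phases, "phase_series"))
  th <- phases$phases
  N <- nrow(th); TT <- ncol(th)
  vals <- array(0, dim = c(N, N, TT))
  for (t in seq_len(TT)) {
    ct <- cos(th[, t]); st <- sin(th[, t])
    sl <- tcrossprod(ct) + tcrossprod(st)
    diag(sl) <- 1
    vals[, , t] <- sl
  }
  structure(
    list(values = vals, estimator = "phase_coherence", window_length = NULL,
         region_labels = phases$region_labels,
         tr_seconds = phases$tr_seconds),
    class = "dfc_tensor")
}

#' @export
print.dfc_tensor <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<dfc_tensor> %s: %d x %d regions x %d timepoints\n",
              x$estimator, d[1], d[2], d[3]))
  invisible(x)
}

#' Nonoverlapping Gaussian-windowed correlation dFC
#'
#' Reliability-check alternative to phase coherence: the series is tiled into
#' consecutive nonoverlapping windows of `window_length` timepoints and, in
#' each window, region pairs are correlated with a Gaussian taper
#' (sd = `window_length / 4`, truncated to the window) centred in the window.
#' Yields `floor(T / window_length)` symmetric correlation slices.
#'
#' @param ts a [bold_ts()] object with `T >= 2 * window_length`.
#' @param window_length window size in timepoints (>= 4); the study varied
#'   it over 10, 20, 30.
#' @param gaussian_sd taper standard deviation in timepoints; default
#'   `window_length / 4`.
#' @return A `"dfc_tensor"` with `estimator = "sliding_window"`.
#' @export
sliding_window_dfc <- function(ts, window_length, gaussian_sd = window_length / 4) {
  stopifnot(inherits(ts, "bold_ts"))
  window_length <- as.integer(window_length)
  if (window_length < 4)
    stop("window_length must be >= 4 (correlation unstable below)",
         call. = FALSE)
  TT <- ncol(ts$values)
  nw <- TT %/% window_length
  if (nw < 2)
    stop(sprintf("need T >= 2 * window_length (T = %d, window = %d)",
                 TT, window_length), call. = FALSE)
  N <- nrow(ts$values)
  centre <- (window_length + 1) / 2
  w <- exp(-((seq_len(window_length) - centre)^2) / (2 * gaussian_sd^2))
  w <- w / sum(w)
  vals <- array(0, dim = c(N, N, nw))
  for (i in seq_len(nw)) {
    idx <- ((i - 1) * window_length + 1):(i * window_length)
    vals[, , i] <- weighted_correlation(ts$values[, idx, drop = FALSE], w)
  }
  structure(
    list(values = vals, estimator = "sliding_window",
         window_length = window_length, region_labels = ts$region_labels,
         tr_seconds = ts$tr_seconds),
    class = "dfc_tensor")
}

# Weighted Pearson correlation across columns (time) of an N x L block.
weighted_correlation <- function(block, w) {
  mu <- as.vector(block %*% w)
  cent <- block - mu
  cw <- cent * rep(w, each = nrow(block))
  cov <- tcrossprod(cw, cent)          # sum_t w_t (x - mu)(y - mu)
  sd <- sqrt(diag(cov))
  if (any(sd <= 0))
    stop("zero-variance region within a window", call. = FALSE)
  r <- cov / tcrossprod(sd)
  r[r > 1] <- 1; r[r < -1] <- -1
  diag(r) <- 1
  (r + t(r)) / 2
}
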