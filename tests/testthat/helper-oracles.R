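# Independent brute-force oracles used to cross-check the implementation.
# These deliberately avoid the code paths of the package (explicit DFT sums,
# Gram-Schmidt, longhand quadratic forms, manual histograms).

# Analytic signal by explicit DFT sums with negative-frequency bins zeroed.
oracle_analytic_signal <- function(x) {
  n <- length(x)
  ks <- 0:(n - 1)
  X <- vapply(ks, function(k)
    sum(x * exp(-2i * pi * k * (0:(n - 1)) / n)), complex(1))
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  Xh <- X * h
  vapply(0:(n - 1), function(t)
    sum(Xh * exp(2i * pi * ks * t / n)) / n, complex(1))
}

# Weighted Pearson correlation, elementwise sums.
oracle_weighted_cor <- function(x, y, w) {
  w <- w / sum(w)
  mx <- sum(w * x); my <- sum(w * y)
  sxy <- sum(w * (x - mx) * (y - my))
  sxx <- sum(w * (x - mx)^2)
  syy <- sum(w * (y - my)^2)
  sxy / sqrt(sxx * syy)
}

# Classical Gram-Schmidt orthonormalization (no rank truncation).
oracle_gram_schmidt <- function(M) {
  Q <- matrix(0, nrow(M), 0)
  for (j in seq_len(ncol(M))) {
    v <- M[, j]
    if (ncol(Q) > 0) for (i in seq_len(ncol(Q)))
      v <- v - sum(Q[, i] * M[, j]) * Q[, i]
    nv <- sqrt(sum(v^2))
    if (nv > 1e-10) Q <- cbind(Q, v / nv)
  }
  Q
}

# All principal angles via Gram-Schmidt bases and the cross-Gram SVD.
oracle_principal_angles <- function(A, B) {
  Qa <- oracle_gram_schmidt(A)
  Qb <- oracle_gram_schmidt(B)
  G <- t(Qa) %*% Qb
  sv <- svd(G)$d
  sort(acos(pmin(pmax(sv, -1), 1)), decreasing = TRUE)
}

# Longhand per-row Mahalanobis profile: explicit inverse and scalar loops.
oracle_mahalanobis_profile <- function(A, B, mode = "rowpair",
                                       epsilon_scale = 1e-8) {
  k <- ncol(A)
  mu <- colMeans(A)
  Ac <- sweep(A, 2, mu)
  C <- matrix(0, k, k)
  for (i in seq_len(nrow(A))) C <- C + Ac[i, ] %o% Ac[i, ]
  C <- C / (nrow(A) - 1)
  C <- C + diag(epsilon_scale * sum(diag(C)) / k, k)
  Ci <- solve(C)
  out <- numeric(nrow(A))
  for (p in seq_len(nrow(A))) {
    d <- if (mode == "rowpair") A[p, ] - B[p, ] else B[p, ] - mu
    out[p] <- sqrt(drop(t(d) %*% Ci %*% d))
  }
  out
}

# Manual histogram entropy on already-mapped unit-range values.
oracle_entropy <- function(u, bins = 256) {
  counts <- integer(bins)
  for (v in u) {
    b <- min(floor(v * bins) + 1, bins)
    counts[b] <- counts[b] + 1
  }
  p <- counts / sum(counts)
  -sum(ifelse(p > 0, p * log2(p), 0))
}

oracle_frobenius <- function(a, b) {
  s <- 0
  for (i in seq_len(nrow(a))) for (j in seq_len(ncol(a)))
    s <- s + abs(a[i, j] - b[i, j])^2
  sqrt(s)
}

# Small synthetic trajectory used across stability tests.
make_test_trajectory <- function(N = 20, T_len = 60, n_regimes = 2,
                                 dwell = 20, noise_sd = 0.2, seed = 5) {
  g <- generate_regime_bold(
    regime_spec(n_regimes, dwell_mean = dwell,
                dwell_distribution = "fixed"),
    N = N, T_len = T_len, seed = seed, noise_sd = noise_sd)
  list(traj = subspace_trajectory(phase_coherence_dfc(hilbert_phase(g$ts))),
       states = g$states, switches = g$switches, ts = g$ts)
}

# Constant trajectory: time-constant phases give identical dFC slices.
make_constant_trajectory <- function(N = 10, T_len = 20, seed = 2) {
  set.seed(seed)
  psi <- runif(N, -pi, pi)
  ph <- structure(list(phases = matrix(psi, N, T_len),
                       tr_seconds = 2,
                       region_labels = sprintf("ROI%03d", 1:N),
                       subject_id = "const", source_condition = "synthetic"),
                  class = "phase_series")
  subspace_trajectory(phase_coherence_dfc(ph))
}
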