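#' Specify a regime-switching phase-coupling ground truth
#'
#' Describes the hidden multistable structure the synthetic BOLD generator
#' emulates: `n_regimes` coupling regimes, each partitioning the regions
#' into phase-locked communities with fixed phase offsets; the process
#' dwells in a regime for `dwell_mean` timepoints (exactly, or
#' geometrically distributed with that mean) before switching to the next
#' regime cyclically.
#'
#' By default communities are assigned automatically: regions are split into
#' `n_communities` groups by a cyclic rule that is rotated from regime to
#' regime, and community `c` carries offset \eqn{2\pi (c-1)/n_{comm}}. A
#' fully explicit `coupling` list (one element per regime with integer
#' `membership` of length N and numeric `offsets` per community) overrides
#' this.
#'
#' @param n_regimes number of regimes (>= 1), default 2.
#' @param dwell_mean mean dwell time in timepoints (>= 2), default 20.
#' @param dwell_distribution `"fixed"` (default) or `"geometric"`.
#' @param n_communities number of phase-locked communities per regime when
#'   coupling is auto-generated, default 4.
#' @param coupling optional explicit list described above.
#' @return A `"regime_spec"` list.
#' @export
regime_spec <- function(n_regimes = 2, dwell_mean = 20,
                        dwell_distribution = c("fixed", "geometric"),
                        n_communities = 4, coupling = NULL) {
  dwell_distribution <- match.arg(dwell_distribution)
  if (n_regimes < 1) stop("n_regimes must be >= 1", call. = FALSE)
  if (dwell_mean < 2) stop("dwell_mean must be >= 2", call. = FALSE)
  structure(list(n_regimes = as.integer(n_regimes),
                 dwell_mean = as.numeric(dwell_mean),
                 dwell_distribution = dwell_distribution,
                 n_communities = as.integer(n_communities),
                 coupling = coupling),
            class = "regime_spec")
}

regime_membership <- function(spec, regime, N) {
  if (!is.null(spec$coupling)) {
    cp <- spec$coupling[[regime]]
    if (length(cp$membership) != N)
      stop("explicit membership length must equal N", call. = FALSE)
    return(list(membership = as.integer(cp$membership),
                offsets = as.numeric(cp$offsets)))
  }
  nc <- spec$n_communities
  # rotate the community labelling by one region per regime so each regime
  # induces a genuinely different phase-locking partition
  mem <- ((seq_len(N) - 1 + (regime - 1) * max(1L, N %/% (nc * spec$n_regimes)))
          %/% max(1L, ceiling(N / nc))) %% nc + 1L
  # offsets are deliberately NOT uniformly spaced: equispaced offsets with
  # equal community sizes make the two leading dFC eigenvalues exactly
  # degenerate, leaving the in-plane eigenbasis non-identifiable (noise
  # would rotate it arbitrarily between timepoints of the same regime)
  list(membership = as.integer(mem),
       offsets = 2 * pi * (seq_len(nc) - 1) / nc * 0.8)
}

draw_state_sequence <- function(spec, TT) {
  states <- integer(TT)
  t <- 1L; regime <- 1L
  while (t <= TT) {
    d <- if (spec$dwell_distribution == "fixed") round(spec$dwell_mean)
         else stats::rgeom(1, 1 / spec$dwell_mean) + 1L
    d <- max(1L, as.integer(d))
    states[t:min(TT, t + d - 1L)] <- regime
    t <- t + d
    regime <- regime %% spec$n_regimes + 1L
  }
  states
}

#' Generate regime-switching synthetic parcellated BOLD
#'
#' Each region emits a narrowband sinusoid at `oscillation_hz` whose phase
#' offset is set by its community under the active regime, plus additive
#' Gaussian noise. Phase coherence responds only to relative phase, so this
#' is the minimal generator with exactly controllable ground truth. At a
#' regime switch each region's offset relaxes toward its new target (60% of
#' the remaining angular gap per sample) instead of jumping, keeping the
#' signal phase-continuous and avoiding artificial analytic-signal
#' transients that would confound switch detection.
#'
#' Defaults mirror a typical parcellated lifespan fMRI acquisition: a
#' 0.05 Hz dominant low-frequency oscillation sampled at TR = 2 s, noise
#' sd 0.2 on unit-amplitude signal.
#'
#' @param spec a [regime_spec()].
#' @param N number of regions (>= 4), default 116.
#' @param T_len number of timepoints, default 261.
#' @param tr_seconds sampling interval, default 2.
#' @param oscillation_hz carrier frequency; must be below Nyquist.
#' @param noise_sd additive Gaussian noise sd, default 0.2.
#' @param seed optional integer seed (restores the global RNG state on
#'   exit).
#' @param subject_id,condition forwarded to [bold_ts()].
#' @return List with `ts` (a [bold_ts()]), `states` (length-`T_len` hidden
#'   regime sequence) and `switches` (timepoints at which the regime
#'   changed).
#' @export
generate_regime_bold <- function(spec, N = 116, T_len = 261, tr_seconds = 2,
                                 oscillation_hz = 0.05, noise_sd = 0.2,
                                 seed = NULL, subject_id = "synthetic",
                                 condition = "synthetic") {
  stopifnot(inherits(spec, "regime_spec"))
  if (N < 4) stop("need N >= 4 regions", call. = FALSE)
  if (oscillation_hz >= 1 / (2 * tr_seconds))
    stop(sprintf("oscillation frequency %.4g Hz is at or above Nyquist %.4g Hz",
                 oscillation_hz, 1 / (2 * tr_seconds)), call. = FALSE)
  if (!is.null(seed)) {
    old <- get_rng_state()
    on.exit(restore_rng_state(old))
    set.seed(as.integer(seed))
  }
  states <- draw_state_sequence(spec, T_len)
  mems <- lapply(seq_len(spec$n_regimes), regime_membership, spec = spec,
                 N = N)
  target <- function(t) {
    m <- mems[[states[t]]]
    m$offsets[m$membership]
  }
  psi <- matrix(0, N, T_len)
  psi[, 1] <- target(1)
  for (t in 2:T_len) {
    delta <- wrap_angle(target(t) - psi[, t - 1])
    psi[, t] <- psi[, t - 1] + 0.6 * delta
  }
  carrier <- 2 * pi * oscillation_hz * (seq_len(T_len) - 1) * tr_seconds
  sig <- cos(sweep(psi, 2, carrier, `+`))
  if (noise_sd > 0)
    sig <- sig + matrix(stats::rnorm(N * T_len, sd = noise_sd), N, T_len)
  list(ts = bold_ts(sig, tr_seconds = tr_seconds, subject_id = subject_id,
                    condition = condition),
       states = states,
       switches = which(diff(states) != 0) + 1L)
}

wrap_angle <- function(x) {
  out <- (x + pi) %% (2 * pi) - pi
  out[out == -pi] <- pi
  out
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

restore_rng_state <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Simulate a stationary AR process
#'
#' \eqn{X_t = c + \sum_i \varphi_i X_{t-i} + \varepsilon_t} with Gaussian
#' innovations; a burn-in of `10 * order` samples is discarded. Coefficients
#' must define a stationary process (companion-matrix spectral radius < 1).
#'
#' @param coefficients numeric vector \eqn{\varphi_1 \dots \varphi_\rho}
#'   (may be `numeric(0)` or `0` for white noise).
#' @param constant intercept `c`, default 0.
#' @param noise_sd innovation standard deviation, default 1.
#' @param n output length.
#' @param seed optional integer seed (global RNG state restored on exit).
#' @return Numeric vector of length `n`.
#' @export
generate_ar_series <- function(coefficients, constant = 0, noise_sd = 1, n,
                               seed = NULL) {
  phi <- as.numeric(coefficients)
  if (length(phi) == 1 && phi == 0) phi <- numeric(0)
  p <- length(phi)
  if (p > 0) {
    comp <- matrix(0, p, p)
    comp[1, ] <- phi
    if (p > 1) comp[cbind(2:p, 1:(p - 1))] <- 1
    if (max(Mod(eigen(comp, only.values = TRUE)$values)) >= 1)
      stop("nonstationary AR coefficients", call. = FALSE)
  }
  if (!is.null(seed)) {
    old <- get_rng_state()
    on.exit(restore_rng_state(old))
    set.seed(as.integer(seed))
  }
  burn <- 10 * p
  ntot <- n + burn
  eps <- stats::rnorm(ntot, sd = noise_sd)
  x <- numeric(ntot)
  mu <- if (p > 0) constant / (1 - sum(phi)) else constant
  if (p > 0) x[seq_len(p)] <- mu
  start <- max(p, 0) + 1
  for (t in start:ntot) {
    x[t] <- constant + eps[t] +
      if (p > 0) sum(phi * x[t - seq_len(p)]) else 0
  }
  x[(burn + 1):ntot]
}

#' Specify a synthetic lifespan cohort
#'
#' @param n_subjects number of subjects.
#' @param conditions character vector of conditions to generate per subject
#'   (subset of rest/movie/smt), default `c("rest", "smt")`.
#' @param age_sampler function(n) returning ages in `[18, 88]`; default
#'   uniform.
#' @param dwell_map function(age, condition) returning the regime dwell mean
#'   (timepoints) for that subject/condition — the hook for planting age
#'   trends or condition orderings; default a constant 20.
#' @param n_regimes,n_communities forwarded to [regime_spec()].
#' @param dwell_distribution dwell distribution, default `"geometric"` (so
#'   subjects differ in realized switch times).
#' @param N,tr_seconds,oscillation_hz,noise_sd generator geometry; defaults
#'   mirror the study shapes (116 regions, TR 2 s).
#' @param T_map named vector of series lengths per condition, default
#'   rest/smt 261 and movie 193.
#' @param seed base integer seed; per-subject/condition seeds are derived
#'   deterministically from it.
#' @return A `"cohort_spec"` list.
#' @export
cohort_spec <- function(n_subjects, conditions = c("rest", "smt"),
                        age_sampler = function(n) stats::runif(n, 18, 88),
                        dwell_map = function(age, condition) 20,
                        n_regimes = 3, n_communities = 4,
                        dwell_distribution = "geometric",
                        N = 116, tr_seconds = 2, oscillation_hz = 0.05,
                        noise_sd = 0.2,
                        T_map = c(rest = 261, movie = 193, smt = 261),
                        seed = 1) {
  conditions <- match.arg(conditions, c("rest", "movie", "smt"),
                          several.ok = TRUE)
  structure(list(n_subjects = as.integer(n_subjects),
                 conditions = conditions, age_sampler = age_sampler,
                 dwell_map = dwell_map, n_regimes = n_regimes,
                 n_communities = n_communities,
                 dwell_distribution = dwell_distribution, N = N,
                 tr_seconds = tr_seconds, oscillation_hz = oscillation_hz,
                 noise_sd = noise_sd, T_map = T_map,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Generate a synthetic cohort on disk
#'
#' Draws ages, maps them to per-condition regime dwell times via the spec's
#' `dwell_map`, generates one regime-switching BOLD series per
#' subject/condition, writes each as a regions-by-time CSV alongside its
#' hidden state sequence, and writes a `manifest.csv` subject table
#' (subject_id, age_years, condition, path).
#'
#' @param spec a [cohort_spec()].
#' @param out_dir output directory.
#' @param overwrite allow writing into an existing non-empty directory.
#' @return The manifest as a data.frame (invisibly also written to disk),
#'   with an extra `dwell_mean` column recording the planted ground truth.
#' @export
generate_cohort <- function(spec, out_dir, overwrite = FALSE) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (dir.exists(out_dir) && length(list.files(out_dir)) > 0 && !overwrite)
    stop(sprintf("output directory '%s' is not empty (use overwrite = TRUE)",
                 out_dir), call. = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(spec$seed)
  ages <- spec$age_sampler(spec$n_subjects)
  ages <- pmin(pmax(ages, 18), 88)
  rows <- list()
  for (s in seq_len(spec$n_subjects)) {
    sid <- sprintf("sub%03d", s)
    for (ci in seq_along(spec$conditions)) {
      cond <- spec$conditions[ci]
      dwell <- spec$dwell_map(ages[s], cond)
      rs <- regime_spec(n_regimes = spec$n_regimes, dwell_mean = dwell,
                        dwell_distribution = spec$dwell_distribution,
                        n_communities = spec$n_communities)
      sub_seed <- (spec$seed * 10007L + s * 101L + ci) %% 2147483647L
      g <- generate_regime_bold(rs, N = spec$N,
                                T_len = spec$T_map[[cond]],
                                tr_seconds = spec$tr_seconds,
                                oscillation_hz = spec$oscillation_hz,
                                noise_sd = spec$noise_sd, seed = sub_seed,
                                subject_id = sid, condition = cond)
      path <- file.path(out_dir, sprintf("%s_%s.csv", sid, cond))
      write_matrix(g$ts$values, path)
      utils::write.csv(data.frame(state = g$states),
                       file.path(out_dir, sprintf("%s_%s_states.csv",
                                                  sid, cond)),
                       row.names = FALSE)
      rows[[length(rows) + 1]] <- data.frame(
        subject_id = sid, age_years = ages[s], condition = cond,
        path = path, dwell_mean = dwell, stringsAsFactors = FALSE)
    }
  }
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  manifest
}
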