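---
title: "Temporal stability of dFC subspaces: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Temporal stability of dFC subspaces: models, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dfcstab)
```

This vignette is the package's own account of the science it implements:
the model and its assumptions, the parameters that matter, what the
synthetic generator does and does not emulate, and the numerical and design
choices that were genuinely open.

## The model

The pipeline treats a parcellated BOLD run as a sequence of instantaneous
connectivity configurations and asks how long-lived each configuration is.

**Phase-coherence dFC.** Each region's (mean-removed) series is extended to
its analytic signal; the phase difference between two regions, mapped
through a cosine, is the instantaneous coupling
$\mathrm{dFC}(n,p,t) = \cos(\theta_{n,t} - \theta_{p,t})$. The estimator
assumes the signal of interest is an oscillation whose phase is meaningful,
i.e. a reasonably narrowband process; BOLD's dominant low-frequency
component (around 0.01–0.1 Hz at TR ≈ 2 s) satisfies this loosely, and a
band-pass option exists for stricter narrowband analyses (below).

**The rank-2 identity.** Writing $c_t = \cos\theta_{\cdot t}$ and
$s_t = \sin\theta_{\cdot t}$, every slice equals $c_tc_t^T + s_ts_t^T$
(with the diagonal set to 1 exactly). Each slice therefore has rank at most
2 regardless of the data, which has two consequences used throughout:

* the default $k = 3$ dominant subspace captures essentially **all** of the
  slice variance, a strictly stronger statement than the 99% working
  criterion that motivates $k = 3$;
* the third eigendirection is numerical noise. It is retained (flagged in
  `null_flags`) but must never be *interpreted*; the two distance metrics
  each neutralize it in their own way (below).

**Stability matrices.** The dominant pattern $D_t$ (the $N \times k$ matrix
of $\sqrt{|\lambda_i|}$-scaled leading eigenvectors) is compared across all
timepoint pairs:

* *Principal angle*: both component matrices are orthonormalized and the
  largest canonical angle between their spans is reported,
  $\phi(t_x,t_y) \in [0, \pi/2]$. The span is invariant to scaling, sign
  and any invertible recombination of components, which makes this the
  more robust metric.
* *Mahalanobis*: the $N$ rows of $D_{t_x}$, viewed as points in
  $k$-space, define a mean and covariance $C$; each region's displacement
  (matched-row difference by default) is measured in the metric of
  $C^{-1}$ and averaged over regions. Unlike the angle this is sensitive
  to how the pattern is *distributed over regions*, not only to the span.

**Summaries.** The stability matrix is reduced to: its 256-bin histogram
entropy (how mixed the distance values are); Frobenius distances between
conditions; and an AR characterization of the lag-1 time course, where the
selected order discriminates white-noise ($\rho = 0$), Markovian
($\rho = 1$) and history-dependent ($\rho > 1$) stability dynamics.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| `k` | 3 | components | justified by the ≥ 99% variance criterion; exact here by the rank-2 identity. Configurable for windowed dFC, which is full-rank. |
| `detrend` | TRUE | — | the arctangent phase presumes a zero-mean oscillation; only the temporal mean is removed. |
| `bandpass` | off | Hz | the phase-coherence literature often filters narrowband, but no specific band is assumed here; when enabled, an order-2 zero-phase Butterworth cascade is applied. Edges must lie strictly inside (0, Nyquist). |
| `window_length` (windowed estimator) | user-set, ≥ 4 | volumes | nonoverlapping windows; Gaussian taper with sd `window_length/4`, truncated to the window. Both are conventions, exposed as arguments. |
| `epsilon_scale` | 1e-8 | relative | Mahalanobis covariance regularization $C + \epsilon\,\mathrm{tr}(C)/k\,I$. Mandatory: with rank-2 slices the $k=3$ direction of $C$ is numerically null and $C$ is otherwise singular. The scale-relative form keeps the fix unit-free. |
| `rank_tol` (principal angle) | 1e-6 | relative | singular-value cutoff of the orthonormalization. With `sqrt_eigenvalue` scaling the numerically-null third column has relative magnitude ~1e-7–1e-8 and is dropped, so angles compare the two *real* planes instead of numerical noise. |
| `bins`, `range_policy` | 256, auto | — | angle matrices are binned over the fixed theoretical range $[0, \pi/2]$ (comparable across subjects); Mahalanobis matrices, unbounded, use per-matrix min–max. Entropies under different policies are not comparable with each other. |
| `lag` | 1 | volumes | the stability time course is the superdiagonal: distance between successive subspaces. The matrix-to-series reduction is not dictated by the stability construction itself, so the offset is configurable. |
| `max_order`, `rule` | 100, first local min | — | the AIC curve is computed on a common conditioning sample so values are comparable across orders; `max_order` is capped at n/3. The endpoint never counts as a local minimum; a monotone curve falls back to the global minimum with a flag. |

## What the generator emulates — and what it does not

`generate_regime_bold()` produces the minimal signal with exactly
controllable ground truth for this pipeline: phase coherence responds only
to *relative phase*, so regions are unit-amplitude sinusoids at one carrier
frequency (default 0.05 Hz at TR = 2 s) whose phase offsets are set by
community membership under a hidden regime sequence with controllable dwell
times. Gaussian noise (default sd 0.2 against unit amplitude) stands in for
everything else.

Two non-obvious generator choices:

* **Phase continuity at switches.** Offsets relax toward their new target
  (60% of the remaining angular gap per sample, so a switch completes in
  2–3 volumes) instead of jumping. A hard jump would create a broadband
  analytic-signal transient and the pipeline would detect the *artifact*,
  not the regime change.
* **Non-equispaced community offsets.** With equal-sized communities at
  exactly equispaced offsets, the $c$ and $s$ vectors are orthogonal with
  equal norms and the two leading eigenvalues are exactly degenerate — the
  eigenbasis within the dominant plane is then non-identifiable and noise
  rotates it arbitrarily between same-regime timepoints, which destroys
  the row-matched Mahalanobis block structure (the span, hence the angle
  metric, is unaffected). Default offsets are therefore spaced by
  $0.8 \cdot 2\pi/n_{\mathrm{comm}}$.

What it deliberately does **not** emulate: hemodynamic convolution,
1/f and physiological noise spectra, head motion, amplitude dynamics,
spatial autocorrelation of parcels, or multiband/multi-echo acquisition
effects. A green test on synthetic data therefore establishes that the
*machinery* recovers planted structure (switch times, dwell-entropy
ordering, age trends injected through dwell times); it does not establish
that real aging cohorts show those effects — that evidence lives in the
empirical literature, not in this package's tests.

Cohort-level tests run at reduced geometry (10–20 regions, 100–200
volumes) where the full 116×261 shape is not itself the claim, to keep the
suite fast; the acceptance checks that concern the study geometry run at
full 116×261 scale.

## Numerical choices and degenerate inputs

* **Eigenvector sign** is fixed so each column's largest-magnitude entry is
  positive: sign affects row-matched Mahalanobis differences (not angles),
  and a deterministic convention makes runs reproducible.
* **Small principal angles** are computed from the sine form
  ($\mathrm{svd}(Q_b - Q_aQ_a^TQ_b)$) below $\pi/4$; the arccosine of
  cross-Gram singular values loses half the working precision near zero.
* **Mahalanobis asymmetry**: the covariance comes from the first subspace,
  so the raw distance is asymmetric; the matrix is symmetrized as the
  mean of the two orientations, matching the single symmetric time×time
  display convention.
* **Constant matrices** under min–max binning have no range; the entropy
  is defined as 0 (single occupied bin) with a warning.
* **Unequal run lengths** (rest T = 261 vs movie T = 193) are reconciled
  by truncating both stability matrices to the leading common block before
  the Frobenius distance — the minimal documented choice; interpolation
  would manufacture timepoints.
* **Zero-variance regions**, out-of-range band edges, asymmetric slices,
  nonstationary AR coefficients and undersized networks (< 4 regions for a
  k = 3 subspace) are rejected with named errors rather than propagated.

## Open design decisions

Several points were genuinely underdetermined and resolved as follows:

* **Shape of $D_t$.** The dominant pattern is taken as the $N \times k$
  matrix of scaled leading eigenvectors (not an $N \times N$
  reconstruction): with `sqrt_eigenvalue` scaling, $D_tD_t^T$ is the best
  rank-$k$ reconstruction, preserving both the "subspace" and the
  "pattern" reading.
* **"The" principal angle** is the largest canonical angle — the
  convention whose value actually spans $(0, \pi/2]$; `which = "all"`
  exposes the full angle set.
* **Row-pair vs point-to-distribution Mahalanobis.** Both readings are
  implemented; the matched-row difference is the default and the
  point-to-distribution form is selectable (`mode = "distribution"`,
  affine-invariant, used where scale-free behavior matters).
* **Entropy base and bins.** Base-2 logarithm over 256 bins, the
  image-histogram convention; entropies are in bits and bounded by 8.
* **"First minimal AIC"** is formalized as the first local minimum
  (ρ = 0 qualifies when AIC(0) ≤ AIC(1)); the likelihood is Gaussian and
  conditional, with the ML residual variance, and AIC counts the ρ lag
  coefficients. With a penalty of 2 per lag, an order-0 process is
  selected with asymptotic probability $P(\chi^2_1 < 2) \approx 0.84$ —
  an inherent property of this rule worth knowing when interpreting
  selected orders near zero.
* **Lifespan regression** uses the minimal quadratic-in-age model
  $E \sim \beta_0 + \beta_1\,\mathrm{age}_c + \beta_2\,\mathrm{age}_c^2$
  with age mean-centred for conditioning; the curvature sign is the
  U-shape readout. P-values throughout the group analyses are reported
  uncorrected (an FDR adjustment can be applied downstream).
* **Network memberships.** The bundled AAL-116 network file is a
  *reference reconstruction* of commonly used DMN/CEN/SM/salience/visual
  memberships — the upstream sources cite membership literature without
  enumerating indices. It is plain JSON and intended to be edited.

## A worked miniature

```{r example}
g <- generate_regime_bold(regime_spec(2, dwell_mean = 30), N = 20,
                          T_len = 120, seed = 1)
fit <- temporal_stability(g$ts)
summary(fit)
plot(fit)

# planted switches appear as spikes in the lag-1 time course
head(g$switches)
which.max(fit$timecourse$values)

# order selection on the stability time course
select_order(fit$timecourse, max_order = 20)
```

## Known limitations

* The Mahalanobis metric depends on the eigenbasis, not only the span; on
  data whose leading eigenvalues are nearly degenerate it mixes basis
  rotation into the distance (see the generator note above). The angle
  metric is immune and should be preferred when only the span matters.
* Phase coherence presumes meaningful instantaneous phase; broadband or
  strongly non-oscillatory signals violate this, and the windowed
  estimator is the appropriate fallback.
* Entropy under the min–max policy is not comparable across matrices with
  very different ranges; use the fixed-range policy where a theoretical
  range exists.
* The AR machinery is conditional least squares with a Gaussian
  likelihood; exact-ML and ARMA extensions are out of scope.
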