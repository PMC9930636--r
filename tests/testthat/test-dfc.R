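test_that("analytic-signal phase of a pure cosine advances at the carrier rate", {
  tr <- 2; f <- 0.05; T_len <- 200
  t_idx <- 0:(T_len - 1)
  ts <- bold_ts(rbind(cos(2 * pi * f * t_idx * tr),
                      sin(2 * pi * f * t_idx * tr)), tr_seconds = tr)
  ph <- hilbert_phase(ts)
  # unwrapped increments: 2*pi*f*tr per sample (20 whole cycles fit exactly)
  d <- diff(ph$phases[1, ])
  d <- (d + pi) %% (2 * pi) - pi
  interior <- 10:(T_len - 10)
  expect_true(all(abs(d[interior] - 2 * pi * f * tr) < 1e-6))
  # sin lags cos by pi/2 at every interior sample
  lag <- ph$phases[1, ] - ph$phases[2, ]
  lag <- (lag + pi) %% (2 * pi) - pi
  expect_true(all(abs(lag[interior] - pi / 2) < 1e-6))
  expect_true(all(ph$phases > -pi & ph$phases <= pi + 1e-12))
})

test_that("phases match the explicit-DFT analytic-signal oracle", {
  set.seed(7)
  for (T_len in c(32, 33)) {  # even and odd lengths
    x <- rnorm(T_len)
    ts <- bold_ts(rbind(x, rnorm(T_len)), tr_seconds = 2)
    ph <- hilbert_phase(ts, detrend = FALSE)
    expect_equal(ph$phases[1, ], Arg(oracle_analytic_signal(x)),
                 tolerance = 1e-10)
  }
})

test_that("hilbert_phase validates inputs", {
  flat <- bold_ts(rbind(rep(1, 20), rnorm(20)), tr_seconds = 2)
  expect_error(hilbert_phase(flat), "ROI001")
  ts <- bold_ts(matrix(rnorm(40), 2, 20), tr_seconds = 2)
  expect_error(hilbert_phase(ts, bandpass = c(0.01, 0.3)), "Nyquist")
  expect_error(hilbert_phase(ts, bandpass = c(0.1, 0.05)), "Nyquist")
})

test_that("band-pass keeps an in-band carrier and attenuates out-of-band power", {
  tr <- 1; T_len <- 400; t_idx <- 0:(T_len - 1)
  x <- cos(2 * pi * 0.05 * t_idx) + cos(2 * pi * 0.4 * t_idx)
  ts <- bold_ts(rbind(x, rnorm(T_len)), tr_seconds = tr)
  ph <- hilbert_phase(ts, bandpass = c(0.02, 0.1))
  # after removing the 0.4 Hz component the phase should advance near the
  # 0.05 Hz carrier rate
  d <- diff(ph$phases[1, ])
  d <- (d + pi) %% (2 * pi) - pi
  interior <- 50:(T_len - 50)
  expect_lt(median(abs(d[interior] - 2 * pi * 0.05 * tr)), 0.02)
})

test_that("phase coherence is cos of the phase difference with unit diagonal", {
  set.seed(3)
  ts <- bold_ts(matrix(rnorm(5 * 40), 5, 40), tr_seconds = 2)
  ph <- hilbert_phase(ts)
  dfc <- phase_coherence_dfc(ph)
  expect_equal(dim(dfc$values), c(5, 5, 40))
  for (t in c(1, 17, 40)) {
    sl <- dfc$values[, , t]
    expect_equal(sl, t(sl))
    expect_equal(diag(sl), rep(1, 5))
    expect_true(all(sl >= -1 - 1e-12 & sl <= 1 + 1e-12))
    expect_equal(sl[1, 2], cos(ph$phases[1, t] - ph$phases[2, t]))
  }
  # direct scalar check
  ph$phases[1, 5] <- 0.3; ph$phases[2, 5] <- 1.0
  expect_equal(phase_coherence_dfc(ph)$values[1, 2, 5], cos(-0.7))
})

test_that("antiphase regions give phase coherence -1", {
  t_idx <- 0:99
  ts <- bold_ts(rbind(cos(2 * pi * 0.05 * t_idx * 2),
                      -cos(2 * pi * 0.05 * t_idx * 2)), tr_seconds = 2)
  dfc <- phase_coherence_dfc(hilbert_phase(ts))
  expect_true(all(abs(dfc$values[1, 2, ] + 1) < 1e-8))
})

test_that("every phase-coherence slice is rank 2: third eigenvalue vanishes", {
  set.seed(11)
  ts <- bold_ts(matrix(rnorm(12 * 50), 12, 50), tr_seconds = 2)
  dfc <- phase_coherence_dfc(hilbert_phase(ts))
  for (t in seq(1, 50, by = 7)) {
    ev <- eigen(dfc$values[, , t], symmetric = TRUE,
                only.values = TRUE)$values
    expect_lt(abs(ev[3]), 1e-8 * ev[1])
    # and the slice is exactly cc' + ss' off the diagonal
  }
})

test_that("phase coherence is invariant to per-region amplitude scaling", {
  set.seed(13)
  m <- matrix(rnorm(4 * 60), 4, 60)
  a <- phase_coherence_dfc(hilbert_phase(bold_ts(m, 2)))
  b <- phase_coherence_dfc(hilbert_phase(bold_ts(m * c(3, 0.2, 10, 1), 2)))
  expect_equal(a$values, b$values, tolerance = 1e-10)
})

test_that("sliding-window dFC matches the weighted-correlation oracle", {
  set.seed(9)
  m <- matrix(rnorm(5 * 60), 5, 60)
  ts <- bold_ts(m, tr_seconds = 2)
  dfc <- sliding_window_dfc(ts, 20)
  expect_equal(dim(dfc$values), c(5, 5, 3))
  w <- exp(-((1:20 - 10.5)^2) / (2 * 5^2))
  for (win in 1:3) {
    idx <- ((win - 1) * 20 + 1):(win * 20)
    for (i in 1:4) for (j in (i + 1):5) {
      expect_equal(dfc$values[i, j, win],
                   oracle_weighted_cor(m[i, idx], m[j, idx], w),
                   tolerance = 1e-12)
    }
    expect_equal(diag(dfc$values[, , win]), rep(1, 5))
  }
})

test_that("sliding-window dFC hits exact bounds for copies and negations", {
  set.seed(10)
  x <- rnorm(60)
  ts <- bold_ts(rbind(x, x + 0, -x, rnorm(60)), tr_seconds = 2)
  dfc <- sliding_window_dfc(ts, 20)
  expect_true(all(abs(dfc$values[1, 2, ] - 1) < 1e-12))
  expect_true(all(abs(dfc$values[1, 3, ] + 1) < 1e-12))
  expect_true(all(dfc$values >= -1 & dfc$values <= 1))
})

test_that("sliding-window dFC validates window geometry", {
  ts <- bold_ts(matrix(rnorm(3 * 30), 3, 30), tr_seconds = 2)
  expect_error(sliding_window_dfc(ts, 3), "window_length")
  expect_error(sliding_window_dfc(ts, 20), "2 \\* window_length")
})
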