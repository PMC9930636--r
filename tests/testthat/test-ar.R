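test_that("stability timecourse is the superdiagonal at the requested lag", {
  set.seed(51)
  m <- matrix(rnorm(100), 10); m <- abs(m + t(m)); diag(m) <- 0
  sm <- stability_matrix_from_values(m, "mahalanobis")
  tc <- stability_timecourse(sm, lag = 1)
  expect_length(tc$values, 9)
  expect_equal(tc$values, m[cbind(1:9, 2:10)])
  tc3 <- stability_timecourse(sm, lag = 3)
  expect_equal(tc3$values, m[cbind(1:7, 4:10)])
  expect_error(stability_timecourse(sm, lag = 10), "lag")

  const <- angle_stability_matrix(make_constant_trajectory())
  expect_lt(max(abs(stability_timecourse(const)$values)), 1e-7)
})

test_that("timecourse spikes at planted regime switches", {
  fx <- make_test_trajectory(N = 16, T_len = 200, dwell = 50,
                             noise_sd = 0.15, seed = 8)
  tc <- stability_timecourse(angle_stability_matrix(fx$traj))$values
  # drop analytic-signal edge transients, then every top distance should
  # sit within 2 samples of a planted switch (switch at s: tc index s-1)
  interior <- 5:(length(tc) - 4)
  top <- interior[order(tc[interior], decreasing = TRUE)][1:3]
  for (pk in top)
    expect_lte(min(abs(pk - (fx$switches - 1))), 2)
})

test_that("conditional least squares recovers planted AR coefficients", {
  x1 <- generate_ar_series(0.9, constant = 0, noise_sd = 1, n = 2000,
                           seed = 61)
  f1 <- fit_ar(x1, 1)
  expect_lt(abs(f1$coefficients - 0.9), 0.05)

  x2 <- generate_ar_series(c(0.5, -0.3), constant = 0, noise_sd = 1,
                           n = 2000, seed = 62)
  f2 <- fit_ar(x2, 2)
  expect_lt(max(abs(f2$coefficients - c(0.5, -0.3))), 0.06)

  wn <- generate_ar_series(0, constant = 0, noise_sd = 2, n = 1000,
                           seed = 63)
  f0 <- fit_ar(wn, 0)
  expect_equal(f0$residual_variance, mean((wn - mean(wn))^2),
               tolerance = 1e-10)
  expect_equal(f0$constant, mean(wn), tolerance = 1e-10)
})

test_that("AIC identity and nested residual monotonicity hold", {
  x <- generate_ar_series(c(0.4, 0.2), constant = 1, noise_sd = 1, n = 400,
                          seed = 64)
  rss <- numeric(6)
  for (r in 0:5) {
    f <- fit_ar(x, r, n_condition = 5)
    expect_equal(f$aic, -2 * f$loglik + 2 * r)
    rss[r + 1] <- sum(f$residuals^2)
  }
  expect_true(all(diff(rss) <= 1e-8))
})

test_that("stab_ar model methods behave like a classed fit", {
  x <- generate_ar_series(c(0.6, -0.2), constant = 0.5, noise_sd = 1,
                          n = 800, seed = 65)
  f <- fit_ar(x, 2)
  expect_s3_class(f, "stab_ar")
  cf <- coef(f)
  expect_named(cf, c("constant", "phi1", "phi2"))
  expect_length(residuals(f), f$n_used)
  expect_equal(fitted(f) + residuals(f), x[-(1:2)])
  expect_equal(as.numeric(logLik(f)), f$loglik)
  p1 <- predict(f, n_ahead = 1)
  expect_equal(p1, cf[["constant"]] + cf[["phi1"]] * x[800] +
                 cf[["phi2"]] * x[799])
  sim <- simulate(f, nsim = 300, seed = 1)
  expect_length(sim, 300)
  tab <- summary(f)$coef_table
  expect_equal(dim(tab), c(3, 3))
  expect_output(print(f), "AR\\(2\\)")
})

test_that("AIC curve from the nested decomposition equals per-order fits", {
  x <- generate_ar_series(c(0.5, -0.3), constant = 0, noise_sd = 1,
                          n = 300, seed = 66)
  sel <- select_order(x, max_order = 8)
  direct <- vapply(0:8, function(r) fit_ar(x, r, n_condition = 8)$aic,
                   numeric(1))
  expect_equal(unname(sel$aic_curve), direct, tolerance = 1e-8)
  expect_equal(sel$fit$aic, sel$aic_curve[[sel$selected_order + 1]],
               tolerance = 1e-8)
})

test_that("first-local-minimum selection recovers true orders in simulation", {
  # strong AR(2): selection frequency should peak at the true order
  sels <- vapply(1:20, function(s)
    select_order(generate_ar_series(c(1.2, -0.6), 0, 1, 1000, seed = s),
                 max_order = 10)$selected_order, integer(1))
  tab <- table(factor(sels, levels = 0:10))
  expect_equal(as.integer(names(which.max(tab))), 2L)
  expect_gte(mean(sels == 2), 0.6)
})

test_that("selection rules handle edge cases", {
  # monotone-decreasing AIC: long-memory-like input, tiny max_order
  x <- generate_ar_series(c(0.4, 0.3, 0.2, 0.05), 0, 1, 600, seed = 67)
  sel <- select_order(x, max_order = 2)
  expect_true(sel$fallback_global)
  expect_equal(sel$selected_order, 2L)

  g <- select_order(x, max_order = 12, rule = "global_min")
  expect_equal(g$selected_order,
               as.integer(which.min(g$aic_curve)) - 1L)

  expect_warning(select_order(rnorm(60), max_order = 100), "capped")
  expect_error(fit_ar(rnorm(12), 5), "too short")
})
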