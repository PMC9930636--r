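test_that("principal angles reproduce closed-form plane constructions", {
  I6 <- diag(6)
  expect_equal(principal_angle(I6[, 1:2], I6[, 1:2]), 0)
  expect_equal(principal_angle(I6[, 1:3], I6[, 4:6]), pi / 2)

  alpha <- 0.4
  A <- I6[, 1:2]
  B <- cbind(I6[, 1], cos(alpha) * I6[, 2] + sin(alpha) * I6[, 3])
  expect_equal(principal_angle(A, B), alpha, tolerance = 1e-12)
  expect_equal(principal_angle(A, B, which = "all"), c(alpha, 0),
               tolerance = 1e-12)
  expect_equal(principal_angle(A, B, which = "smallest"), 0,
               tolerance = 1e-12)
})

test_that("principal angles agree with the Gram-SVD oracle on random subspaces", {
  set.seed(31)
  for (rep in 1:10) {
    A <- matrix(rnorm(8 * 3), 8, 3)
    B <- matrix(rnorm(8 * 3), 8, 3)
    expect_equal(principal_angle(A, B, which = "all"),
                 oracle_principal_angles(A, B), tolerance = 1e-8)
  }
})

test_that("principal angle is invariant to right-multiplication by invertible maps", {
  set.seed(32)
  for (rep in 1:10) {
    A <- matrix(rnorm(10 * 3), 10, 3)
    B <- matrix(rnorm(10 * 3), 10, 3)
    L1 <- matrix(rnorm(9), 3) + diag(3)
    L2 <- matrix(rnorm(9), 3) + diag(3)
    expect_equal(principal_angle(A, B),
                 principal_angle(A %*% L1, B %*% L2), tolerance = 1e-8)
  }
  expect_error(principal_angle(matrix(0, 5, 2), diag(5)[, 1:2]),
               "degenerate")
})

test_that("angle stability matrix is symmetric, bounded and block-structured", {
  fx <- make_test_trajectory()
  am <- angle_stability_matrix(fx$traj)
  v <- am$values
  expect_equal(v, t(v))
  expect_equal(diag(v), rep(0, nrow(v)))
  expect_true(all(v >= 0 & v <= pi / 2 + 1e-12))
  same <- outer(fx$states, fx$states, "==") & upper.tri(v)
  diff_ <- outer(fx$states, fx$states, "!=") & upper.tri(v)
  expect_lt(median(v[same]), median(v[diff_]))
})

test_that("mahalanobis profile matches the longhand quadratic-form oracle", {
  set.seed(33)
  A <- matrix(rnorm(6 * 2), 6, 2)
  B <- matrix(rnorm(6 * 2), 6, 2)
  for (mode in c("rowpair", "distribution")) {
    pr <- mahalanobis_profile(A, B, mode = mode)
    expect_equal(pr$per_roi_distance,
                 oracle_mahalanobis_profile(A, B, mode), tolerance = 1e-8)
    expect_true(all(pr$per_roi_distance >= 0))
  }
  expect_equal(mahalanobis_profile(A, A)$per_roi_distance, rep(0, 6))
  expect_error(mahalanobis_profile(matrix(1, 6, 2), B), "singular")
})

test_that("identity-covariance fixture reduces Mahalanobis to Euclidean rows", {
  # rows of A drawn so their sample covariance is the identity
  set.seed(34)
  raw <- matrix(rnorm(40), 20, 2)
  raw <- sweep(raw, 2, colMeans(raw))
  A <- raw %*% solve(chol(crossprod(raw) / (nrow(raw) - 1)))
  B <- A + matrix(rnorm(40, sd = 0.5), 20, 2)
  pr <- mahalanobis_profile(A, B, mode = "rowpair")
  expect_equal(pr$per_roi_distance, sqrt(rowSums((A - B)^2)),
               tolerance = 1e-6)
})

test_that("distribution-mode distance is affine invariant", {
  set.seed(35)
  A <- matrix(rnorm(12 * 3), 12, 3)
  B <- matrix(rnorm(12 * 3), 12, 3)
  L <- matrix(rnorm(9), 3) + 2 * diag(3)
  a <- mahalanobis_profile(A, B, mode = "distribution")$per_roi_distance
  b <- mahalanobis_profile(A %*% L, B %*% L,
                           mode = "distribution")$per_roi_distance
  expect_equal(a, b, tolerance = 1e-6)
})

test_that("mahalanobis stability matrix is symmetrized and consistent with profiles", {
  fx <- make_test_trajectory(N = 12, T_len = 40, dwell = 20)
  mm <- mahalanobis_stability_matrix(fx$traj)
  v <- mm$values
  expect_equal(v, t(v))
  expect_true(all(v >= 0))
  expect_equal(diag(v), rep(0, nrow(v)))
  a <- 5; b <- 30
  pab <- mean(mahalanobis_profile(fx$traj$subspaces[[a]],
                                  fx$traj$subspaces[[b]])$per_roi_distance)
  pba <- mean(mahalanobis_profile(fx$traj$subspaces[[b]],
                                  fx$traj$subspaces[[a]])$per_roi_distance)
  expect_equal(v[a, b], (pab + pba) / 2, tolerance = 1e-12)
  # block structure mirrors the planted regimes
  same <- outer(fx$states, fx$states, "==") & upper.tri(v)
  diff_ <- outer(fx$states, fx$states, "!=") & upper.tri(v)
  expect_lt(mean(v[same]), mean(v[diff_]))
  # constant trajectory degenerates to the zero matrix
  cm <- mahalanobis_stability_matrix(make_constant_trajectory())
  expect_lt(max(cm$values), 1e-6)
})

test_that("short/long-range profiles probe the planted regime structure", {
  const <- make_constant_trajectory(T_len = 25)
  pr <- short_long_range_profiles(const, near_pair = c(2, 7),
                                  far_pair = c(2, 20))
  expect_lt(max(pr$near$per_roi_distance), 1e-6)
  expect_lt(max(pr$far$per_roi_distance), 1e-6)

  fx <- make_test_trajectory(N = 12, T_len = 60, dwell = 30)
  # near pair within regime 1, far pair straddling the switch at t = 31
  pr <- short_long_range_profiles(fx$traj, near_pair = c(10, 15),
                                  far_pair = c(10, 45))
  expect_gt(mean(pr$far$per_roi_distance), mean(pr$near$per_roi_distance))
  expect_error(short_long_range_profiles(fx$traj, far_pair = c(10, 600)),
               "outside")
})
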