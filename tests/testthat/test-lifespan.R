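test_that("cohort assignment respects the published boundaries and bins", {
  tab <- data.frame(subject_id = c("a", "b", "c", "d", "e"),
                    age_years = c(40, 41, 18, 88, 60))
  ca <- assign_cohorts(tab)
  expect_equal(as.character(ca$group),
               c("young", "middle", "young", "old", "middle"))
  expect_equal(as.character(ca$age_bin),
               c("36-40", "41-45", "18-20", "81-88", "56-60"))
  expect_error(assign_cohorts(data.frame(subject_id = "x", age_years = 17)),
               "x")
})

test_that("cohort assignment is a total function partitioning [18, 88]", {
  ages <- seq(18, 88, by = 0.25)
  ca <- assign_cohorts(data.frame(subject_id = seq_along(ages),
                                  age_years = ages))
  expect_false(anyNA(ca$group))
  expect_false(anyNA(ca$age_bin))
  expect_equal(nlevels(ca$age_bin), 14)
  # bins nest inside groups
  split_groups <- tapply(as.character(ca$group), ca$age_bin,
                         function(g) length(unique(g)))
  expect_true(all(split_groups == 1))
})

test_that("hand-rolled normality tests reproduce frozen reference values", {
  x <- c(0.5, -1.2, 3.4, 0.8, -0.3, 2.1, -1.7, 0.9, 1.1, -0.6,
         0.2, 1.9, -2.2, 0.7, 1.4, -0.9, 0.3, 2.6, -1.1, 0.45)
  jb <- jarque_bera_test(x)
  expect_equal(jb$statistic, 0.2924291902682052, tolerance = 1e-10)
  expect_equal(jb$p_value, 0.8639722790427129, tolerance = 1e-10)
  dp <- dagostino_pearson_test(x)
  expect_equal(dp$statistic, 0.1096632401895877, tolerance = 1e-8)
  expect_equal(dp$p_value, 0.9466445304510037, tolerance = 1e-8)
  # a strongly skewed sample is flagged by both
  y <- exp(x)
  expect_equal(jarque_bera_test(y)$statistic, 81.19490528821183,
               tolerance = 1e-8)
  expect_equal(dagostino_pearson_test(y)$statistic, 35.14074964245469,
               tolerance = 1e-6)
  expect_lt(jarque_bera_test(y)$p_value, 1e-10)
  expect_lt(dagostino_pearson_test(y)$p_value, 1e-6)
})

test_that("group comparisons run the right Wilcoxon variant", {
  set.seed(71)
  a <- rnorm(30)
  same <- compare_groups(list(g1 = a, g2 = a))
  expect_equal(same$test, "wilcoxon_rank_sum")
  expect_gt(same$p_value, 0.9)
  expect_named(same$normality, c("g1", "g2"))
  expect_true(all(is.finite(unlist(same$normality))))

  sep <- compare_groups(list(lo = rnorm(30), hi = rnorm(30) + 50))
  expect_lt(sep$p_value, 0.001)

  b <- a + rnorm(30, 0.8)
  paired <- compare_groups(list(pre = a, post = b), paired = TRUE)
  expect_equal(paired$test, "wilcoxon_sign_rank")
  expect_lt(paired$p_value, 0.01)

  expect_error(compare_groups(list(a = a, b = a), paired = TRUE),
               "degenerate")
  expect_error(compare_groups(list(a = a, b = rnorm(5)), paired = TRUE),
               "equal-length")
  expect_error(compare_groups(list(a = 1:2, b = 1:5)), "at least 3")
})

test_that("ushape regression recovers planted curvature of either sign", {
  set.seed(72)
  ages <- runif(200, 18, 88)
  up <- 0.002 * (ages - 53)^2 + rnorm(200, sd = 0.3)
  fit <- ushape_regression(ages, up)
  expect_gt(fit$coefficients[["age2"]], 0)
  expect_equal(fit$curvature_sign, 1)
  expect_lt(fit$p_values[["age2"]], 0.01)

  down <- -0.002 * (ages - 53)^2 + rnorm(200, sd = 0.3)
  expect_equal(ushape_regression(ages, down)$curvature_sign, -1)

  expect_error(ushape_regression(1:5, 1:5), "n >= 10")
  expect_error(ushape_regression(rep(30, 20), rnorm(20)), "variance")
})

test_that("network_subset restricts regions while preserving order", {
  set.seed(73)
  ts <- bold_ts(matrix(rnorm(116 * 30), 116, 30), tr_seconds = 2)
  nets <- read_network_definition(n_regions = 116)
  wb <- network_subset(ts, nets$whole_brain)
  expect_equal(wb$values, ts$values)
  sm <- network_subset(ts, nets$SM)
  expect_equal(nrow(sm$values), length(nets$SM$region_indices))
  expect_equal(unname(sm$values),
               unname(ts$values[nets$SM$region_indices, ]))
  expect_equal(sm$region_labels,
               ts$region_labels[nets$SM$region_indices])
  tenet <- network_definition("custom", 1:10)
  expect_equal(dim(network_subset(ts, tenet)), c(10, 30))
  small <- bold_ts(matrix(rnorm(5 * 30), 5, 30), tr_seconds = 2)
  expect_error(network_subset(small, nets$SM), "beyond N")
})

test_that("a planted stable subnetwork shows lower subset entropy", {
  # regions 1-6 keep the same community/offset in every regime; the rest
  # reshuffle. The stable-network subset should be quieter than whole brain.
  N <- 20
  stable_idx <- 1:6
  coupling <- lapply(1:3, function(r) {
    mem <- c(rep(1L, 6), ((7:N + r) %% 3L) + 2L)
    list(membership = mem, offsets = c(0, 2 * pi * (1:3) / 4 + r))
  })
  g <- generate_regime_bold(regime_spec(3, dwell_mean = 12,
                                        coupling = coupling,
                                        dwell_distribution = "geometric"),
                            N = N, T_len = 200, seed = 21, noise_sd = 0.05)
  whole <- temporal_stability(g$ts)$entropy$E
  net <- network_definition("stable", stable_idx)
  sub <- temporal_stability(network_subset(g$ts, net))$entropy$E
  expect_lt(sub, whole)
})

test_that("run_pipeline produces entropies, comparisons and determinism", {
  out <- withr::local_tempdir()
  spec <- cohort_spec(n_subjects = 12, conditions = c("rest", "smt"),
                      N = 10, T_map = c(rest = 60, movie = 50, smt = 60),
                      dwell_map = function(age, cond)
                        if (cond == "rest") 8 else 30,
                      seed = 31)
  man <- generate_cohort(spec, out, overwrite = TRUE)
  res_dir <- withr::local_tempdir()
  cfg <- list(subject_table = file.path(out, "manifest.csv"),
              metrics = "angle", out_dir = res_dir)
  res <- run_pipeline(cfg, quiet = TRUE)
  expect_equal(nrow(res$entropy_table), 24)
  expect_length(list.files(res_dir, pattern = "stability\\.csv$"), 24)
  expect_true(file.exists(file.path(res_dir, "entropy_table.csv")))
  expect_true("rest_vs_smt" %in% res$group_tests$contrast)
  expect_length(res$lifespan_fits, 2)

  res2 <- run_pipeline(list(subject_table = file.path(out, "manifest.csv"),
                            metrics = "angle"), quiet = TRUE)
  expect_identical(res$entropy_table$entropy, res2$entropy_table$entropy)

  bad <- man; bad$path[1] <- "missing.csv"
  bad_tab <- file.path(out, "bad_manifest.csv")
  write.csv(bad, bad_tab, row.names = FALSE)
  expect_error(run_pipeline(list(subject_table = bad_tab), quiet = TRUE),
               "missing.csv")
  expect_error(run_pipeline(list(metrics = "angle")), "subject_table")
  expect_error(run_pipeline("no/such/config.json"), "not found")
})
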