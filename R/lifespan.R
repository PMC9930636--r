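#' Assign lifespan age cohorts and 5-year bins
#'
#' Ages in `[18, 88]` are partitioned into three cohorts — young (18-40),
#' middle (41-60), old (61-88) — and into nonoverlapping 5-year bins
#' starting at 18 (18-20, 21-25, ..., 76-80, 81-88). Both partitions are
#' exhaustive over the range; non-integer ages fall in the bin whose
#' interval contains them (e.g. 40.5 is middle).
#'
#' @param table data.frame with columns `subject_id` and `age_years` (e.g.
#'   from [read_subject_table()] or [generate_cohort()]).
#' @return A data.frame with columns `subject_id`, `age_years`, `group`
#'   (factor young/middle/old) and `age_bin` (factor of 14 bins).
#' @examples
#' assign_cohorts(data.frame(subject_id = c("a", "b"),
#'                           age_years = c(40, 41)))
#' @export
assign_cohorts <- function(table) {
  age <- as.numeric(table$age_years)
  bad <- !is.finite(age) | age < 18 | age > 88
  if (any(bad))
    stop(sprintf("age outside [18, 88] for subject(s): %s",
                 paste(unique(table$subject_id[bad]), collapse = ", ")),
         call. = FALSE)
  group <- cut(age, breaks = c(18, 40, 60, 88),
               labels = c("young", "middle", "old"), include.lowest = TRUE)
  ub <- c(20, seq(25, 80, by = 5), 88)
  lb <- c(18, ub[-length(ub)] + 1)
  bin_labels <- sprintf("%d-%d", lb, ub)
  age_bin <- cut(age, breaks = c(18, ub), labels = bin_labels,
                 include.lowest = TRUE)
  data.frame(subject_id = as.character(table$subject_id), age_years = age,
             group = group, age_bin = age_bin, stringsAsFactors = FALSE)
}

#' Jarque-Bera normality test
#'
#' \eqn{JB = n/6\,(S^2 + (K-3)^2/4)} with sample skewness `S` and kurtosis
#' `K`; approximately \eqn{\chi^2_2} under normality.
#'
#' @param x numeric vector, length >= 4.
#' @return List with `statistic` and `p_value`.
#' @export
jarque_bera_test <- function(x) {
  x <- as.numeric(x[is.finite(x)])
  n <- length(x)
  if (n < 4) stop("need at least 4 observations", call. = FALSE)
  m <- x - mean(x)
  m2 <- mean(m^2); m3 <- mean(m^3); m4 <- mean(m^4)
  S <- m3 / m2^1.5
  K <- m4 / m2^2
  jb <- n / 6 * (S^2 + (K - 3)^2 / 4)
  list(statistic = jb, p_value = stats::pchisq(jb, df = 2,
                                               lower.tail = FALSE))
}

#' D'Agostino-Pearson omnibus normality test
#'
#' Combines D'Agostino's transformed skewness Z and the Anscombe-Glynn
#' transformed kurtosis Z into \eqn{K^2 = Z_s^2 + Z_k^2 \sim \chi^2_2}.
#'
#' @param x numeric vector, length >= 20 recommended (>= 8 required).
#' @return List with `statistic`, `p_value`, `z_skewness`, `z_kurtosis`.
#' @export
dagostino_pearson_test <- function(x) {
  x <- as.numeric(x[is.finite(x)])
  n <- length(x)
  if (n < 8) stop("need at least 8 observations", call. = FALSE)
  m <- x - mean(x)
  m2 <- mean(m^2)
  g1 <- mean(m^3) / m2^1.5
  g2 <- mean(m^4) / m2^2
  # skewness (D'Agostino 1970)
  Y <- g1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  b2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  W2 <- -1 + sqrt(2 * (b2 - 1))
  delta <- 1 / sqrt(log(sqrt(W2)))
  alpha <- sqrt(2 / (W2 - 1))
  Zs <- delta * log(Y / alpha + sqrt((Y / alpha)^2 + 1))
  # kurtosis (Anscombe-Glynn 1983)
  Eb2 <- 3 * (n - 1) / (n + 1)
  Vb2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  xk <- (g2 - Eb2) / sqrt(Vb2)
  beta <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  A <- 6 + 8 / beta * (2 / beta + sqrt(1 + 4 / beta^2))
  Zk <- ((1 - 2 / (9 * A)) -
           ((1 - 2 / A) / (1 + xk * sqrt(2 / (A - 4))))^(1 / 3)) /
    sqrt(2 / (9 * A))
  K2 <- Zs^2 + Zk^2
  list(statistic = K2,
       p_value = stats::pchisq(K2, df = 2, lower.tail = FALSE),
       z_skewness = Zs, z_kurtosis = Zk)
}

#' Nonparametric two-sample comparison with normality diagnostics
#'
#' Runs both normality checks (Jarque-Bera and D'Agostino-Pearson omnibus)
#' on each sample, then the Wilcoxon rank-sum test for independent groups
#' or the Wilcoxon signed-rank test for paired samples (e.g. rest vs task
#' within subject). P-values are reported raw (uncorrected).
#'
#' @param values_by_group named list of exactly two numeric vectors, each of
#'   length >= 3.
#' @param paired use the signed-rank test (vectors must be equal length and
#'   subject-aligned).
#' @return A `"group_comparison"`: list with `test`, `statistic`, `p_value`,
#'   `group_labels`, `normality` (per-group list of both tests' p-values;
#'   `NA` where a sample is too small for a check).
#' @export
compare_groups <- function(values_by_group, paired = FALSE) {
  if (length(values_by_group) != 2)
    stop("exactly two groups are compared at a time", call. = FALSE)
  labs <- names(values_by_group)
  if (is.null(labs)) labs <- c("group1", "group2")
  a <- as.numeric(values_by_group[[1]])
  b <- as.numeric(values_by_group[[2]])
  if (length(a) < 3 || length(b) < 3)
    stop("need at least 3 values per group", call. = FALSE)
  if (paired && length(a) != length(b))
    stop("paired comparison requires equal-length samples", call. = FALSE)
  norm_flags <- lapply(list(a, b), function(v) {
    list(jarque_bera_p = tryCatch(jarque_bera_test(v)$p_value,
                                  error = function(e) NA_real_),
         dagostino_p = tryCatch(dagostino_pearson_test(v)$p_value,
                                error = function(e) NA_real_))
  })
  names(norm_flags) <- labs
  if (paired) {
    d <- a - b
    if (all(d == 0))
      stop("all paired differences are zero; signed-rank test degenerate",
           call. = FALSE)
    wt <- stats::wilcox.test(a, b, paired = TRUE, exact = FALSE)
    test <- "wilcoxon_sign_rank"
  } else {
    wt <- stats::wilcox.test(a, b, exact = FALSE)
    test <- "wilcoxon_rank_sum"
  }
  structure(list(test = test, statistic = unname(wt$statistic),
                 p_value = wt$p.value, group_labels = labs,
                 normality = norm_flags),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> %s: %s vs %s, W = %g, p = %.4g (uncorrected)\n",
              x$test, x$group_labels[1], x$group_labels[2], x$statistic,
              x$p_value))
  invisible(x)
}

#' Quadratic-in-age ("U-shape") regression of entropy on age
#'
#' Fits `E ~ b0 + b1 * age_c + b2 * age_c^2` by least squares, with age
#' mean-centred before squaring for conditioning. A positive quadratic
#' coefficient is a U-shaped lifespan trend (low entropy in young and old,
#' peak in middle age flips the sign).
#'
#' @param ages numeric vector of ages (variance > 0, n >= 10).
#' @param entropies numeric vector, same length.
#' @return A `"ushape_fit"`: list with `coefficients` (intercept, age,
#'   age^2 — on the centred-age scale), `p_values`, `r_squared`,
#'   `curvature_sign`, `age_center`, and the underlying `lm` object as
#'   `model`.
#' @export
ushape_regression <- function(ages, entropies) {
  ages <- as.numeric(ages); entropies <- as.numeric(entropies)
  if (length(ages) != length(entropies))
    stop("ages and entropies must have equal length", call. = FALSE)
  if (length(ages) < 10) stop("need n >= 10", call. = FALSE)
  if (stats::var(ages) <= 0) stop("age variance is zero", call. = FALSE)
  age_c <- ages - mean(ages)
  dat <- data.frame(E = entropies, age_c = age_c)
  fit <- stats::lm(E ~ age_c + I(age_c^2), data = dat)
  if (fit$rank < 3) stop("rank-deficient design", call. = FALSE)
  sm <- summary(fit)
  cf <- stats::coef(fit)
  names(cf) <- c("intercept", "age", "age2")
  pv <- sm$coefficients[, 4]
  names(pv) <- names(cf)
  structure(list(coefficients = cf, p_values = pv,
                 r_squared = sm$r.squared,
                 curvature_sign = sign(cf[["age2"]]),
                 age_center = mean(ages), model = fit),
            class = "ushape_fit")
}

#' @export
print.ushape_fit <- function(x, ...) {
  cat(sprintf(
    "<ushape_fit> E ~ age + age^2 (age centred at %.1f): b2 = %.4g (p = %.3g), %s curvature, R^2 = %.3f\n",
    x$age_center, x$coefficients[["age2"]], x$p_values[["age2"]],
    if (x$curvature_sign > 0) "U-shaped" else "inverted-U",
    x$r_squared))
  invisible(x)
}

#' Restrict a BOLD series to a named network's regions
#'
#' @param ts a [bold_ts()].
#' @param net a [network_definition()]; indices are 1-based into the rows
#'   of `ts` and their order is preserved.
#' @return A [bold_ts()] with `N = length(net$region_indices)` rows.
#' @export
network_subset <- function(ts, net) {
  stopifnot(inherits(ts, "bold_ts"), inherits(net, "network_definition"))
  idx <- net$region_indices
  if (any(idx > nrow(ts$values)))
    stop(sprintf("network '%s' has indices beyond N = %d", net$name,
                 nrow(ts$values)), call. = FALSE)
  if (length(idx) < 4)
    stop("network too small: a k = 3 subspace needs >= 4 regions",
         call. = FALSE)
  bold_ts(ts$values[idx, , drop = FALSE], tr_seconds = ts$tr_seconds,
          region_labels = ts$region_labels[idx], subject_id = ts$subject_id,
          condition = ts$condition)
}

#' Run the full temporal-stability pipeline over a subject table
#'
#' For every subject/condition row: read the parcellated series, optionally
#' restrict it to each requested network, run dFC estimation, the dominant
#' subspace trajectory, the requested stability matrices, and the entropy
#' summary; then compute group statistics: paired condition comparisons of
#' entropy within subjects, cohort (young/middle/old) comparisons within
#' conditions, and the quadratic-in-age regression per condition.
#' Deterministic given the same inputs.
#'
#' @param config either a JSON file path or a list with fields:
#'   `subject_table` (path, see [read_subject_table()]), and optionally
#'   `estimator` ("phase" default, or "window"), `window_length` (20),
#'   `k` (3), `metrics` (`"angle"` default, any of angle/mahalanobis),
#'   `networks` (`"whole_brain"` default, or path to a network-definition
#'   JSON), `bins` (256), `lag` (1), `out_dir` (optional: per-subject
#'   stability matrices, entropy_table.csv, group_tests.csv,
#'   lifespan_fit.json are written there).
#' @param quiet suppress progress messages.
#' @return List with `entropy_table` (subject_id, age_years, condition,
#'   network, metric, entropy), `group_tests` (data.frame), `lifespan_fits`
#'   (named list of [ushape_regression()] fits or `NULL`), `ar_reports`
#'   (named list of [select_order()] results per subject/condition for the
#'   first metric), `config`.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  if (is.character(config)) {
    if (!file.exists(config))
      stop(sprintf("config file not found: '%s'", config), call. = FALSE)
    config <- jsonlite::fromJSON(config, simplifyVector = TRUE)
  }
  cfg <- utils::modifyList(
    list(estimator = "phase", window_length = 20, k = 3, metrics = "angle",
         networks = "whole_brain", bins = 256, lag = 1, tr_seconds = 2,
         out_dir = NULL, max_order = 30, ar = FALSE),
    config)
  if (is.null(cfg$subject_table))
    stop("config must name a subject_table", call. = FALSE)
  tab <- read_subject_table(cfg$subject_table)
  nets <- if (identical(cfg$networks, "whole_brain")) NULL
          else read_network_definition(cfg$networks)
  if (!is.null(cfg$out_dir))
    dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(sprintf(...))
  rows <- list(); ar_reports <- list()
  for (i in seq_len(nrow(tab))) {
    sid <- tab$subject_id[i]; cond <- tab$condition[i]
    say("[%d/%d] %s / %s", i, nrow(tab), sid, cond)
    ts <- tryCatch(
      read_timeseries(tab$path[i], tr_seconds = cfg$tr_seconds,
                      subject_id = sid, condition = cond),
      error = function(e)
        stop(sprintf("subject %s, condition %s: %s", sid, cond,
                     conditionMessage(e)), call. = FALSE))
    net_list <- if (is.null(nets)) list(whole_brain = NULL) else nets
    for (nname in names(net_list)) {
      sub_ts <- if (is.null(net_list[[nname]])) ts
                else network_subset(ts, net_list[[nname]])
      dfc <- if (cfg$estimator == "phase")
               phase_coherence_dfc(hilbert_phase(sub_ts))
             else sliding_window_dfc(sub_ts, cfg$window_length)
      traj <- subspace_trajectory(dfc, k = cfg$k)
      for (metric in cfg$metrics) {
        sm <- if (metric == "angle") angle_stability_matrix(traj)
              else mahalanobis_stability_matrix(traj)
        ent <- stability_entropy(sm, bins = cfg$bins)
        rows[[length(rows) + 1]] <- data.frame(
          subject_id = sid, age_years = tab$age_years[i], condition = cond,
          network = nname, metric = metric, entropy = ent$E,
          stringsAsFactors = FALSE)
        if (!is.null(cfg$out_dir))
          write_matrix(sm$values,
                       file.path(cfg$out_dir,
                                 sprintf("%s_%s_%s_%s_stability.csv",
                                         sid, cond, nname, metric)))
        if (isTRUE(cfg$ar) && metric == cfg$metrics[1] &&
            nname == names(net_list)[1]) {
          tc <- stability_timecourse(sm, lag = cfg$lag)
          ar_reports[[paste(sid, cond, sep = "_")]] <-
            select_order(tc, max_order = cfg$max_order)
        }
      }
    }
  }
  entropy_table <- do.call(rbind, rows)
  group_tests <- pipeline_group_tests(entropy_table)
  lifespan_fits <- pipeline_lifespan_fits(entropy_table)
  if (!is.null(cfg$out_dir)) {
    utils::write.csv(entropy_table,
                     file.path(cfg$out_dir, "entropy_table.csv"),
                     row.names = FALSE)
    if (nrow(group_tests))
      utils::write.csv(group_tests,
                       file.path(cfg$out_dir, "group_tests.csv"),
                       row.names = FALSE)
    if (length(lifespan_fits))
      jsonlite::write_json(
        lapply(lifespan_fits, function(f)
          list(coefficients = as.list(f$coefficients),
               p_values = as.list(f$p_values), r_squared = f$r_squared,
               curvature_sign = f$curvature_sign)),
        file.path(cfg$out_dir, "lifespan_fit.json"), auto_unbox = TRUE)
  }
  list(entropy_table = entropy_table, group_tests = group_tests,
       lifespan_fits = lifespan_fits, ar_reports = ar_reports, config = cfg)
}

# paired condition contrasts within subject + cohort contrasts within
# condition, per network x metric stratum
pipeline_group_tests <- function(entropy_table) {
  out <- list()
  strata <- unique(entropy_table[, c("network", "metric")])
  for (s in seq_len(nrow(strata))) {
    et <- entropy_table[entropy_table$network == strata$network[s] &
                          entropy_table$metric == strata$metric[s], ]
    conds <- unique(et$condition)
    if (length(conds) >= 2) {
      for (i in seq_len(length(conds) - 1)) for (j in (i + 1):length(conds)) {
        a <- et[et$condition == conds[i], ]
        b <- et[et$condition == conds[j], ]
        common <- intersect(a$subject_id, b$subject_id)
        if (length(common) >= 3) {
          av <- a$entropy[match(common, a$subject_id)]
          bv <- b$entropy[match(common, b$subject_id)]
          cmp <- tryCatch(
            compare_groups(stats::setNames(list(av, bv),
                                           c(conds[i], conds[j])),
                           paired = TRUE),
            error = function(e) NULL)
          if (!is.null(cmp))
            out[[length(out) + 1]] <- data.frame(
              network = strata$network[s], metric = strata$metric[s],
              contrast = sprintf("%s_vs_%s", conds[i], conds[j]),
              test = cmp$test, statistic = cmp$statistic,
              p_value = cmp$p_value, stringsAsFactors = FALSE)
        }
      }
    }
    coh <- assign_cohorts(et)
    et$group <- coh$group
    for (cond in conds) {
      ec <- et[et$condition == cond, ]
      gl <- levels(ec$group)
      for (i in 1:2) for (j in (i + 1):3) {
        a <- ec$entropy[ec$group == gl[i]]
        b <- ec$entropy[ec$group == gl[j]]
        if (length(a) >= 3 && length(b) >= 3) {
          cmp <- compare_groups(stats::setNames(list(a, b), gl[c(i, j)]))
          out[[length(out) + 1]] <- data.frame(
            network = strata$network[s], metric = strata$metric[s],
            contrast = sprintf("%s_%s_vs_%s", cond, gl[i], gl[j]),
            test = cmp$test, statistic = cmp$statistic,
            p_value = cmp$p_value, stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (length(out)) do.call(rbind, out)
  else data.frame(network = character(), metric = character(),
                  contrast = character(), test = character(),
                  statistic = numeric(), p_value = numeric())
}

pipeline_lifespan_fits <- function(entropy_table) {
  out <- list()
  strata <- unique(entropy_table[, c("network", "metric", "condition")])
  for (s in seq_len(nrow(strata))) {
    et <- entropy_table[entropy_table$network == strata$network[s] &
                          entropy_table$metric == strata$metric[s] &
                          entropy_table$condition == strata$condition[s], ]
    if (nrow(et) >= 10 && stats::var(et$age_years) > 0) {
      key <- paste(strata$condition[s], strata$network[s], strata$metric[s],
                   sep = "_")
      out[[key]] <- ushape_regression(et$age_years, et$entropy)
    }
  }
  out
}
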