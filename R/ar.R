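#' Stability time course from a temporal stability matrix
#'
#' Extracts the superdiagonal at offset `lag` — the distance between the
#' dominant subspaces at `t` and `t + lag` — as the scalar time course
#' \eqn{\phi(t)} (angle metric) or \eqn{M(t)} (Mahalanobis metric) whose
#' stochastic structure is then characterized with AR models. Default lag 1:
#' successive dFC subspaces.
#'
#' @param mat a `"stability_matrix"`.
#' @param lag positive integer offset, `lag < T'`.
#' @return A `"stability_timecourse"`: list with `values` (length
#'   `T' - lag`), `metric`, `lag`.
#' @export
stability_timecourse <- function(mat, lag = 1) {
  stopifnot(inherits(mat, "stability_matrix"))
  TT <- nrow(mat$values)
  lag <- as.integer(lag)
  if (lag < 1 || lag >= TT)
    stop(sprintf("lag must be in [1, %d]", TT - 1), call. = FALSE)
  idx <- seq_len(TT - lag)
  structure(list(values = mat$values[cbind(idx, idx + lag)],
                 metric = mat$metric, lag = lag),
            class = "stability_timecourse")
}

#' @export
print.stability_timecourse <- function(x, ...) {
  cat(sprintf("<stability_timecourse> %s, lag %d, length %d\n",
              x$metric, x$lag, length(x$values)))
  invisible(x)
}

#' Fit an AR(rho) model by conditional least squares
#'
#' Fits \eqn{X_t = c + \sum_{i=1}^{\rho} \varphi_i X_{t-i} + \varepsilon_t}
#' by least squares conditional on the first `n_condition` observations
#' (default `n_condition = order`). When comparing fits across orders pass a
#' common `n_condition` (as [select_order()] does) so every fit uses the
#' same sample and likelihoods are comparable. The Gaussian log-likelihood
#' uses the maximum-likelihood residual variance (mean squared error), and
#' \eqn{AIC = -2L + 2\rho} counts the lag coefficients as the model's free
#' parameters.
#'
#' @param series numeric vector (e.g. a `"stability_timecourse"`'s values).
#' @param order AR order \eqn{\rho \ge 0}; 0 fits mean plus white noise.
#' @param n_condition number of leading observations conditioned on
#'   (`>= order`).
#' @return An object of class `"stab_ar"`: list with `order`, `constant`,
#'   `coefficients` (length `order`), `residual_variance` (MLE),
#'   `loglik`, `aic`, `fitted`, `residuals`, `n_used`, `n_condition`,
#'   `mean_` (process mean implied by the fit), `series`.
#' @examples
#' x <- generate_ar_series(0.8, constant = 0, noise_sd = 1, n = 500, seed = 1)
#' fit <- fit_ar(x, 1)
#' coef(fit)
#' @export
fit_ar <- function(series, order, n_condition = order) {
  if (inherits(series, "stability_timecourse")) series <- series$values
  x <- as.numeric(series)
  order <- as.integer(order)
  n_condition <- as.integer(n_condition)
  if (order < 0) stop("order must be >= 0", call. = FALSE)
  if (n_condition < order) stop("n_condition must be >= order", call. = FALSE)
  n <- length(x)
  if (n < order + 10)
    stop(sprintf("series too short for order %d (need >= %d points)",
                 order, order + 10), call. = FALSE)
  if (n <= n_condition + 1)
    stop("series too short for requested conditioning sample", call. = FALSE)
  tsel <- (n_condition + 1):n
  y <- x[tsel]
  X <- cbind(intercept = rep(1, length(tsel)))
  if (order > 0)
    X <- cbind(X, vapply(seq_len(order), function(i) x[tsel - i],
                         numeric(length(tsel))))
  fit <- stats::lm.fit(X, y)
  if (fit$rank < ncol(X))
    stop(sprintf(
      "near-collinear lag matrix at order %d; try a lower order", order),
      call. = FALSE)
  res <- fit$residuals
  n_eff <- length(y)
  s2 <- sum(res^2) / n_eff
  if (s2 <= 0) s2 <- .Machine$double.eps
  L <- -n_eff / 2 * (log(2 * pi * s2) + 1)
  phi <- if (order > 0) unname(fit$coefficients[-1]) else numeric(0)
  cst <- unname(fit$coefficients[1])
  structure(
    list(order = order, constant = cst, coefficients = phi,
         residual_variance = s2, loglik = L, aic = -2 * L + 2 * order,
         fitted = unname(fit$fitted.values), residuals = unname(res),
         n_used = n_eff, n_condition = n_condition,
         mean_ = if (order > 0 && abs(1 - sum(phi)) > 1e-12)
                   cst / (1 - sum(phi)) else cst,
         series = x),
    class = "stab_ar")
}

#' @export
print.stab_ar <- function(x, digits = 4, ...) {
  cat(sprintf("AR(%d) fit by conditional least squares (n = %d)\n",
              x$order, x$n_used))
  cat("  constant:", format(x$constant, digits = digits), "\n")
  if (x$order > 0)
    cat("  coefficients:",
        paste(format(x$coefficients, digits = digits), collapse = " "), "\n")
  cat(sprintf("  sigma^2 = %s, logLik = %s, AIC = %s\n",
              format(x$residual_variance, digits = digits),
              format(x$loglik, digits = digits),
              format(x$aic, digits = digits)))
  invisible(x)
}

#' @export
summary.stab_ar <- function(object, ...) {
  x <- object
  n <- length(x$series)
  tsel <- (x$n_condition + 1):n
  X <- cbind(rep(1, length(tsel)))
  if (x$order > 0)
    X <- cbind(X, vapply(seq_len(x$order), function(i) x$series[tsel - i],
                         numeric(length(tsel))))
  # dof-corrected variance for standard errors
  s2 <- sum(x$residuals^2) / (x$n_used - ncol(X))
  se <- sqrt(diag(chol2inv(chol(crossprod(X)))) * s2)
  est <- c(x$constant, x$coefficients)
  tab <- cbind(Estimate = est, `Std. Error` = se, `t value` = est / se)
  rownames(tab) <- c("constant",
                     if (x$order > 0) paste0("phi", seq_len(x$order)))
  out <- list(fit = x, coef_table = tab)
  class(out) <- "summary.stab_ar"
  out
}

#' @export
print.summary.stab_ar <- function(x, ...) {
  print(x$fit)
  cat("\n")
  stats::printCoefmat(x$coef_table)
  invisible(x)
}

#' @export
coef.stab_ar <- function(object, ...) {
  cf <- c(constant = object$constant)
  if (object$order > 0) {
    phi <- object$coefficients
    names(phi) <- paste0("phi", seq_along(phi))
    cf <- c(cf, phi)
  }
  cf
}

#' @export
residuals.stab_ar <- function(object, ...) object$residuals

#' @export
fitted.stab_ar <- function(object, ...) object$fitted

#' @export
logLik.stab_ar <- function(object, ...) {
  structure(object$loglik, df = object$order + 2, class = "logLik")
}

#' @export
predict.stab_ar <- function(object, n_ahead = 1, ...) {
  x <- object$series
  phi <- object$coefficients
  p <- object$order
  out <- numeric(n_ahead)
  hist <- x
  for (h in seq_len(n_ahead)) {
    xt <- object$constant +
      if (p > 0) sum(phi * hist[length(hist) - seq_len(p) + 1]) else 0
    out[h] <- xt
    hist <- c(hist, xt)
  }
  out
}

#' @export
simulate.stab_ar <- function(object, nsim = length(object$series),
                             seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  generate_ar_series(object$coefficients, constant = object$constant,
                     noise_sd = sqrt(object$residual_variance), n = nsim,
                     seed = NULL)
}

#' AIC-based AR order selection ("first minimal AIC")
#'
#' Fits AR(0) ... AR(`max_order`) on a common conditioning sample (the first
#' `max_order` observations are conditioned on for every order, so AIC
#' values are comparable) and selects the order at the first local minimum
#' of the AIC curve: the smallest \eqn{\rho} with
#' \eqn{AIC(\rho) < AIC(\rho-1)} and \eqn{AIC(\rho) \le AIC(\rho+1)}
#' (\eqn{\rho = 0} qualifies when \eqn{AIC(0) \le AIC(1)}). If the curve has
#' no local minimum (monotonically decreasing), the global minimum — i.e.
#' `max_order` — is returned with `fallback_global = TRUE`. Orders above 1
#' indicate a non-Markovian stability time course; order 0 is white noise.
#'
#' `max_order` is capped at one third of the series length to avoid
#' degenerate fits (a warning is emitted when the cap binds).
#'
#' @param series numeric vector or `"stability_timecourse"`.
#' @param max_order largest candidate order, default 100.
#' @param rule `"first_local_min"` (default) or `"global_min"`.
#' @return An `"ar_order_selection"`: list with `aic_curve` (named, orders
#'   0..max_order), `selected_order`, `rule`, `fallback_global`, `fit`
#'   (the `"stab_ar"` fit at the selected order on the common sample).
#' @export
select_order <- function(series, max_order = 100,
                         rule = c("first_local_min", "global_min")) {
  rule <- match.arg(rule)
  if (inherits(series, "stability_timecourse")) series <- series$values
  x <- as.numeric(series)
  n <- length(x)
  cap <- max(1L, n %/% 3L)
  max_order <- as.integer(max_order)
  if (max_order > cap) {
    warning(sprintf("max_order capped at n/3 = %d", cap), call. = FALSE)
    max_order <- cap
  }
  if (n <= max_order + 10)
    stop("series too short for requested max_order", call. = FALSE)
  aic <- ar_aic_curve(x, max_order)
  if (rule == "global_min") {
    sel <- which.min(aic) - 1L
    fallback <- FALSE
  } else {
    sel <- NA_integer_
    for (r in 0:max_order) {
      ok_left <- if (r == 0) TRUE else aic[r + 1] < aic[r]
      # the right neighbour must exist: the endpoint is not a local minimum
      ok_right <- if (r == max_order) FALSE else aic[r + 1] <= aic[r + 2]
      if (ok_left && ok_right) { sel <- r; break }
    }
    fallback <- is.na(sel)
    if (fallback) sel <- which.min(aic) - 1L
  }
  structure(
    list(aic_curve = stats::setNames(aic, 0:max_order),
         selected_order = as.integer(sel), rule = rule,
         fallback_global = fallback,
         fit = fit_ar(x, sel, n_condition = max_order)),
    class = "ar_order_selection")
}

#' @export
print.ar_order_selection <- function(x, ...) {
  cat(sprintf(
    "<ar_order_selection> selected order %d by %s%s (AIC = %.4f)\n",
    x$selected_order, x$rule,
    if (x$fallback_global) " [global-min fallback]" else "",
    x$aic_curve[[x$selected_order + 1]]))
  invisible(x)
}

# AIC over nested AR orders from one QR factorization of the full lag
# matrix; columns enter in lag order, so residual sums of squares for all
# nested models fall out of the orthogonalized responses. Falls back to
# per-order fits if the decomposition pivots.
ar_aic_curve <- function(x, max_order) {
  n <- length(x)
  tsel <- (max_order + 1):n
  y <- x[tsel]
  n_eff <- length(y)
  X <- cbind(rep(1, n_eff))
  if (max_order > 0)
    X <- cbind(X, vapply(seq_len(max_order), function(i) x[tsel - i],
                         numeric(n_eff)))
  qr_ <- qr(X)
  if (qr_$rank < ncol(X) || !identical(qr_$pivot, seq_len(ncol(X)))) {
    return(vapply(0:max_order, function(r)
      fit_ar(x, r, n_condition = max_order)$aic, numeric(1)))
  }
  qty <- qr.qty(qr_, y)
  tss <- sum(y^2)
  proj <- cumsum(qty[seq_len(ncol(X))]^2)
  rss <- pmax(tss - proj, .Machine$double.eps)  # rss[j]: model with j-1 lags
  s2 <- rss / n_eff
  L <- -n_eff / 2 * (log(2 * pi * s2) + 1)
  -2 * L + 2 * (0:max_order)
}
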