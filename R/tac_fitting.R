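#' Time-activity-curve fitting and cumulated activity
#'
#' Sum-of-exponential fits to tumor time-activity curves (%IA vs hours),
#' AICc model selection between mono- and bi-exponential candidates, and the
#' analytic time-integral of the selected curve (cumulated activity, A-tilde).
#' The fitted data are treated as decay-corrected, so the physical decay
#' constant is re-added to the biological rates before integration.
#'
#' @name tac-fitting
NULL

#' Construct a time-activity curve
#'
#' @param times hours post-injection, strictly increasing, >= 0.
#' @param values %IA at each time, >= 0.
#' @param sds optional per-point SDs (%IA), for 1/SD^2 weighting.
#' @param n_per_point optional animals contributing to each point.
#' @return object of class `tac`.
#' @export
make_tac <- function(times, values, sds = NULL, n_per_point = NULL) {
  stopifnot(length(times) == length(values),
            all(is.finite(times)), all(is.finite(values)),
            all(times >= 0), all(values >= 0))
  if (anyDuplicated(times)) stop("times must be distinct")
  if (!is.null(sds)) stopifnot(length(sds) == length(times), all(sds >= 0))
  o <- order(times)  # stored strictly increasing regardless of input order
  if (length(n_per_point) == length(times)) n_per_point <- n_per_point[o]
  structure(list(times = times[o], values = values[o], sds = sds[o],
                 n_per_point = n_per_point),
            class = "tac")
}

biexp_eval <- function(p, t) {
  # p = c(A1, l1, A2, l2); mono is A2 = 0
  p[1] * exp(-p[2] * t) + p[3] * exp(-p[4] * t)
}

model_k <- function(model_form) {
  switch(model_form, mono_exp = 2L, bi_exp = 4L, bi_exp_fixed_phys = 3L,
         stop("unknown model form: ", model_form))
}

#' Corrected Akaike information criterion
#'
#' `AICc = n log(rss/n) + 2k + 2k(k+1)/(n - k - 1)` for a least-squares fit
#' with `k` free parameters. Returns `NA` (with a message) when
#' `n - k - 1 <= 0`, i.e. when the candidate cannot be scored at this n.
#'
#' @param n number of data points.
#' @param rss residual sum of squares.
#' @param k number of free parameters.
#' @return AICc value or `NA_real_`.
#' @export
aicc <- function(n, rss, k) {
  if (n - k - 1 <= 0) {
    message("AICc undefined for k = ", k, " at n = ", n, "; candidate excluded")
    return(NA_real_)
  }
  n * log(rss / n) + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

# Weighted linear solve for amplitudes given fixed rates; clamps at 0.
amplitudes_for_rates <- function(t, y, w, lambdas) {
  X <- sapply(lambdas, function(l) exp(-l * t))
  X <- matrix(X, nrow = length(t))
  XtW <- t(X * w)
  a <- tryCatch(solve(XtW %*% X, XtW %*% y), error = function(e) NULL)
  if (is.null(a)) return(rep(0, length(lambdas)))
  pmax(as.numeric(a), 0)
}

#' Fit a sum-of-exponentials model to a time-activity curve
#'
#' Nonlinear least squares with nonnegative amplitudes and positive rates,
#' using a deterministic multi-start over a log-spaced rate grid spanning
#' `[1/(10 t_max), 10/t_min]` (amplitudes seeded by a clamped linear solve),
#' refined by quasi-Newton optimisation on log-parameters and polished with
#' `nls`. Rates are reported in descending order (`lambda1 >= lambda2`).
#'
#' @param tac a [make_tac()] object.
#' @param model_form `"bi_exp"`, `"mono_exp"` or `"bi_exp_fixed_phys"` (second
#'   rate pinned to `fixed_lambda`).
#' @param weighting `"none"` (unweighted LS on the means, the default) or
#'   `"inv_var"` (1/SD^2 using `tac$sds`).
#' @param n_grid rate-grid resolution of the multi-start.
#' @param fixed_lambda physical decay constant (1/h) for
#'   `bi_exp_fixed_phys`.
#' @param max_amplitude upper bound on each amplitude. Amplitudes are %IA, so
#'   the physical ceiling is 100; the default `max(100, 3 max(values))` keeps
#'   the bound inactive for ordinary data while excluding the degenerate
#'   "spike" optimum (a huge amplitude on a rate faster than the first
#'   sampling time) that unconstrained sum-of-exponential LS admits.
#' @param seed unused by the deterministic start grid; accepted for interface
#'   stability.
#' @return object of class `fit_result`: `model_form, A1, lambda1, A2,
#'   lambda2, rss, aicc, n_points, k, converged, fitted`.
#' @export
fit_model <- function(tac, model_form = c("bi_exp", "mono_exp", "bi_exp_fixed_phys"),
                      weighting = c("none", "inv_var"), n_grid = 6,
                      fixed_lambda = NULL, max_amplitude = NULL, seed = NULL) {
  stopifnot(inherits(tac, "tac"))
  model_form <- match.arg(model_form)
  weighting <- match.arg(weighting)
  t <- tac$times; y <- tac$values; n <- length(t)
  k <- model_k(model_form)
  if (n < k + 1) stop("need at least ", k + 1, " points for ", model_form)
  w <- if (weighting == "inv_var") {
    if (is.null(tac$sds) || any(tac$sds <= 0)) stop("inv_var weighting needs positive sds")
    1 / tac$sds^2
  } else rep(1, n)

  tmin <- max(min(t[t > 0], Inf), 1e-3)
  lam_hi <- 10 / tmin                  # rates faster than this are unidentifiable
  lam_lo <- 1 / (1000 * max(t))
  A_hi <- max_amplitude %||% max(100, 3 * max(y))
  lgrid <- exp(seq(log(1 / (10 * max(t))), log(lam_hi), length.out = n_grid))

  obj_full <- function(par) {  # par = log(A1), log(l1), [log(A2), log(l2)]
    p <- exp(par)
    pr <- if (length(p) == 2) c(p, 0, 1) else c(p[1], p[2], p[3], p[4])
    r <- y - biexp_eval(pr, t)
    sum(w * r^2)
  }
  rss_of <- function(pr) sum(w * (y - biexp_eval(pr, t))^2)

  eps <- 1e-9
  box <- function(npar) {
    lo <- rep(c(log(eps / 10), log(lam_lo)), npar / 2)
    hi <- rep(c(log(A_hi), log(lam_hi)), npar / 2)
    list(lo = lo, hi = hi)
  }
  best <- NULL
  try_start <- function(par) {
    b <- box(length(par))
    par <- pmin(pmax(par, b$lo), b$hi)
    fit <- tryCatch(optim(par, obj_full, method = "L-BFGS-B",
                          lower = b$lo, upper = b$hi,
                          control = list(maxit = 500, factr = 1e3)),
                    error = function(e) NULL)
    if (is.null(fit)) return()
    if (is.null(best) || fit$value < best$value) best <<- fit
  }

  if (model_form == "mono_exp") {
    for (l in lgrid) {
      A <- amplitudes_for_rates(t, y, w, l)
      try_start(log(c(max(A, eps), l)))
    }
  } else if (model_form == "bi_exp") {
    pairs <- which(upper.tri(matrix(0, n_grid, n_grid)), arr.ind = TRUE)
    for (r in seq_len(nrow(pairs))) {
      l1 <- lgrid[pairs[r, 2]]; l2 <- lgrid[pairs[r, 1]]  # l1 > l2
      A <- amplitudes_for_rates(t, y, w, c(l1, l2))
      try_start(log(c(max(A[1], eps), l1, max(A[2], eps), l2)))
    }
  } else {  # bi_exp_fixed_phys: free (A1, l1), amplitude A2 on fixed rate
    if (is.null(fixed_lambda) || fixed_lambda <= 0) {
      stop("bi_exp_fixed_phys requires a positive fixed_lambda")
    }
    obj_fixed <- function(par) {
      p <- exp(par)  # log A1, log l1, log A2
      r <- y - (p[1] * exp(-p[2] * t) + p[3] * exp(-fixed_lambda * t))
      sum(w * r^2)
    }
    lo <- c(log(eps / 10), log(lam_lo), log(eps / 10))
    hi <- c(log(A_hi), log(lam_hi), log(A_hi))
    for (l in lgrid) {
      A <- amplitudes_for_rates(t, y, w, c(l, fixed_lambda))
      par <- pmin(pmax(log(c(max(A[1], eps), l, max(A[2], eps))), lo), hi)
      fit <- tryCatch(optim(par, obj_fixed, method = "L-BFGS-B",
                            lower = lo, upper = hi,
                            control = list(maxit = 500, factr = 1e3)),
                      error = function(e) NULL)
      if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
    }
  }
  if (is.null(best)) {
    return(structure(list(model_form = model_form, converged = FALSE,
                          rss = NA_real_, aicc = NA_real_, n_points = n, k = k),
                     class = "fit_result"))
  }

  p <- exp(best$par)
  if (model_form == "mono_exp") {
    pr <- c(p[1], p[2], 0, 0)
  } else if (model_form == "bi_exp") {
    pr <- c(p[1], p[2], p[3], p[4])
    # nls polish from the multi-start optimum (port handles the bound A >= 0)
    pol <- tryCatch({
      df <- data.frame(t = t, y = y, w = w)
      lo <- c(0, lam_lo, 0, lam_lo); hi <- c(A_hi, lam_hi, A_hi, lam_hi)
      st <- pmin(pmax(pr, lo), hi)
      m <- suppressWarnings(
        nls(y ~ A1 * exp(-l1 * t) + A2 * exp(-l2 * t), data = df,
            start = list(A1 = st[1], l1 = st[2], A2 = st[3], l2 = st[4]),
            weights = w, algorithm = "port", lower = lo, upper = hi,
            control = list(warnOnly = TRUE, maxiter = 200)))
      as.numeric(coef(m))
    }, error = function(e) NULL)
    if (!is.null(pol) && all(is.finite(pol)) && rss_of(pol) <= rss_of(pr)) pr <- pol
  } else {
    pr <- c(p[1], p[2], p[3], fixed_lambda)
  }
  # order components by descending rate
  if (pr[4] > pr[2]) pr <- pr[c(3, 4, 1, 2)]
  rss <- rss_of(pr)
  structure(list(model_form = model_form,
                 A1 = pr[1], lambda1 = pr[2], A2 = pr[3], lambda2 = pr[4],
                 rss = rss, aicc = suppressMessages(aicc(n, rss, k)),
                 n_points = n, k = k, weighting = weighting,
                 converged = TRUE,
                 fitted = biexp_eval(pr, t)),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  if (!isTRUE(x$converged)) {
    cat("Fit (", x$model_form, "): NOT CONVERGED\n"); return(invisible(x))
  }
  cat(sprintf("Fit (%s): A1 = %.4g %%IA, lambda1 = %.4g /h, A2 = %.4g %%IA, lambda2 = %.4g /h\n",
              x$model_form, x$A1, x$lambda1, x$A2, x$lambda2))
  cat(sprintf("  rss = %.4g, AICc = %.4g (n = %d, k = %d)\n",
              x$rss, x$aicc, x$n_points, x$k))
  invisible(x)
}

#' Select the best fit by AICc
#'
#' Minimum-AICc candidate among fits of the same data; candidates whose AICc
#' is undefined (`n - k - 1 <= 0`) or that failed to converge are excluded
#' with a notice. Ties go to the model with fewer parameters.
#'
#' @param fits list of `fit_result` objects on identical data.
#' @return the selected `fit_result`.
#' @export
select_model <- function(fits) {
  if (inherits(fits, "fit_result")) return(fits)
  stopifnot(length(fits) >= 1)
  ns <- vapply(fits, `[[`, integer(1), "n_points")
  if (length(unique(ns)) != 1) stop("candidate fits are not on identical data")
  ok <- vapply(fits, function(f) isTRUE(f$converged) && is.finite(f$aicc), logical(1))
  if (!any(ok)) stop("no candidate has a defined AICc")
  if (any(!ok)) message(sum(!ok), " candidate(s) excluded (no AICc or not converged)")
  fits <- fits[ok]
  a <- vapply(fits, `[[`, numeric(1), "aicc")
  kk <- vapply(fits, `[[`, integer(1), "k")
  fits[[order(a, kk)[1]]]
}

#' Cumulated activity from a fitted curve
#'
#' Analytic time-integral of the fitted sum of exponentials. When the fitted
#' data are decay-corrected (the default convention for gamma-counting
#' quantification), the physical decay constant is added back to each
#' biological rate before integrating, so the integral reflects physically
#' decaying activity: `A-tilde = sum_i A_i / (lambda_i + lambda_phys)` for an
#' infinite horizon.
#'
#' @param fit converged `fit_result`.
#' @param physical_lambda physical decay constant in 1/h.
#' @param data_is_decay_corrected if `TRUE` (default) add `physical_lambda`
#'   to the fitted rates; if `FALSE` integrate the fitted rates as-is.
#' @param horizon hours (default `Inf`).
#' @return object of class `cumulated_activity` with `value` in %IA·h.
#' @examples
#' f <- structure(list(A1 = 1, lambda1 = 0.1, A2 = 0, lambda2 = 1,
#'                     converged = TRUE), class = "fit_result")
#' cumulated_activity(f, physical_lambda = 0)$value  # 10
#' @export
cumulated_activity <- function(fit, physical_lambda, data_is_decay_corrected = TRUE,
                               horizon = Inf) {
  stopifnot(inherits(fit, "fit_result"))
  if (!isTRUE(fit$converged)) stop("cannot integrate a non-converged fit")
  stopifnot(physical_lambda >= 0)
  A <- c(fit$A1, fit$A2)
  lam <- c(fit$lambda1, fit$lambda2)
  keep <- A > 0
  lam_eff <- lam + if (data_is_decay_corrected) physical_lambda else 0
  if (is.infinite(horizon) && any(lam_eff[keep] <= 0)) {
    stop("divergent integral: nonpositive effective rate with infinite horizon")
  }
  terms <- ifelse(keep,
                  A / lam_eff * (1 - if (is.infinite(horizon)) 0 else exp(-lam_eff * horizon)),
                  0)
  structure(list(value = sum(terms), horizon = horizon,
                 physical_decay_applied = data_is_decay_corrected,
                 physical_lambda = physical_lambda,
                 lambda_eff = lam_eff, amplitudes = A),
            class = "cumulated_activity")
}

# Asymptotic parameter covariance of a bi-exponential fit at known per-point
# noise SDs (delta method on the weighted LS estimator). Used by the
# recovery checks; sigma defaults to tac$sds.
fit_param_se <- function(fit, tac, sigma = NULL) {
  stopifnot(inherits(fit, "fit_result"), inherits(tac, "tac"))
  sigma <- sigma %||% tac$sds
  if (is.null(sigma)) stop("per-point noise SDs required")
  t <- tac$times
  J <- cbind(exp(-fit$lambda1 * t), -fit$A1 * t * exp(-fit$lambda1 * t),
             exp(-fit$lambda2 * t), -fit$A2 * t * exp(-fit$lambda2 * t))
  W <- diag(1 / sigma^2)
  cov <- tryCatch(solve(t(J) %*% W %*% J), error = function(e) {
    MASSlike <- svd(t(J) %*% W %*% J)
    d <- MASSlike$d; d[d > 1e-12 * max(d)] <- 1 / d[d > 1e-12 * max(d)]
    d[d <= 1e-12 * max(MASSlike$d)] <- 0
    MASSlike$v %*% diag(d) %*% t(MASSlike$u)
  })
  se <- sqrt(pmax(diag(cov), 0))
  setNames(se, c("A1", "lambda1", "A2", "lambda2"))
}
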