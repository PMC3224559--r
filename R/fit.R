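#' Fit the capacity-limited surge model to observed triage timescales
#'
#' Recovers the rate constants (ka, kd, k') of the capacity-limited
#' single-center model from two observable timescales and one constraint:
#' the time t1 at which the center saturated, the time t99 at which the
#' chosen fraction of the cohort had been discharged, and the assumed gap
#' tau = t99 - t2 between complete discharge and queue exhaustion (needed
#' because three equations in three unknowns built from t1 and t99 alone
#' are not uniquely determined). The system
#' \deqn{t_1(k_a, k_d) = t_1^{obs}, \quad t_2(k_a, k_d, k') = t_{99}^{obs} - \tau,
#'   \quad t_{99}(k_a, k_d, k') = t_{99}^{obs}}
#' has two roots, one with admission slower than discharge (\code{ka < kd})
#' and one with the roles reversed; the branch is selected by the starting
#' point of a damped Newton iteration and reported in the result.
#'
#' Parameter uncertainties assume unit variance on each observed timescale
#' (overridable via \code{obs_var}): the sum of squared errors is profiled
#' on a local grid around the optimum for each parameter in turn, a
#' quadratic is fitted, and the variance is approximated as twice the
#' inverse curvature, neglecting covariances.
#'
#' @param t1 Observed saturation time (days).
#' @param t99 Observed time to discharge \code{threshold} of the cohort
#'   (days).
#' @param tau Assumed t99 - t2 gap (days).
#' @param branch Which root to select: \code{"ka<kd"} (default; admission
#'   slower than discharge) or \code{"ka>kd"}.
#' @param threshold Discharged fraction defining t99.
#' @param obs_var Variances of the observed (t1, t2, t99), used only for
#'   the uncertainty estimate.
#' @return An object of class \code{"surge_fit"}: a list with the fitted
#'   [rate_set()] (\code{rates}), one-standard-deviation uncertainties
#'   (\code{sigmas}), the residual sum of squares at the optimum
#'   (\code{residual}), the selected \code{branch}, the observations, and
#'   convergence details. Methods: \code{print}, \code{summary},
#'   \code{coef}, \code{predict}, \code{plot}, \code{residuals},
#'   \code{vcov}.
#' @examples
#' fit <- surge_fit(t1 = 2, t99 = 10, tau = 2)
#' coef(fit)
#' summary(fit)
#' @export
surge_fit <- function(t1 = 2, t99 = 10, tau = 2,
                      branch = c("ka<kd", "ka>kd"),
                      threshold = 0.99, obs_var = c(1, 1, 1)) {
  branch <- match.arg(branch)
  if (!(tau > 0)) stop("'tau' must be positive")
  if (!(t1 > 0) || !(t1 < t99 - tau)) {
    stop("observations must satisfy 0 < t1 < t99 - tau")
  }
  t2_obs <- t99 - tau
  obs <- c(t1 = t1, t2 = t2_obs, t99 = t99)

  resid_fn <- function(theta) {
    r <- rate_set_quiet(exp(theta[1]), exp(theta[2]), exp(theta[3]))
    bp <- capacity_breakpoints(r)
    suppressWarnings(
      c(bp$t1 - t1, bp$t2 - t2_obs, capacity_t99(r, threshold) - t99))
  }

  starts <- fit_starts(branch, t1, t2_obs)
  sol <- NULL
  for (th0 in starts) {
    cand <- try(newton_damped(resid_fn, th0), silent = TRUE)
    if (inherits(cand, "try-error") || !cand$converged) next
    ka <- exp(cand$x[1]); kd <- exp(cand$x[2])
    if ((branch == "ka<kd") == (ka < kd)) { sol <- cand; break }
  }
  if (is.null(sol)) {
    stop("fit did not converge to the requested branch '", branch,
         "' from any starting point")
  }
  rates <- rate_set_quiet(exp(sol$x[1]), exp(sol$x[2]), exp(sol$x[3]))
  fit <- structure(
    list(rates = rates, sigmas = NULL,
         residual = sum(sol$r^2 / obs_var), branch = branch,
         observations = obs, tau = tau, threshold = threshold,
         obs_var = obs_var, iterations = sol$iter),
    class = "surge_fit")
  fit$sigmas <- fit_uncertainties(fit)
  fit
}

#' @rdname surge_fit
#' @param obs Alias interface: a list or named vector with elements
#'   \code{t1}, \code{t99}, \code{tau}.
#' @param ... Passed on to [surge_fit()].
#' @export
fit_capacity_model <- function(obs, ...) {
  obs <- as.list(obs)
  surge_fit(t1 = obs$t1, t99 = obs$t99, tau = obs$tau, ...)
}

#' Curvature-based parameter uncertainties for a surge fit
#'
#' Profiles the (variance-weighted) sum of squared timescale errors along
#' each parameter in turn, holding the others at their fitted values, fits
#' a quadratic on a local grid, and reports sigma = sqrt(2 / curvature).
#' Covariances are neglected.
#'
#' @param fit A [surge_fit()] result.
#' @param span Half-width of the profiling grid, as a fraction of each
#'   parameter value.
#' @param n_grid Number of grid points per parameter.
#' @param degree Degree of the polynomial fitted to the profiled error.
#'   The polynomial is fitted in the parameter offset from the optimum, so
#'   its quadratic coefficient is the local curvature there; degrees above
#'   2 let the fit absorb the asymmetry of the profile across the grid
#'   instead of biasing the curvature.
#' @return Named vector of one-standard-deviation uncertainties for
#'   \code{ka}, \code{kd}, \code{kprime}.
#' @export
fit_uncertainties <- function(fit, span = 0.2, n_grid = 11, degree = 4) {
  stopifnot(inherits(fit, "surge_fit"))
  p0 <- coef(fit)
  obs <- fit$observations
  sse <- function(p) {
    r <- rate_set_quiet(p[1], p[2], p[3])
    bp <- capacity_breakpoints(r)
    model <- c(bp$t1, bp$t2, capacity_t99(r, fit$threshold))
    sum((model - obs)^2 / fit$obs_var)
  }
  sig <- vapply(seq_along(p0), function(j) {
    grid <- p0[j] * seq(1 - span, 1 + span, length.out = n_grid)
    vals <- vapply(grid, function(g) { p <- p0; p[j] <- g; sse(p) }, numeric(1))
    x <- grid - p0[j]
    co <- stats::coef(stats::lm(vals ~ stats::poly(x, degree, raw = TRUE)))
    curvature <- 2 * co[[3]]   # d2 SSE / dp2 at the optimum (x = 0)
    if (!is.finite(curvature) || curvature <= 0) {
      stop("non-positive profiled curvature for parameter ", names(p0)[j],
           ": the optimum appears misidentified")
    }
    sqrt(2 / curvature)
  }, numeric(1))
  names(sig) <- names(p0)
  sig
}

#' Re-fit the model across a range of the t99 - t2 constraint
#'
#' The gap tau = t99 - t2 is an assumption, not an observation; this scan
#' re-fits the model for each supplied tau with t1 and t99 held at their
#' observed values, showing how the inferred rates trade off against the
#' assumed constraint.
#'
#' @inheritParams surge_fit
#' @param tau_values Constraint values (days) to scan.
#' @return A data.frame with one row per tau: the fitted rates, their
#'   uncertainties and the fit residual.
#' @examples
#' tau_scan(tau_values = c(1.5, 2, 2.5))
#' @export
tau_scan <- function(t1 = 2, t99 = 10, tau_values = seq(1, 3, by = 0.25),
                     branch = "ka<kd") {
  rows <- lapply(tau_values, function(tv) {
    f <- surge_fit(t1 = t1, t99 = t99, tau = tv, branch = branch)
    data.frame(tau = tv, ka = f$rates$ka, kd = f$rates$kd,
               kprime = f$rates$kprime,
               sigma_ka = f$sigmas[["ka"]], sigma_kd = f$sigmas[["kd"]],
               sigma_kprime = f$sigmas[["kprime"]],
               residual = f$residual)
  })
  do.call(rbind, rows)
}

#' @export
coef.surge_fit <- function(object, ...) {
  c(ka = object$rates$ka, kd = object$rates$kd, kprime = object$rates$kprime)
}

#' @export
vcov.surge_fit <- function(object, ...) {
  v <- diag(object$sigmas^2)
  dimnames(v) <- list(names(object$sigmas), names(object$sigmas))
  v
}

#' @export
residuals.surge_fit <- function(object, ...) {
  bp <- capacity_breakpoints(object$rates)
  model <- c(t1 = bp$t1, t2 = bp$t2,
             t99 = capacity_t99(object$rates, object$threshold))
  model - object$observations
}

#' Predicted trajectory from a fitted surge model
#'
#' @param object A [surge_fit()] result.
#' @param times Times (days) at which to evaluate; defaults to a dense grid
#'   up to a little past the observed t99.
#' @param ... Unused.
#' @return The capacity-model trajectory data.frame (see
#'   [capacity_model_at()]).
#' @export
predict.surge_fit <- function(object, times = NULL, ...) {
  if (is.null(times)) {
    times <- seq(0, 1.2 * object$observations[["t99"]], length.out = 201)
  }
  capacity_model_at(times, object$rates)
}

#' @export
print.surge_fit <- function(x, ...) {
  cat("Capacity-limited surge model fit\n")
  cat(sprintf("  observations: t1 = %g, t99 = %g, tau = %g days (branch %s)\n",
              x$observations[["t1"]], x$observations[["t99"]], x$tau, x$branch))
  p <- coef(x)
  for (nm in names(p)) {
    cat(sprintf("  %-7s %0.4f +/- %0.4f day^-1\n", nm, p[[nm]], x$sigmas[[nm]]))
  }
  cat(sprintf("  residual SSE %.3g after %d Newton iterations\n",
              x$residual, x$iterations))
  invisible(x)
}

#' @export
summary.surge_fit <- function(object, ...) {
  bp <- capacity_breakpoints(object$rates)
  out <- list(fit = object,
              timescales = c(t1 = bp$t1, t2 = bp$t2,
                             t99 = capacity_t99(object$rates, object$threshold)),
              surge_capacity = max_admitted_fraction(object$rates))
  class(out) <- "summary.surge_fit"
  out
}

#' @export
print.summary.surge_fit <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  implied timescales: t1 = %.3f, t2 = %.3f, t99 = %.3f days\n",
              x$timescales[["t1"]], x$timescales[["t2"]], x$timescales[["t99"]]))
  cat(sprintf("  intrinsic surge capacity: %.3f of the cohort\n",
              x$surge_capacity))
  invisible(x)
}

#' @export
plot.surge_fit <- function(x, times = NULL, ...) {
  tr <- predict(x, times)
  plot_trajectory(tr, c(Ns = "Surge", Na = "Admitted", Nd = "Discharged"),
                  main = "Fitted capacity-limited surge model", ...)
  graphics::abline(v = x$observations[c("t1", "t2", "t99")],
                   lty = 3, col = "grey40")
  invisible(tr)
}

# Damped Newton iteration with a central-difference Jacobian, in
# log-parameter space so positivity is automatic.
newton_damped <- function(fn, x0, tol = 1e-12, max_iter = 100L) {
  x <- x0
  r <- fn(x)
  for (iter in seq_len(max_iter)) {
    if (max(abs(r)) < tol) {
      return(list(x = x, r = r, iter = iter, converged = TRUE))
    }
    J <- num_jacobian(fn, x)
    dx <- tryCatch(solve(J, -r), error = function(e) NULL)
    if (is.null(dx)) break
    lambda <- 1
    repeat {
      r_new <- tryCatch(fn(x + lambda * dx), error = function(e) NULL)
      if (!is.null(r_new) && all(is.finite(r_new)) &&
          sqrt(sum(r_new^2)) < sqrt(sum(r^2))) break
      lambda <- lambda / 2
      if (lambda < 1e-8) return(list(x = x, r = r, iter = iter,
                                     converged = FALSE))
    }
    x <- x + lambda * dx
    r <- r_new
  }
  list(x = x, r = r, iter = max_iter, converged = max(abs(r)) < tol)
}

num_jacobian <- function(fn, x, h = 1e-7) {
  n <- length(x)
  r0 <- fn(x)
  J <- matrix(NA_real_, length(r0), n)
  for (j in seq_len(n)) {
    xp <- x; xp[j] <- xp[j] + h
    xm <- x; xm[j] <- xm[j] - h
    J[, j] <- (fn(xp) - fn(xm)) / (2 * h)
  }
  J
}

fit_starts <- function(branch, t1_obs, t2_obs) {
  base <- if (branch == "ka<kd") c(0.1, 1.0) else c(1.0, 0.1)
  mk <- function(kakd) {
    kp <- exp(-kakd[1] * t1_obs) / (t2_obs - t1_obs)
    log(c(kakd, kp))
  }
  list(mk(base), mk(base * c(0.5, 2)), mk(base * c(2, 0.5)), mk(base * 0.25))
}

# rate_set() without the kprime-slower-than-kd warning: intermediate Newton
# iterates may wander through that region harmlessly.
rate_set_quiet <- function(ka, kd, kprime) {
  suppressWarnings(rate_set(ka, kd, kprime))
}
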