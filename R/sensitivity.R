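#' Analytic sensitivity matrix of the capacity-limited model
#'
#' Closed-form partial derivatives of the three output timescales
#' (t1, t2, t99) with respect to the three rate constants (ka, kd, k').
#' t1 depends only on the pre-capacity rates, so its derivative with
#' respect to k' is identically zero; the t99 row carries the full chain
#' through the breakpoint populations Na(t2) and Nd(t2).
#'
#' @param rates A [rate_set()] with \code{kprime} set; the pre-capacity
#'   rates must be non-degenerate.
#' @param threshold Discharged fraction defining t99.
#' @return A 3x3 matrix with rows \code{t1}, \code{t2}, \code{t99} and
#'   columns \code{ka}, \code{kd}, \code{kprime} (units: days per day^-1).
#' @examples
#' analytic_sensitivity_capacity(rate_set(0.158, 1.151, 0.122))
#' @export
analytic_sensitivity_capacity <- function(rates, threshold = 0.99) {
  stopifnot(inherits(rates, "rate_set"))
  check_kprime(rates)
  ka <- rates$ka; kd <- rates$kd; kp <- rates$kprime
  if (rates_degenerate(ka, kd)) {
    stop("analytic sensitivities require non-degenerate rates (ka != kd)")
  }
  t1 <- time_of_max_admitted(rates)
  E1 <- exp(-ka * t1)   # Ns(t1)
  E2 <- exp(-kd * t1)
  d <- kd - ka

  dt1_ka <- (t1 - 1 / ka) / d
  dt1_kd <- (1 / kd - t1) / d

  dt2_ka <- (1 - (ka / kp) * E1) * dt1_ka - (t1 / kp) * E1
  dt2_kd <- (1 - (ka / kp) * E1) * dt1_kd
  dt2_kp <- -E1 / kp^2

  # breakpoint populations and their pre-capacity-rate derivatives
  Na2 <- ka / d * (E1 - E2)                  # = Na(t1), constant to t2
  Nd1 <- 1 + ka / d * E2 - kd / d * E1
  Nd2 <- Nd1 + kp * (capacity_breakpoints(rates)$t2 - t1)

  dNd1_ka <- kd / d^2 * (E2 - E1) + (ka * kd / d) * (E1 - E2) * dt1_ka +
    (kd * t1 / d) * E1
  dNd1_kd <- ka / d^2 * (E1 - E2) - (ka * t1 / d) * E2 +
    (ka * kd / d) * (E1 - E2) * dt1_kd
  dNa2_ka <- kd / d^2 * (E1 - E2) - (ka * t1 / d) * E1 +
    (ka / d) * (kd * E2 - ka * E1) * dt1_ka
  dNa2_kd <- -ka / d^2 * (E1 - E2) + (ka * t1 / d) * E2 +
    (ka / d) * (kd * E2 - ka * E1) * dt1_kd
  dNd2_ka <- dNd1_ka + kp * (dt2_ka - dt1_ka)
  dNd2_kd <- dNd1_kd + kp * (dt2_kd - dt1_kd)

  # t99 = t2 - log(Q)/kd with Q = 1 - (threshold - Nd2)/Na2
  gap <- threshold - Nd2
  denom <- Na2 - gap           # = Q * Na2
  Q <- 1 - gap / Na2
  dt99_ka <- dt2_ka - (dNd2_ka + (gap / Na2) * dNa2_ka) / (kd * denom)
  dt99_kd <- log(Q) / kd^2 + dt2_kd -
    (dNd2_kd + (gap / Na2) * dNa2_kd) / (kd * denom)
  dt99_kp <- dt2_kp

  matrix(c(dt1_ka, dt1_kd, 0,
           dt2_ka, dt2_kd, dt2_kp,
           dt99_ka, dt99_kd, dt99_kp),
         nrow = 3, byrow = TRUE,
         dimnames = list(c("t1", "t2", "t99"), c("ka", "kd", "kprime")))
}

#' Output variance matrix from a sensitivity matrix
#'
#' Elementwise variance contributions V_ij = S_ij^2 sigma_j^2 of each
#' parameter's uncertainty to each output, neglecting covariances. The
#' magnitudes within a row rank which parameter dominates that output's
#' uncertainty.
#'
#' @param S A sensitivity matrix (outputs x parameters).
#' @param sigmas One-standard-deviation parameter uncertainties, one per
#'   column of \code{S}.
#' @return A matrix of the same shape as \code{S}.
#' @examples
#' f <- surge_fit(2, 10, 2)
#' variance_matrix(analytic_sensitivity_capacity(f$rates), f$sigmas)
#' @export
variance_matrix <- function(S, sigmas) {
  stopifnot(is.matrix(S), length(sigmas) == ncol(S))
  V <- sweep(S^2, 2, as.numeric(sigmas)^2, `*`)
  dimnames(V) <- dimnames(S)
  V
}

#' Numeric sensitivity and variance matrices of the two-center model
#'
#' Central-difference sensitivities of the four output timescales
#' (t1a, t1p, t2, t99) of the two-center model with respect to its six rate
#' constants (kpaa, kpap, kpda, kpdp, ka', kp'). Each parameter is
#' incremented by plus and minus an absolute step (default 0.001 day^-1)
#' and the two one-sided difference quotients are averaged. t99 inside the
#' difference quotient uses the same 1e-8-day root tolerance as
#' [ptc_t99()], so the quotients are not noise-dominated.
#'
#' @param rates A [ptc_rate_set()] valid on both sides of every increment.
#' @param sigmas One-standard-deviation uncertainties for the six
#'   parameters, in the column order above; see
#'   [ptc_reference_sigmas()] for the reference choice.
#' @param step Absolute increment (day^-1).
#' @param threshold Discharged fraction defining t99.
#' @return A list of class \code{"ptc_sensitivity"} with the 4x6 matrices
#'   \code{S} and \code{V}, the \code{sigmas} used and the \code{step}.
#' @export
numeric_sensitivity_ptc <- function(rates, sigmas, step = 0.001,
                                    threshold = 0.99) {
  stopifnot(inherits(rates, "ptc_rate_set"))
  pnames <- c("kpaa", "kpap", "kpda", "kpdp", "ka_prime", "kp_prime")
  onames <- c("t1a", "t1p", "t2", "t99")
  if (length(sigmas) != length(pnames)) {
    stop("'sigmas' must supply one value per parameter (", length(pnames), ")")
  }
  p0 <- unlist(rates[pnames])

  eval_outputs <- function(p) {
    r <- ptc_rate_set(p[["kpaa"]], p[["kpap"]], p[["kpda"]], p[["kpdp"]],
                      p[["ka_prime"]], p[["kp_prime"]])
    bd <- ptc_boundaries(r)
    c(bd$t1a, bd$t1p, bd$t2, ptc_t99(r, threshold))
  }

  S <- matrix(NA_real_, 4, 6, dimnames = list(onames, pnames))
  for (j in seq_along(pnames)) {
    pp <- p0; pp[j] <- pp[j] + step
    pm <- p0; pm[j] <- pm[j] - step
    up <- tryCatch(eval_outputs(pp), error = function(e) e)
    dn <- tryCatch(eval_outputs(pm), error = function(e) e)
    if (inherits(up, "error") || inherits(dn, "error")) {
      stop("incrementing '", pnames[j], "' by ", step,
           " crosses a model validity boundary: ",
           conditionMessage(if (inherits(up, "error")) up else dn))
    }
    S[, j] <- (up - dn) / (2 * step)
  }
  structure(list(S = S, V = variance_matrix(S, sigmas),
                 sigmas = stats::setNames(as.numeric(sigmas), pnames),
                 step = step),
            class = "ptc_sensitivity")
}

#' @export
print.ptc_sensitivity <- function(x, digits = 3, ...) {
  cat("Two-center model numeric sensitivity (step ", x$step, " day^-1)\n",
      sep = "")
  cat("S (days per day^-1):\n")
  print(round(x$S, digits))
  cat("V = S^2 * sigma^2:\n")
  print(round(x$V, digits))
  invisible(x)
}

#' Reference parameter uncertainties for the two-center sensitivity study
#'
#' The reference uncertainty assignment when the pediatric rates are set
#' equal to the fitted adult-center rates: the adult-center-side parameters
#' (kpaa, kpda, ka') inherit the one-standard-deviation uncertainties of
#' the fitted (ka, kd, k'), while each PTC-side parameter (kpap, kpdp, kp')
#' is assigned a variance of 35% of its own value (sigma = sqrt(0.35 p)),
#' reflecting the absence of historical data for a PTC.
#'
#' @param rates A [ptc_rate_set()].
#' @param fit_sigmas Named uncertainties from [surge_fit()] (elements
#'   \code{ka}, \code{kd}, \code{kprime}).
#' @return Named vector of six sigmas in the column order of
#'   [numeric_sensitivity_ptc()].
#' @export
ptc_reference_sigmas <- function(rates, fit_sigmas) {
  stopifnot(inherits(rates, "ptc_rate_set"))
  c(kpaa = unname(fit_sigmas[["ka"]]),
    kpap = sqrt(0.35 * rates$kpap),
    kpda = unname(fit_sigmas[["kd"]]),
    kpdp = sqrt(0.35 * rates$kpdp),
    ka_prime = unname(fit_sigmas[["kprime"]]),
    kp_prime = sqrt(0.35 * rates$kp_prime))
}
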