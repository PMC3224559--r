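#' Rate constants for the basic surge model
#'
#' Bundles the kinetic rate constants of the single-center surge model:
#' first-order admission and discharge rates that apply while the trauma
#' center has free surge beds, and the zeroth-order throughput rate that
#' applies while it is saturated (one admission per discharge).
#'
#' @param ka Admission rate before the center reaches capacity (day^-1).
#' @param kd Discharge rate before the center reaches capacity and again
#'   after the surge queue has vanished (day^-1).
#' @param kprime Steady-state throughput while the center is at capacity,
#'   expressed as the fraction of the initial cohort admitted (and
#'   discharged) per day. Expected to be slower than \code{kd}.
#' @return An object of class \code{"rate_set"}.
#' @examples
#' rate_set(ka = 0.158, kd = 1.151, kprime = 0.122)
#' @export
rate_set <- function(ka, kd, kprime = NA_real_) {
  stopifnot(is.numeric(ka), is.numeric(kd), length(ka) == 1L, length(kd) == 1L)
  if (!(ka > 0) || !(kd > 0)) {
    stop("rate constants 'ka' and 'kd' must be strictly positive")
  }
  if (!is.na(kprime)) {
    if (!(kprime > 0)) stop("'kprime' must be strictly positive")
    if (kprime > kd) {
      warning("'kprime' exceeds 'kd'; the model assumes at-capacity throughput is slower")
    }
  }
  structure(list(ka = ka, kd = kd, kprime = kprime), class = "rate_set")
}

#' @export
print.rate_set <- function(x, ...) {
  cat("Surge model rate constants (day^-1):\n")
  cat(sprintf("  ka = %.4g  kd = %.4g  k' = %.4g\n", x$ka, x$kd, x$kprime))
  if (rates_degenerate(x$ka, x$kd)) cat("  (degenerate: ka ~ kd, limit forms in use)\n")
  invisible(x)
}

#' Rate constants for the delayed-surge model
#'
#' Adds an exposure/delay stage ahead of the surge compartment: the initial
#' cohort starts exposed and becomes part of the surge at rate \code{ks},
#' after which admission and discharge proceed as in the basic model.
#'
#' @param ks Exposure (delay) rate at which the exposed cohort joins the
#'   surge (day^-1).
#' @inheritParams rate_set
#' @return An object of class \code{"delayed_rate_set"}.
#' @export
delayed_rate_set <- function(ks, ka, kd) {
  stopifnot(is.numeric(ks), length(ks) == 1L)
  if (!(ks > 0)) stop("'ks' must be strictly positive")
  base <- rate_set(ka, kd)
  structure(list(ks = ks, ka = base$ka, kd = base$kd),
            class = "delayed_rate_set")
}

#' Rate constants for the two-center (adult + pediatric trauma center) model
#'
#' The pediatric surge cohort can be admitted to the adult trauma center or
#' to a pediatric trauma center (PTC); adults are never triaged to the PTC.
#' Rates are named by cohort, action and center: \code{kpaa} is pediatric
#' admission to the adult center, \code{kpdp} pediatric discharge from the
#' PTC, and so on. \code{ka_prime}/\code{kp_prime} are the zeroth-order
#' throughput rates of each center while it is saturated.
#'
#' The model derivation assumes the adult center saturates before the PTC
#' (\code{t1a < t1p}); when the opposite holds, swap the roles of the two
#' centers by relabeling the rate constants.
#'
#' @param kpaa,kpda Pediatric admission to / discharge from the adult center
#'   (day^-1).
#' @param kpap,kpdp Pediatric admission to / discharge from the PTC
#'   (day^-1). \code{kpap = 0} together with \code{kp_prime = 0} encodes the
#'   absence of a PTC and collapses the model to the single-center case.
#' @param ka_prime,kp_prime At-capacity throughput of the adult center and
#'   the PTC (fraction of the pediatric cohort per day).
#' @param kaa,kad Optional adult-cohort admission/discharge rates (day^-1);
#'   only needed when the adult cohort itself is of interest.
#' @return An object of class \code{"ptc_rate_set"} with derived totals
#'   \code{k = kpaa + kpap} and \code{kappa = ka_prime + kp_prime}.
#' @examples
#' ptc_rate_set(kpaa = 0.158, kpap = 0.158, kpda = 1.151, kpdp = 1.151,
#'              ka_prime = 0.122, kp_prime = 0.122)
#' @export
ptc_rate_set <- function(kpaa, kpap, kpda, kpdp, ka_prime, kp_prime,
                         kaa = NA_real_, kad = NA_real_) {
  vals <- c(kpaa = kpaa, kpap = kpap, kpda = kpda, kpdp = kpdp,
            ka_prime = ka_prime, kp_prime = kp_prime)
  if (any(!is.finite(vals)) || any(vals < 0)) {
    stop("all PTC-model rate constants must be finite and nonnegative")
  }
  if (!(kpaa > 0) || !(kpda > 0) || !(ka_prime > 0)) {
    stop("adult-center rates 'kpaa', 'kpda', 'ka_prime' must be strictly positive")
  }
  has_ptc <- kpap > 0
  if (!has_ptc && kp_prime > 0) {
    stop("'kp_prime' > 0 requires 'kpap' > 0 (a PTC that admits no one cannot discharge)")
  }
  k <- kpaa + kpap
  if (has_ptc) {
    if (rates_degenerate(k, kpda) || rates_degenerate(k, kpdp)) {
      stop("degenerate rates: the total admission rate k = kpaa + kpap must differ from kpda and kpdp")
    }
    if (!(kpdp > 0)) stop("'kpdp' must be strictly positive when a PTC is present")
  } else if (rates_degenerate(k, kpda)) {
    stop("degenerate rates: kpaa must differ from kpda")
  }
  structure(list(kpaa = kpaa, kpap = kpap, kpda = kpda, kpdp = kpdp,
                 ka_prime = ka_prime, kp_prime = kp_prime,
                 k = k, kappa = ka_prime + kp_prime,
                 kaa = kaa, kad = kad, has_ptc = has_ptc),
            class = "ptc_rate_set")
}

#' @export
print.ptc_rate_set <- function(x, ...) {
  cat("Two-center surge model rate constants (day^-1):\n")
  cat(sprintf("  adult center: kpaa = %.4g  kpda = %.4g  ka' = %.4g\n",
              x$kpaa, x$kpda, x$ka_prime))
  if (x$has_ptc) {
    cat(sprintf("  PTC:          kpap = %.4g  kpdp = %.4g  kp' = %.4g\n",
                x$kpap, x$kpdp, x$kp_prime))
  } else {
    cat("  PTC:          absent (kpap = kp' = 0)\n")
  }
  cat(sprintf("  totals:       k = %.4g  kappa = %.4g\n", x$k, x$kappa))
  invisible(x)
}

#' Per-compartment death rates for the mortality extension
#'
#' Death rates (day^-1) for each population of the two-center model: the
#' untreated surge, inpatients at the adult center and at the PTC (before
#' capacity and, separately, during the saturated steady state), and
#' discharged patients. Defaults for the steady-state inpatient rates equal
#' the pre-capacity inpatient rates.
#'
#' @param omega_s Death rate of the untreated surge cohort.
#' @param omega_a,omega_p Death rates of inpatients at the adult center and
#'   the PTC before the centers saturate.
#' @param omega_d Death rate of discharged patients (background rate).
#' @param omega_a_prime,omega_p_prime Inpatient death rates while the
#'   respective center is operating at capacity.
#' @return An object of class \code{"death_rate_set"}.
#' @seealso [haiti_death_rates()] for the literature-derived reference set.
#' @export
death_rate_set <- function(omega_s, omega_a, omega_p, omega_d,
                           omega_a_prime = omega_a, omega_p_prime = omega_p) {
  vals <- c(omega_s, omega_a, omega_p, omega_d, omega_a_prime, omega_p_prime)
  if (any(!is.finite(vals)) || any(vals < 0)) {
    stop("death rates must be finite and nonnegative")
  }
  structure(list(omega_s = omega_s, omega_a = omega_a, omega_p = omega_p,
                 omega_d = omega_d, omega_a_prime = omega_a_prime,
                 omega_p_prime = omega_p_prime),
            class = "death_rate_set")
}

#' Literature-derived death rates for the historical scenario
#'
#' The reference parameterization used throughout the mortality analyses:
#' a background death rate of 2e-5 day^-1 after discharge (US age-adjusted
#' all-cause rate), an inpatient death rate of 0.086/15 day^-1 (8.6\%
#' inpatient mortality over 15 days reported after the 1995 Hanshin-Awaji
#' earthquake), and a surge death rate obtained by scaling the inpatient
#' rate by 0.93/0.07 (7\% of Chi-Chi earthquake fatalities died while
#' hospitalized). Steady-state inpatient rates equal the pre-capacity ones.
#'
#' @return A [death_rate_set()].
#' @export
haiti_death_rates <- function() {
  omega_hosp <- 0.086 / 15
  death_rate_set(omega_s = omega_hosp * 0.93 / 0.07,
                 omega_a = omega_hosp, omega_p = omega_hosp,
                 omega_d = 2e-5)
}

#' @export
print.death_rate_set <- function(x, ...) {
  cat("Per-compartment death rates (day^-1):\n")
  cat(sprintf("  surge %.3g | inpatient adult %.3g (steady %.3g) | inpatient PTC %.3g (steady %.3g) | discharged %.3g\n",
              x$omega_s, x$omega_a, x$omega_a_prime,
              x$omega_p, x$omega_p_prime, x$omega_d))
  invisible(x)
}

# |a - b| below a relative tolerance: the two-exponential closed forms have
# removable singularities there and limit forms must be used instead.
rates_degenerate <- function(a, b, tol = 1e-8) {
  abs(a - b) < tol * max(abs(a), abs(b))
}
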