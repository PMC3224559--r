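#' Evaluate the unconstrained three-compartment surge model
#'
#' Closed-form solution of the sequential kinetic scheme
#' surge -> admitted -> discharged with first-order rates \code{ka} and
#' \code{kd} and no capacity limit. Populations are fractions of the initial
#' cohort (N0 = 1): Ns(t) = exp(-ka t), Na(t) rises to a single maximum and
#' decays, and Nd(t) relaxes to one. When \code{ka} and \code{kd} coincide
#' to within the degeneracy tolerance the removable singularity is replaced
#' by its analytic limit, Na(t) = ka t exp(-ka t).
#'
#' @param t Time(s) in days, nonnegative; may be a vector.
#' @param rates A [rate_set()] (the at-capacity rate \code{kprime} is not
#'   used here).
#' @return A data.frame with columns \code{t}, \code{Ns}, \code{Na},
#'   \code{Nd}; rows sum to one.
#' @examples
#' simple_model_at(c(0, 2, 50), rate_set(0.158, 1.151))
#' @export
simple_model_at <- function(t, rates) {
  stopifnot(inherits(rates, "rate_set"))
  check_times(t)
  ka <- rates$ka
  kd <- rates$kd
  Ns <- exp(-ka * t)
  if (rates_degenerate(ka, kd)) {
    Na <- ka * t * exp(-ka * t)
  } else {
    Na <- ka / (kd - ka) * (exp(-ka * t) - exp(-kd * t))
  }
  data.frame(t = t, Ns = Ns, Na = Na, Nd = 1 - Ns - Na)
}

#' Time at which the admitted population peaks
#'
#' The analytic argmax of Na(t) in the unconstrained model,
#' ln(kd/ka)/(kd - ka), with the limit 1/ka when the rates coincide. In the
#' capacity-limited model this instant defines t1, the time the center
#' saturates.
#'
#' @inheritParams simple_model_at
#' @return Time of the admitted maximum, in days.
#' @export
time_of_max_admitted <- function(rates) {
  stopifnot(inherits(rates, "rate_set"))
  if (rates_degenerate(rates$ka, rates$kd)) return(1 / rates$ka)
  log(rates$kd / rates$ka) / (rates$kd - rates$ka)
}

#' Peak admitted fraction (intrinsic surge capacity)
#'
#' The maximum of Na(t) in the unconstrained model. The capacity-limited
#' model identifies this value with the center's surge capacity as a
#' fraction of the cohort: it depends only on the admission and discharge
#' rates, not on a bed count. Equals exp(-1) in the equal-rates limit.
#'
#' @inheritParams simple_model_at
#' @return The peak admitted fraction of the initial cohort.
#' @export
max_admitted_fraction <- function(rates) {
  stopifnot(inherits(rates, "rate_set"))
  simple_model_at(time_of_max_admitted(rates), rates)$Na
}

#' Evaluate the delayed-surge four-compartment model
#'
#' Closed-form solution of exposed -> surge -> admitted -> discharged, for
#' mass-casualty events where the surge builds up at a finite exposure rate
#' \code{ks} instead of appearing instantaneously. The three rates must be
#' pairwise distinct: the sequential-decay closed form (a Bateman-type
#' solution) is singular at equal rates and no limit form is provided.
#'
#' @inheritParams simple_model_at
#' @param rates A [delayed_rate_set()].
#' @return A data.frame with columns \code{t}, \code{Ne}, \code{Ns},
#'   \code{Na}, \code{Nd}; rows sum to one.
#' @export
delayed_model_at <- function(t, rates) {
  stopifnot(inherits(rates, "delayed_rate_set"))
  check_times(t)
  ks <- rates$ks; ka <- rates$ka; kd <- rates$kd
  if (rates_degenerate(ks, ka) || rates_degenerate(ks, kd) ||
      rates_degenerate(ka, kd)) {
    stop("delayed-surge closed form requires pairwise distinct rates ks, ka, kd")
  }
  Es <- exp(-ks * t); Ea <- exp(-ka * t); Ed <- exp(-kd * t)
  Ne <- Es
  Ns <- ks / (ka - ks) * (Es - Ea)
  Na <- ka * ks / (ka - ks) *
    (Es / (kd - ks) - Ea / (kd - ka) - (1 / (kd - ks) - 1 / (kd - ka)) * Ed)
  Nd <- ks * ka * kd / (ka - ks) *
    ((Ea - 1) / (ka * (kd - ka)) - (Es - 1) / (ks * (kd - ks)) +
       (1 / (kd - ks) - 1 / (kd - ka)) * (Ed - 1) / kd)
  data.frame(t = t, Ne = Ne, Ns = Ns, Na = Na, Nd = Nd)
}

#' Time of the maximum surge in the delayed model
#'
#' Argmax of Ns(t) when the surge builds up at rate \code{ks}:
#' ln(ka/ks)/(ka - ks), with limit 1/ka at equal rates. Useful either to
#' predict when the surge peaks or, run backwards, to constrain \code{ka}
#' against \code{ks} from an observed peak time.
#'
#' @param rates A [delayed_rate_set()].
#' @return Time of the surge maximum, in days.
#' @export
time_of_max_surge_delayed <- function(rates) {
  stopifnot(inherits(rates, "delayed_rate_set"))
  if (rates_degenerate(rates$ks, rates$ka)) return(1 / rates$ka)
  log(rates$ka / rates$ks) / (rates$ka - rates$ks)
}

check_times <- function(t) {
  if (!is.numeric(t) || any(!is.finite(t)) || any(t < 0)) {
    stop("'t' must be a vector of finite nonnegative times (days)")
  }
  invisible(t)
}
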