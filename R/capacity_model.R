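#' Breakpoints of the capacity-limited single-center model
#'
#' The capacity-limited ("maximum capacity") model follows the unconstrained
#' kinetics until the admitted census reaches its intrinsic maximum at t1;
#' it then holds the census constant, draining the surge at the zeroth-order
#' throughput rate k' until the queue vanishes at t2 = t1 + Ns(t1)/k'.
#'
#' @param rates A [rate_set()] with \code{kprime} set.
#' @return A list with elements \code{t1} and \code{t2} (days).
#' @examples
#' capacity_breakpoints(rate_set(0.158, 1.151, 0.122))
#' @export
capacity_breakpoints <- function(rates) {
  stopifnot(inherits(rates, "rate_set"))
  check_kprime(rates)
  t1 <- time_of_max_admitted(rates)
  Ns_t1 <- exp(-rates$ka * t1)
  list(t1 = t1, t2 = t1 + Ns_t1 / rates$kprime)
}

# Compartment values at the two breakpoints. Na is constant on [t1, t2]
# (census pinned at the surge capacity) and Ns(t2) = 0 by definition of t2.
capacity_boundary_state <- function(rates) {
  bp <- capacity_breakpoints(rates)
  at1 <- simple_model_at(bp$t1, rates)
  list(t1 = bp$t1, t2 = bp$t2,
       Ns_t1 = at1$Ns, Na_t1 = at1$Na, Nd_t1 = at1$Nd,
       Ns_t2 = 0, Na_t2 = at1$Na, Nd_t2 = at1$Nd + at1$Ns)
}

#' Evaluate the capacity-limited single-center model
#'
#' Piecewise closed-form trajectory over the three regimes: region I
#' (\code{[0, t1)}), free exponential kinetics; region II (\code{[t1, t2)}),
#' center saturated, zeroth-order drain of the surge at rate k' with the
#' admitted census constant; region III (\code{[t2, Inf)}), queue exhausted,
#' exponential discharge relaxation at rate kd. The populations are
#' continuous at both breakpoints; floating-point undershoot of the linear
#' region-II surge is clamped so Ns is exactly 0 from t2 on.
#'
#' @inheritParams simple_model_at
#' @param rates A [rate_set()] with \code{kprime} set.
#' @return A data.frame with columns \code{t}, \code{Ns}, \code{Na},
#'   \code{Nd}, \code{region} (one of \code{"I"}, \code{"II"},
#'   \code{"III"}).
#' @examples
#' capacity_model_at(c(1, 5, 10), rate_set(0.158, 1.151, 0.122))
#' @export
capacity_model_at <- function(t, rates) {
  stopifnot(inherits(rates, "rate_set"))
  check_times(t)
  bs <- capacity_boundary_state(rates)
  kprime <- rates$kprime
  kd <- rates$kd

  region <- ifelse(t < bs$t1, "I", ifelse(t < bs$t2, "II", "III"))
  Ns <- Na <- Nd <- numeric(length(t))

  i1 <- region == "I"
  if (any(i1)) {
    r1 <- simple_model_at(t[i1], rates)
    Ns[i1] <- r1$Ns; Na[i1] <- r1$Na; Nd[i1] <- r1$Nd
  }
  i2 <- region == "II"
  if (any(i2)) {
    s <- t[i2] - bs$t1
    Ns[i2] <- pmax(bs$Ns_t1 - kprime * s, 0)
    Na[i2] <- bs$Na_t1
    Nd[i2] <- bs$Nd_t1 + kprime * s
  }
  i3 <- region == "III"
  if (any(i3)) {
    u <- t[i3] - bs$t2
    Ns[i3] <- 0
    Na[i3] <- bs$Na_t2 * exp(-kd * u)
    Nd[i3] <- bs$Nd_t2 + bs$Na_t2 * (1 - exp(-kd * u))
  }
  data.frame(t = t, Ns = Ns, Na = Na, Nd = Nd, region = region)
}

#' Time to discharge a given fraction of the surge cohort
#'
#' The operational "complete treatment" timescale: the time at which the
#' discharged fraction Nd reaches \code{threshold} (conventionally 99%,
#' written t99). In region III the crossing has the closed form
#' t99 = t2 - (1/kd) log(1 - (threshold - Nd(t2)) / Na(t2)). If the
#' threshold is already met before the queue vanishes (possible only for
#' small thresholds) the crossing is located numerically in regions I/II
#' with a warning.
#'
#' @param rates A [rate_set()] with \code{kprime} set.
#' @param threshold Discharged fraction defining completion, in (0, 1).
#' @return The crossing time in days.
#' @examples
#' capacity_t99(rate_set(0.158, 1.151, 0.122))
#' @export
capacity_t99 <- function(rates, threshold = 0.99) {
  stopifnot(inherits(rates, "rate_set"))
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold <= 0 || threshold >= 1) {
    stop("'threshold' must be a single fraction in (0, 1)")
  }
  bs <- capacity_boundary_state(rates)
  if (threshold <= bs$Nd_t2) {
    if (threshold == bs$Nd_t2) return(bs$t2)
    warning("threshold reached before the surge queue vanished; solving numerically in regions I/II")
    f <- function(tt) capacity_model_at(tt, rates)$Nd - threshold
    return(stats::uniroot(f, c(0, bs$t2), tol = 1e-10)$root)
  }
  bs$t2 - log(1 - (threshold - bs$Nd_t2) / bs$Na_t2) / rates$kd
}

check_kprime <- function(rates) {
  if (is.na(rates$kprime)) {
    stop("this operation needs the at-capacity throughput rate: supply 'kprime' in rate_set()")
  }
  invisible(rates)
}
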