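#' Adult cohort of the two-center model
#'
#' The adult cohort only ever sees the adult trauma center, so its
#' pre-capacity kinetics are the unconstrained three-compartment solution
#' with the adult-cohort rates.
#'
#' @inheritParams simple_model_at
#' @param kaa,kad Adult-cohort admission and discharge rates (day^-1).
#' @return A data.frame with columns \code{t}, \code{As}, \code{Aa},
#'   \code{Ad}, fractions of the initial adult cohort.
#' @export
adult_cohort_at <- function(t, kaa, kad) {
  out <- simple_model_at(t, rate_set(kaa, kad))
  names(out) <- c("t", "As", "Aa", "Ad")
  out
}

#' Pediatric cohort before either center saturates (region I)
#'
#' Closed-form solution of the branched scheme in which the pediatric surge
#' is admitted to the adult center (rate kpaa) or the PTC (rate kpap) and
#' discharged at center-specific rates. Populations are fractions of the
#' initial pediatric cohort (P0 = 1). With \code{kpap = 0} the PTC branch
#' is exactly absent and the solution reduces to the single-center model.
#'
#' @inheritParams simple_model_at
#' @param rates A [ptc_rate_set()].
#' @return A data.frame with columns \code{t}, \code{Ps}, \code{Paa},
#'   \code{Pap}, \code{Pd}; rows sum to one.
#' @export
ptc_region1_at <- function(t, rates) {
  stopifnot(inherits(rates, "ptc_rate_set"))
  check_times(t)
  k <- rates$k
  Ek <- exp(-k * t)
  Ps <- Ek
  Paa <- rates$kpaa / (rates$kpda - k) * (Ek - exp(-rates$kpda * t))
  if (rates$has_ptc) {
    Pap <- rates$kpap / (rates$kpdp - k) * (Ek - exp(-rates$kpdp * t))
  } else {
    Pap <- numeric(length(t))
  }
  data.frame(t = t, Ps = Ps, Paa = Paa, Pap = Pap, Pd = 1 - Ps - Paa - Pap)
}

#' Breakpoints and boundary constants of the two-center model
#'
#' Computes, in dependency order, the saturation time of the adult center
#' (t1a, the argmax of its pediatric census), the region-I exit values
#' (A, C, E, H) and region-II integration constants (alpha, gamma, beta),
#' the PTC saturation time t1p (argmax of the region-II PTC census) with
#' its exit values (B, D, F), the queue-exhaustion time t2 = t1p + B/kappa,
#' and G = F + B, the discharged fraction at t2.
#'
#' The derivation requires the adult center to saturate first
#' (\code{t1a < t1p}); if the PTC is faster, relabel the rate constants so
#' the roles of the two centers are swapped. With \code{kpap = kp_prime = 0}
#' (no PTC) the model collapses exactly to the single-center capacity model
#' and the PTC-specific quantities degenerate (t1p = t1a, D = 0).
#'
#' @param rates A [ptc_rate_set()].
#' @return A list with \code{t1a}, \code{t1p}, \code{t2}, a named list
#'   \code{constants} (A, C, E, H, alpha, gamma, beta, B, D, F, G) and a
#'   flag \code{collapsed}.
#' @examples
#' r <- ptc_rate_set(0.158, 0.158, 1.151, 1.151, 0.122, 0.122)
#' ptc_boundaries(r)
#' @export
ptc_boundaries <- function(rates) {
  stopifnot(inherits(rates, "ptc_rate_set"))
  kap <- rates$ka_prime

  if (!rates$has_ptc) {
    eq <- rate_set(rates$kpaa, rates$kpda, kap)
    bs <- capacity_boundary_state(eq)
    return(list(
      t1a = bs$t1, t1p = bs$t1, t2 = bs$t2,
      constants = list(A = bs$Ns_t1, C = bs$Na_t1, E = bs$Nd_t1,
                       H = 0, alpha = NA_real_, gamma = NA_real_,
                       beta = NA_real_, B = bs$Ns_t1, D = 0,
                       F = bs$Nd_t1, G = bs$Nd_t2),
      collapsed = TRUE))
  }

  k <- rates$k; kpap <- rates$kpap; kpdp <- rates$kpdp
  t1a <- log(rates$kpda / k) / (rates$kpda - k)
  if (!is.finite(t1a) || t1a <= 0) {
    stop("invalid adult-center saturation time t1a; check kpaa, kpap, kpda")
  }
  r1 <- ptc_region1_at(t1a, rates)
  A <- r1$Ps; C <- r1$Paa; H <- r1$Pap; E <- r1$Pd

  if (rates_degenerate(kpap, kpdp)) {
    stop("degenerate rates: region II requires kpap != kpdp")
  }
  alpha <- A + kap / kpap
  gamma <- alpha * kpap / (kpdp - kpap)
  beta <- H - gamma + kap / kpdp

  # argmax of the region-II PTC census: set dPap/ds = 0
  arg <- -kpap * gamma / (kpdp * beta)
  if (!is.finite(arg) || arg <= 0) {
    stop("no PTC saturation time in region II (log argument nonpositive; ",
         "constants gamma = ", signif(gamma, 4), ", beta = ", signif(beta, 4),
         "); check the rate combination")
  }
  s_star <- log(arg) / (kpap - kpdp)
  # When the two centers are rate-matched they saturate simultaneously
  # (s_star = 0 up to rounding), and a perturbation of a discharge rate can
  # push the formal argmax marginally before t1a. The closed forms remain
  # smooth there, so small negative s_star is evaluated as written
  # (analytic continuation); only a genuinely faster PTC is rejected.
  if (!is.finite(s_star) || s_star < -0.1) {
    stop("model assumes the adult center saturates first (t1a < t1p); ",
         "for a faster PTC, relabel the rate constants so the centers swap roles")
  }
  t1p <- t1a + s_star

  B <- -kap / kpap + alpha * exp(-kpap * s_star)
  D <- -kap / kpdp + gamma * exp(-kpap * s_star) + beta * exp(-kpdp * s_star)
  F_ <- E + (kpdp * gamma / kpap) * (1 - exp(-kpap * s_star)) +
    beta * (1 - exp(-kpdp * s_star))
  if (B <= 0) {
    stop("surge exhausted before the PTC saturated (B <= 0); ",
         "the four-region solution does not apply to this rate combination")
  }
  list(t1a = t1a, t1p = t1p, t2 = t1p + B / rates$kappa,
       constants = list(A = A, C = C, E = E, H = H, alpha = alpha,
                        gamma = gamma, beta = beta, B = B, D = D,
                        F = F_, G = F_ + B),
       collapsed = FALSE)
}

#' Evaluate the two-center (adult + PTC) surge model
#'
#' Piecewise closed-form trajectory of the pediatric cohort over four
#' regimes: region I, both centers below capacity (branched exponential
#' kinetics); region II, adult center saturated (its census constant at C)
#' while the PTC still admits first-order; region III, both centers
#' saturated, the surge drained at the combined zeroth-order rate kappa;
#' region IV, queue exhausted, exponential discharge relaxation of both
#' centers. Populations are continuous at t1a, t1p and t2.
#'
#' @inheritParams ptc_region1_at
#' @return A data.frame with columns \code{t}, \code{Ps}, \code{Paa},
#'   \code{Pap}, \code{Pd}, \code{region} (\code{"I"}-\code{"IV"}).
#' @examples
#' r <- ptc_rate_set(0.158, 0.158, 1.151, 1.151, 0.122, 0.122)
#' ptc_model_at(c(1, 2, 4, 6), r)
#' @export
ptc_model_at <- function(t, rates) {
  stopifnot(inherits(rates, "ptc_rate_set"))
  check_times(t)
  bd <- ptc_boundaries(rates)

  if (bd$collapsed) {
    eq <- rate_set(rates$kpaa, rates$kpda, rates$ka_prime)
    cm <- capacity_model_at(t, eq)
    return(data.frame(t = t, Ps = cm$Ns, Paa = cm$Na,
                      Pap = 0, Pd = cm$Nd,
                      region = c(I = "I", II = "III", III = "IV")[cm$region]))
  }

  cs <- bd$constants
  kpap <- rates$kpap; kpdp <- rates$kpdp; kpda <- rates$kpda
  kap <- rates$ka_prime; kappa <- rates$kappa

  t1p_eff <- max(bd$t1p, bd$t1a)   # region II empty at simultaneous saturation
  region <- ifelse(t < bd$t1a, "I",
                   ifelse(t < t1p_eff, "II",
                          ifelse(t < bd$t2, "III", "IV")))
  Ps <- Paa <- Pap <- Pd <- numeric(length(t))

  i <- region == "I"
  if (any(i)) {
    r <- ptc_region1_at(t[i], rates)
    Ps[i] <- r$Ps; Paa[i] <- r$Paa; Pap[i] <- r$Pap; Pd[i] <- r$Pd
  }
  i <- region == "II"
  if (any(i)) {
    s <- t[i] - bd$t1a
    Ps[i] <- -kap / kpap + cs$alpha * exp(-kpap * s)
    Paa[i] <- cs$C
    Pap[i] <- -kap / kpdp + cs$gamma * exp(-kpap * s) + cs$beta * exp(-kpdp * s)
    Pd[i] <- cs$E + (kpdp * cs$gamma / kpap) * (1 - exp(-kpap * s)) +
      cs$beta * (1 - exp(-kpdp * s))
  }
  i <- region == "III"
  if (any(i)) {
    s <- t[i] - bd$t1p
    Ps[i] <- pmax(cs$B - kappa * s, 0)
    Paa[i] <- cs$C
    Pap[i] <- cs$D
    Pd[i] <- cs$F + kappa * s
  }
  i <- region == "IV"
  if (any(i)) {
    u <- t[i] - bd$t2
    Ps[i] <- 0
    Paa[i] <- cs$C * exp(-kpda * u)
    Pap[i] <- cs$D * exp(-kpdp * u)
    Pd[i] <- 1 - Paa[i] - Pap[i]
  }
  data.frame(t = t, Ps = Ps, Paa = Paa, Pap = Pap, Pd = Pd, region = region)
}

#' Queue-exhaustion time of the two-center model
#'
#' t2 = t1p + B/kappa: the instant the pediatric surge queue vanishes, with
#' both centers at capacity draining it at the combined zeroth-order rate
#' kappa = ka' + kp'.
#'
#' @inheritParams ptc_region1_at
#' @return Time in days.
#' @export
ptc_t2 <- function(rates) {
  ptc_boundaries(rates)$t2
}

#' Time to discharge a given fraction in the two-center model
#'
#' The region-IV discharged fraction
#' Pd(t) = 1 - C exp(-kpda (t - t2)) - D exp(-kpdp (t - t2)) is
#' transcendental in t, so the crossing of \code{threshold} is located by a
#' bracketed root search on \code{[t2, t2 + 1000/min(kpda, kpdp)]} with
#' absolute tolerance 1e-8 days (Pd is monotone there, so the bracket is
#' guaranteed once Pd(t2) is below the threshold). If the threshold is
#' already met at t2 the crossing is searched in the earlier regions with a
#' warning.
#'
#' @inheritParams capacity_t99
#' @param rates A [ptc_rate_set()].
#' @return The crossing time in days.
#' @examples
#' ptc_t99(ptc_rate_set(0.158, 0.158, 1.151, 1.151, 0.122, 0.122))
#' @export
ptc_t99 <- function(rates, threshold = 0.99) {
  stopifnot(inherits(rates, "ptc_rate_set"))
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold <= 0 || threshold >= 1) {
    stop("'threshold' must be a single fraction in (0, 1)")
  }
  bd <- ptc_boundaries(rates)
  if (bd$collapsed) {
    return(capacity_t99(rate_set(rates$kpaa, rates$kpda, rates$ka_prime),
                        threshold))
  }
  cs <- bd$constants
  if (threshold == cs$G) return(bd$t2)
  if (threshold < cs$G) {
    warning("threshold reached before the surge queue vanished; solving numerically in regions I-III")
    f <- function(tt) ptc_model_at(tt, rates)$Pd - threshold
    return(stats::uniroot(f, c(0, bd$t2), tol = 1e-8)$root)
  }
  f <- function(u) {
    cs$C * exp(-rates$kpda * u) + cs$D * exp(-rates$kpdp * u) - (1 - threshold)
  }
  upper <- 1e3 / min(rates$kpda, rates$kpdp)
  if (f(upper) > 0) {
    stop("bracket failure locating t99: Pd(t2) = ", signif(cs$G, 6),
         ", residual not crossed by t2 + ", signif(upper, 4), " days")
  }
  bd$t2 + stats::uniroot(f, c(0, upper), tol = 1e-8)$root
}
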