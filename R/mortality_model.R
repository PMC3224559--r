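#' Breakpoints and constants of the two-center model with death rates
#'
#' Extends the two-center surge model with a per-compartment death rate:
#' the surge dies at rate omega_s while untreated, inpatients die at
#' omega_a/omega_p (omega_a'/omega_p' while the centers run at capacity),
#' and discharged patients die at the background rate omega_d. The flows
#' keep the closed-form piecewise structure, with composite decay constants
#' lambda_s = k + omega_s, lambda_a = kpda + omega_a,
#' lambda_p = kpdp + omega_p, lambda_II = kpap + omega_s,
#' lambda_a' = ka' + omega_a' and mu = kappa + omega_a' + omega_p'.
#' While a center is saturated its census is held constant, deaths being
#' backfilled from the queue, so its inpatient deaths accrue at the constant
#' rate omega' during that regime.
#'
#' With every death rate zero the model reduces exactly to
#' [ptc_boundaries()]; with \code{kpap = kp_prime = 0} (no PTC) the
#' PTC-specific region II is skipped. In the no-PTC configuration the
#' steady-state death flow omits omega_p' (there are no PTC inpatients).
#'
#' @param rates A [ptc_rate_set()].
#' @param deaths A [death_rate_set()].
#' @return A list with breakpoints \code{t1a}, \code{t1p}, \code{t2}, the
#'   boundary constants (region-exit populations A, C, E, H, B, D, F, G and
#'   deceased fractions J, K, L, plus the region-II integration constants),
#'   and a flag \code{collapsed}.
#' @export
mortality_boundaries <- function(rates, deaths) {
  stopifnot(inherits(rates, "ptc_rate_set"), inherits(deaths, "death_rate_set"))
  if (all_deaths_zero(deaths)) {
    pb <- ptc_boundaries(rates)
    cs <- pb$constants
    return(list(t1a = pb$t1a, t1p = pb$t1p, t2 = pb$t2,
                constants = c(cs, list(J = 0, K = 0, L = 0)),
                collapsed = pb$collapsed, death_free = TRUE))
  }
  mk <- mortality_kinetics(rates, deaths)
  list(t1a = mk$t1a, t1p = mk$t1p, t2 = mk$t2,
       constants = mk$constants, collapsed = mk$collapsed, death_free = FALSE)
}

# All composite constants and breakpoints of the mortality model, computed
# in region order I -> II -> III. Shared by the evaluators below.
mortality_kinetics <- function(rates, deaths) {
  kpaa <- rates$kpaa; kpap <- rates$kpap
  kpda <- rates$kpda; kpdp <- rates$kpdp
  kap <- rates$ka_prime; kpp <- rates$kp_prime
  ws <- deaths$omega_s; wa <- deaths$omega_a; wp <- deaths$omega_p
  wd <- deaths$omega_d; wap <- deaths$omega_a_prime; wpp <- deaths$omega_p_prime
  has_ptc <- rates$has_ptc

  ls <- rates$k + ws          # lambda_s
  la <- kpda + wa             # lambda_a
  lp <- kpdp + wp             # lambda_p
  if (rates_degenerate(ls, la) || rates_degenerate(wd, la) ||
      rates_degenerate(wd, ls)) {
    stop("degenerate composite rates (lambda_s, lambda_a, omega_d must be pairwise distinct)")
  }
  if (has_ptc && (rates_degenerate(ls, lp) || rates_degenerate(wd, lp))) {
    stop("degenerate composite rates (lambda_p coincides with lambda_s or omega_d)")
  }

  t1a <- log(ls / la) / (ls - la)
  if (!is.finite(t1a) || t1a <= 0) {
    stop("invalid adult-center saturation time t1a under the supplied death rates")
  }

  # region-I closed forms (fractions of the initial pediatric cohort)
  region1 <- function(t) {
    Es <- exp(-ls * t); Ea <- exp(-la * t); Ed <- exp(-wd * t)
    Ps <- Es
    Paa <- kpaa / (la - ls) * (Es - Ea)
    T1a_ <- kpda * kpaa / (la - ls)
    if (has_ptc) {
      Ep <- exp(-lp * t)
      Pap <- kpap / (lp - ls) * (Es - Ep)
      T1p_ <- kpdp * kpap / (lp - ls)
      T3 <- kpdp * kpap / ((wd - lp) * (ls - lp))
      Pd <- (T1a_ + T1p_) / (wd - ls) * (Es - Ed) +
        kpda * kpaa / ((wd - la) * (ls - la)) * (Ea - Ed) +
        T3 * (Ep - Ed)
    } else {
      Pap <- numeric(length(t))
      Pd <- T1a_ / (wd - ls) * (Es - Ed) +
        kpda * kpaa / ((wd - la) * (ls - la)) * (Ea - Ed)
    }
    data.frame(Ps = Ps, Paa = Paa, Pap = Pap, Pd = Pd,
               PD = 1 - Ps - Paa - Pap - Pd)
  }

  r1 <- region1(t1a)
  A <- r1$Ps; C <- r1$Paa; H <- r1$Pap; E <- r1$Pd; J <- r1$PD

  collapsed <- !has_ptc
  reg2 <- NULL
  if (has_ptc) {
    if (wd <= 0) {
      stop("region II of the mortality model requires omega_d > 0 when any death rate is nonzero")
    }
    lII <- kpap + ws
    lap <- kap + wap
    if (rates_degenerate(lp, lII) || rates_degenerate(wd, lII)) {
      stop("degenerate composite rates (lambda_II coincides with lambda_p or omega_d)")
    }
    rho <- lap / lII
    alpha_p <- A + rho
    theta <- alpha_p * kpap / (lp - lII)
    phi <- rho * kpap / lp
    Gam <- (H + phi - theta) * kpdp / (wd - lp)
    Del <- theta * kpdp / (wd - lII)
    Lam <- (kap - phi * kpdp) / wd

    arg <- -lII * theta / (lp * (H + phi - theta))
    if (!is.finite(arg) || arg <= 0) {
      stop("no PTC saturation time in region II under the supplied death rates ",
           "(log argument nonpositive)")
    }
    # Small negative s_star (rate-matched centers saturating together, or a
    # sensitivity increment nudging the formal argmax marginally before
    # t1a) is evaluated as written; see ptc_boundaries().
    s_star <- log(arg) / (lII - lp)
    if (!is.finite(s_star) || s_star < -0.1) {
      stop("model assumes the adult center saturates first (t1a < t1p); ",
           "relabel the rate constants if the PTC is faster")
    }
    t1p <- t1a + s_star

    region2 <- function(s) {
      EII <- exp(-lII * s); Ep <- exp(-lp * s); Ed <- exp(-wd * s)
      Ps <- alpha_p * EII - rho
      Pap <- (H + phi - theta) * Ep + theta * EII - phi
      Pd <- Gam * (Ep - Ed) + Del * (EII - Ed) + Lam * (1 - Ed) + E * Ed
      data.frame(Ps = Ps, Paa = C, Pap = Pap, Pd = Pd,
                 PD = 1 - Ps - C - Pap - Pd)
    }
    r2 <- region2(s_star)
    B <- r2$Ps; D <- r2$Pap; F_ <- r2$Pd; K <- r2$PD
    if (B <= 0) {
      stop("surge exhausted before the PTC saturated (B <= 0) under the supplied death rates")
    }
    reg2 <- list(lII = lII, lap = lap, rho = rho, alpha_p = alpha_p,
                 theta = theta, phi = phi, Gam = Gam, Del = Del, Lam = Lam,
                 fn = region2)
  } else {
    # no PTC: the single center saturates and region II never occurs
    t1p <- t1a
    B <- A; D <- 0; F_ <- E; K <- J
  }

  kappa <- kap + kpp
  mu <- kappa + wap + if (has_ptc) wpp else 0
  t2 <- if (ws > 0) t1p + log1p(B * ws / mu) / ws else t1p + B / mu

  region3 <- function(s) {
    Ps <- if (ws > 0) -mu / ws + (B + mu / ws) * exp(-ws * s) else B - mu * s
    Ps <- pmax(Ps, 0)
    Pd <- if (wd > 0) kappa / wd + (F_ - kappa / wd) * exp(-wd * s) else F_ + kappa * s
    data.frame(Ps = Ps, Paa = C, Pap = D, Pd = Pd,
               PD = 1 - Ps - C - D - Pd)
  }
  r3 <- region3(t2 - t1p)
  G <- r3$Pd; L <- r3$PD

  region4 <- function(u) {
    Ea <- exp(-la * u); Ed <- exp(-wd * u)
    Paa <- C * Ea
    if (has_ptc) {
      Ep <- exp(-lp * u)
      Pap <- D * Ep
      Pd <- C * kpda / (wd - la) * (Ea - Ed) +
        D * kpdp / (wd - lp) * (Ep - Ed) + G * Ed
    } else {
      Pap <- numeric(length(u))
      Pd <- C * kpda / (wd - la) * (Ea - Ed) + G * Ed
    }
    data.frame(Ps = 0, Paa = Paa, Pap = Pap, Pd = Pd,
               PD = 1 - Paa - Pap - Pd)
  }

  list(t1a = t1a, t1p = t1p, t2 = t2, collapsed = collapsed,
       constants = list(A = A, C = C, E = E, H = H, J = J,
                        B = B, D = D, F = F_, K = K, G = G, L = L,
                        alpha_prime = if (has_ptc) reg2$alpha_p else NA_real_,
                        rho = if (has_ptc) reg2$rho else NA_real_,
                        theta = if (has_ptc) reg2$theta else NA_real_,
                        phi = if (has_ptc) reg2$phi else NA_real_,
                        Gamma = if (has_ptc) reg2$Gam else NA_real_,
                        Delta = if (has_ptc) reg2$Del else NA_real_,
                        Lambda = if (has_ptc) reg2$Lam else NA_real_),
       region1 = region1, region2 = if (has_ptc) reg2$fn else NULL,
       region3 = region3, region4 = region4)
}

#' Evaluate the two-center model with explicit death rates
#'
#' Piecewise closed-form trajectory of the five compartments (surge,
#' adult-center inpatients, PTC inpatients, living discharged, deceased)
#' across the regions of [mortality_boundaries()]. The deceased fraction PD
#' is obtained from exact conservation (the five flows sum to zero in every
#' region, so PD = 1 minus the living compartments), which is algebraically
#' identical to integrating its own rate equation.
#'
#' @inheritParams mortality_boundaries
#' @param t Time(s) in days, nonnegative; may be a vector.
#' @return A data.frame with columns \code{t}, \code{Ps}, \code{Paa},
#'   \code{Pap}, \code{Pd}, \code{PD}, \code{region}.
#' @examples
#' r <- ptc_rate_set(0.158, 0.158, 1.151, 1.151, 0.122, 0.122)
#' mortality_model_at(c(2, 5, 10), r, haiti_death_rates())
#' @export
mortality_model_at <- function(t, rates, deaths) {
  stopifnot(inherits(rates, "ptc_rate_set"), inherits(deaths, "death_rate_set"))
  check_times(t)
  if (all_deaths_zero(deaths)) {
    out <- ptc_model_at(t, rates)
    return(data.frame(t = t, Ps = out$Ps, Paa = out$Paa, Pap = out$Pap,
                      Pd = out$Pd, PD = 0, region = out$region))
  }
  mk <- mortality_kinetics(rates, deaths)
  t1p_eff <- max(mk$t1p, mk$t1a)   # region II empty at simultaneous saturation
  region <- ifelse(t < mk$t1a, "I",
                   ifelse(t < t1p_eff, "II",
                          ifelse(t < mk$t2, "III", "IV")))
  out <- data.frame(Ps = numeric(length(t)), Paa = 0, Pap = 0, Pd = 0, PD = 0)
  for (rg in unique(region)) {
    i <- region == rg
    vals <- switch(rg,
                   I = mk$region1(t[i]),
                   II = mk$region2(t[i] - mk$t1a),
                   III = mk$region3(t[i] - mk$t1p),
                   IV = mk$region4(t[i] - mk$t2))
    out[i, ] <- vals
  }
  cbind(t = t, out, region = region)
}

#' Deceased fraction of the pediatric cohort at a given time
#'
#' @inheritParams mortality_model_at
#' @param t_eval Evaluation time in days (default 10, the duration of the
#'   historical field-hospital deployment).
#' @return The deceased fraction of the initial pediatric cohort.
#' @examples
#' no_ptc <- ptc_rate_set(0.158, 0, 1.151, 0, 0.122, 0)
#' deceased_fraction(no_ptc, haiti_death_rates(), 10)
#' @export
deceased_fraction <- function(rates, deaths, t_eval = 10) {
  stopifnot(is.numeric(t_eval), length(t_eval) == 1L, t_eval >= 0)
  mortality_model_at(t_eval, rates, deaths)$PD
}

#' Mortality risk reduction conferred by one configuration over another
#'
#' Compares the deceased fractions of two center configurations (typically
#' "no PTC" versus "PTC available") at a common evaluation time under a
#' common set of death rates.
#'
#' @param rates_ref Reference configuration (e.g. no PTC), a
#'   [ptc_rate_set()].
#' @param rates_alt Alternative configuration (e.g. PTC available).
#' @param deaths A [death_rate_set()].
#' @inheritParams deceased_fraction
#' @return A list with the two deceased fractions, the \code{absolute} risk
#'   reduction (reference minus alternative), the \code{relative} reduction
#'   (absolute divided by the reference, reported as 0 with
#'   \code{relative_defined = FALSE} when the reference risk is zero).
#' @export
mortality_risk_reduction <- function(rates_ref, rates_alt, deaths, t_eval = 10) {
  pd_ref <- deceased_fraction(rates_ref, deaths, t_eval)
  pd_alt <- deceased_fraction(rates_alt, deaths, t_eval)
  absolute <- pd_ref - pd_alt
  defined <- pd_ref > 0
  list(deceased_ref = pd_ref, deceased_alt = pd_alt,
       absolute = absolute,
       relative = if (defined) absolute / pd_ref else 0,
       relative_defined = defined)
}

all_deaths_zero <- function(deaths) {
  all(c(deaths$omega_s, deaths$omega_a, deaths$omega_p, deaths$omega_d,
        deaths$omega_a_prime, deaths$omega_p_prime) == 0)
}
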