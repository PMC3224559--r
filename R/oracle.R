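#' Governing ODE system of a model variant, for numerical verification
#'
#' Builds the right-hand sides, regime breakpoints and initial state of the
#' chosen model variant's differential equations, for use by
#' [oracle_trajectory()]. Each region's flows conserve the total population
#' (including the deceased compartment where present); the breakpoints are
#' the analytically known regime-switching times, so the integrator can
#' restart exactly on them instead of locating events numerically.
#'
#' @param model One of \code{"simple"}, \code{"delayed"},
#'   \code{"capacity"}, \code{"ptc"}, \code{"mortality"}.
#' @param rates The matching rate-set object ([rate_set()],
#'   [delayed_rate_set()] or [ptc_rate_set()]).
#' @param deaths A [death_rate_set()], required for
#'   \code{model = "mortality"}.
#' @return A list with \code{compartments}, \code{y0}, \code{breakpoints}
#'   and \code{rhs} (one function per region, in order).
#' @export
surge_ode_spec <- function(model = c("simple", "delayed", "capacity", "ptc",
                                     "mortality"),
                           rates, deaths = NULL) {
  model <- match.arg(model)
  switch(model,
    simple = {
      stopifnot(inherits(rates, "rate_set"))
      ka <- rates$ka; kd <- rates$kd
      list(compartments = c("Ns", "Na", "Nd"),
           y0 = c(Ns = 1, Na = 0, Nd = 0),
           breakpoints = numeric(0),
           rhs = list(function(t, y, p) {
             list(c(-ka * y[1], ka * y[1] - kd * y[2], kd * y[2]))
           }))
    },
    delayed = {
      stopifnot(inherits(rates, "delayed_rate_set"))
      ks <- rates$ks; ka <- rates$ka; kd <- rates$kd
      list(compartments = c("Ne", "Ns", "Na", "Nd"),
           y0 = c(Ne = 1, Ns = 0, Na = 0, Nd = 0),
           breakpoints = numeric(0),
           rhs = list(function(t, y, p) {
             list(c(-ks * y[1], ks * y[1] - ka * y[2],
                    ka * y[2] - kd * y[3], kd * y[3]))
           }))
    },
    capacity = {
      stopifnot(inherits(rates, "rate_set"))
      check_kprime(rates)
      ka <- rates$ka; kd <- rates$kd; kp <- rates$kprime
      bp <- capacity_breakpoints(rates)
      list(compartments = c("Ns", "Na", "Nd"),
           y0 = c(Ns = 1, Na = 0, Nd = 0),
           breakpoints = c(bp$t1, bp$t2),
           rhs = list(
             function(t, y, p) list(c(-ka * y[1], ka * y[1] - kd * y[2],
                                      kd * y[2])),
             function(t, y, p) list(c(-kp, 0, kp)),
             function(t, y, p) list(c(0, -kd * y[2], kd * y[2]))))
    },
    ptc = {
      stopifnot(inherits(rates, "ptc_rate_set"))
      bd <- ptc_boundaries(rates)
      kpaa <- rates$kpaa; kpap <- rates$kpap
      kpda <- rates$kpda; kpdp <- rates$kpdp
      kap <- rates$ka_prime; kappa <- rates$kappa
      rhs1 <- function(t, y, p) {
        list(c(-(kpaa + kpap) * y[1],
               kpaa * y[1] - kpda * y[2],
               kpap * y[1] - kpdp * y[3],
               kpda * y[2] + kpdp * y[3]))
      }
      rhs2 <- function(t, y, p) {
        list(c(-kap - kpap * y[1], 0,
               kpap * y[1] - kpdp * y[3],
               kap + kpdp * y[3]))
      }
      rhs3 <- function(t, y, p) list(c(-kappa, 0, 0, kappa))
      rhs4 <- function(t, y, p) {
        list(c(0, -kpda * y[2], -kpdp * y[3],
               kpda * y[2] + kpdp * y[3]))
      }
      if (bd$collapsed) {
        list(compartments = c("Ps", "Paa", "Pap", "Pd"),
             y0 = c(Ps = 1, Paa = 0, Pap = 0, Pd = 0),
             breakpoints = c(bd$t1a, bd$t2),
             rhs = list(rhs1, rhs3, rhs4))
      } else {
        list(compartments = c("Ps", "Paa", "Pap", "Pd"),
             y0 = c(Ps = 1, Paa = 0, Pap = 0, Pd = 0),
             breakpoints = c(bd$t1a, bd$t1p, bd$t2),
             rhs = list(rhs1, rhs2, rhs3, rhs4))
      }
    },
    mortality = {
      stopifnot(inherits(rates, "ptc_rate_set"),
                inherits(deaths, "death_rate_set"))
      bd <- mortality_boundaries(rates, deaths)
      kpaa <- rates$kpaa; kpap <- rates$kpap
      kpda <- rates$kpda; kpdp <- rates$kpdp
      kap <- rates$ka_prime; kappa <- rates$kappa
      ws <- deaths$omega_s; wa <- deaths$omega_a; wp <- deaths$omega_p
      wd <- deaths$omega_d; wap <- deaths$omega_a_prime
      wpp <- if (rates$has_ptc) deaths$omega_p_prime else 0
      mu <- kappa + wap + wpp
      rhs1 <- function(t, y, p) {
        list(c(-(kpaa + kpap + ws) * y[1],
               kpaa * y[1] - (kpda + wa) * y[2],
               kpap * y[1] - (kpdp + wp) * y[3],
               kpda * y[2] + kpdp * y[3] - wd * y[4],
               ws * y[1] + wa * y[2] + wp * y[3] + wd * y[4]))
      }
      rhs2 <- function(t, y, p) {
        list(c(-(kpap + ws) * y[1] - (kap + wap),
               0,
               kpap * y[1] - (kpdp + wp) * y[3],
               kpdp * y[3] + kap - wd * y[4],
               ws * y[1] + wap + wp * y[3] + wd * y[4]))
      }
      rhs3 <- function(t, y, p) {
        list(c(-mu - ws * y[1], 0, 0,
               kappa - wd * y[4],
               ws * y[1] + wd * y[4] + wap + wpp))
      }
      rhs4 <- function(t, y, p) {
        list(c(0, -(kpda + wa) * y[2], -(kpdp + wp) * y[3],
               kpda * y[2] + kpdp * y[3] - wd * y[4],
               wa * y[2] + wp * y[3] + wd * y[4]))
      }
      bps <- if (bd$collapsed) c(bd$t1a, bd$t2) else c(bd$t1a, bd$t1p, bd$t2)
      rhss <- if (bd$collapsed) list(rhs1, rhs3, rhs4) else
        list(rhs1, rhs2, rhs3, rhs4)
      list(compartments = c("Ps", "Paa", "Pap", "Pd", "PD"),
           y0 = c(Ps = 1, Paa = 0, Pap = 0, Pd = 0, PD = 0),
           breakpoints = bps,
           rhs = rhss)
    })
}

#' Fixed-step numerical integration of a model's governing ODEs
#'
#' Integrates the governing equations of a model variant with classical
#' fourth-order Runge-Kutta (via \code{deSolve::rk4}) on a fixed grid,
#' restarting exactly at each analytically known regime breakpoint so that
#' no event-location error enters. This integrator is deliberately
#' independent of the closed-form evaluators and serves as the package's
#' brute-force verification surface.
#'
#' @inheritParams surge_ode_spec
#' @param t_grid Sorted nonnegative times (days) at which to report the
#'   state.
#' @param step Integration step in days. The local truncation error is
#'   O(step^4); the default resolves all closed-form comparisons well below
#'   1e-6.
#' @return A data.frame with column \code{t} followed by one column per
#'   compartment.
#' @examples
#' oracle_trajectory("simple", rate_set(0.158, 1.151), t_grid = c(1, 2, 5))
#' @export
oracle_trajectory <- function(model, rates, t_grid, step = 1e-3,
                              deaths = NULL) {
  spec <- if (is.list(model) && !is.null(model$rhs)) model else
    surge_ode_spec(model, rates, deaths)
  check_times(t_grid)
  if (is.unsorted(t_grid)) stop("'t_grid' must be sorted")
  t_max <- max(t_grid)
  # enforce nondecreasing breakpoints (simultaneous saturation can produce
  # a zero-length, or rounding a marginally inverted, region II)
  bps <- cummax(spec$breakpoints)
  edges <- c(0, pmin(bps, t_max), t_max)
  y <- spec$y0
  out_t <- numeric(0)
  out_y <- NULL
  if (t_grid[1] == 0) {
    out_t <- 0
    out_y <- matrix(y, nrow = 1)
  }
  for (seg in seq_len(length(edges) - 1L)) {
    t0 <- edges[seg]; t1 <- edges[seg + 1L]
    if (t1 - t0 < 1e-9) next
    rhs <- spec$rhs[[min(seg, length(spec$rhs))]]
    report <- t_grid[t_grid > t0 & t_grid <= t1]
    # keep at least ten steps inside a short regime
    seg_step <- min(step, (t1 - t0) / 10)
    times <- sort(unique(c(seq(t0, t1, by = seg_step), t1, report)))
    sol <- deSolve::rk4(y, times, rhs, parms = NULL)
    if (length(report)) {
      idx <- vapply(report, function(g) which.min(abs(times - g)), integer(1))
      out_t <- c(out_t, report)
      out_y <- rbind(out_y, unname(sol[idx, -1, drop = FALSE]))
    }
    y <- sol[nrow(sol), -1]
    if (any(y < -1e-8)) {
      stop("oracle produced a negative population (", signif(min(y), 3),
           "): region/RHS mismatch")
    }
  }
  out <- data.frame(t = out_t)
  out[spec$compartments] <- out_y
  out[order(out$t), , drop = FALSE]
}
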