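#' Scan PTC efficiency as a scale factor of the adult-center rates
#'
#' Explores how the admission-complete time t2 and the discharge-complete
#' time t99 of the pediatric cohort respond as the PTC's rates are scaled
#' from near zero up to (almost) the adult center's fitted rates. Two
#' one-parameter families are supported: \code{"uniform"} scales all three
#' PTC-side rates (kpap, kpdp, kp') by a common factor s of the
#' corresponding adult values, while \code{"fixed_discharge"} pins the PTC
#' discharge rate at the adult value (kpdp = kpda) and scales only the
#' admission and steady-state rates. The uniform family exhibits the
#' trapping effect: a slow-discharging PTC accumulates patients it cannot
#' release, so t99 first rises above the no-PTC baseline before falling.
#'
#' @param adult_rates The fitted adult-center [rate_set()]; its (ka, kd,
#'   k') become (kpaa, kpda, ka') and the reference values for scaling.
#' @param s_grid Scale factors in (0, 1); default a 60-point logarithmic
#'   grid on [1e-3, 0.999].
#' @param mode \code{"uniform"} or \code{"fixed_discharge"}.
#' @param threshold Discharged fraction defining t99.
#' @return A data.frame of class \code{"scale_scan"} with one row per
#'   factor: \code{s}, \code{t1a}, \code{t1p}, \code{t2}, \code{t99},
#'   \code{D} (PTC census at capacity), \code{ok} and \code{message} for
#'   factors where the four-region solution does not apply.
#' @examples
#' scan <- scale_factor_scan(rate_set(0.158, 1.151, 0.122),
#'                           s_grid = c(0.02, 0.1, 0.5, 0.999))
#' @export
scale_factor_scan <- function(adult_rates,
                              s_grid = exp(seq(log(1e-3), log(0.999),
                                               length.out = 60)),
                              mode = c("uniform", "fixed_discharge"),
                              threshold = 0.99) {
  stopifnot(inherits(adult_rates, "rate_set"))
  check_kprime(adult_rates)
  mode <- match.arg(mode)
  if (any(s_grid <= 0) || any(s_grid >= 1)) {
    stop("scale factors must lie strictly inside (0, 1)")
  }
  rows <- lapply(s_grid, function(s) {
    r <- scaled_ptc_rates(adult_rates, s, mode)
    res <- tryCatch({
      bd <- ptc_boundaries(r)
      data.frame(s = s, t1a = bd$t1a, t1p = bd$t1p, t2 = bd$t2,
                 t99 = ptc_t99(r, threshold), D = bd$constants$D,
                 ok = TRUE, message = "")
    }, error = function(e) {
      data.frame(s = s, t1a = NA_real_, t1p = NA_real_, t2 = NA_real_,
                 t99 = NA_real_, D = NA_real_, ok = FALSE,
                 message = conditionMessage(e))
    })
    res
  })
  out <- do.call(rbind, rows)
  attr(out, "mode") <- mode
  attr(out, "adult_rates") <- adult_rates
  attr(out, "threshold") <- threshold
  class(out) <- c("scale_scan", "data.frame")
  out
}

scaled_ptc_rates <- function(adult_rates, s, mode) {
  ka <- adult_rates$ka; kd <- adult_rates$kd; kp <- adult_rates$kprime
  if (mode == "uniform") {
    ptc_rate_set(kpaa = ka, kpap = s * ka, kpda = kd, kpdp = s * kd,
                 ka_prime = kp, kp_prime = s * kp)
  } else {
    ptc_rate_set(kpaa = ka, kpap = s * ka, kpda = kd, kpdp = kd,
                 ka_prime = kp, kp_prime = s * kp)
  }
}

#' Locate the interior maximum of t99 along a scale-factor scan
#'
#' Finds the scale factor at which t99 peaks (the worst-case trapping
#' effect). The coarse grid maximum is refined by golden-section search
#' between its neighboring grid points. A maximum on the edge of the grid
#' is reported as non-interior (the monotone, non-trapping case).
#'
#' @param scan A [scale_factor_scan()] result.
#' @param tol Absolute refinement tolerance on the scale factor.
#' @return A list with \code{s_star}, \code{t99_star} and \code{interior}
#'   (FALSE when t99 is monotone over the grid, in which case \code{s_star}
#'   is NA).
#' @export
find_t99_peak <- function(scan, tol = 1e-4) {
  stopifnot(inherits(scan, "scale_scan"))
  ok <- scan$ok & is.finite(scan$t99)
  s <- scan$s[ok]; t99 <- scan$t99[ok]
  if (length(s) < 3) stop("scan has fewer than three valid points")
  i <- which.max(t99)
  if (i == 1L || i == length(s)) {
    return(list(s_star = NA_real_, t99_star = max(t99), interior = FALSE))
  }
  adult <- attr(scan, "adult_rates")
  mode <- attr(scan, "mode")
  threshold <- attr(scan, "threshold")
  f <- function(sv) ptc_t99(scaled_ptc_rates(adult, sv, mode), threshold)
  opt <- stats::optimize(f, lower = s[i - 1L], upper = s[i + 1L],
                         maximum = TRUE, tol = tol)
  list(s_star = opt$maximum, t99_star = opt$objective, interior = TRUE)
}

#' @export
plot.scale_scan <- function(x, ...) {
  ok <- x$ok
  graphics::matplot(x$s[ok], cbind(x$t2[ok], x$t99[ok]), type = "l",
                    lty = 1, col = c("steelblue", "firebrick"), log = "x",
                    xlab = "PTC scale factor s", ylab = "days",
                    main = paste0("t2 and t99 vs PTC efficiency (",
                                  attr(x, "mode"), " scaling)"), ...)
  graphics::legend("topright", c("t2 (admission complete)",
                                 "t99 (discharge complete)"),
                   col = c("steelblue", "firebrick"), lty = 1, bty = "n")
  invisible(x)
}

#' Mortality comparison: no PTC versus a PTC matching the adult center
#'
#' Builds the two arms of the mortality analysis from the fitted
#' adult-center rates: a reference arm with no PTC (kpap = kp' = 0) and an
#' intervention arm whose PTC admits and discharges at the same rates as
#' the adult center. Both arms share the same death rates; the outcome is
#' the deceased fraction of the initial pediatric cohort at \code{t_eval}.
#'
#' @param adult_rates The fitted adult-center [rate_set()].
#' @param deaths A [death_rate_set()]; defaults to the literature-derived
#'   [haiti_death_rates()].
#' @param t_eval Evaluation time in days.
#' @return A list with the two arm definitions and the outcome block of
#'   [mortality_risk_reduction()].
#' @examples
#' mortality_comparison(rate_set(0.158, 1.151, 0.122))
#' @export
mortality_comparison <- function(adult_rates, deaths = haiti_death_rates(),
                                 t_eval = 10) {
  stopifnot(inherits(adult_rates, "rate_set"))
  check_kprime(adult_rates)
  ka <- adult_rates$ka; kd <- adult_rates$kd; kp <- adult_rates$kprime
  no_ptc <- ptc_rate_set(kpaa = ka, kpap = 0, kpda = kd, kpdp = 0,
                         ka_prime = kp, kp_prime = 0)
  with_ptc <- ptc_rate_set(kpaa = ka, kpap = ka, kpda = kd, kpdp = kd,
                           ka_prime = kp, kp_prime = kp)
  out <- mortality_risk_reduction(no_ptc, with_ptc, deaths, t_eval)
  c(list(no_ptc = no_ptc, with_ptc = with_ptc, deaths = deaths,
         t_eval = t_eval), out)
}
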