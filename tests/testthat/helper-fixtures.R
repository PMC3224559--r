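# Shared fixtures: the historical fitted rates and random-parameter
# generators used across the property-style tests.

haiti_rates <- function() rate_set(ka = 0.158, kd = 1.151, kprime = 0.122)

# cache the (slow-ish) full fit once per test run
haiti_fit <- local({
  fit <- NULL
  function() {
    if (is.null(fit)) fit <<- surge_fit(t1 = 2, t99 = 10, tau = 2)
    fit
  }
})

random_rate_set <- function() {
  ka <- stats::runif(1, 0.05, 0.8)
  kd <- ka * stats::runif(1, 1.3, 8)        # distinct, discharge faster
  kprime <- kd * stats::runif(1, 0.05, 0.6)
  rate_set(ka, kd, kprime)
}

# A PTC rate set on which the four-region solution is valid: adult center
# faster, PTC discharge slower than the adult one, B > 0.
random_ptc_rate_set <- function(max_tries = 50) {
  for (i in seq_len(max_tries)) {
    kpaa <- stats::runif(1, 0.05, 0.5)
    kpap <- stats::runif(1, 0.05, 0.5)
    kpda <- (kpaa + kpap) * stats::runif(1, 1.5, 6)
    kpdp <- kpda * stats::runif(1, 0.25, 0.9)
    kap <- kpda * stats::runif(1, 0.05, 0.3)
    kpp <- kpdp * stats::runif(1, 0.05, 0.3)
    r <- tryCatch(ptc_rate_set(kpaa, kpap, kpda, kpdp, kap, kpp),
                  error = function(e) NULL)
    if (is.null(r)) next
    bd <- tryCatch(ptc_boundaries(r), error = function(e) NULL)
    if (!is.null(bd) && bd$t1p > bd$t1a) return(r)
  }
  stop("could not draw a valid PTC rate set")
}

random_death_rate_set <- function() {
  death_rate_set(omega_s = stats::runif(1, 0.01, 0.15),
                 omega_a = stats::runif(1, 0.001, 0.02),
                 omega_p = stats::runif(1, 0.001, 0.02),
                 omega_d = stats::runif(1, 1e-5, 1e-3))
}

expect_conserved <- function(df, cols, tol = 1e-9) {
  expect_lt(max(abs(rowSums(df[cols]) - 1)), tol)
}
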