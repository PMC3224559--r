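fd_sensitivity_capacity <- function(rates, rel_step = 1e-6) {
  p0 <- c(rates$ka, rates$kd, rates$kprime)
  outs <- function(p) {
    r <- suppressWarnings(rate_set(p[1], p[2], p[3]))
    bp <- capacity_breakpoints(r)
    c(bp$t1, bp$t2, capacity_t99(r))
  }
  S <- matrix(NA_real_, 3, 3)
  for (j in 1:3) {
    h <- rel_step * p0[j]
    pp <- p0; pp[j] <- pp[j] + h
    pm <- p0; pm[j] <- pm[j] - h
    S[, j] <- (outs(pp) - outs(pm)) / (2 * h)
  }
  S
}

test_that("analytic sensitivities at the historical fit match the closed forms", {
  S <- analytic_sensitivity_capacity(haiti_fit()$rates)
  expected <- matrix(c(-4.36, -1.14, 0,
                       -12.23, -0.06, -49.37,
                       -7.87, -2.40, -49.37), 3, byrow = TRUE)
  rel <- abs(S - expected) / pmax(abs(expected), 0.01)
  expect_lt(max(rel), 0.02)
})

test_that("analytic derivative chain agrees with finite differences", {
  set.seed(71)
  for (i in 1:20) {
    r <- random_rate_set()
    S <- analytic_sensitivity_capacity(r)
    S_fd <- fd_sensitivity_capacity(r)
    rel <- abs(S - S_fd) / pmax(abs(S_fd), 1e-8)
    expect_lt(max(rel[abs(S_fd) > 1e-8]), 1e-4)
    expect_identical(S["t1", "kprime"], 0)     # t1 never depends on k'
    expect_lt(S["t2", "kprime"], 0)            # Eq for t2: -Ns(t1)/k'^2
  }
})

test_that("variance matrix is the elementwise squared-sensitivity product", {
  fit <- haiti_fit()
  S <- analytic_sensitivity_capacity(fit$rates)
  V <- variance_matrix(S, fit$sigmas)
  expect_true(all(V >= 0))
  expect_equal(V, S^2 * rep(fit$sigmas^2, each = 3), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(variance_matrix(S, c(0, 0, 0)),
               matrix(0, 3, 3, dimnames = dimnames(S)), tolerance = 1e-15)
  # published variance contributions for the historical fit
  expect_lt(abs(V["t1", "ka"] - 0.082) / 0.082, 0.05)
  expect_lt(abs(V["t99", "kd"] - 0.815) / 0.815, 0.05)
})

test_that("discharge rate dominates t1 and t99 uncertainty in the fit", {
  fit <- haiti_fit()
  V <- variance_matrix(analytic_sensitivity_capacity(fit$rates), fit$sigmas)
  expect_identical(colnames(V)[which.max(V["t99", ])], "kd")
  expect_identical(colnames(V)[which.max(V["t1", ])], "kd")
})

test_that("two-center numeric sensitivity is step-robust and kp'-dominated", {
  fit <- haiti_fit()
  r <- fit$rates
  rp <- ptc_rate_set(r$ka, r$ka, r$kd, r$kd, r$kprime, r$kprime)
  sig <- ptc_reference_sigmas(rp, fit$sigmas)
  sens <- numeric_sensitivity_ptc(rp, sig)
  expect_identical(dim(sens$S), c(4L, 6L))
  expect_true(all(sens$V >= 0))
  # t1a is independent of the PTC discharge and steady-state rates
  expect_equal(unname(sens$S["t1a", c("kpdp", "ka_prime", "kp_prime")]),
               c(0, 0, 0), tolerance = 1e-9)
  # step adequacy: halving the increment moves no element by more than 1%
  half <- numeric_sensitivity_ptc(rp, sig, step = 5e-4)
  big <- abs(sens$S) > 1e-3
  expect_lt(max(abs(half$S[big] - sens$S[big]) / abs(sens$S[big])), 0.01)
  # the PTC steady-state throughput dominates the t99 uncertainty
  expect_identical(colnames(sens$V)[which.max(sens$V["t99", ])], "kp_prime")
  # zero uncertainties null the variance matrix
  expect_equal(max(numeric_sensitivity_ptc(rp, rep(0, 6))$V), 0)
})

test_that("reference sigma assignment separates adult and PTC parameters", {
  fit <- haiti_fit()
  r <- fit$rates
  rp <- ptc_rate_set(r$ka, r$ka, r$kd, r$kd, r$kprime, r$kprime)
  sig <- ptc_reference_sigmas(rp, fit$sigmas)
  expect_equal(sig[["kpaa"]], fit$sigmas[["ka"]])
  expect_equal(sig[["kpda"]], fit$sigmas[["kd"]])
  expect_equal(sig[["ka_prime"]], fit$sigmas[["kprime"]])
  expect_equal(sig[["kpdp"]]^2, 0.35 * r$kd)
  expect_equal(sig[["kpap"]]^2, 0.35 * r$ka)
})

test_that("degenerate rates are rejected for the analytic chain", {
  expect_error(analytic_sensitivity_capacity(rate_set(1, 1, 0.5)),
               "non-degenerate")
})
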