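test_that("historical observations recover the published rate constants", {
  fit <- haiti_fit()
  p <- coef(fit)
  expect_lt(abs(p[["ka"]] - 0.158) / 0.158, 0.01)
  expect_lt(abs(p[["kd"]] - 1.151) / 1.151, 0.01)
  expect_lt(abs(p[["kprime"]] - 0.122) / 0.122, 0.01)
  expect_lt(abs(fit$sigmas[["ka"]] - 0.066) / 0.066, 0.15)
  expect_lt(abs(fit$sigmas[["kd"]] - 0.377) / 0.377, 0.15)
  expect_lt(abs(fit$sigmas[["kprime"]] - 0.014) / 0.014, 0.15)
  expect_identical(fit$branch, "ka<kd")
  expect_lt(fit$residual, 1e-6)
})

test_that("fitted rates reproduce the observations (round trip)", {
  fit <- haiti_fit()
  res <- residuals(fit)
  expect_lt(max(abs(res)), 1e-6)
  bp <- capacity_breakpoints(fit$rates)
  expect_equal(c(bp$t1, bp$t2, capacity_t99(fit$rates)), c(2, 8, 10),
               tolerance = 1e-8)
})

test_that("the admission-faster branch is fit when the data admit it", {
  # observations generated from an admission-faster-than-discharge truth
  truth <- rate_set(1.2, 0.3, 0.1)
  bp <- capacity_breakpoints(truth)
  t99 <- capacity_t99(truth)
  alt <- surge_fit(bp$t1, t99, t99 - bp$t2, branch = "ka>kd")
  expect_identical(alt$branch, "ka>kd")
  expect_gt(alt$rates$ka, alt$rates$kd)
  expect_lt(max(abs(residuals(alt))), 1e-6)
  expect_lt(max(abs(coef(alt) - c(1.2, 0.3, 0.1))), 1e-6)
  # the historical constraint admits only the discharge-faster root:
  # requesting the other branch must fail loudly, not silently cross over
  expect_error(surge_fit(2, 10, 2, branch = "ka>kd"), "branch")
})

test_that("forward-simulated timescales are inverted to the true rates", {
  set.seed(67)
  n_ok <- 0
  for (i in 1:10) {
    r <- random_rate_set()
    bp <- capacity_breakpoints(r)
    t99 <- capacity_t99(r)
    tau <- t99 - bp$t2
    if (bp$t1 >= t99 - tau) next
    branch <- if (r$ka < r$kd) "ka<kd" else "ka>kd"
    fit <- surge_fit(bp$t1, t99, tau, branch = branch)
    expect_lt(max(abs(coef(fit) - c(r$ka, r$kd, r$kprime))), 1e-6)
    n_ok <- n_ok + 1
  }
  expect_gte(n_ok, 8)
})

test_that("uncertainties follow the stated variance scaling law", {
  fit1 <- haiti_fit()
  fit2 <- surge_fit(2, 10, 2, obs_var = c(2, 2, 2))
  expect_equal(unname(fit2$sigmas / fit1$sigmas), rep(sqrt(2), 3),
               tolerance = 1e-6)
})

test_that("profiled curvature agrees with a finite-difference second derivative", {
  fit <- haiti_fit()
  p0 <- coef(fit)
  obs <- fit$observations
  sse <- function(p) {
    r <- rate_set(p[1], p[2], p[3])
    bp <- capacity_breakpoints(r)
    sum((c(bp$t1, bp$t2, capacity_t99(r)) - obs)^2)
  }
  for (j in seq_along(p0)) {
    h <- 1e-4 * p0[j]
    pp <- p0; pp[j] <- pp[j] + h
    pm <- p0; pm[j] <- pm[j] - h
    curv_fd <- (sse(pp) - 2 * sse(p0) + sse(pm)) / h^2
    sigma_fd <- sqrt(2 / curv_fd)
    expect_lt(abs(sigma_fd - fit$sigmas[[j]]) / sigma_fd, 0.05)
  }
})

test_that("invalid observations and non-convergence are rejected", {
  expect_error(surge_fit(2, 10, -1), "tau")
  expect_error(surge_fit(9, 10, 2), "t1 < t99 - tau")
})

test_that("relaxing the t99 - t2 constraint trades the rates as expected", {
  scan <- tau_scan(tau_values = seq(1, 3, by = 0.5))
  base <- scan[scan$tau == 2, ]
  fit <- haiti_fit()
  expect_equal(c(base$ka, base$kd, base$kprime), unname(coef(fit)),
               tolerance = 1e-8)
  # slower post-surge discharge must be compensated before and during
  expect_true(all(diff(scan$ka) > 0))
  expect_true(all(diff(scan$kd) < 0))
  expect_true(all(diff(scan$kprime) > 0))
})
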