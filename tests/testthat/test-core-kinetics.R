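test_that("unconstrained model satisfies its boundary conditions", {
  r <- haiti_rates()
  at0 <- simple_model_at(0, r)
  expect_equal(unlist(at0[c("Ns", "Na", "Nd")]), c(Ns = 1, Na = 0, Nd = 0))
  late <- simple_model_at(1e3 / r$ka, r)
  expect_equal(unlist(late[c("Ns", "Na", "Nd")]), c(Ns = 0, Na = 0, Nd = 1),
               tolerance = 1e-6)
  expect_error(simple_model_at(-1, r), "nonnegative")
})

test_that("closed forms match fixed-step integration of the rate equations", {
  r <- haiti_rates()
  grid <- c(0.5, 1, 2, 5, 10)
  num <- oracle_trajectory("simple", r, grid)
  cf <- simple_model_at(grid, r)
  expect_lt(max(abs(as.matrix(cf[c("Ns", "Na", "Nd")]) -
                      as.matrix(num[c("Ns", "Na", "Nd")]))), 1e-6)

  set.seed(11)
  for (i in 1:10) {
    rr <- random_rate_set()
    g <- seq(0.5, 6 / rr$ka, length.out = 6)
    num <- oracle_trajectory("simple", rr, g)
    cf <- simple_model_at(g, rr)
    expect_lt(max(abs(as.matrix(cf[-1]) - as.matrix(num[-1]))), 1e-6)
  }
})

test_that("admitted-population maximum matches its analytic argmax", {
  r <- haiti_rates()
  expect_equal(time_of_max_admitted(r), 2, tolerance = 5e-3)

  # equal rates: the removable singularity has limit 1/ka, peak exp(-1)
  eq <- rate_set(1, 1)
  expect_equal(time_of_max_admitted(eq), 1)
  expect_equal(max_admitted_fraction(eq), exp(-1))

  # grid-search verification of the argmax and peak height
  set.seed(7)
  for (i in 1:5) {
    rr <- random_rate_set()
    tmax <- time_of_max_admitted(rr)
    tt <- seq(1e-4, 4 * tmax, length.out = 4000)
    na <- simple_model_at(tt, rr)$Na
    expect_equal(tt[which.max(na)], tmax, tolerance = 1e-2)
    expect_lte(max(na), max_admitted_fraction(rr))
    expect_equal(simple_model_at(tmax, rr)$Na, max_admitted_fraction(rr),
                 tolerance = 1e-10)
  }
})

test_that("rates collapsing to equality stay continuous (limit forms)", {
  ka <- 0.4
  t <- c(0.5, 2, 5)
  limit <- simple_model_at(t, rate_set(ka, ka))
  for (eps in c(1e-4, 1e-6)) {
    near <- simple_model_at(t, rate_set(ka, ka * (1 + eps)))
    expect_equal(as.matrix(near[-1]), as.matrix(limit[-1]), tolerance = 1e-3)
  }
  expect_equal(time_of_max_admitted(rate_set(ka, ka * (1 + 1e-6))),
               1 / ka, tolerance = 1e-5)
})

test_that("delayed-surge model: boundary conditions, conservation, oracle", {
  r <- delayed_rate_set(ks = 0.5, ka = 0.2, kd = 1.0)
  at0 <- delayed_model_at(0, r)
  expect_equal(unlist(at0[c("Ne", "Ns", "Na", "Nd")]),
               c(Ne = 1, Ns = 0, Na = 0, Nd = 0))
  tt <- seq(0, 100, by = 0.5)
  tr <- delayed_model_at(tt, r)
  expect_conserved(tr, c("Ne", "Ns", "Na", "Nd"))
  expect_true(all(diff(tr$Ne) <= 0))
  expect_true(all(diff(tr$Nd) >= -1e-12))

  grid <- c(0.5, 1, 3, 6, 12)
  num <- oracle_trajectory("delayed", r, grid)
  cf <- delayed_model_at(grid, r)
  expect_lt(max(abs(as.matrix(cf[-1]) - as.matrix(num[-1]))), 1e-6)

  expect_error(delayed_model_at(1, delayed_rate_set(0.2, 0.2 + 1e-12, 1)),
               "pairwise distinct")
})

test_that("fast exposure limit recovers the instantaneous-surge model", {
  ka <- 0.3; kd <- 1.2
  r <- delayed_rate_set(ks = 1e3 * ka, ka = ka, kd = kd)
  t <- seq(0.5, 10, by = 0.5)
  del <- delayed_model_at(t, r)
  sim <- simple_model_at(t, rate_set(ka, kd))
  expect_lt(max(abs(del$Na - sim$Na)), 1e-2)
  expect_lt(max(abs(del$Nd - sim$Nd)), 1e-2)
})

test_that("delayed-surge peak time matches dense evaluation", {
  r <- delayed_rate_set(ks = 0.5, ka = 0.2, kd = 1.0)
  expect_equal(time_of_max_surge_delayed(r), log(0.2 / 0.5) / (0.2 - 0.5),
               tolerance = 1e-12)
  set.seed(23)
  for (i in 1:20) {
    ks <- stats::runif(1, 0.1, 2)
    ka <- ks * stats::runif(1, 1.2, 5)
    kd <- ka * stats::runif(1, 1.3, 4)
    rr <- delayed_rate_set(ks, ka, kd)
    ts <- time_of_max_surge_delayed(rr)
    tt <- seq(1e-4, 5 * ts, length.out = 4000)
    ns <- delayed_model_at(tt, rr)$Ns
    expect_equal(tt[which.max(ns)], ts, tolerance = 2e-2)
  }
})

test_that("conservation and monotonicity hold across random rate sets", {
  set.seed(41)
  tt <- seq(0, 100, length.out = 400)
  for (i in 1:10) {
    rr <- random_rate_set()
    tr <- simple_model_at(tt, rr)
    expect_conserved(tr, c("Ns", "Na", "Nd"))
    expect_true(all(diff(tr$Ns) <= 0))
    expect_true(all(diff(tr$Nd) >= -1e-12))
  }
})
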