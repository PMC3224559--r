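eq_rates <- function() {
  r <- haiti_rates()
  ptc_rate_set(r$ka, r$ka, r$kd, r$kd, r$kprime, r$kprime)
}

test_that("pre-saturation pediatric kinetics behave structurally", {
  r <- random_ptc_rate_set()
  at0 <- ptc_region1_at(0, r)
  expect_equal(unlist(at0[c("Ps", "Paa", "Pap", "Pd")]),
               c(Ps = 1, Paa = 0, Pap = 0, Pd = 0))

  # no PTC: reduces to the single-center kinetics, PTC census identically 0
  no_ptc <- ptc_rate_set(0.2, 0, 1.0, 0, 0.1, 0)
  tt <- seq(0, 3, by = 0.25)
  r1 <- ptc_region1_at(tt, no_ptc)
  sim <- simple_model_at(tt, rate_set(0.2, 1.0))
  expect_equal(r1$Pap, rep(0, length(tt)))
  expect_equal(r1$Ps, sim$Ns, tolerance = 1e-12)
  expect_equal(r1$Paa, sim$Na, tolerance = 1e-12)

  # symmetric centers: the two admitted censuses coincide for all t
  sym <- ptc_rate_set(0.2, 0.2, 1.3, 1.3, 0.1, 0.1)
  r1 <- ptc_region1_at(tt, sym)
  expect_equal(r1$Paa, r1$Pap, tolerance = 1e-12)
})

test_that("rate-matched PTC halves the admission time of the cohort", {
  r <- eq_rates()
  bd <- ptc_boundaries(r)
  expect_gt(bd$t2, 4.0)
  expect_lt(bd$t2, 4.5)
  t99 <- ptc_t99(r)
  expect_gte(t99, 6.5)
  expect_lt(t99, 7.0)
  # both centers saturate simultaneously when their rates match
  expect_equal(bd$t1p, bd$t1a, tolerance = 1e-6)
})

test_that("PTC saturation time is the argmax of its census", {
  set.seed(31)
  for (i in 1:8) {
    r <- random_ptc_rate_set()
    bd <- ptc_boundaries(r)
    tt <- seq(1e-4, bd$t2 - 1e-6, length.out = 4000)
    pap <- ptc_model_at(tt, r)$Pap
    expect_equal(tt[which.max(pap)], bd$t1p,
                 tolerance = 2e-3 * max(1, bd$t1p))
    expect_equal(max(pap), bd$constants$D, tolerance = 1e-6)
  }
})

test_that("populations are continuous at all three breakpoints", {
  set.seed(37)
  for (i in 1:8) {
    r <- random_ptc_rate_set()
    bd <- ptc_boundaries(r)
    eps <- 1e-11
    for (b in c(bd$t1a, bd$t1p, bd$t2)) {
      left <- ptc_model_at(b - eps, r)
      right <- ptc_model_at(b, r)
      expect_lt(max(abs(unlist(left[c("Ps", "Paa", "Pap", "Pd")]) -
                          unlist(right[c("Ps", "Paa", "Pap", "Pd")]))), 1e-9)
    }
  }
})

test_that("conservation, censuses pinned at capacity, full discharge", {
  set.seed(43)
  for (i in 1:5) {
    r <- random_ptc_rate_set()
    bd <- ptc_boundaries(r)
    tt <- seq(0, 3 * bd$t2, length.out = 600)
    tr <- ptc_model_at(tt, r)
    expect_conserved(tr, c("Ps", "Paa", "Pap", "Pd"))
    ii <- tt >= bd$t1a & tt < bd$t2
    expect_equal(tr$Paa[ii], rep(bd$constants$C, sum(ii)), tolerance = 1e-9)
    ii <- tt >= bd$t1p & tt < bd$t2
    expect_equal(tr$Pap[ii], rep(bd$constants$D, sum(ii)), tolerance = 1e-9)
  }
  late <- ptc_model_at(1e3, eq_rates())
  expect_equal(unlist(late[c("Ps", "Paa", "Pap", "Pd")]),
               c(Ps = 0, Paa = 0, Pap = 0, Pd = 1), tolerance = 1e-6)
})

test_that("no-PTC configuration collapses to the single-center model", {
  r <- haiti_rates()
  no_ptc <- ptc_rate_set(r$ka, 0, r$kd, 0, r$kprime, 0)
  tt <- seq(0, 12, by = 0.25)
  pt <- ptc_model_at(tt, no_ptc)
  cm <- capacity_model_at(tt, r)
  expect_equal(pt$Ps, cm$Ns, tolerance = 1e-12)
  expect_equal(pt$Paa, cm$Na, tolerance = 1e-12)
  expect_equal(pt$Pd, cm$Nd, tolerance = 1e-12)
  expect_equal(pt$Pap, rep(0, length(tt)))
  expect_equal(ptc_t99(no_ptc), capacity_t99(r), tolerance = 1e-12)
  expect_equal(ptc_boundaries(no_ptc)$constants$D, 0)
})

test_that("queue-exhaustion and completion times are well defined", {
  r <- random_ptc_rate_set()
  bd <- ptc_boundaries(r)
  # large combined throughput leaves no region III
  fast <- ptc_rate_set(r$kpaa, r$kpap, r$kpda, r$kpdp, 1e6, 1e6)
  bdf <- ptc_boundaries(fast)
  expect_equal(bdf$t2, bdf$t1p, tolerance = 1e-5)
  # threshold equal to the discharged fraction at t2 gives t2 itself
  expect_identical(ptc_t99(r, bd$constants$G), bd$t2)
  # self-consistency of the numeric root
  th <- 0.995
  t99 <- ptc_t99(r, th)
  expect_equal(ptc_model_at(t99, r)$Pd, th, tolerance = 1e-7)
})

test_that("two-center closed forms match event-switched integration", {
  set.seed(47)
  for (i in 1:5) {
    r <- random_ptc_rate_set()
    t99 <- ptc_t99(r)
    grid <- seq(0.3, min(1.2 * t99, 100), length.out = 8)
    num <- oracle_trajectory("ptc", r, grid)
    cf <- ptc_model_at(grid, r)
    expect_lt(max(abs(as.matrix(cf[c("Ps", "Paa", "Pap", "Pd")]) -
                        as.matrix(num[c("Ps", "Paa", "Pap", "Pd")]))), 1e-6)
  }
})

test_that("a genuinely faster PTC is rejected with relabeling advice", {
  expect_error(ptc_boundaries(ptc_rate_set(0.2, 0.2, 0.9, 2.5, 0.1, 0.1)),
               "relabel")
})
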