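arm_no_ptc <- function() {
  r <- haiti_rates()
  ptc_rate_set(r$ka, 0, r$kd, 0, r$kprime, 0)
}
arm_with_ptc <- function() {
  r <- haiti_rates()
  ptc_rate_set(r$ka, r$ka, r$kd, r$kd, r$kprime, r$kprime)
}

test_that("death-free limit reproduces the two-center model exactly", {
  zero <- death_rate_set(0, 0, 0, 0)
  for (r in list(arm_with_ptc(), random_ptc_rate_set())) {
    bd <- mortality_boundaries(r, zero)
    pb <- ptc_boundaries(r)
    expect_equal(bd$t1a, pb$t1a, tolerance = 1e-9)
    expect_equal(bd$t2, pb$t2, tolerance = 1e-9)
    tt <- seq(0, 2 * pb$t2, length.out = 50)
    md <- mortality_model_at(tt, r, zero)
    pt <- ptc_model_at(tt, r)
    expect_equal(md$PD, rep(0, length(tt)))
    expect_equal(md$Pd, pt$Pd, tolerance = 1e-12)
    expect_equal(deceased_fraction(r, zero, 25), 0)
  }
})

test_that("small death rates perturb the death-free model continuously", {
  set.seed(53)
  r <- random_ptc_rate_set()
  zero <- death_rate_set(0, 0, 0, 0)
  tiny <- death_rate_set(1e-6, 1e-6, 1e-6, 1e-6)
  tt <- seq(0.5, 2 * ptc_t2(r), length.out = 30)
  d0 <- mortality_model_at(tt, r, zero)
  d1 <- mortality_model_at(tt, r, tiny)
  expect_lt(max(abs(d1$Pd - d0$Pd)), 1e-4)
  expect_lt(max(d1$PD), 1e-4)
})

test_that("vanishing surge death rate uses the linear-drain limit for t2", {
  r <- arm_with_ptc()
  base <- haiti_death_rates()
  no_surge_deaths <- death_rate_set(0, base$omega_a, base$omega_p,
                                    base$omega_d)
  tiny_surge <- death_rate_set(1e-8, base$omega_a, base$omega_p,
                               base$omega_d)
  t2_limit <- mortality_boundaries(r, no_surge_deaths)$t2
  t2_tiny <- mortality_boundaries(r, tiny_surge)$t2
  expect_equal(t2_limit, t2_tiny, tolerance = 1e-6)
})

test_that("five-compartment closed forms match integration in every region", {
  deaths <- haiti_death_rates()
  for (r in list(arm_no_ptc(), arm_with_ptc())) {
    bd <- mortality_boundaries(r, deaths)
    grid <- sort(c(bd$t1a * c(0.5, 0.99), bd$t1a + 0.2,
                   (bd$t1p + bd$t2) / 2, bd$t2 * c(1.2, 2)))
    num <- oracle_trajectory("mortality", r, grid, deaths = deaths)
    cf <- mortality_model_at(grid, r, deaths)
    expect_lt(max(abs(as.matrix(cf[c("Ps", "Paa", "Pap", "Pd", "PD")]) -
                        as.matrix(num[c("Ps", "Paa", "Pap", "Pd", "PD")]))),
              1e-6)
  }
  set.seed(59)
  for (i in 1:4) {
    r <- random_ptc_rate_set()
    d <- random_death_rate_set()
    bd <- tryCatch(mortality_boundaries(r, d), error = function(e) NULL)
    if (is.null(bd)) next
    grid <- sort(c(bd$t1a * 0.6, (bd$t1a + bd$t1p) / 2,
                   (bd$t1p + bd$t2) / 2, bd$t2 * 1.5))
    num <- oracle_trajectory("mortality", r, grid, deaths = d)
    cf <- mortality_model_at(grid, r, d)
    expect_lt(max(abs(as.matrix(cf[-c(1, 7)]) - as.matrix(num[-1]))), 1e-6)
  }
})

test_that("deceased fraction is conserved, nondecreasing and ordered", {
  deaths <- haiti_death_rates()
  for (r in list(arm_no_ptc(), arm_with_ptc())) {
    bd <- mortality_boundaries(r, deaths)
    tt <- seq(0, 3 * bd$t2, length.out = 500)
    tr <- mortality_model_at(tt, r, deaths)
    expect_conserved(tr, c("Ps", "Paa", "Pap", "Pd", "PD"))
    expect_true(all(diff(tr$PD) >= -1e-12))
    cs <- bd$constants
    expect_lte(cs$J, cs$K + 1e-12)
    expect_lte(cs$K, cs$L + 1e-12)
  }
})

test_that("historical death rates give the expected deceased fractions", {
  deaths <- haiti_death_rates()
  pd_no <- deceased_fraction(arm_no_ptc(), deaths, 10)
  pd_yes <- deceased_fraction(arm_with_ptc(), deaths, 10)
  expect_lt(abs(pd_no - 0.240), 0.005)
  expect_lt(abs(pd_yes - 0.152), 0.005)
  rr <- mortality_risk_reduction(arm_no_ptc(), arm_with_ptc(), deaths, 10)
  expect_lt(abs(rr$absolute - 0.088), 0.005)
  expect_lt(abs(rr$relative - 0.37), 0.02)
})

test_that("risk reduction degenerates sensibly", {
  deaths <- haiti_death_rates()
  same <- mortality_risk_reduction(arm_no_ptc(), arm_no_ptc(), deaths, 10)
  expect_equal(same$absolute, 0)
  expect_equal(same$relative, 0)
  at0 <- mortality_risk_reduction(arm_no_ptc(), arm_with_ptc(), deaths, 0)
  expect_equal(at0$absolute, 0)
  expect_false(at0$relative_defined)
})

test_that("a faster PTC arm strictly reduces deaths", {
  set.seed(61)
  for (i in 1:5) {
    d <- random_death_rate_set()
    r <- haiti_rates()
    no_ptc <- ptc_rate_set(r$ka, 0, r$kd, 0, r$kprime, 0)
    with_ptc <- ptc_rate_set(r$ka, r$ka, r$kd, r$kd, r$kprime, r$kprime)
    rr <- mortality_risk_reduction(no_ptc, with_ptc, d, 10)
    expect_gt(rr$absolute, 0)
  }
})
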