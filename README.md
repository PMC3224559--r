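# surgekinetics

Deterministic population-kinetics models of mass-casualty surge triage,
for disaster planners and modelers who want closed-form, auditable
answers to two questions: how long does it take a trauma system to admit
and to definitively treat a surge cohort, and how much does adding a
pediatric trauma center (PTC) change that — including its effect on
mortality.

## The model

A surge cohort of size N0 flows through sequential care states with
first-order rate constants (a fluid/compartmental approximation of the
triage queue):

    Ns --ka--> Na --kd--> Nd        (all rates in day^-1, populations as
                                     fractions of N0)

so dNs/dt = -ka Ns, dNa/dt = ka Ns - kd Na, dNd/dt = kd Na, with the
two-exponential closed forms Ns = e^(-ka t),
Na = ka/(kd-ka) (e^(-ka t) - e^(-kd t)). The **capacity-limited** model
lets this run until the admitted census peaks at
t1 = ln(kd/ka)/(kd-ka) — the peak value Na(t1) *is* the center's surge
capacity, a function of the rates alone — then pins the census,
draining the queue at a zeroth-order throughput k' until it vanishes at
t2 = t1 + Ns(t1)/k', after which the wards empty exponentially. The
operational completion time t99 (99% discharged) follows in closed form:
t99 = t2 - (1/kd) ln(1 - (0.99 - Nd(t2))/Na(t2)).

The **two-center** variant splits a pediatric cohort between the adult
center (rates kpaa, kpda) and a PTC (kpap, kpdp), producing four
piecewise regimes as first one center and then the other saturates; the
**mortality** extension adds per-compartment death rates
(omega_s, omega_a, omega_p, omega_d) and an absorbing deceased
compartment. Rate constants are recovered from observed timescales
(t1, t99, and an assumed gap tau = t99 - t2) by simultaneous root
finding, with curvature-based uncertainties; local sensitivity is
propagated as S_ij = dX_i/dp_j and V_ij = S_ij^2 sigma_j^2. Every
closed form is cross-checked against fixed-step RK4 integration of the
governing ODEs with exact regime restarts.

## Worked example: the 2010 Haiti field-hospital deployment

An Israeli Defense Forces field hospital treated 1111 patients in
10 days and saturated before day 2, giving t1 = 2 d and t99 = 10 d;
assuming the post-queue cleanup took as long as the fill-up (tau = 2 d):

```r
library(surgekinetics)
fit <- surge_fit(t1 = 2, t99 = 10, tau = 2)
summary(fit)
#> Capacity-limited surge model fit
#>   observations: t1 = 2, t99 = 10, tau = 2 days (branch ka<kd)
#>   ka      0.1579 +/- 0.0659 day^-1
#>   kd      1.1513 +/- 0.3780 day^-1
#>   kprime  0.1215 +/- 0.0144 day^-1
#>   residual SSE 6.51e-30 after 5 Newton iterations
#>   implied timescales: t1 = 2.000, t2 = 8.000, t99 = 10.000 days
#>   intrinsic surge capacity: 0.100 of the cohort
```

The admission bottleneck (ka = 0.158/d) is an order of magnitude slower
than discharge (kd = 1.151/d), and the hospital's derived surge capacity
is 10% of the cohort. Now give the pediatric cohort a PTC as fast as
the adult center:

```r
r <- fit$rates
ptc <- ptc_rate_set(kpaa = r$ka, kpap = r$ka, kpda = r$kd, kpdp = r$kd,
                    ka_prime = r$kprime, kp_prime = r$kprime)
c(t2 = ptc_t2(ptc), t99 = ptc_t99(ptc))
#>       t2      t99
#> 4.071399 6.523077
```

Admission of the whole pediatric cohort is nearly halved (8 d to
4.1 d) and complete treatment drops by more than a third (10 d to
6.5 d). But a *slow* PTC is worse than none: `scale_factor_scan()`
shows t99 rising above the 10-day baseline for PTC rates below ~0.44 of
the adult values (peaking near a scale factor of 0.045) — the trapping
effect of a center that admits children it cannot discharge. With
literature-derived death rates, `mortality_comparison(r)` puts the
pediatric deceased fraction at day 10 at 24.1% without a PTC versus
15.3% with a rate-matched one: an absolute risk reduction of 8.8
percentage points, a relative reduction of 37%.

A command-line wrapper covers the same workflow
(`inst/cli/surgekin fit --t1 2 --t99 10 --tau 2`, plus `simulate`,
`sensitivity`, `scan` and `mortality` subcommands driven by YAML
scenario files; see `inst/extdata/haiti.yaml`).

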