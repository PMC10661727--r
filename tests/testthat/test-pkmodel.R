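test_that("individualization applies allometry and lognormal random effects", {
  pop <- pop_parameters()
  ref <- individualize(pop, pop$lbm_ref, "scig")
  expect_equal(ref$cl, pop$cl_ref)
  expect_equal(ref$vc, pop$vc_ref)
  expect_equal(ref$q, pop$q_ref)
  expect_equal(ref$vp, pop$vp_ref)
  expect_equal(ref$ka, pop$ka_scig)
  expect_equal(ref$f, pop$f_scig)
  expect_equal(ref$ksyn, pop$ksyn_ref)

  lin <- pop_parameters(theta_cl = 1)
  expect_equal(individualize(lin, 2 * lin$lbm_ref, "scig")$cl, 2 * lin$cl_ref)

  # power law: child at 26.32% of reference fat-free mass
  p88 <- pop_parameters(theta_cl = 0.88)
  ind <- individualize(p88, 0.2632 * p88$lbm_ref, "scig")
  expect_equal(ind$cl / p88$cl_ref, 0.2632^0.88, tolerance = 1e-12)
  expect_equal(ind$cl / p88$cl_ref, 0.3088, tolerance = 1e-3)

  # etas act on the log scale through the omegas
  eta <- c(0.5, -0.3, 1.2, -2)
  ind2 <- individualize(pop, pop$lbm_ref, "fscig", etas = eta)
  expect_equal(ind2$cl, pop$cl_ref * exp(pop$omega_cl * 0.5))
  expect_equal(ind2$ka, pop$ka_fscig * exp(pop$omega_ka * 1.2))
  expect_equal(ind2$ksyn, pop$ksyn_ref * exp(pop$omega_ksyn * -2))
  expect_equal(ind2$f, pop$f_fscig)
})

test_that("endogenous baseline is synthesis over clearance", {
  expect_equal(endogenous_css(make_ind(0.1, 3, 0.3, 3, 0.25, 0.7, 0.2)), 2.0)
  expect_equal(endogenous_css(make_ind(0.1, 3, 0.3, 3, 0.25, 0.7, 0)), 0)
  a <- make_ind(0.1, 3, 0.3, 3, 0.25, 0.7, 0.2)
  b <- make_ind(0.3, 3, 0.3, 3, 0.25, 0.7, 0.6) # both scaled by 3
  expect_equal(endogenous_css(a), endogenous_css(b))
})

test_that("unit-dose response is zero at dose time, non-negative, and conserves dose", {
  set.seed(314)
  for (i in 1:5) {
    ind <- rand_ind()
    tt <- seq(0, 2000, by = 0.05)
    resp <- sc_unit_response(ind, tt)
    expect_equal(resp[1], 0, tolerance = 1e-12)
    expect_true(all(resp >= 0))
    expect_equal(pracma::trapz(tt, resp), ind$f / ind$cl, tolerance = 1e-4)
  }
})

test_that("unit-dose response collapses to the Bateman function as q -> 0", {
  ind <- make_ind(cl = 0.09, vc = 3, q = 1e-10, vp = 3, ka = 0.25,
                  f = 0.7, ksyn = 0.2)
  ke <- ind$cl / ind$vc
  tt <- seq(0.25, 120, by = 0.25)
  bateman <- ind$f * ind$ka / (ind$vc * (ind$ka - ke)) *
    (exp(-ke * tt) - exp(-ind$ka * tt))
  expect_equal(sc_unit_response(ind, tt), bateman, tolerance = 1e-6)
})

test_that("switch-time excess starts exactly at c0, decays monotonically, and matches the one-compartment closed form", {
  ind <- make_ind(0.1, 3, 0.3, 3, 0.25, 0.7, 0.2)
  tt <- seq(0, 140, 0.25)
  expect_equal(initial_excess_response(ind, 0, tt), rep(0, length(tt)))
  y <- initial_excess_response(ind, 5, tt)
  expect_equal(y[1], 5)
  expect_true(all(diff(y) <= 0))
  expect_true(all(y >= 0))
  # one-compartment limit: ke = 0.03/day, 5 * exp(-0.84) at 28 days
  ind1 <- make_ind(cl = 0.03 * 3, vc = 3, q = 1e-10, vp = 3, ka = 0.25,
                   f = 0.7, ksyn = 0.2)
  expect_equal(initial_excess_response(ind1, 5, 28), 5 * exp(-0.84),
               tolerance = 1e-6)
  expect_equal(initial_excess_response(ind1, 5, 28), 2.158, tolerance = 1e-3)
})

test_that("profiles decompose exactly and respect degenerate inputs", {
  ind <- make_ind(0.1, 3, 0.3, 3, 0.25, 0.7, 0.2)
  reg <- regimen_scig()
  tg <- seq(0, 140, 0.25)
  css <- endogenous_css(ind)
  # no dosing from the endogenous steady state: flat profile
  flat <- simulate_profile(ind, reg, 0, css, tg)
  expect_equal(flat$conc_total, rep(css, length(tg)), tolerance = 1e-12)
  # starting below the endogenous baseline violates the precondition
  expect_error(simulate_profile(ind, reg, 10, css / 2, tg), "endogenous baseline")
  # total = endogenous + exogenous pointwise
  prof <- simulate_profile(ind, reg, 10, 7, tg)
  expect_equal(prof$conc_total, prof$conc_endogenous + prof$conc_exogenous,
               tolerance = 1e-12)
  expect_true(all(prof$conc_total >= 0))
})

test_that("the exogenous component is dose-linear and time-invariant", {
  ind <- make_ind(0.12, 3.5, 0.25, 4, 0.2, 0.8, 0.25)
  tg <- seq(0, 140, 0.25)
  css <- endogenous_css(ind)
  p1 <- simulate_profile(ind, regimen_scig(), 5, css, tg)
  p2 <- simulate_profile(ind, regimen_scig(), 10, css, tg)
  expect_equal(p2$conc_exogenous, 2 * p1$conc_exogenous, tolerance = 1e-12)
  # shifting the dose train shifts the response
  shift <- 14
  rs <- regimen("scig", 0.15, 7, horizon = 140 + shift, first_dose_time = shift)
  ps <- simulate_profile(ind, rs, 5, css, seq(0, 140 + shift, 0.25))
  expect_equal(ps$conc_exogenous[ps$times >= shift], p1$conc_exogenous,
               tolerance = 1e-12)
})

test_that("superposition matches brute-force ODE integration on representative cases", {
  set.seed(2718)
  tg <- seq(0, 140, 0.25)
  for (reg in list(regimen_scig(), regimen_fscig())) {
    ind <- rand_ind()
    prof <- simulate_profile(ind, reg, 8, 7, tg)
    oracle <- ode_oracle(ind, reg, 8, 7, tg)
    expect_lt(max(abs(prof$conc_total - oracle$conc) / oracle$conc), 1e-5)
  }
})

test_that("mass balance holds in the full system: absorbed = f * dose given - depot remainder", {
  set.seed(99)
  ind <- rand_ind()
  reg <- regimen_scig()
  oracle <- ode_oracle(ind, reg, 6, 7, seq(0, 140, 0.5))
  total_in <- ind$f * 6 * oracle$n_doses
  expect_equal(oracle$absorbed_final + oracle$depot_final, total_in,
               tolerance = 1e-6)
})

test_that("repeated weekly dosing approaches the closed-form accumulation trough (one-compartment limit)", {
  ind <- make_ind(cl = 0.09, vc = 3, q = 1e-10, vp = 3, ka = 0.25,
                  f = 0.7, ksyn = 0.18)
  ke <- ind$cl / ind$vc
  tau <- 7
  css <- endogenous_css(ind)
  reg <- regimen("scig", 0.15, tau, horizon = 504)
  prof <- simulate_profile(ind, reg, 6, css, seq(0, 504, 0.25))
  trough_formula <- ind$f * 6 * ind$ka / (ind$vc * (ind$ka - ke)) *
    (exp(-ke * tau) / (1 - exp(-ke * tau)) -
       exp(-ind$ka * tau) / (1 - exp(-ind$ka * tau))) + css
  expect_equal(prof$conc_total[prof$times == 504], trough_formula,
               tolerance = 1e-6)
})

test_that("profiles become periodic beyond five terminal half-lives", {
  ind <- make_ind(0.1, 3, 0.3, 3, 0.25, 0.7, 0.2)
  d <- igsim:::disposition(ind)
  t_half <- log(2) / d$l2
  reg <- regimen("scig", 0.15, 7, horizon = 364)
  tg <- seq(0, 364, 0.25)
  prof <- simulate_profile(ind, reg, 8, 7, tg)
  sel <- tg >= 5 * t_half & tg <= 364 - 7
  shifted <- prof$conc_total[match(round(tg[sel] + 7, 9), round(tg, 9))]
  expect_true(all(abs(shifted - prof$conc_total[sel]) < 0.005 * prof$conc_total[sel]))
})
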