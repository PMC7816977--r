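cmp <- diacerein_params()
fast_form <- formulation_input("optimized", k_diss = 0.449)
slow_form <- formulation_input("plain", k_diss = 0.012)

test_that("constructors validate compound, formulation and physiology", {
  expect_error(compound_params(368, 3.4, 2.1, 0.6, 1.5, 0.23, 1.5),
               "fu.*<= 1")
  expect_error(compound_params(368, 3.4, 2.1, 0.6, -0.1, 0.23, 1.5),
               "positive")
  expect_error(formulation_input("x"), "exactly one")
  expect_error(formulation_input("x", k_diss = 0), "positive")
  short <- gen_dissolution_profile("first_order", k = 0.05,
                                   times = c(0, 5, 10, 15, 30))
  expect_error(formulation_input("x", profile = short), ">= 60 min")
  prof <- gen_dissolution_profile("first_order", k = 0.05)
  f <- formulation_input("x", profile = prof)
  expect_equal(f$k_diss, 0.05, tolerance = 1e-4)
  expect_error(default_subject(F = 1.2), "<= 1")
})

test_that("mass is conserved through the transit chain", {
  for (form in list(fast_form, slow_form)) {
    sim <- simulate_subject(cmp, form, default_subject())
    expect_lt(mass_balance_error(sim), 1e-3)
  }
  # also with extreme rates
  sim <- simulate_subject(cmp, formulation_input("f", k_diss = 50),
                          default_subject(ka = 50, F = 1))
  expect_lt(mass_balance_error(sim), 1e-3)
})

test_that("the instant-absorption limit matches the one-compartment bolus", {
  subj <- default_subject(gastric_emptying_rate = 5e3, ka = 5e3, F = 1,
                          intestinal_transit_rate = 7 / 3.32)
  sim <- simulate_subject(cmp, formulation_input("f", k_diss = 100), subj)
  V <- sim$volume
  ke <- sim$clearance / V
  sel <- sim$time >= 0.25  # past the (arbitrarily fast) absorption transient
  analytic <- (50 / V) * exp(-ke * sim$time[sel])
  expect_lt(max(abs(sim$conc[sel] - analytic) / analytic), 0.01)
})

test_that("AUC to infinity equals F*D/CL for complete absorption", {
  subj <- default_subject(ka = 50, F = 0.45)
  sim <- simulate_subject(cmp, fast_form, subj, t_end = 150, dt = 0.05)
  expect_equal(auc_total(sim), 0.45 * 50 / sim$clearance, tolerance = 5e-3)
  # and the identity is insensitive to ka / dissolution / transit details
  for (pars in list(list(ka = 30, kd = 0.449), list(ka = 80, kd = 5),
                    list(ka = 50, kd = 1))) {
    s <- simulate_subject(cmp, formulation_input("f", k_diss = pars$kd),
                          default_subject(ka = pars$ka, F = 0.45),
                          t_end = 150)
    expect_equal(auc_total(s), 0.45 * 50 / s$clearance, tolerance = 0.01)
  }
})

test_that("slower dissolution lowers Cmax and delays Tmax", {
  subj <- default_subject()
  for (k in c(0.4, 0.1, 0.04)) {
    a <- pk_summary(simulate_subject(cmp, formulation_input("a", k_diss = k),
                                     subj))
    b <- pk_summary(simulate_subject(cmp,
                                     formulation_input("b", k_diss = k / 2),
                                     subj))
    expect_lt(b$cmax, a$cmax)
    expect_gte(b$tmax, a$tmax)
  }
})

test_that("halving the output grid step barely moves Cmax and AUC", {
  subj <- default_subject()
  s1 <- pk_summary(simulate_subject(cmp, fast_form, subj, dt = 0.05))
  s2 <- pk_summary(simulate_subject(cmp, fast_form, subj, dt = 0.025))
  expect_lt(abs(s1$cmax - s2$cmax) / s2$cmax, 0.002)
  expect_lt(abs(s1$auc_0_24 - s2$auc_0_24) / s2$auc_0_24, 0.002)
})

test_that("pk_summary reads curve geometry correctly", {
  const <- xy_series(seq(0, 24, 0.5), rep(3, 49))
  s <- pk_summary(const)
  expect_equal(s$auc_0_24, 72)
  expect_equal(s$tmax, 0)  # earliest time attaining the maximum
  tri <- xy_series(c(0, 2, 6), c(0, 5, 0))
  st <- pk_summary(tri)
  expect_equal(st$cmax, 5)
  expect_equal(st$tmax, 2)
  expect_equal(st$auc_0_24, 15)  # two triangles: 5 + 10
  expect_error(pk_summary(xy_series(numeric(), numeric())), "empty")
})

test_that("population simulation is seeded, structured and variable", {
  spec <- population_spec("healthy_adult", n_trials = 2, n_subjects = 3,
                          seed = 5)
  a <- simulate_population(cmp, fast_form, spec)
  b <- simulate_population(cmp, fast_form, spec)
  expect_identical(a$subjects, b$subjects)
  expect_identical(a$summary, b$summary)
  expect_equal(nrow(a$subjects), 6)
  expect_gt(a$summary$cmax_sd, 0)

  # any subject is reproducible in isolation
  sp <- draw_subject(spec, 2, 3)
  sim <- pk_summary(simulate_subject(cmp, fast_form, sp, dose = spec$dose))
  row <- a$subjects[a$subjects$trial == 2 & a$subjects$subject == 3, ]
  expect_equal(row$cmax, sim$cmax)
  expect_equal(row$auc_0_24, sim$auc_0_24)

  # zero variability collapses the population to one subject
  ph0 <- population_physiology("healthy_adult", cv_cl = 0, cv_ka = 0,
                               cv_v = 0, weight_sd = 0)
  spec0 <- population_spec("healthy_adult", n_trials = 2, n_subjects = 2,
                           seed = 5, physiology = ph0)
  s0 <- simulate_population(cmp, fast_form, spec0)
  expect_equal(s0$summary$cmax_sd, 0)
  expect_equal(s0$summary$auc_sd, 0)
})

test_that("empirical AUC variability reflects the clearance CV", {
  # sampling-distribution check at reduced scale: the log-normal CV 30%
  # on clearance propagates to an AUC CV in a [20%, 40%] band
  cvs <- vapply(1:8, function(s) {
    spec <- population_spec("healthy_adult", n_trials = 5, n_subjects = 8,
                            seed = s)
    sim <- simulate_population(cmp, fast_form, spec)
    sim$summary$auc_sd / sim$summary$auc_mean
  }, 0)
  expect_gte(mean(cvs >= 0.20 & cvs <= 0.40), 7 / 8)
})

test_that("the geriatric arm shows the higher exposure at identical seeds", {
  ad <- simulate_population(cmp, fast_form,
                            population_spec("healthy_adult", n_trials = 2,
                                            n_subjects = 4, seed = 7))
  ge <- simulate_population(cmp, fast_form,
                            population_spec("geriatric", n_trials = 2,
                                            n_subjects = 4, seed = 7))
  expect_gt(ge$summary$auc_mean, ad$summary$auc_mean)
  # driven by the documented scalings: lower clearance, lower weight
  expect_lt(mean(ge$subjects$cl), mean(ad$subjects$cl))
})

test_that("ratio reporters round half-even to 2 decimals and validate", {
  expect_equal(as.numeric(relative_bioavailability(35.53, 15.48)), 229.52)
  expect_equal(as.numeric(relative_bioavailability(40.56, 15.48)), 262.02)
  expect_equal(as.numeric(relative_bioavailability(12, 12)), 100)
  expect_error(relative_bioavailability(10, 0), "> 0")
  expect_equal(as.numeric(simulated_observed_ratio(1.80, 2.50)), 0.72)
  expect_equal(as.numeric(simulated_observed_ratio(3, 3)), 1)
  expect_equal(attr(simulated_observed_ratio(1.80, 2.50), "raw"), 0.72)
  expect_error(simulated_observed_ratio(1, -2), "> 0")
})
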