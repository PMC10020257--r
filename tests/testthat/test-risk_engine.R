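test_that("family-history RRs are centered by the prevalence-weighted mean", {
  p <- demo_params()
  # c_fh = 0.65*1 + 0.13*1.8 + 0.02*2.9 + 0.20*1.3 = 1.202 (hand arithmetic)
  expect_equal(centering_constant(p, "family_history"), 1.202)
  prof0 <- risk_profile(age = 50, n_fdr = 0, n_sdr = 0)
  expect_equal(family_history_rr(prof0, p), 1.0 / 1.202, tolerance = 1e-12)
  prof1 <- risk_profile(age = 50, n_fdr = 1, age_youngest_fdr = 55)
  expect_equal(family_history_rr(prof1, p), 1.8 / 1.202, tolerance = 1e-12)

  # constant table centers to exactly 1 for every category
  flat <- p
  flat$family_history$rr <- rep(1, 4)
  for (prof in list(prof0, prof1, risk_profile(50, n_fdr = 3, age_youngest_fdr = 40)))
    expect_equal(family_history_rr(prof, flat), 1.0)

  # property: population mean of the centered RR is 1 under the weights
  set.seed(42)
  for (rep in 1:20) {
    q <- p
    q$family_history$rr <- runif(4, 0.5, 5)
    w <- runif(4); q$family_history$weight <- w / sum(w)
    centered <- q$family_history$rr / centering_constant(q, "family_history")
    expect_equal(sum(q$family_history$weight * centered), 1, tolerance = 1e-9)
  }

  # uncovered band is a configuration error naming the band
  q <- p
  q$family_history <- q$family_history[1:2, ]
  q$family_history$weight <- c(0.5, 0.5)
  expect_error(family_history_rr(risk_profile(50, n_fdr = 0, n_sdr = 2), q),
               "does not cover")
})

test_that("density and BMI components match their closed forms", {
  p <- demo_params()
  expect_equal(density_rr(risk_profile(50, percent_density = 35), p), exp(0.2))
  expect_equal(density_rr(risk_profile(50, percent_density = 25), p), 1.0)
  flat <- p; flat$density$continuous$slope <- 0
  expect_equal(density_rr(risk_profile(50, percent_density = 80), flat), 1.0)

  pc <- demo_params("categorical")
  # c_dens = 0.6*0.8 + 0.4*1.5 = 1.08
  expect_equal(density_rr(risk_profile(50, density_category = 2), pc),
               1.5 / 1.08, tolerance = 1e-12)
  expect_equal(density_rr(risk_profile(50, density_category = 1), pc), 0.8 / 1.08)
  expect_error(density_rr(risk_profile(50), pc), "density_category")
  expect_error(density_rr(risk_profile(50), p), "percent_density")

  expect_equal(bmi_rr(risk_profile(50, bmi = 30, menopausal_status = "post"), p),
               exp(0.15))
  expect_equal(bmi_rr(risk_profile(50, bmi = 30, menopausal_status = "pre"), p),
               exp(-0.10))
  expect_equal(bmi_rr(risk_profile(50, bmi = 25, menopausal_status = "pre"), p), 1.0)
})

test_that("combined relative risk is a commutative product", {
  expect_equal(combined_rr(1.0, 1.0, 1.0, 1.0), 1.0)
  expect_equal(combined_rr(1.2, 1.5, 0.9, 1.1), 1.782, tolerance = 1e-12)
  expect_equal(combined_rr(0.9, 1.1, 1.5, 1.2), combined_rr(1.2, 1.5, 0.9, 1.1))
  expect_equal(combined_rr(list(c(1.2, 2), c(1.5, 0.5))), c(1.8, 1.0))
  expect_error(combined_rr(1.2, 0), "> 0")
  expect_error(combined_rr(1.2, -1), "> 0")
})

test_that("absolute risk matches closed forms and day-step integration", {
  expect_equal(absolute_risk(50, 10, 2, const_hazards(0, 0)), 0)
  expect_equal(absolute_risk(50, 5, 1, const_hazards(0.01, 0)),
               1 - exp(-0.05), tolerance = 1e-12)
  expect_equal(absolute_risk(50, 1, 1, const_hazards(0.01, 1.0)),
               (0.01 / 1.01) * (1 - exp(-1.01)), tolerance = 1e-12)

  set.seed(7)
  for (rep in 1:5) {
    hz <- random_hazards()
    rr <- runif(1, 0.5, 3)
    got <- absolute_risk(45, 4, rr, hz)
    expect_lt(abs(got - euler_absolute_risk(45, 4, rr, hz)), 1e-4)
  }
})

test_that("absolute risk satisfies interval-splitting and survival identities", {
  set.seed(11)
  for (rep in 1:10) {
    hz <- random_hazards()
    rr <- runif(1, 0.5, 3)
    a <- sample(30:60, 1); t1 <- sample(1:10, 1); t2 <- sample(1:10, 1)
    h <- brisk:::.hazard_at(hz, a:(a + t1 - 1))
    S <- exp(-sum(rr * h$h1 + h$h2))
    expect_equal(absolute_risk(a, t1 + t2, rr, hz),
                 absolute_risk(a, t1, rr, hz) + S * absolute_risk(a + t1, t2, rr, hz),
                 tolerance = 1e-12)
  }
  # with no competing mortality and rr = 1 the survival form is exact
  hz <- random_hazards()
  hz$mortality[] <- 0
  h1 <- brisk:::.hazard_at(hz, 40:69)$h1
  expect_equal(absolute_risk(40, 30, 1, hz), 1 - exp(-sum(h1)), tolerance = 1e-12)
})

test_that("risk projections are monotone, bounded, and error out of coverage", {
  hz <- const_hazards(0.01, 0.02, ages = 20:89)
  expect_true(absolute_risk(50, 10, 2, hz) > absolute_risk(50, 10, 1, hz))
  expect_true(absolute_risk(50, 20, 1, hz) > absolute_risk(50, 10, 1, hz))
  expect_lte(absolute_risk(20, 69, 50, hz), 1)
  expect_gt(remaining_lifetime_risk(40, 1, hz), remaining_lifetime_risk(70, 1, hz))
  expect_gt(remaining_lifetime_risk(50, 2, hz), remaining_lifetime_risk(50, 1, hz))
  expect_equal(remaining_lifetime_risk(85, 1, hz, max_age = 85), 0)
  expect_error(remaining_lifetime_risk(86, 1, hz, max_age = 85), "max_age")
  expect_error(absolute_risk(80, 30, 1, hz), "out of range")
  expect_error(absolute_risk(50, -1, 1, hz), "nonnegative")
})

test_that("score_cohort preserves order, is deterministic, and reports bad rows", {
  p <- demo_params()
  hz <- default_hazards()
  empty <- score_cohort(risk_profile(50, percent_density = 20, bmi = 25)[0, ], p, hz)
  expect_equal(nrow(empty), 0)
  expect_true(all(c("combined_rr", "score_brisk5", "score_brisklt") %in% names(empty)))

  ref <- risk_profile(55, n_fdr = 0, n_sdr = 0, percent_density = 25, bmi = 25,
                      menopausal_status = "pre")
  sc <- score_cohort(ref, p, hz)
  expect_equal(sc$combined_rr, 1 / 1.202, tolerance = 1e-12)
  expect_equal(sc$score_brisk5, absolute_risk(55, 5, sc$combined_rr, hz))
  expect_lte(sc$score_brisk5, sc$score_brisklt)

  two <- rbind(ref, ref)
  sc2 <- score_cohort(two, p, hz)
  expect_equal(sc2$score_brisklt[1], sc2$score_brisklt[2])

  bad <- rbind(ref, risk_profile(55, percent_density = 25, bmi = 120,
                                 menopausal_status = "post"))
  expect_error(score_cohort(bad, p, hz), "row 2")
  expect_warning(ok <- score_cohort(bad, p, hz, skip_invalid = TRUE), "dropping")
  expect_equal(nrow(ok), 1)
})
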