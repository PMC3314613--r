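wilson <- frs_coefficients()

reference_woman <- function(age = 70) {
  make_surv_cohort(time = 7.6, event = 0, sex = "female", age = age,
                   total_cholesterol = 180, hdl_cholesterol = 55,
                   sbp = 125, dbp = 70, diabetes = 0, smoking = "never")
}

test_that("risk factors are binned per the NCEP/JNC scheme", {
  co <- make_surv_cohort(time = rep(1, 3), event = rep(0, 3),
                         total_cholesterol = c(205, 160, 300),
                         hdl_cholesterol = c(52, 34.9, 60),
                         sbp = c(124, 118, 161), dbp = c(82, 92, 70),
                         smoking = c("former", "current", "never"))
  cat <- categorize_risk_factors(co)
  expect_equal(as.character(cat$tc_cat), c("200-239", "160-199", ">=280"))
  expect_equal(as.character(cat$hdl_cat), c("50-59", "<35", ">=60"))
  # row 1: both readings imply "normal"; row 2: DBP dominates into stage1;
  # row 3: SBP >= 160 -> stage2_4
  expect_equal(as.character(cat$bp_cat), c("normal", "stage1", "stage2_4"))
  expect_equal(cat$current_smoker, c(0L, 1L, 0L))
  bad <- co
  bad$sbp[1] <- -1
  expect_error(as_cohort(bad), "strictly positive")
})

test_that("baseline survival rescales across horizons under the exponential model", {
  expect_equal(round(horizon_baseline_survival(0.96246, 7.5)$value, 4), 0.9717)
  expect_equal(round(horizon_baseline_survival(0.90015, 7.5)$value, 4), 0.9241)
  s <- runif(1, 0.5, 0.99)
  expect_equal(horizon_baseline_survival(s, 10)$value, s)
  # consistency: S0(t1) = S0(t2)^(t1/t2)
  s1 <- horizon_baseline_survival(0.9, 3)$value
  s2 <- horizon_baseline_survival(0.9, 6)$value
  expect_equal(s1, s2^(3 / 6))
  expect_gt(horizon_baseline_survival(0.96246, 7.5)$value, 0.96246)
  expect_error(horizon_baseline_survival(0.9, 0), "> 0")
  expect_error(baseline_survival(1.2, 10), "in \\(0, 1\\]")
})

test_that("the linear predictor reproduces hand-computed sums", {
  woman <- reference_woman(age = 70)
  expect_equal(linear_predictor(woman, wilson$female),
               0.33766 * 70 - 0.00268 * 70^2)
  diabetic <- woman
  diabetic$diabetes <- 1
  expect_equal(linear_predictor(diabetic, wilson$female) -
                 linear_predictor(woman, wilson$female),
               0.59626)
  # the men's HDL referent is 45-49, so the male reference profile differs
  man <- make_surv_cohort(time = 7.6, event = 0, sex = "male", age = 70,
                          total_cholesterol = 180, hdl_cholesterol = 47,
                          sbp = 125, dbp = 70, diabetes = 0, smoking = "never")
  expect_equal(linear_predictor(man, wilson$male), 0.04826 * 70)
})

test_that("the risk transform has its closed-form values and limits", {
  s0 <- baseline_survival(0.9717, 7.5, "exponential_transform")
  expect_equal(predicted_risk(5, 5, s0), 1 - 0.9717)
  expect_equal(predicted_risk(5 + log(2), 5, s0), 1 - 0.9717^2)
  expect_equal(predicted_risk(-50, 0, s0), 0, tolerance = 1e-12)
  lp <- seq(-3, 3, by = 0.1)
  r <- predicted_risk(lp, 0, s0)
  expect_true(all(diff(r) > 0))
  expect_true(all(r > 0 & r < 1))
})

test_that("frs_score composes categorization, linear predictor and baseline", {
  woman <- reference_woman()
  # a coefficient set whose means equal this exact profile: risk at the
  # mean profile is 1 - S0(7.5)
  cs <- coefficient_set(
    sex = "female", terms = wilson$female$terms,
    means = term_matrix(woman, wilson$female)[1, ],
    baseline = baseline_survival(0.96246, 10, "cox_at_means"),
    provenance = "custom"
  )
  scored <- frs_score(woman, cs, horizon = 7.5)
  expect_equal(scored$.risk, 1 - 0.96246^0.75)
  expect_equal(round(scored$.risk, 4), 0.0283)

  # determinism: identical records get identical risks
  two <- make_surv_cohort(time = c(5, 5), event = c(0, 0), sex = "female")
  s2 <- suppressMessages(frs_score(two))
  expect_equal(s2$.risk[1], s2$.risk[2])

  # same raw factors, different sex-specific equations -> different risks
  pair <- make_surv_cohort(time = c(5, 5), event = c(0, 0),
                           sex = c("female", "male"), age = 72)
  sp <- suppressMessages(frs_score(pair))
  expect_false(sp$.risk[1] == sp$.risk[2])
})

test_that("the women's age-squared term puts the risk peak near age 63", {
  ages <- seq(40, 80, by = 0.01)
  risks <- vapply(ages, function(a) {
    suppressMessages(frs_score(reference_woman(age = a), wilson$female,
                               horizon = 7.5))$.risk
  }, 0)
  expect_equal(ages[which.max(risks)], 0.33766 / (2 * 0.00268), tolerance = 1e-3)
})

test_that("scores increase with the linear predictor on a mixed cohort", {
  co <- generate_cohort(cohort_spec(n = 300), seed = 11)
  scored <- suppressMessages(frs_score(co))
  for (s in c("female", "male")) {
    sub <- scored[scored$sex == s, ]
    expect_equal(order(sub$.lp), order(sub$.risk))
  }
  expect_true(all(scored$.risk > 0 & scored$.risk < 1))
  dia <- scored
  dia$diabetes <- 1
  rescored <- suppressMessages(frs_score(dia))
  expect_true(all(rescored$.risk >= scored$.risk - 1e-12))
})

test_that("scoring the elderly with the original equation flags age extrapolation", {
  co <- generate_cohort(cohort_spec(n = 50), seed = 3)
  expect_message(frs_score(co), class = "frscal_age_extrapolation")
})

test_that("10-year risk classes use the guideline cut points", {
  cls <- frs_risk_class(c(0.049, 0.05, 0.0999, 0.1, 0.1999, 0.2, 0.9))
  expect_equal(as.character(cls),
               c("<5%", "5-9.99%", "5-9.99%", "10-19.99%", "10-19.99%",
                 ">=20%", ">=20%"))
})
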