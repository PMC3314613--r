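diabetes_only <- term_spec("male", indicators = "diabetes")
null_spec <- term_spec("male")

test_that("fit_cox matches brute-force partial-likelihood maximization", {
  co <- make_surv_cohort(time = c(1, 2, 3, 4, 5, 6),
                         event = c(1, 1, 0, 1, 1, 0),
                         diabetes = c(1, 0, 1, 1, 0, 0))
  fit <- fit_cox(co, diabetes_only)
  beta_hat <- coef(fit$fit)[["diabetes"]]
  beta_opt <- stats::optimize(function(b) coxpl_1d(b, co$time, co$event, co$diabetes),
                              c(-8, 8), maximum = TRUE, tol = 1e-10)$maximum
  expect_equal(beta_hat, beta_opt, tolerance = 1e-6)
  expect_equal(fit$loglik[2], coxpl_1d(beta_hat, co$time, co$event, co$diabetes))

  # random micro-instances (distinct times, so the hand likelihood is exact)
  set.seed(99)
  done <- 0
  while (done < 20) {
    inst <- random_surv_instance(sample(4:8, 1))
    co_i <- make_surv_cohort(time = inst$time, event = inst$event,
                             diabetes = inst$x)
    # draws where one diabetes level has no events still have a finite
    # maximum; fit_cox flags them with a warning we deliberately tolerate
    fit_i <- tryCatch(suppressWarnings(fit_cox(co_i, diabetes_only)),
                      error = function(e) NULL)
    if (is.null(fit_i)) next  # degenerate draw (no events / separation)
    opt <- stats::optimize(function(b) coxpl_1d(b, inst$time, inst$event, inst$x),
                           c(-10, 10), maximum = TRUE, tol = 1e-10)
    expect_equal(coef(fit_i$fit)[["diabetes"]], opt$maximum, tolerance = 1e-4)
    done <- done + 1
  }
})

test_that("the null model log partial likelihood is the risk-set sum", {
  co <- make_surv_cohort(time = c(1, 2, 3, 4, 5), event = c(1, 0, 1, 0, 1))
  fit <- fit_cox(co, null_spec)
  expect_equal(fit$loglik[2], -(log(5) + log(3) + log(1)))
})

test_that("degenerate designs raise diagnostic errors", {
  co <- make_surv_cohort(time = 1:6, event = rep(1, 6), diabetes = rep(1, 6))
  expect_error(fit_cox(co, diabetes_only), "Zero-variance.*diabetes")
  none <- make_surv_cohort(time = 1:4, event = rep(0, 4))
  expect_error(fit_cox(none, diabetes_only), "one event")
  # perfect separation: covariate perfectly ordered with event times
  sep <- make_surv_cohort(time = 1:6, event = rep(1, 6),
                          diabetes = c(1, 1, 1, 0, 0, 0))
  expect_error(fit_cox(sep, diabetes_only), "separation")
})

test_that("hazard ratios and their intervals are exp-transformed Wald quantities", {
  co <- generate_cohort(cohort_spec(n = 500), seed = 21)
  men <- co[co$sex == "male", ]
  fit <- fit_cox(men, habc_terms("male"))
  hr <- hazard_ratios(fit)
  expect_equal(hr$hr, exp(hr$estimate))
  expect_equal(hr$hr.low, exp(hr$estimate - 1.96 * hr$std.error))
  expect_equal(hr$hr.high, exp(hr$estimate + 1.96 * hr$std.error))
  expect_true(all(hr$hr.low < hr$hr & hr$hr < hr$hr.high))
  # tidy/glance accounting
  g <- glance(fit)
  expect_equal(g$k, nrow(hr))
  expect_equal(g$aic, -2 * g$loglik + 2 * g$k)
  expect_equal(g$bic, -2 * g$loglik + g$k * log(g$n_events))
})

test_that("baseline survival at the means matches the hand Breslow estimate", {
  # null model: S(t) = exp(-sum d_i/n_i) over event times <= t
  co <- make_surv_cohort(time = c(1, 2, 3, 4, 5), event = c(1, 1, 0, 1, 0))
  fit <- fit_cox(co, null_spec)
  expect_equal(baseline_survival_at_means(fit, 3.5)$value,
               exp(-(1 / 5 + 1 / 4)))
  # no events before t -> 1
  expect_equal(baseline_survival_at_means(fit, 0.5)$value, 1)
  # monotone non-increasing in t, and capped beyond follow-up with a warning
  s_vals <- vapply(c(1, 2, 4, 5), function(t)
    baseline_survival_at_means(fit, t)$value, 0)
  expect_true(all(diff(s_vals) <= 0))
  expect_warning(baseline_survival_at_means(fit, 99), "beyond")
})

test_that("refit risks follow the Cox risk transform", {
  co <- generate_cohort(cohort_spec(n = 2000), seed = 31)
  men <- co[co$sex == "male", ]
  fit <- fit_cox(men, habc_terms("male"))
  scored <- refit_risk(fit, men, horizon = 7.5)
  s0 <- baseline_survival_at_means(fit, 7.5)
  # person at the covariate means (lp = 0) has risk 1 - S0
  expect_equal(predicted_risk(0, 0, s0), 1 - s0$value)
  expect_equal(scored$.risk, 1 - s0$value^exp(scored$.lp))
  # two persons differing only in diabetes: log-cumulative-hazard ratio
  pair <- make_surv_cohort(time = c(5, 5), event = c(0, 0),
                           diabetes = c(0, 1))
  pr <- refit_risk(fit, pair, horizon = 7.5)
  expect_equal(log(log(1 - pr$.risk[2]) / log(1 - pr$.risk[1])),
               coef(fit$fit)[["diabetes"]])
})

test_that("refit coefficient sets round-trip through frs_score and JSON", {
  co <- generate_cohort(cohort_spec(n = 800), seed = 41)
  women <- co[co$sex == "female", ]
  fit <- fit_cox(women, habc_terms("female"))
  cs <- as_coefficient_set(fit, horizon = 7.5)
  expect_equal(cs$provenance, "refit")
  direct <- refit_risk(fit, women, horizon = 7.5)
  via_set <- frs_score(women, cs, horizon = 7.5)
  expect_equal(via_set$.risk, direct$.risk)
  path <- withr::local_tempfile(fileext = ".json")
  write_coefficient_set(cs, path)
  back <- read_coefficient_set(path)
  expect_equal(back$terms, cs$terms)
  expect_equal(frs_score(women, back, horizon = 7.5)$.risk, direct$.risk)
})

test_that("the proportional-hazards diagnostic behaves like a score test", {
  co <- generate_cohort(cohort_spec(n = 700), seed = 51)
  men <- co[co$sex == "male", ]
  fit <- fit_cox(men, diabetes_only)
  res <- tidy(ph_test(fit))
  expect_equal(nrow(res), 2)  # one term + GLOBAL
  expect_equal(res$chisq[res$term == "GLOBAL"],
               res$chisq[res$term == "diabetes"])
  expect_true(all(res$p.value >= 0 & res$p.value <= 1))
  one_event <- make_surv_cohort(time = 1:3, event = c(1, 0, 0),
                                age = c(72, 70, 74))
  age_only <- term_spec("male", continuous = "age")
  expect_error(ph_test(fit_cox(one_event, age_only)), "two events")
})
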