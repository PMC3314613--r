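test_that("harrell_c enumerates usable pairs with the stated conventions", {
  d <- tibble::tibble(time = c(2, 4, 6, 8), event = 1,
                      score = c(0.9, 0.7, 0.8, 0.1))
  expect_equal(harrell_c(d, score = score)$c_index, 5 / 6)
  # perfect ranking and all-ties
  d2 <- tibble::tibble(time = c(1, 3, 5, 9), event = 1, score = -c(1, 3, 5, 9))
  expect_equal(harrell_c(d2, score = score)$c_index, 1)
  d3 <- tibble::tibble(time = c(1, 3, 5), event = c(1, 1, 0), score = 0.4)
  expect_equal(harrell_c(d3, score = score)$c_index, 0.5)
  # an event tied in time with a censoring is usable; two tied events are not
  d4 <- tibble::tibble(time = c(2, 2, 2), event = c(1, 0, 1),
                       score = c(0.8, 0.2, 0.5))
  res <- harrell_c(d4, score = score)
  expect_equal(res$n_pairs, 2)
  expect_equal(res$c_index, 1)
  expect_error(harrell_c(tibble::tibble(time = 1, event = 1, score = 1),
                         score = score), "usable")
})

test_that("harrell_c equals the all-pairs oracle and is rank-invariant", {
  set.seed(7)
  for (rep in 1:30) {
    n <- sample(5:30, 1)
    d <- tibble::tibble(time = sample(1:12, n, replace = TRUE),
                        event = rbinom(n, 1, 0.6),
                        score = sample(seq(0, 1, 0.05), n, replace = TRUE))
    if (sum(d$event) == 0) next
    got <- harrell_c(d, score = score)
    want <- cindex_oracle(d$time, d$event, d$score)
    expect_equal(got$c_index, want$c)
    expect_equal(got$n_pairs, want$n_pairs)
    # strictly increasing transforms leave C unchanged
    expect_equal(harrell_c(d, score = exp(3 * score))$c_index, want$c)
  }
})

test_that("bootstrap optimism correction is seeded and detects overfitting", {
  co <- generate_cohort(cohort_spec(n = 1400), seed = 61)
  men <- co[co$sex == "male", ]
  a <- optimism_corrected_c(men, habc_terms("male"), B = 10, seed = 17)
  b <- optimism_corrected_c(men, habc_terms("male"), B = 10, seed = 17)
  expect_identical(a, b)
  # a null model has constant score everywhere: optimism is exactly zero
  nul <- optimism_corrected_c(men, term_spec("male"), B = 2, seed = 1)
  expect_equal(nul$optimism, 0)
  expect_equal(nul$corrected, nul$apparent)
  # a rich model on a small cohort is optimistic: corrected < apparent
  small <- generate_cohort(cohort_spec(n = 700), seed = 71)
  small_men <- small[small$sex == "male", ]
  oc <- optimism_corrected_c(small_men, habc_terms("male"), B = 40, seed = 5)
  expect_lt(oc$corrected, oc$apparent)
  expect_gt(oc$optimism, 0)
})

test_that("the calibration chi-square is zero for exact agreement", {
  # two risk strata; events before the horizon, censorings after, so the
  # within-group KM complement equals the raw event fraction, which in turn
  # equals the constant predicted risk of the group: O_g = E_g exactly
  d <- tibble::tibble(
    id = as.character(1:20),
    time = c(rep(1, 4), rep(9, 6), rep(1, 6), rep(9, 4)),
    event = c(rep(1L, 4), rep(0L, 6), rep(1L, 6), rep(0L, 4)),
    score = c(rep(0.4, 10), rep(0.6, 10))
  )
  res <- hl_cox(d, score = score, horizon = 5, groups = 2)
  expect_equal(res$statistic, 0)
  expect_equal(res$p.value, 1)
  expect_equal(res$df, 1)
})

test_that("observed counts reduce to raw event counts without censoring", {
  set.seed(19)
  n <- 200
  d <- tibble::tibble(id = as.character(seq_len(n)),
                      time = runif(n, 0, 6), event = 1L,
                      score = runif(n, 0.05, 0.95))
  res <- hl_cox(d, score = score, horizon = 7.5, groups = 10)
  tab <- tidy(res)
  raw <- tapply(d$event[order(d$score, d$id)],
                rep(1:10, each = 20), sum)
  expect_equal(tab$observed, as.numeric(raw))
  expect_equal(sum(tab$n), n)
  expect_equal(res$df, 9)
})

test_that("groups with zero expected events are merged into a neighbor", {
  d <- tibble::tibble(id = as.character(1:30),
                      time = runif(30, 1, 10), event = rbinom(30, 1, 0.5),
                      score = c(rep(0, 10), runif(20, 0.2, 0.8)))
  expect_message(res <- hl_cox(d, score = score, horizon = 5, groups = 3),
                 "Merged")
  expect_lt(res$df, 2)
  expect_equal(sum(tidy(res)$n), 30)
})

test_that("decile ratios scale with the predicted column and handle degeneracies", {
  set.seed(23)
  n <- 300
  d <- tibble::tibble(id = as.character(seq_len(n)),
                      time = rexp(n, 0.15), event = rbinom(n, 1, 0.7),
                      score = runif(n, 0.01, 0.45))
  r1 <- decile_ratio(d, score = score, horizon = 5)
  d$score2 <- 2 * d$score
  r2 <- decile_ratio(d, score = score2, horizon = 5)
  overall1 <- r1$ratio[r1$group == "overall"]
  overall2 <- r2$ratio[r2$group == "overall"]
  expect_equal(overall2, 2 * overall1)
  expect_equal(nrow(r1), 11)
  # single group: overall only
  r3 <- decile_ratio(d, score = score, horizon = 5, groups = 1)
  expect_equal(r3$group, "overall")
  # zero observed risk in a group -> undefined ratio marker
  d0 <- tibble::tibble(id = as.character(1:20), time = rep(10, 20),
                       event = 0L, score = runif(20, 0.1, 0.2))
  r0 <- decile_ratio(d0, score = score, horizon = 5, groups = 2)
  expect_true(all(is.na(r0$ratio)))
})

test_that("compare_c is exact under monotone-equivalent scores and has power", {
  co <- generate_cohort(cohort_spec(n = 250), seed = 81)
  scored <- suppressMessages(frs_score(co))
  scored$same <- scored$.risk
  expect_equal(compare_c(scored, .risk, same, B = 20, seed = 2)$p.value, 1)
  scored$mono <- qlogis(pmin(pmax(scored$.risk, 1e-6), 1 - 1e-6))
  expect_equal(compare_c(scored, .risk, mono, B = 20, seed = 2)$p.value, 1)
  # informative vs pure noise on a decent sample: significant difference
  spec <- cohort_spec(n = 500)
  big <- generate_cohort(spec, seed = 91)
  big$truth <- true_risk(spec, big)
  set.seed(123)
  big$noise <- runif(nrow(big))
  cmp <- compare_c(big, truth, noise, B = 200, seed = 3)
  expect_lt(cmp$p.value, 0.05)
  expect_gt(cmp$difference, 0)
})

test_that("result objects expose tidy, glance and autoplot surfaces", {
  co <- generate_cohort(cohort_spec(n = 300), seed = 101)
  scored <- suppressMessages(frs_score(co, recalibrate_frs(co)))
  hl <- hl_cox(scored)
  expect_s3_class(glance(hl), "tbl_df")
  expect_named(glance(hl), c("statistic", "df", "p.value", "horizon", "groups"))
  expect_s3_class(autoplot(hl), "ggplot")
  dr <- decile_ratio(scored)
  expect_s3_class(autoplot(dr), "ggplot")
  men <- co[co$sex == "male", ]
  fit <- fit_cox(men, habc_terms("male"))
  expect_s3_class(autoplot(fit), "ggplot")
})
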