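# Fixture builders and independent brute-force oracles used across tests.

# minimal valid cohort around supplied follow-up data; risk factors default
# to an unremarkable reference-category profile
make_surv_cohort <- function(time, event, ...,
                             sex = "male", age = 72,
                             total_cholesterol = 180, hdl_cholesterol = 55,
                             sbp = 124, dbp = 70, diabetes = 0,
                             smoking = "never", horizon = 7.5) {
  n <- length(time)
  rep_n <- function(x) if (length(x) == 1) rep(x, n) else x
  tbl <- tibble::tibble(
    id = sprintf("p%03d", seq_len(n)),
    age = rep_n(age), sex = rep_n(sex),
    total_cholesterol = rep_n(total_cholesterol),
    hdl_cholesterol = rep_n(hdl_cholesterol),
    sbp = rep_n(sbp), dbp = rep_n(dbp),
    diabetes = rep_n(diabetes), smoking = rep_n(smoking),
    time = time, event = event, ...
  )
  as_cohort(tbl, horizon = horizon)
}

# product-limit estimate by explicit risk-set enumeration (events precede
# censorings at tied times)
km_oracle <- function(time, event, t) {
  s <- 1
  for (tt in sort(unique(time[event == 1 & time <= t]))) {
    n_risk <- sum(time >= tt)
    d <- sum(time == tt & event == 1)
    s <- s * (1 - d / n_risk)
  }
  s
}

# all-pairs enumeration of Harrell's C with the package's stated pair
# conventions
cindex_oracle <- function(time, event, score) {
  conc <- disc <- tied <- 0
  n <- length(time)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      # orient the pair so a is the candidate earlier subject
      for (ord in list(c(i, j), c(j, i))) {
        a <- ord[1]; b <- ord[2]
        usable <- event[a] == 1 &&
          (time[a] < time[b] || (time[a] == time[b] && event[b] == 0))
        if (usable) {
          if (score[a] > score[b]) conc <- conc + 1
          else if (score[a] < score[b]) disc <- disc + 1
          else tied <- tied + 1
          break
        }
      }
    }
  }
  list(c = (conc + 0.5 * tied) / (conc + disc + tied),
       n_pairs = conc + disc + tied)
}

# hand-written Cox log partial likelihood for a single covariate and
# distinct event times (no ties, so all tie conventions coincide)
coxpl_1d <- function(beta, time, event, x) {
  ll <- 0
  for (i in which(event == 1)) {
    risk <- time >= time[i]
    ll <- ll + beta * x[i] - log(sum(exp(beta * x[risk])))
  }
  ll
}

# draw a small random censored-survival instance with distinct times
random_surv_instance <- function(n, p_event = 0.6) {
  list(time = sample(seq_len(100), n) + runif(n) * 0.5,
       event = rbinom(n, 1, p_event),
       x = rbinom(n, 1, 0.5))
}
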