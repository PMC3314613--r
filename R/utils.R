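# internal helpers shared across modules

# equal-sized grouping of n subjects into `groups` bins after a stable
# ordering; returns integer group labels aligned with the input order
stable_groups <- function(score, id, groups) {
  n <- length(score)
  ord <- order(score, id, method = "radix")
  sizes <- rep(n %/% groups, groups)
  if (n %% groups > 0) sizes[seq_len(n %% groups)] <- sizes[seq_len(n %% groups)] + 1L
  g <- integer(n)
  g[ord] <- rep.int(seq_len(groups), sizes)
  g
}

# Wald chi-square for a set of coefficients of a coxph fit (joint test)
wald_test <- function(fit, idx = seq_along(coef(fit))) {
  b <- coef(fit)[idx]
  V <- vcov(fit)[idx, idx, drop = FALSE]
  stat <- drop(t(b) %*% solve(V) %*% b)
  list(chisq = stat, df = length(idx), p = pchisq(stat, length(idx), lower.tail = FALSE))
}

check_prob <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
    abort(sprintf("`%s` must be a probability in [0, 1].", name))
  }
  invisible(x)
}

# right-continuous Kaplan-Meier survival value at time t
km_value_at <- function(time, event, t) {
  sf <- survival::survfit(survival::Surv(time, event) ~ 1, se.fit = FALSE)
  keep <- sf$time <= t
  if (!any(keep)) return(1)
  sf$surv[max(which(keep))]
}
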