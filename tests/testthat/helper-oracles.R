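# Independent oracles and small fixtures used across the suite.

# Negative Bernoulli log-likelihood, maximized directly with optim as an
# independent check on the IRLS fit.
logistic_loglik <- function(beta, X, y, w = rep(1, length(y))) {
  eta <- drop(X %*% beta)
  sum(w * (y * eta - log1p(exp(eta))))
}

optim_logistic <- function(X, y, w = rep(1, length(y))) {
  stats::optim(rep(0, ncol(X)), function(b) -logistic_loglik(b, X, y, w),
               method = "BFGS", control = list(maxit = 500, reltol = 1e-14))$par
}

# Breslow partial log-likelihood for a single covariate, right-censored,
# unit weights: used for brute-force grid maximization.
cox_pl_1d <- function(beta, time, event, x) {
  dt <- sort(unique(time[event == 1]))
  ll <- 0
  for (t in dt) {
    at <- time >= t
    ev <- event == 1 & time == t
    ll <- ll + sum(beta * x[ev]) - sum(ev) * log(sum(exp(beta * x[at])))
  }
  ll
}

grid_maximize_cox <- function(time, event, x) {
  beta <- seq(-5, 5, by = 0.05)
  width <- 0.05
  repeat {
    ll <- vapply(beta, cox_pl_1d, 0, time = time, event = event, x = x)
    best <- beta[which.max(ll)]
    if (width < 1e-6) return(best)
    width <- width / 10
    beta <- seq(best - 10 * width, best + 10 * width, by = width)
  }
}

# expand integer-weighted data into unit-weight duplicated rows
duplicate_rows <- function(df, weights) {
  df[rep(seq_len(nrow(df)), weights), , drop = FALSE]
}

# minimal valid cohort with hand-set phase columns
manual_cohort <- function(n, started_asct, started_consolidation,
                          pfs_time = NULL, event = NULL, seed = 99) {
  cfg <- sim_config(n_patients = n, seed = seed)
  cohort <- simulate_baseline(cfg)
  cohort$started_asct <- started_asct
  cohort$cr_induction <- ifelse(started_asct == 1, 0L, NA_integer_)
  cohort$started_consolidation <- ifelse(started_asct == 1, started_consolidation, NA_integer_)
  cohort$pfs_time <- if (is.null(pfs_time)) ifelse(started_asct == 1, 10, NA_real_) else pfs_time
  cohort$event <- if (is.null(event)) ifelse(started_asct == 1, 1L, NA_integer_) else event
  cohort
}

# simulate a simple weighted survival sample with confounded group assignment
confounded_survival <- function(n, base_rate = 0.04, group_effect = 0) {
  x <- stats::rbinom(n, 1, 0.5)
  p <- stats::plogis(-0.3 + 1.2 * x)
  g <- stats::rbinom(n, 1, p)
  w <- stabilize_weight(g, p, mean(g))
  t <- stats::rexp(n, base_rate * exp(0.7 * x + group_effect * g))
  cens <- pmin(36, stats::rexp(n, 0.02))
  data.frame(time = pmin(t, cens), event = as.integer(t <= cens),
             weight = w, group = g, x = x)
}
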