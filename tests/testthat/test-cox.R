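test_that("episode splitting builds the early/late dummies as specified", {
  cohort <- manual_cohort(4, rep(1, 4), c(1, 1, 0, 1),
                          pfs_time = c(24, 10, 30, 18), event = c(1L, 1L, 1L, 1L))
  ep <- split_at_changepoint(cohort, rep(1, 4), changepoint = 18)
  # consolidated, T = 24 > changepoint: two episodes
  e1 <- ep[ep$id == cohort$id[1], ]
  expect_equal(nrow(e1), 2)
  expect_equal(e1$start, c(0, 18))
  expect_equal(e1$stop, c(18, 24))
  expect_equal(e1$event, c(0, 1))
  expect_equal(e1$early, c(1, 0))
  expect_equal(e1$late, c(0, 1))
  # consolidated, T = 10 <= changepoint: one early episode, late never set
  e2 <- ep[ep$id == cohort$id[2], ]
  expect_equal(nrow(e2), 1)
  expect_equal(c(e2$early, e2$late, e2$event), c(1, 0, 1))
  # non-consolidated: dummies all zero, no split needed
  e3 <- ep[ep$id == cohort$id[3], ]
  expect_true(all(e3$early == 0 & e3$late == 0))
  # follow-up ending exactly at the changepoint belongs to the early interval
  e4 <- ep[ep$id == cohort$id[4], ]
  expect_equal(nrow(e4), 1)
  expect_equal(c(e4$early, e4$stop), c(1, 18))
  # events are conserved by splitting and weights constant per patient
  expect_equal(sum(ep$event), sum(cohort$event))
  expect_error(split_at_changepoint(cohort, rep(1, 4), changepoint = -1), "positive")
})

test_that("ASCT non-starters are excluded and bad follow-up rejected", {
  cohort <- manual_cohort(3, c(1, 0, 1), c(1, NA, 0))
  ep <- make_episodes(cohort, rep(1, 3))
  expect_equal(nrow(ep), 2)
  bad <- cohort; bad$pfs_time[1] <- 0
  expect_error(make_episodes(bad, rep(1, 3)), "positive")
})

test_that("unit-weight estimates match brute-force partial-likelihood maximization", {
  time <- c(1, 2.5, 3, 4.2, 5, 7)
  event <- c(1, 0, 1, 1, 0, 1)
  x <- c(1, 1, 0, 1, 0, 0)
  ep <- data.frame(id = 1:6, start = 0, stop = time, event = event, x = x, weight = 1)
  fit <- fit_weighted_cox(ep, "x")
  oracle <- grid_maximize_cox(time, event, x)
  expect_equal(unname(coef(fit)), oracle, tolerance = 1e-5)
  skip_if_not_installed("survival")
  ref <- survival::coxph(survival::Surv(time, event) ~ x, ties = "breslow")
  expect_equal(unname(coef(fit)), unname(coef(ref)), tolerance = 1e-6)
})

test_that("weighted fits with start-stop episodes match the reference implementation", {
  skip_if_not_installed("survival")
  cohort <- simulate_trial(sim_config(n_patients = 250, seed = 51))
  w <- runif(nrow(cohort), 0.3, 2.5)
  ep <- split_at_changepoint(cohort, w, 18)
  fit <- fit_weighted_cox(ep, c("early", "late"))
  ref <- survival::coxph(survival::Surv(start, stop, event) ~ early + late,
                         data = ep, weights = weight, ties = "breslow",
                         robust = TRUE, cluster = id)
  expect_equal(coef(fit), coef(ref), tolerance = 1e-6)
  expect_equal(unname(fit$se_naive), unname(sqrt(diag(ref$naive.var))), tolerance = 1e-6)
  expect_equal(unname(fit$se_robust), unname(sqrt(diag(vcov(ref)))), tolerance = 1e-6)
})

test_that("rescaling weights leaves estimates and robust variance unchanged, shrinking naive SEs", {
  cohort <- simulate_trial(sim_config(n_patients = 200, seed = 52))
  w <- runif(nrow(cohort), 0.5, 2)
  ep <- split_at_changepoint(cohort, w, 18)
  fit1 <- fit_weighted_cox(ep, c("early", "late"))
  ep2 <- ep; ep2$weight <- ep$weight * 3.7
  fit2 <- fit_weighted_cox(ep2, c("early", "late"))
  expect_equal(coef(fit1), coef(fit2), tolerance = 1e-7)
  expect_equal(fit1$var_robust, fit2$var_robust, tolerance = 1e-7)
  expect_equal(fit2$se_naive, fit1$se_naive / sqrt(3.7), tolerance = 1e-7)
})

test_that("a covariate independent of the outcome is estimated near zero", {
  set.seed(53)
  n <- 2000
  x <- rbinom(n, 1, 0.5)
  t <- rexp(n, 0.04); c0 <- pmin(54, rexp(n, 0.02))
  ep <- data.frame(id = seq_len(n), start = 0, stop = pmin(t, c0),
                   event = as.integer(t <= c0), x = x, weight = 1)
  fit <- fit_weighted_cox(ep, "x")
  expect_lt(abs(coef(fit)), 3 * fit$se_robust)
  # naive and robust SEs agree asymptotically for a correct unweighted model
  expect_gt(fit$se_robust / fit$se_naive, 0.9)
  expect_lt(fit$se_robust / fit$se_naive, 1.1)
})

test_that("the sandwich aggregates score residuals per patient", {
  # splitting a patient's follow-up must not change the robust variance
  set.seed(54)
  n <- 40
  t <- rexp(n, 0.05) + 0.5; ev <- rbinom(n, 1, 0.8)
  x <- rbinom(n, 1, 0.5); w <- runif(n, 0.5, 2)
  whole <- data.frame(id = seq_len(n), start = 0, stop = t, event = ev, x = x, weight = w)
  cut <- t / 2
  pieces <- rbind(
    data.frame(id = seq_len(n), start = 0, stop = cut, event = 0L, x = x, weight = w),
    data.frame(id = seq_len(n), start = cut, stop = t, event = ev, x = x, weight = w))
  f1 <- fit_weighted_cox(whole, "x")
  f2 <- fit_weighted_cox(pieces, "x")
  expect_equal(coef(f1), coef(f2), tolerance = 1e-8)
  expect_equal(f1$var_robust, f2$var_robust, tolerance = 1e-8)
})

test_that("duplicating patients at half weight keeps the estimate and matches the sandwich oracle", {
  skip_if_not_installed("survival")
  set.seed(55)
  n <- 60
  t <- rexp(n, 0.05) + 0.2; ev <- rbinom(n, 1, 0.7); x <- rbinom(n, 1, 0.5)
  base <- data.frame(id = seq_len(n), start = 0, stop = t, event = ev, x = x, weight = 1)
  dup <- rbind(base, base)
  dup$id <- seq_len(2 * n)  # duplicates treated as distinct patients
  dup$weight <- 0.5
  f0 <- fit_weighted_cox(base, "x")
  f1 <- fit_weighted_cox(dup, "x")
  expect_equal(coef(f0), coef(f1), tolerance = 1e-7)
  ref <- survival::coxph(survival::Surv(stop, event) ~ x, data = dup,
                         weights = weight, ties = "breslow", robust = TRUE,
                         cluster = id)
  expect_equal(unname(f1$se_robust), unname(sqrt(diag(vcov(ref)))), tolerance = 1e-6)
})

test_that("degenerate inputs are refused", {
  ep <- data.frame(id = 1:4, start = 0, stop = 1:4, event = 0L, x = c(0, 1, 0, 1), weight = 1)
  expect_error(fit_weighted_cox(ep, "x"), "no events")
  # monotone likelihood: the covariate perfectly orders the failures
  sep <- data.frame(id = 1:8, start = 0, stop = c(1:4, 11:14),
                    event = c(1L, 1L, 1L, 1L, 0L, 0L, 0L, 0L),
                    x = rep(c(1, 0), each = 4), weight = 1)
  expect_error(fit_weighted_cox(sep, "x"), "diverging|singular")
})

test_that("the proportional-hazards test holds its size under a constant hazard ratio", {
  set.seed(56)
  pv <- replicate(500, {
    n <- 150
    x <- rbinom(n, 1, 0.5)
    t <- rexp(n, 0.03 * exp(0.5 * x))
    c0 <- pmin(54, rexp(n, 0.01))
    ep <- data.frame(id = seq_len(n), start = 0, stop = pmin(t, c0),
                     event = as.integer(t <= c0), x = x, weight = 1)
    schoenfeld_ph_test(fit_weighted_cox(ep, "x"))$table$p_value[2]
  })
  rate <- mean(pv < 0.05)
  expect_gte(rate, 0.03)
  expect_lte(rate, 0.08)
})

test_that("crossing hazards are detected before splitting and absorbed by the split", {
  set.seed(57)
  sim_crossing <- function(n = 1000) {
    g <- rbinom(n, 1, 0.5)
    E <- -log(runif(n))
    h_early <- 0.024 * ifelse(g == 1, 0.4, 1)
    h_late <- 0.024 * ifelse(g == 1, 1.98, 1)
    t <- ifelse(E <= h_early * 18, E / h_early, 18 + (E - h_early * 18) / h_late)
    data.frame(time = pmin(t, 54), event = as.integer(t <= 54), g = g)
  }
  res <- t(replicate(60, {
    d <- sim_crossing()
    ep0 <- data.frame(id = seq_len(nrow(d)), start = 0, stop = d$time,
                      event = d$event, g = d$g, weight = 1)
    p_before <- schoenfeld_ph_test(fit_weighted_cox(ep0, "g"))$table$p_value[2]
    coh <- manual_cohort(nrow(d), rep(1L, nrow(d)), d$g, pfs_time = d$time,
                         event = d$event)
    ep <- split_at_changepoint(coh, rep(1, nrow(d)), 18)
    p_after <- schoenfeld_ph_test(fit_weighted_cox(ep, c("early", "late")))$table$p_value[3]
    c(p_before, p_after)
  }))
  expect_gt(mean(res[, 1] < 0.05), 0.8)     # strong power against crossing hazards
  expect_gt(mean(res[, 2] >= 0.05), 0.8)    # split model satisfies PH
  # too few events for the test
  tiny <- data.frame(id = 1:3, start = 0, stop = 1:3, event = c(1L, 0L, 0L),
                     x = c(0.5, 0, 1), weight = 1)
  expect_error(schoenfeld_ph_test(fit_weighted_cox(tiny, "x")), "2 events")
})
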