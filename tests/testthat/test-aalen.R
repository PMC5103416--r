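test_that("a single event solves the risk-set least squares exactly", {
  # two at risk, intercept + binary covariate, event in the covariate-1 subject
  X <- cbind("(Intercept)" = 1, x = c(0, 1))
  fit <- fit_weighted_aalen(c(2, 1), c(0, 1), X)
  expect_equal(unname(fit$increments[1, ]), c(0, 1))
  expect_equal(unname(fit$B[1, ]), c(0, 1))
  expect_error(fit_weighted_aalen(c(2, 1), c(0, 1), cbind(x = c(0, 1))), "intercept")
})

test_that("unit-weight fits reproduce the reference additive-hazards implementation", {
  skip_if_not_installed("survival")
  set.seed(61)
  n <- 120
  x <- rbinom(n, 1, 0.5)
  t <- rexp(n, 0.05 * (1 + x)); c0 <- rexp(n, 0.03)
  time <- pmin(t, c0); ev <- as.integer(t <= c0)
  X <- cbind("(Intercept)" = 1, x = x)
  fit <- fit_weighted_aalen(time, ev, X)
  ref <- survival::aareg(survival::Surv(time, ev) ~ x, nmin = 1)
  keep <- which(!is.na(fit$increments[, 1]))
  m <- min(length(keep), nrow(ref$coefficient))
  expect_equal(unname(fit$increments[seq_len(m), ]),
               unname(ref$coefficient[seq_len(m), ]), tolerance = 1e-8)
})

test_that("the intercept-only cumulative baseline equals the weighted Nelson-Aalen estimate", {
  set.seed(62)
  n <- 80
  time <- rexp(n, 0.05) + 0.1; ev <- rbinom(n, 1, 0.7); w <- runif(n, 0.2, 3)
  fit <- fit_weighted_aalen(time, ev, matrix(1, n, 1, dimnames = list(NULL, "(Intercept)")), w)
  dt <- sort(unique(time[ev == 1]))
  na_hand <- cumsum(vapply(dt, function(t) {
    sum(w[time == t & ev == 1]) / sum(w[time >= t])
  }, 0))
  expect_equal(unname(fit$B[, 1]), na_hand, tolerance = 1e-10)
})

test_that("integer weights are equivalent to duplicating subjects", {
  set.seed(63)
  n <- 50
  time <- round(rexp(n, 0.05), 1) + 0.1; ev <- rbinom(n, 1, 0.7)
  x <- rbinom(n, 1, 0.5); w <- sample(1:3, n, replace = TRUE)
  X <- cbind("(Intercept)" = 1, x = x)
  f_w <- fit_weighted_aalen(time, ev, X, w)
  idx <- rep(seq_len(n), w)
  f_d <- fit_weighted_aalen(time[idx], ev[idx], X[idx, ], rep(1, length(idx)))
  expect_equal(f_w$B, f_d$B, tolerance = 1e-10)
})

test_that("a constant additive hazard difference appears as a linear cumulative coefficient", {
  set.seed(64)
  n <- 2000
  x <- rep(0:1, each = n / 2)
  t <- rexp(n, ifelse(x == 1, 0.05, 0.02))
  X <- cbind("(Intercept)" = 1, x = x)
  fit <- fit_weighted_aalen(t, rep(1, n), X)
  # slope over [0, 12] should recover the hazard difference 0.03
  i12 <- max(which(fit$times <= 12 & !is.na(fit$B[, 2])))
  slope <- fit$B[i12, 2] / fit$times[i12]
  mc_se <- sqrt(fit$varB[i12, 2]) / fit$times[i12]
  expect_lt(abs(slope - 0.03), 3 * mc_se)
})

test_that("pointwise bands use the normal quantile and bracket the estimate", {
  set.seed(65)
  n <- 100
  time <- rexp(n, 0.05) + 0.1; ev <- rbinom(n, 1, 0.8)
  X <- cbind("(Intercept)" = 1, x = rbinom(n, 1, 0.5))
  fit <- fit_weighted_aalen(time, ev, X)
  bands <- cumulative_bands(fit, 0.95)$x
  keep <- !is.na(bands$estimate) & fit$varB[, 2] > 0
  mult <- (bands$upper[keep] - bands$estimate[keep]) / sqrt(fit$varB[keep, 2])
  expect_equal(mult, rep(qnorm(0.975), sum(keep)), tolerance = 1e-10)
  expect_true(all(bands$lower[keep] <= bands$estimate[keep]))
  expect_error(cumulative_bands(fit, 1.2), "level")
  # zero variance gives a degenerate band
  expect_equal(qnorm(0.975), 1.959964, tolerance = 1e-6)
})

test_that("an early protective effect pushes the upper band below zero in early follow-up", {
  set.seed(66)
  n <- 3000
  g <- rbinom(n, 1, 0.5)
  E <- -log(runif(n))
  h_early <- 0.024 * ifelse(g == 1, 0.4, 1)
  h_late <- 0.024 * ifelse(g == 1, 1.98, 1)
  t <- ifelse(E <= h_early * 18, E / h_early, 18 + (E - h_early * 18) / h_late)
  time <- pmin(t, 54); ev <- as.integer(t <= 54)
  fit <- fit_weighted_aalen(time, ev, cbind("(Intercept)" = 1, g = g))
  bands <- cumulative_bands(fit)$g
  early <- bands$time > 6 & bands$time <= 18 & !is.na(bands$upper)
  expect_true(any(bands$upper[early] < 0))
})

test_that("the suggested changepoint recovers a kink and flags linear trajectories", {
  times <- seq(0.5, 40, by = 0.5)
  kinked <- structure(list(times = times,
                           B = cbind(x = ifelse(times <= 18, -0.02 * times,
                                                -0.02 * 18 + 0 * (times - 18)))),
                      class = "waalen")
  sug <- suggest_changepoint(kinked, "x")
  expect_equal(sug$months, 18)
  expect_false(sug$no_change)
  linear <- structure(list(times = times, B = cbind(x = 0.01 * times)), class = "waalen")
  sug2 <- suggest_changepoint(linear, "x")
  expect_true(sug2$no_change)
  expect_lt(abs(sug2$slopes[1] - sug2$slopes[2]), 1e-6)
  short <- structure(list(times = 1:5, B = cbind(x = 1:5)), class = "waalen")
  expect_error(suggest_changepoint(short, "x"), "few")
})

test_that("the suggested changepoint recovers the truth across simulated cohorts", {
  set.seed(67)
  suggested <- replicate(200, {
    n <- 1000
    g <- rbinom(n, 1, 0.5)
    E <- -log(runif(n))
    h_early <- 0.024 * ifelse(g == 1, 0.4, 1)
    h_late <- 0.024 * ifelse(g == 1, 1.98, 1)
    t <- ifelse(E <= h_early * 18, E / h_early, 18 + (E - h_early * 18) / h_late)
    time <- pmin(t, 54); ev <- as.integer(t <= 54)
    fit <- fit_weighted_aalen(time, ev, cbind("(Intercept)" = 1, g = g))
    suggest_changepoint(fit, "g")$months
  })
  expect_gte(median(suggested), 14)
  expect_lte(median(suggested), 22)
})
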