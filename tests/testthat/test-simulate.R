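test_that("a default cohort has the full column dictionary with no missing baseline", {
  cohort <- simulate_trial(sim_config(n_patients = 414, seed = 1))
  expect_equal(nrow(cohort), 414)
  expect_true(all(c("id", "age", "sex", "iss_stage", "arm", "started_asct",
                    "started_consolidation", "pfs_time", "event") %in% names(cohort)))
  baseline <- c("age", "sex", "haemoglobin_abnormal", "platelets_abnormal",
                "creatinine_abnormal", "ldh_abnormal", "iss_stage", "iga_isotype",
                "del13q", "del17p", "t4_14", "arm")
  expect_false(anyNA(cohort[baseline]))
  expect_true(all(cohort$age >= 18 & cohort$age <= 65))
  # second-phase fields are defined exactly for ASCT starters
  st <- cohort$started_asct == 1
  expect_false(anyNA(cohort$started_consolidation[st]))
  expect_true(all(is.na(cohort$started_consolidation[!st])))
  expect_false(anyNA(cohort$pfs_time[st]))
  expect_true(all(is.na(cohort$pfs_time[!st])))
})

test_that("zero prevalences give all-zero flags and identical configs give identical cohorts", {
  pv <- list(male = 0, haemoglobin_abnormal = 0, platelets_abnormal = 0,
             creatinine_abnormal = 0, ldh_abnormal = 0, iss_stage = c(1, 0, 0),
             iga_isotype = 0, del13q = 0, del17p = 0, t4_14 = 0)
  cohort <- simulate_baseline(sim_config(n_patients = 100, seed = 2,
                                         covariate_prevalences = pv))
  flags <- c("haemoglobin_abnormal", "platelets_abnormal", "creatinine_abnormal",
             "ldh_abnormal", "iga_isotype", "del13q", "del17p", "t4_14")
  expect_true(all(cohort[flags] == 0))
  expect_true(all(cohort$sex == "female"))
  expect_true(all(cohort$iss_stage == 1))
  cfg <- sim_config(n_patients = 250, seed = 77)
  expect_identical(simulate_trial(cfg), simulate_trial(cfg))
})

test_that("invalid configuration fields are rejected by name", {
  expect_error(sim_config(n_patients = 0), "n_patients")
  expect_error(sim_config(baseline_hazard = -1), "baseline_hazard")
  expect_error(sim_config(covariate_prevalences = modifyList(
    sim_config()$covariate_prevalences, list(male = 1.2))), "male")
  expect_error(sim_config(covariate_prevalences = modifyList(
    sim_config()$covariate_prevalences, list(iss_stage = c(0.5, 0.4, 0.4)))),
    "sum to 1")
})

test_that("configured prevalences are recovered at large n", {
  cohort <- simulate_baseline(sim_config(n_patients = 50000, seed = 3))
  pv <- sim_config()$covariate_prevalences
  checks <- list(male = mean(cohort$sex == "male"),
                 del13q = mean(cohort$del13q),
                 ldh_abnormal = mean(cohort$ldh_abnormal))
  for (nm in names(checks)) {
    p <- pv[[nm]]
    tol <- 3 * sqrt(p * (1 - p) / 50000)
    expect_lt(abs(checks[[nm]] - p), tol, label = sprintf("prevalence of %s", nm))
  }
  expect_lt(abs(mean(cohort$iss_stage == 3) - pv$iss_stage[3]),
            3 * sqrt(pv$iss_stage[3] * (1 - pv$iss_stage[3]) / 50000))
})

test_that("a saturated first selection model makes everyone a starter and structure holds", {
  b1 <- default_ps1_coefficients(); b1["(Intercept)"] <- 20
  cohort <- simulate_trial(sim_config(n_patients = 200, seed = 4, ps1_coefficients = b1))
  expect_true(all(cohort$started_asct == 1))
  # structural rule on an ordinary cohort
  cohort2 <- simulate_trial(sim_config(n_patients = 500, seed = 5))
  expect_true(all(is.na(cohort2$started_consolidation[cohort2$started_asct == 0])))
  expect_true(all(cohort2$started_consolidation[cohort2$started_asct == 1] %in% 0:1))
})

test_that("realized selection fraction matches a brute-force Monte-Carlo oracle", {
  cfg <- sim_config(n_patients = 50000, seed = 6)
  cohort <- simulate_trial(cfg)
  realized <- mean(cohort$started_asct)
  # independent oracle: draw the covariate distribution longhand and average
  # the logistic probability written out term by term
  set.seed(1234)
  m <- 50000
  pv <- cfg$covariate_prevalences
  age <- qnorm(runif(m, pnorm(18, 56, 7.21), pnorm(65, 56, 7.21)), 56, 7.21)
  eta <- 0.7531 +
    0.2192 * (age > 50) -
    0.3034 * rbinom(m, 1, pv$male) -
    0.1751 * rbinom(m, 1, pv$haemoglobin_abnormal) -
    0.1085 * rbinom(m, 1, pv$platelets_abnormal) +
    0.0577 * rbinom(m, 1, pv$creatinine_abnormal) +
    0.3097 * rbinom(m, 1, pv$ldh_abnormal) +
    0.2584 * (sample(1:3, m, TRUE, pv$iss_stage) > 1) +
    0.0031 * rbinom(m, 1, pv$iga_isotype) +
    0.0375 * rbinom(m, 1, pv$del13q) -
    0.1485 * rbinom(m, 1, pv$t4_14) -
    0.2640 * rbinom(m, 1, pv$del17p) +
    0.2628 * rbinom(m, 1, 0.5)
  expected <- mean(plogis(eta))
  tol <- 3 * sqrt(2 * expected * (1 - expected) / m)
  expect_lt(abs(realized - expected), tol)
})

test_that("equal early and late multipliers give identical event-time distributions", {
  cfg <- sim_config(n_patients = 20000, seed = 7, early_hr = 1, late_hr = 1,
                    admin_censoring_months = 1e6)
  b1 <- cfg$ps1_coefficients; b1["(Intercept)"] <- 20; cfg$ps1_coefficients <- b1
  cohort <- simulate_trial(cfg)
  t1 <- cohort$pfs_time[cohort$started_consolidation == 1]
  t0 <- cohort$pfs_time[cohort$started_consolidation == 0]
  ks <- suppressWarnings(ks.test(sample(t1, 10000), sample(t0, min(10000, length(t0)))))
  expect_gt(ks$p.value, 0.01)
})

test_that("piecewise-exponential sampling matches the closed-form survival", {
  b <- default_ps1_coefficients(); b["(Intercept)"] <- 20
  b2 <- default_ps2_coefficients(); b2["(Intercept)"] <- 20; b2["age_gt50"] <- 0
  cfg <- sim_config(n_patients = 50000, seed = 8, baseline_hazard = 0.02,
                    early_hr = 0.4, late_hr = 1.98,
                    ps1_coefficients = b, ps2_coefficients = b2,
                    admin_censoring_months = 1e6)
  cohort <- simulate_trial(cfg)
  t <- cohort$pfs_time[cohort$started_consolidation == 1]
  n <- length(t)
  expect_gt(n, 45000)  # near-saturated selection
  for (tt in c(6, 18, 36)) {
    H <- 0.02 * (0.4 * min(tt, 18) + 1.98 * max(tt - 18, 0))
    S <- exp(-H)
    expect_lt(abs(mean(t > tt) - S), 3 * sqrt(S * (1 - S) / n),
              label = sprintf("S(%d)", tt))
  }
  expect_equal(exp(-0.4 * 0.02 * 18), 0.8659, tolerance = 1e-4)
})

test_that("administrative censoring caps follow-up with event = 0 at the horizon", {
  cohort <- simulate_trial(sim_config(n_patients = 2000, seed = 9))
  st <- cohort$started_asct == 1
  expect_true(all(cohort$pfs_time[st] <= 54))
  at_cap <- st & cohort$pfs_time == 54
  expect_true(any(at_cap))
  expect_true(all(cohort$event[at_cap] == 0))
})
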