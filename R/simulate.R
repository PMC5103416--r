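#' Configuration for the synthetic multiphase-trial generator
#'
#' Bundles every knob of the generator: cohort size, baseline covariate
#' marginals, the 1:1 arm allocation, the two sequential logistic selection
#' processes (first transplantation, then consolidation among transplanted
#' patients), and a piecewise-constant hazard in which consolidation
#' multiplies the baseline hazard by `early_hr` up to `changepoint_months`
#' and by `late_hr` afterwards.
#'
#' Default covariate prevalences and the default selection coefficients are
#' the published baseline table and propensity-model estimates of a phase III
#' newly-diagnosed multiple myeloma trial, so that the simulated selection
#' strength and case mix match a realistic study of 414 complete-case
#' patients. `early_hr = 0.40` and `late_hr = 1.98` reproduce an early
#' benefit of consolidation that disappears (indeed reverses) after 18
#' months, the scenario the time-split analysis is designed to detect.
#'
#' @param n_patients number of patients (rows) to generate.
#' @param seed optional integer seed; when non-`NULL`, [simulate_trial()] and
#'   [simulate_baseline()] seed the RNG before drawing.
#' @param age_mean,age_sd mean and SD (years) of the age distribution, a
#'   normal truncated to the trial eligibility window 18-65 years.
#' @param covariate_prevalences named list of marginal probabilities for the
#'   binary baseline factors (`male`, `haemoglobin_abnormal`,
#'   `platelets_abnormal`, `creatinine_abnormal`, `ldh_abnormal`,
#'   `iga_isotype`, `del13q`, `del17p`, `t4_14`) and a length-3 probability
#'   vector `iss_stage` over stages 1-3.
#' @param arm_a_probability probability of allocation to arm A (1:1 default).
#' @param cr_probability probability of complete response at induction among
#'   patients who start the first transplant.
#' @param ps1_coefficients named log-odds coefficients (intercept first) of
#'   the first selection process (starting at least one autologous stem cell
#'   transplant, ASCT); names must match [covariate_spec()] terms.
#' @param ps2_coefficients same for the second process (starting
#'   consolidation among ASCT starters), including a `cr_induction` term.
#' @param baseline_hazard events per month for a non-consolidated patient.
#' @param early_hr hazard multiplier of consolidation on (0, changepoint].
#' @param late_hr hazard multiplier of consolidation after the changepoint.
#' @param changepoint_months changepoint of the treatment effect (months).
#' @param admin_censoring_months administrative censoring time (months).
#' @param random_censoring_rate rate (events/month) of an independent
#'   exponential censoring process; 0 disables it.
#' @return an object of class `sim_config` (a validated named list).
#' @seealso [simulate_trial()], [read_sim_config()]
#' @export
sim_config <- function(n_patients = 414,
                       seed = NULL,
                       age_mean = 56.0,
                       age_sd = 7.21,
                       covariate_prevalences = list(
                         male = 0.57,
                         haemoglobin_abnormal = 0.3937,
                         platelets_abnormal = 0.1087,
                         creatinine_abnormal = 0.2126,
                         ldh_abnormal = 0.8575,
                         iss_stage = c(0.4348, 0.3913, 0.1739),
                         iga_isotype = 0.1957,
                         del13q = 0.4831,
                         del17p = 0.07,
                         t4_14 = 0.2005),
                       arm_a_probability = 0.5,
                       cr_probability = 0.30,
                       ps1_coefficients = default_ps1_coefficients(),
                       ps2_coefficients = default_ps2_coefficients(),
                       baseline_hazard = 0.024,
                       early_hr = 0.40,
                       late_hr = 1.98,
                       changepoint_months = 18,
                       admin_censoring_months = 54,
                       random_censoring_rate = 0) {
  cfg <- list(n_patients = n_patients, seed = seed,
              age_mean = age_mean, age_sd = age_sd,
              covariate_prevalences = covariate_prevalences,
              arm_a_probability = arm_a_probability,
              cr_probability = cr_probability,
              ps1_coefficients = ps1_coefficients,
              ps2_coefficients = ps2_coefficients,
              baseline_hazard = baseline_hazard,
              early_hr = early_hr, late_hr = late_hr,
              changepoint_months = changepoint_months,
              admin_censoring_months = admin_censoring_months,
              random_censoring_rate = random_censoring_rate)
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

#' Default selection coefficients of the first phase (starting ASCT)
#'
#' Published propensity-model point estimates (log-odds) of starting at
#' least one transplant, used as the generator's true selection process.
#' @return named numeric vector, intercept first.
#' @export
default_ps1_coefficients <- function() {
  c("(Intercept)" = 0.7531,
    age_gt50 = 0.2192, male_sex = -0.3034, hb_low = -0.1751,
    plt_low = -0.1085, crea_high = 0.0577, ldh_high = 0.3097,
    iss_gt1 = 0.2584, iga_isotype = 0.0031, del13q = 0.0375,
    t4_14 = -0.1485, del17p = -0.2640, arm_a = 0.2628)
}

#' Default selection coefficients of the second phase (starting consolidation)
#'
#' Published propensity-model point estimates (log-odds) of starting the
#' consolidation phase among transplanted patients, including the
#' induction-response term.
#' @return named numeric vector, intercept first.
#' @export
default_ps2_coefficients <- function() {
  c("(Intercept)" = 1.3012,
    age_gt50 = -1.1036, male_sex = 0.1046, hb_low = 0.0556,
    plt_low = 0.3935, crea_high = 0.0155, ldh_high = 0.3123,
    iss_gt1 = 0.1231, iga_isotype = -0.1299, del13q = -0.0420,
    t4_14 = 0.3715, del17p = 0.4939, arm_a = 0.0036,
    cr_induction = 0.1073)
}

validate_sim_config <- function(cfg) {
  if (!is.numeric(cfg$n_patients) || length(cfg$n_patients) != 1 ||
      cfg$n_patients < 1 || cfg$n_patients != round(cfg$n_patients)) {
    stop_field("n_patients", "must be a positive integer")
  }
  if (!is.numeric(cfg$age_sd) || cfg$age_sd <= 0) stop_field("age_sd", "must be > 0")
  pv <- cfg$covariate_prevalences
  needed <- c("male", "haemoglobin_abnormal", "platelets_abnormal",
              "creatinine_abnormal", "ldh_abnormal", "iss_stage",
              "iga_isotype", "del13q", "del17p", "t4_14")
  missing <- setdiff(needed, names(pv))
  if (length(missing)) {
    stop_field("covariate_prevalences", paste("missing entries:", paste(missing, collapse = ", ")))
  }
  for (nm in setdiff(needed, "iss_stage")) check_probability(pv[[nm]], nm)
  iss <- pv$iss_stage
  if (length(iss) != 3 || any(iss < 0)) stop_field("iss_stage", "must be 3 non-negative probabilities")
  if (abs(sum(iss) - 1) > 1e-8) stop_field("iss_stage", "distribution must sum to 1")
  check_probability(cfg$arm_a_probability, "arm_a_probability")
  check_probability(cfg$cr_probability, "cr_probability")
  for (nm in c("baseline_hazard", "early_hr", "late_hr", "changepoint_months")) {
    if (!is.numeric(cfg[[nm]]) || length(cfg[[nm]]) != 1 || cfg[[nm]] <= 0) {
      stop_field(nm, "must be a positive number")
    }
  }
  if (cfg$admin_censoring_months <= 0) stop_field("admin_censoring_months", "must be > 0")
  if (cfg$random_censoring_rate < 0) stop_field("random_censoring_rate", "must be >= 0")
  invisible(cfg)
}

# inverse-CDF draw from N(mean, sd) truncated to [lo, hi]
rtruncnorm_icdf <- function(n, mean, sd, lo, hi) {
  plo <- stats::pnorm(lo, mean, sd)
  phi <- stats::pnorm(hi, mean, sd)
  stats::qnorm(stats::runif(n, plo, phi), mean, sd)
}

#' Generate baseline covariates and arm allocation
#'
#' Draws `n_patients` rows with covariates sampled independently from the
#' configured marginals (the joint correlation structure of a real trial is
#' not modelled), age from a normal truncated to the 18-65 year eligibility
#' window, and the randomized arm as Bernoulli(`arm_a_probability`).
#'
#' @param config a [sim_config()].
#' @return a `data.frame` cohort table (baseline columns only).
#' @export
simulate_baseline <- function(config) {
  validate_sim_config(config)
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- config$n_patients
  pv <- config$covariate_prevalences
  cohort <- data.frame(
    id = sprintf("pt%05d", seq_len(n)),
    age = rtruncnorm_icdf(n, config$age_mean, config$age_sd, 18, 65),
    sex = ifelse(stats::rbinom(n, 1, pv$male) == 1, "male", "female"),
    haemoglobin_abnormal = stats::rbinom(n, 1, pv$haemoglobin_abnormal),
    platelets_abnormal = stats::rbinom(n, 1, pv$platelets_abnormal),
    creatinine_abnormal = stats::rbinom(n, 1, pv$creatinine_abnormal),
    ldh_abnormal = stats::rbinom(n, 1, pv$ldh_abnormal),
    iss_stage = sample(1:3, n, replace = TRUE, prob = pv$iss_stage),
    iga_isotype = stats::rbinom(n, 1, pv$iga_isotype),
    del13q = stats::rbinom(n, 1, pv$del13q),
    del17p = stats::rbinom(n, 1, pv$del17p),
    t4_14 = stats::rbinom(n, 1, pv$t4_14),
    arm = ifelse(stats::rbinom(n, 1, config$arm_a_probability) == 1, "A", "B"),
    stringsAsFactors = FALSE)
  cohort
}

#' Simulate the two sequential selection processes
#'
#' Adds phase-compliance columns to a baseline cohort: `started_asct` is
#' Bernoulli on the logistic scale of `ps1_coefficients` applied to the
#' dichotomized design of [covariate_spec()]; for ASCT starters only,
#' `cr_induction` is Bernoulli(`cr_probability`) and `started_consolidation`
#' is Bernoulli on the logistic scale of `ps2_coefficients` (which includes
#' the induction-response term). Both second-phase columns are `NA` for
#' patients who never started a transplant: consolidation is structurally
#' undefined for them.
#'
#' @param cohort baseline cohort from [simulate_baseline()].
#' @param config a [sim_config()].
#' @return the cohort with `cr_induction`, `started_asct`,
#'   `started_consolidation` columns added.
#' @export
simulate_selection <- function(cohort, config) {
  validate_sim_config(config)
  n <- nrow(cohort)
  X1 <- build_design(cohort, covariate_spec(include_cr = FALSE))
  b1 <- config$ps1_coefficients
  if (length(b1) != ncol(X1)) {
    stop(sprintf("ps1_coefficients has length %d but the design has %d columns",
                 length(b1), ncol(X1)), call. = FALSE)
  }
  p1 <- expit(drop(X1 %*% b1))
  cohort$started_asct <- stats::rbinom(n, 1, p1)
  started <- cohort$started_asct == 1
  cohort$cr_induction <- NA_integer_
  cohort$cr_induction[started] <- stats::rbinom(sum(started), 1, config$cr_probability)
  cohort$started_consolidation <- NA_integer_
  if (any(started)) {
    X2 <- build_design(cohort[started, , drop = FALSE], covariate_spec(include_cr = TRUE))
    b2 <- config$ps2_coefficients
    if (length(b2) != ncol(X2)) {
      stop(sprintf("ps2_coefficients has length %d but the design has %d columns",
                   length(b2), ncol(X2)), call. = FALSE)
    }
    p2 <- expit(drop(X2 %*% b2))
    cohort$started_consolidation[started] <- stats::rbinom(sum(started), 1, p2)
  }
  cohort
}

#' Simulate progression-free survival outcomes
#'
#' For ASCT starters, draws an event time from a piecewise-exponential
#' distribution by inverse-CDF sampling: the hazard is `baseline_hazard`,
#' multiplied by `early_hr` on (0, changepoint] and by `late_hr` afterwards
#' for consolidated patients. Follow-up is censored at the administrative
#' horizon and, optionally, by an independent exponential censoring process.
#' `pfs_time` and `event` stay `NA` for patients who never started a
#' transplant (their time origin, the last transplant evaluation, does not
#' exist).
#'
#' @param cohort cohort with selection columns from [simulate_selection()].
#' @param config a [sim_config()].
#' @return the cohort with `pfs_time` (months) and `event` columns added.
#' @export
simulate_outcomes <- function(cohort, config) {
  validate_sim_config(config)
  if (is.null(cohort$started_asct)) {
    stop("cohort has no 'started_asct' column; run simulate_selection() first", call. = FALSE)
  }
  n <- nrow(cohort)
  cohort$pfs_time <- NA_real_
  cohort$event <- NA_integer_
  started <- which(cohort$started_asct == 1)
  if (!length(started)) return(cohort)
  h0 <- config$baseline_hazard
  cp <- config$changepoint_months
  consol <- cohort$started_consolidation[started] == 1
  # cumulative-hazard inversion: E ~ Exp(1), solve H(t) = E
  E <- -log(stats::runif(length(started)))
  t_event <- E / h0  # non-consolidated: constant hazard
  he <- h0 * config$early_hr
  hl <- h0 * config$late_hr
  t_c <- ifelse(E <= he * cp, E / he, cp + (E - he * cp) / hl)
  t_event[consol] <- t_c[consol]
  t_cens <- rep(config$admin_censoring_months, length(started))
  if (config$random_censoring_rate > 0) {
    t_cens <- pmin(t_cens, stats::rexp(length(started), config$random_censoring_rate))
  }
  cohort$pfs_time[started] <- pmin(t_event, t_cens)
  cohort$event[started] <- as.integer(t_event <= t_cens)
  cohort
}

#' Simulate a complete synthetic multiphase-trial cohort
#'
#' Runs [simulate_baseline()], [simulate_selection()] and
#' [simulate_outcomes()] in sequence, seeding the RNG once from
#' `config$seed` so the full cohort is reproducible bit for bit.
#'
#' @param config a [sim_config()].
#' @return a complete cohort `data.frame` with the generating `config`
#'   attached as an attribute.
#' @examples
#' cohort <- simulate_trial(sim_config(n_patients = 200, seed = 7))
#' table(cohort$started_asct, useNA = "ifany")
#' @export
simulate_trial <- function(config = sim_config()) {
  validate_sim_config(config)
  if (!is.null(config$seed)) set.seed(config$seed)
  cfg_noseed <- config
  cfg_noseed$seed <- NULL  # stages draw from the already-seeded stream
  cohort <- simulate_baseline(cfg_noseed)
  cohort <- simulate_selection(cohort, cfg_noseed)
  cohort <- simulate_outcomes(cohort, cfg_noseed)
  attr(cohort, "config") <- config
  cohort
}

#' Read a generator configuration from a YAML key-value file
#'
#' Keys mirror the arguments of [sim_config()]; unknown keys are an error.
#'
#' @param path file path.
#' @return a validated `sim_config`.
#' @export
read_sim_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(sim_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) {
    stop(sprintf("unknown configuration keys: %s", paste(unknown, collapse = ", ")), call. = FALSE)
  }
  if (!is.null(vals$ps1_coefficients)) vals$ps1_coefficients <- unlist(vals$ps1_coefficients)
  if (!is.null(vals$ps2_coefficients)) vals$ps2_coefficients <- unlist(vals$ps2_coefficients)
  if (!is.null(vals$covariate_prevalences$iss_stage)) {
    vals$covariate_prevalences$iss_stage <- unlist(vals$covariate_prevalences$iss_stage)
  }
  do.call(sim_config, vals)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic multiphase-trial configuration\n")
  cat(sprintf("  n_patients: %d   seed: %s\n", x$n_patients,
              if (is.null(x$seed)) "none" else format(x$seed)))
  cat(sprintf("  baseline hazard %.4g/month; consolidation HR %.3g (<= %g mo), %.3g (> %g mo)\n",
              x$baseline_hazard, x$early_hr, x$changepoint_months,
              x$late_hr, x$changepoint_months))
  cat(sprintf("  administrative censoring at %g months; random censoring rate %.3g\n",
              x$admin_censoring_months, x$random_censoring_rate))
  invisible(x)
}
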