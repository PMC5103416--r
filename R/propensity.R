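#' Covariate dichotomization scheme of the propensity models
#'
#' The selection models enter every baseline factor as a 0/1 indicator:
#' age > 50 years (strict), male sex, abnormal haemoglobin (<= 10.5 g/dL),
#' abnormal platelets (<= 150 x 10^9/L), abnormal creatinine (> 1.2),
#' abnormal LDH (> 190 U/L), ISS stage > 1, IgA isotype, del(13q), t(4;14),
#' del(17p) and arm A; the second-phase model adds complete response at
#' induction. Laboratory cutoffs are applied upstream when the cohort is
#' built, so those rules read the stored abnormality flags.
#'
#' @param include_cr add the `cr_induction` term (second selection model).
#' @return an object of class `covariate_spec`: an ordered list of terms,
#'   each with a `name`, a human-readable `label`, the `source` column and a
#'   rule mapping a cohort row to 0/1.
#' @export
covariate_spec <- function(include_cr = FALSE) {
  term <- function(name, label, source, fn) list(name = name, label = label, source = source, fn = fn)
  terms <- list(
    term("age_gt50", "Age > 50 years", "age", function(d) as.integer(d$age > 50)),
    term("male_sex", "Male sex", "sex", function(d) as.integer(d$sex == "male")),
    term("hb_low", "HB <= 10.5 g/dL", "haemoglobin_abnormal",
         function(d) as.integer(d$haemoglobin_abnormal == 1)),
    term("plt_low", "Plts <= 150 x10^9/L", "platelets_abnormal",
         function(d) as.integer(d$platelets_abnormal == 1)),
    term("crea_high", "Crea > 1.2", "creatinine_abnormal",
         function(d) as.integer(d$creatinine_abnormal == 1)),
    term("ldh_high", "LDH > 190 U/L", "ldh_abnormal",
         function(d) as.integer(d$ldh_abnormal == 1)),
    term("iss_gt1", "ISS > 1", "iss_stage", function(d) as.integer(d$iss_stage > 1)),
    term("iga_isotype", "IgA isotype", "iga_isotype",
         function(d) as.integer(d$iga_isotype == 1)),
    term("del13q", "Del(13q)", "del13q", function(d) as.integer(d$del13q == 1)),
    term("t4_14", "t(4;14)", "t4_14", function(d) as.integer(d$t4_14 == 1)),
    term("del17p", "Del(17p)", "del17p", function(d) as.integer(d$del17p == 1)),
    term("arm_a", "Arm A", "arm", function(d) as.integer(d$arm == "A")))
  if (include_cr) {
    terms <- c(terms, list(term("cr_induction", "CR at induction", "cr_induction",
                                function(d) as.integer(d$cr_induction == 1))))
  }
  structure(list(terms = terms), class = "covariate_spec")
}

#' Build the 0/1 design matrix of a propensity model
#'
#' @param cohort a cohort `data.frame`.
#' @param spec a [covariate_spec()].
#' @return numeric matrix with an intercept column of ones followed by one
#'   0/1 column per term, rows aligned to `cohort`.
#' @export
build_design <- function(cohort, spec = covariate_spec()) {
  stopifnot(inherits(spec, "covariate_spec"))
  for (tm in spec$terms) {
    if (!tm$source %in% names(cohort)) {
      stop(sprintf("cohort is missing source field '%s' needed by term '%s'",
                   tm$source, tm$name), call. = FALSE)
    }
  }
  if (nrow(cohort) == 0) {
    X <- matrix(numeric(0), 0, length(spec$terms) + 1)
  } else {
    cols <- lapply(spec$terms, function(tm) tm$fn(cohort))
    X <- cbind(1, do.call(cbind, lapply(cols, as.numeric)))
  }
  colnames(X) <- c("(Intercept)", vapply(spec$terms, `[[`, "", "name"))
  if (anyNA(X)) stop("design matrix contains missing values; the analysis set must be complete cases", call. = FALSE)
  X
}

#' Fit a logistic selection (propensity) model by maximum likelihood
#'
#' Maximum-likelihood logistic regression of a binary selection indicator on
#' a 0/1 design, via iteratively reweighted least squares (IRLS; the
#' `stats::glm.fit` engine with convergence tolerance 1e-8 and at most 25
#' iterations). Standard errors come from the inverse observed information
#' and 95% confidence intervals are Wald, estimate +/- 1.959964 SE.
#' Complete or quasi-complete separation (non-convergence, a non-finite
#' information matrix, or any |coefficient| > 15) is an error rather than a
#' silently absurd fit.
#'
#' @param design design matrix from [build_design()] (intercept included).
#' @param outcome 0/1 vector, same length as `nrow(design)`.
#' @param case_weights optional positive case weights.
#' @return an object of class `ps_fit` with coefficient table, fitted
#'   probabilities, log-likelihood and convergence diagnostics.
#' @export
fit_logistic <- function(design, outcome, case_weights = NULL) {
  if (!is.matrix(design)) design <- as.matrix(design)
  n <- nrow(design)
  if (length(outcome) != n) stop("outcome length does not match the design", call. = FALSE)
  if (!is_binary01(outcome) || anyNA(outcome)) stop("outcome must be 0/1 with no missing values", call. = FALSE)
  if (all(outcome == 1) || all(outcome == 0)) {
    stop("degenerate outcome: no variation (all 0 or all 1); the selection model cannot be fitted", call. = FALSE)
  }
  if (is.null(case_weights)) case_weights <- rep(1, n)
  if (any(case_weights <= 0)) stop("case_weights must be positive", call. = FALSE)
  if (qr(design)$rank < ncol(design)) {
    stop("design matrix is rank deficient; remove collinear covariates", call. = FALSE)
  }
  fit <- withCallingHandlers(
    stats::glm.fit(design, outcome, weights = case_weights,
                   family = stats::binomial(),
                   control = stats::glm.control(epsilon = 1e-8, maxit = 25)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1|algorithm did not converge",
                conditionMessage(w))) invokeRestart("muffleWarning")
    })
  beta <- fit$coefficients
  mu <- fit$fitted.values
  info <- crossprod(design, design * (case_weights * mu * (1 - mu)))
  finite_info <- all(is.finite(info))
  if (!fit$converged || anyNA(beta) || any(abs(beta) > 15) || !finite_info) {
    stop(paste("logistic fit failed: complete or quasi-complete separation suspected;",
               "consider removing the offending covariate"), call. = FALSE)
  }
  vcov <- solve(info)
  se <- sqrt(diag(vcov))
  z <- beta / se
  p <- 2 * stats::pnorm(-abs(z))
  zcrit <- stats::qnorm(0.975)
  out <- list(
    terms = colnames(design),
    coefficients = beta,
    se = se,
    z = z,
    p_value = p,
    conf_low = beta - zcrit * se,
    conf_high = beta + zcrit * se,
    vcov = vcov,
    loglik = -fit$deviance / 2,
    n = n,
    converged = fit$converged,
    iter = fit$iter,
    fitted = mu)
  class(out) <- "ps_fit"
  out
}

#' @export
coef.ps_fit <- function(object, ...) object$coefficients

#' @export
vcov.ps_fit <- function(object, ...) object$vcov

#' @export
confint.ps_fit <- function(object, parm, level = 0.95, ...) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  ci <- cbind(object$coefficients - z * object$se, object$coefficients + z * object$se)
  rownames(ci) <- object$terms
  colnames(ci) <- sprintf("%.1f %%", c((1 - level) / 2, 1 - (1 - level) / 2) * 100)
  if (!missing(parm)) ci <- ci[parm, , drop = FALSE]
  ci
}

#' Coefficient table of a fitted propensity model
#'
#' @param object a `ps_fit`.
#' @param ... unused.
#' @return a `data.frame` with columns `coeff`, `se`, `p_value`, `ci_low`,
#'   `ci_high` (one row per term, intercept last, mirroring the usual
#'   published layout of selection-model tables).
#' @export
summary.ps_fit <- function(object, ...) {
  tab <- data.frame(term = object$terms, coeff = object$coefficients,
                    se = object$se, p_value = object$p_value,
                    ci_low = object$conf_low, ci_high = object$conf_high,
                    row.names = NULL)
  ord <- c(setdiff(seq_len(nrow(tab)), 1), 1)  # constant printed last
  structure(tab[ord, ], class = c("summary.ps_fit", "data.frame"),
            loglik = object$loglik, n = object$n)
}

#' @export
print.ps_fit <- function(x, digits = 4, ...) {
  cat(sprintf("Logistic propensity model (%d obs, logLik %.3f, %d IRLS iterations)\n",
              x$n, x$loglik, x$iter))
  tab <- summary(x)
  tab[-1] <- lapply(tab[-1], round, digits)
  print.data.frame(tab, row.names = FALSE)
  invisible(x)
}

#' @export
print.summary.ps_fit <- function(x, ...) {
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

#' Predicted selection probabilities
#'
#' Evaluates expit(design %*% coefficients). Probabilities are clamped to
#' [1e-6, 1 - 1e-6] so that downstream inverse weights stay finite; the
#' number of clamped values is reported in the `n_clamped` attribute (a
#' fitted probability of exactly 1 would otherwise give an untreated patient
#' an infinite weight).
#'
#' @param object a `ps_fit`.
#' @param design design matrix whose columns match the fit's terms; defaults
#'   to returning the fitted probabilities.
#' @param clamp clamp into the open unit interval (default `TRUE`).
#' @param ... unused.
#' @return probability vector strictly inside (0, 1), with attribute
#'   `n_clamped`.
#' @export
predict.ps_fit <- function(object, design = NULL, clamp = TRUE, ...) {
  if (is.null(design)) {
    p <- object$fitted
  } else {
    if (!is.matrix(design)) design <- as.matrix(design)
    if (ncol(design) != length(object$coefficients) ||
        !identical(colnames(design), object$terms)) {
      stop("design columns do not match the fitted model terms", call. = FALSE)
    }
    p <- expit(drop(design %*% object$coefficients))
  }
  if (clamp) clamp_probability(p) else p
}

#' Covariate balance before and after weighting
#'
#' Standardized mean differences of every dichotomized term between the two
#' treatment groups: SMD = (m1 - m0) / sqrt((v1 + v0) / 2) with (optionally
#' weighted) group means and variances. A term constant in both groups has
#' SMD 0 by convention.
#'
#' @param cohort cohort `data.frame`.
#' @param treatment 0/1 vector aligned to `cohort` rows.
#' @param weights optional positive weights.
#' @param spec a [covariate_spec()].
#' @return `data.frame` with per-term group means and the SMD.
#' @export
standardized_differences <- function(cohort, treatment, weights = NULL,
                                     spec = covariate_spec()) {
  X <- build_design(cohort, spec)[, -1, drop = FALSE]
  if (length(treatment) != nrow(X)) stop("treatment length does not match the cohort", call. = FALSE)
  if (is.null(weights)) weights <- rep(1, nrow(X))
  if (any(weights <= 0)) stop("weights must be positive", call. = FALSE)
  if (!any(treatment == 1) || !any(treatment == 0)) {
    stop("both treatment groups must be non-empty", call. = FALSE)
  }
  wmean <- function(x, w) sum(w * x) / sum(w)
  wvar <- function(x, w) {
    m <- wmean(x, w)
    sum(w * (x - m)^2) / sum(w)
  }
  res <- t(apply(X, 2, function(x) {
    m1 <- wmean(x[treatment == 1], weights[treatment == 1])
    m0 <- wmean(x[treatment == 0], weights[treatment == 0])
    v1 <- wvar(x[treatment == 1], weights[treatment == 1])
    v0 <- wvar(x[treatment == 0], weights[treatment == 0])
    pooled <- sqrt((v1 + v0) / 2)
    smd <- if (pooled == 0) 0 else (m1 - m0) / pooled
    c(mean_treated = m1, mean_untreated = m0, smd = smd)
  }))
  data.frame(term = rownames(res), res, row.names = NULL)
}

#' Export a coefficient table as delimited text
#'
#' @param fit a `ps_fit`.
#' @param path output file path (tab-separated, header row).
#' @return `path`, invisibly.
#' @export
write_coefficient_table <- function(fit, path) {
  utils::write.table(summary(fit), path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
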