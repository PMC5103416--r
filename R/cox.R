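#' Build an unsplit episode table from a cohort
#'
#' One (0, pfs_time] episode per ASCT starter with a single `consolidation`
#' dummy. Patients who never started a transplant are excluded: their time
#' origin (last transplant evaluation) does not exist.
#'
#' @param cohort cohort `data.frame` with outcome columns.
#' @param weights per-patient weights aligned to the cohort rows (e.g. the
#'   total stabilized weight).
#' @return an `episode_table` data.frame: `id`, `start`, `stop`, `event`,
#'   `consolidation`, `weight`.
#' @export
make_episodes <- function(cohort, weights) {
  if (length(weights) != nrow(cohort)) stop("weights must align with the cohort", call. = FALSE)
  keep <- which(cohort$started_asct == 1)
  if (!length(keep)) stop("no ASCT starters in the cohort", call. = FALSE)
  t <- cohort$pfs_time[keep]
  if (any(!is.finite(t) | t <= 0)) stop("follow-up times must be positive", call. = FALSE)
  out <- data.frame(id = cohort$id[keep], start = 0, stop = t,
                    event = cohort$event[keep],
                    consolidation = as.integer(cohort$started_consolidation[keep] == 1),
                    weight = weights[keep], stringsAsFactors = FALSE)
  class(out) <- c("episode_table", "data.frame")
  out
}

#' Split follow-up at a changepoint into early/late treatment dummies
#'
#' Episode splitting for a two-interval time-varying treatment effect. A
#' consolidated patient followed beyond the changepoint contributes two
#' episodes: (0, changepoint] with `early = 1` (event 0 there) and
#' (changepoint, T] with `late = 1` carrying the observed event status. A
#' consolidated patient whose follow-up ends at or before the changepoint
#' contributes a single `early = 1` episode (the boundary belongs to the
#' early interval). Both dummies are 0 on every episode of a
#' non-consolidated patient. Weights are constant across a patient's
#' episodes.
#'
#' @param cohort cohort `data.frame` with outcome columns.
#' @param weights per-patient weights aligned to the cohort rows.
#' @param changepoint changepoint in months (default 18).
#' @return an `episode_table` data.frame: `id`, `start`, `stop`, `event`,
#'   `early`, `late`, `consolidation`, `weight`.
#' @export
split_at_changepoint <- function(cohort, weights, changepoint = 18) {
  if (changepoint <= 0) stop("changepoint must be positive", call. = FALSE)
  base <- make_episodes(cohort, weights)
  split_two <- base$consolidation == 1 & base$stop > changepoint
  one <- base[!split_two, , drop = FALSE]
  one$early <- as.integer(one$consolidation == 1)  # stop <= changepoint here
  one$late <- 0L
  first <- base[split_two, , drop = FALSE]
  second <- first
  first$stop <- changepoint
  first$event <- 0L
  first$early <- 1L
  first$late <- 0L
  second$start <- changepoint
  second$early <- 0L
  second$late <- 1L
  out <- rbind(one, first, second)
  out <- out[order(match(out$id, base$id), out$start),
             c("id", "start", "stop", "event", "early", "late", "consolidation", "weight")]
  rownames(out) <- NULL
  class(out) <- c("episode_table", "data.frame")
  out
}

# one full pass of the weighted Breslow partial likelihood:
# log-likelihood, score and information at beta
cox_pass <- function(start, stop, event, X, w, beta, want_deriv = TRUE) {
  p <- ncol(X)
  eta <- drop(X %*% beta)
  r <- w * exp(eta)
  dt <- sort(unique(stop[event == 1]))
  ll <- 0
  U <- numeric(p)
  I <- matrix(0, p, p)
  for (t in dt) {
    at <- start < t & stop >= t
    ev <- event == 1 & stop == t
    S0 <- sum(r[at])
    wd <- sum(w[ev])
    ll <- ll + sum(w[ev] * eta[ev]) - wd * log(S0)
    if (want_deriv) {
      Xa <- X[at, , drop = FALSE]
      ra <- r[at]
      S1 <- colSums(Xa * ra)
      xbar <- S1 / S0
      S2 <- crossprod(Xa, Xa * ra)
      U <- U + colSums(X[ev, , drop = FALSE] * w[ev]) - wd * xbar
      I <- I + wd * (S2 / S0 - tcrossprod(xbar))
    }
  }
  list(loglik = ll, score = U, info = I, dtimes = dt)
}

#' Weighted Cox proportional hazards model on start-stop episodes
#'
#' Maximizes the weighted partial likelihood with Breslow tie handling and
#' counting-process (start, stop] risk sets by Newton-Raphson with step
#' halving; convergence at a relative log-likelihood change below 1e-8,
#' at most 50 iterations. Naive standard errors come from the inverse of
#' the weighted information; robust standard errors from the Lin-Wei
#' sandwich with score residuals aggregated per patient (see
#' [robust_sandwich_variance()]), which is what makes the inference valid
#' under inverse-probability weighting. A coefficient diverging beyond
#' |log HR| > 15 is reported as monotone likelihood rather than returned.
#'
#' @param episodes an `episode_table` (or any data frame with `id`,
#'   `start`, `stop`, `event`, `weight` and the term columns).
#' @param terms character vector of covariate column names to enter the
#'   model (default `c("early", "late")`).
#' @return an object of class `ipwcox`: coefficients (log hazard ratios),
#'   naive and robust variance matrices, hazard ratios with robust 95%
#'   confidence intervals, Wald p-values, event counts and convergence
#'   diagnostics. The episode data are kept in the object for residual
#'   diagnostics.
#' @export
fit_weighted_cox <- function(episodes, terms = c("early", "late")) {
  need <- c("id", "start", "stop", "event", "weight", terms)
  miss <- setdiff(need, names(episodes))
  if (length(miss)) stop(sprintf("episodes table is missing columns: %s",
                                 paste(miss, collapse = ", ")), call. = FALSE)
  if (any(episodes$stop <= episodes$start)) stop("episodes must have stop > start", call. = FALSE)
  if (any(episodes$weight <= 0)) stop("weights must be positive", call. = FALSE)
  nev <- sum(episodes$event == 1)
  if (nev < 1) stop("no events: the partial likelihood is undefined", call. = FALSE)
  X <- as.matrix(episodes[, terms, drop = FALSE])
  storage.mode(X) <- "double"
  start <- episodes$start; stop_ <- episodes$stop
  event <- episodes$event; w <- episodes$weight
  p <- ncol(X)
  beta <- numeric(p)
  pass <- cox_pass(start, stop_, event, X, w, beta)
  ll0 <- pass$loglik
  converged <- FALSE
  iter <- 0
  for (it in seq_len(50)) {
    iter <- it
    step <- tryCatch(solve(pass$info, pass$score), error = function(e) {
      stop("singular information matrix: design not full rank on the event risk sets",
           call. = FALSE)
    })
    beta_new <- beta + step
    pass_new <- cox_pass(start, stop_, event, X, w, beta_new)
    halvings <- 0
    while (pass_new$loglik < pass$loglik && halvings < 20) {
      step <- step / 2
      beta_new <- beta + step
      pass_new <- cox_pass(start, stop_, event, X, w, beta_new)
      halvings <- halvings + 1
    }
    if (any(abs(beta_new) > 15)) {
      stop("monotone partial likelihood: a coefficient is diverging (|log HR| > 15)",
           call. = FALSE)
    }
    rel <- abs(pass_new$loglik - pass$loglik) / (abs(pass$loglik) + 0.1)
    beta <- beta_new
    pass <- pass_new
    if (rel < 1e-8) { converged <- TRUE; break }
  }
  names(beta) <- terms
  var_naive <- solve(pass$info)
  dimnames(var_naive) <- list(terms, terms)
  fit <- list(coefficients = beta, var_naive = var_naive,
              loglik = c(null = ll0, final = pass$loglik),
              n_events = nev, n_episodes = nrow(episodes),
              n_patients = length(unique(episodes$id)),
              iter = iter, converged = converged,
              terms = terms, episodes = episodes)
  class(fit) <- "ipwcox"
  fit$var_robust <- robust_sandwich_variance(fit)
  fit$se_naive <- sqrt(diag(var_naive))
  fit$se_robust <- sqrt(diag(fit$var_robust))
  z <- beta / fit$se_robust
  zc <- stats::qnorm(0.975)
  fit$hr <- exp(beta)
  fit$hr_low <- exp(beta - zc * fit$se_robust)
  fit$hr_high <- exp(beta + zc * fit$se_robust)
  fit$p_value <- 2 * stats::pnorm(-abs(z))
  fit
}

#' Lin-Wei robust sandwich variance of a weighted Cox fit
#'
#' A^-1 B A^-1 with A the weighted partial-likelihood information and B the
#' outer product of per-patient weighted score residuals: the residuals of
#' a patient's episodes are summed before squaring, so split follow-up does
#' not masquerade as independent information. The sandwich is invariant to
#' rescaling all weights by a constant, unlike the naive variance.
#'
#' @param fit an `ipwcox` fit.
#' @param episodes episode table; defaults to the one stored in the fit.
#' @return robust covariance matrix of the log hazard ratios.
#' @export
robust_sandwich_variance <- function(fit, episodes = fit$episodes) {
  terms <- fit$terms
  X <- as.matrix(episodes[, terms, drop = FALSE])
  storage.mode(X) <- "double"
  start <- episodes$start; stop_ <- episodes$stop
  event <- episodes$event; w <- episodes$weight
  beta <- fit$coefficients
  eta <- drop(X %*% beta)
  r <- w * exp(eta)
  dt <- sort(unique(stop_[event == 1]))
  R <- matrix(0, nrow(X), length(terms))
  for (t in dt) {
    at <- which(start < t & stop_ >= t)
    ev <- which(event == 1 & stop_ == t)
    S0 <- sum(r[at])
    Xa <- X[at, , drop = FALSE]
    xbar <- colSums(Xa * r[at]) / S0
    dLambda <- sum(w[ev]) / S0
    R[ev, ] <- R[ev, , drop = FALSE] + w[ev] * (X[ev, , drop = FALSE] - rep(xbar, each = length(ev)))
    R[at, ] <- R[at, , drop = FALSE] - dLambda * r[at] * (Xa - rep(xbar, each = length(at)))
  }
  Ragg <- rowsum(R, group = episodes$id)
  B <- crossprod(Ragg)
  V <- fit$var_naive %*% B %*% fit$var_naive
  dimnames(V) <- list(terms, terms)
  V
}

#' @export
coef.ipwcox <- function(object, ...) object$coefficients

#' @export
vcov.ipwcox <- function(object, type = c("robust", "naive"), ...) {
  switch(match.arg(type), robust = object$var_robust, naive = object$var_naive)
}

#' @export
confint.ipwcox <- function(object, parm, level = 0.95, ...) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  ci <- cbind(object$coefficients - z * object$se_robust,
              object$coefficients + z * object$se_robust)
  colnames(ci) <- sprintf("%.1f %%", c((1 - level) / 2, 1 - (1 - level) / 2) * 100)
  if (!missing(parm)) ci <- ci[parm, , drop = FALSE]
  ci
}

#' @export
print.ipwcox <- function(x, digits = 3, ...) {
  cat(sprintf("Weighted Cox model: %d events, %d episodes, %d patients (%s in %d iterations)\n",
              x$n_events, x$n_episodes, x$n_patients,
              if (x$converged) "converged" else "NOT converged", x$iter))
  tab <- data.frame(term = x$terms, coef = x$coefficients, HR = x$hr,
                    `robust SE` = x$se_robust,
                    `HR low` = x$hr_low, `HR high` = x$hr_high,
                    p = x$p_value, check.names = FALSE, row.names = NULL)
  tab[-1] <- lapply(tab[-1], signif, digits)
  print.data.frame(tab, row.names = FALSE)
  invisible(x)
}

#' @export
summary.ipwcox <- function(object, ...) {
  data.frame(term = object$terms, coef = object$coefficients,
             se_naive = object$se_naive, se_robust = object$se_robust,
             hr = object$hr, hr_low = object$hr_low, hr_high = object$hr_high,
             p_value = object$p_value, row.names = NULL)
}

#' Schoenfeld residual test of proportional hazards
#'
#' Scaled-Schoenfeld (Grambsch-Therneau style) test with the identity time
#' transform: weighted Schoenfeld residuals at event times are regressed on
#' event time, giving a score-type chi-square per term and a global test.
#' Weights are normalized to mean 1 within the test so the result does not
#' depend on an arbitrary rescaling of the weights.
#'
#' @param fit an `ipwcox` fit.
#' @param episodes episode table; defaults to the one stored in the fit.
#' @return an object of class `ph_test`: a table of chi-square statistics,
#'   degrees of freedom and p-values, one row per term plus a global row.
#' @export
schoenfeld_ph_test <- function(fit, episodes = fit$episodes) {
  terms <- fit$terms
  X <- as.matrix(episodes[, terms, drop = FALSE])
  storage.mode(X) <- "double"
  start <- episodes$start; stop_ <- episodes$stop
  event <- episodes$event
  w <- episodes$weight / mean(episodes$weight)
  if (sum(event) < 2) stop("at least 2 events are needed to test proportional hazards", call. = FALSE)
  beta <- fit$coefficients
  r <- w * exp(drop(X %*% beta))
  dt <- sort(unique(stop_[event == 1]))
  rows <- list()
  times <- numeric(0)
  for (t in dt) {
    at <- start < t & stop_ >= t
    ev <- which(event == 1 & stop_ == t)
    xbar <- colSums(X[at, , drop = FALSE] * r[at]) / sum(r[at])
    for (i in ev) {
      rows[[length(rows) + 1]] <- w[i] * (X[i, ] - xbar)
      times <- c(times, t)
    }
  }
  S <- do.call(rbind, rows)
  d <- nrow(S)
  gt <- times - mean(times)
  sg2 <- sum(gt^2)
  # information of the weight-normalized fit
  info <- cox_pass(start, stop_, event, X, w, beta)$info
  V <- solve(info)
  z <- drop(crossprod(S, gt))
  vz <- drop(V %*% z)
  chisq_term <- d * vz^2 / (diag(V) * sg2)
  chisq_global <- d * sum(z * vz) / sg2
  tab <- data.frame(
    term = c(terms, "GLOBAL"),
    chisq = c(chisq_term, chisq_global),
    df = c(rep(1, length(terms)), length(terms)),
    p_value = c(stats::pchisq(chisq_term, 1, lower.tail = FALSE),
                stats::pchisq(chisq_global, length(terms), lower.tail = FALSE)),
    row.names = NULL)
  structure(list(table = tab, transform = "identity", n_events = d),
            class = "ph_test")
}

#' @export
print.ph_test <- function(x, digits = 4, ...) {
  cat(sprintf("Proportional-hazards test (scaled Schoenfeld residuals, %s transform, %d events)\n",
              x$transform, x$n_events))
  tab <- x$table
  tab$chisq <- round(tab$chisq, digits)
  tab$p_value <- signif(tab$p_value, digits)
  print.data.frame(tab, row.names = FALSE)
  invisible(x)
}

#' Export a Cox fit summary as delimited text
#'
#' @param fit an `ipwcox`.
#' @param path output file path (tab-separated: term, HR, robust CI, p).
#' @return `path`, invisibly.
#' @export
write_cox_table <- function(fit, path) {
  utils::write.table(summary(fit), path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
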