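#' Weighted Kaplan-Meier (product-limit) survival estimate
#'
#' Product-limit estimator in which every subject contributes its weight to
#' the risk and event sums: S(t) = prod over event times t_j <= t of
#' (1 - D_j / Y_j), with D_j the weighted events at t_j and Y_j the weighted
#' number at risk. With inverse-probability weights this estimates the
#' survival curve of the pseudo-population in which treatment is
#' independent of the measured covariates. The pointwise variance is a
#' weighted Greenwood form in which squared weights enter the numerator:
#' Var log S(t) = sum_j Y2_j D_j / (Y_j^3 (1 - D_j/Y_j)) with
#' Y2_j = sum of squared weights at risk; at unit weights this is exactly
#' Greenwood's formula. Ties are aggregated; events precede censorings at
#' the same time (a subject censored at t is still at risk for an event
#' at t).
#'
#' @param time follow-up times (> 0).
#' @param event 0/1 event indicator.
#' @param weights positive subject weights (default 1).
#' @param group optional group labels; when given, one curve per group.
#' @return an object of class `wkm`: a data frame with columns `group`,
#'   `time`, `n_risk` (weighted), `n_event` (weighted), `surv`, `var`,
#'   `std_err`, one row per distinct event time.
#' @export
weighted_km <- function(time, event, weights = NULL, group = NULL) {
  n <- length(time)
  if (n == 0) stop("no observations", call. = FALSE)
  if (length(event) != n) stop("time and event lengths differ", call. = FALSE)
  if (any(!is.finite(time) | time <= 0)) stop("times must be positive", call. = FALSE)
  if (!is_binary01(event) || anyNA(event)) stop("event must be 0/1", call. = FALSE)
  if (is.null(weights)) weights <- rep(1, n)
  if (length(weights) != n || any(!is.finite(weights) | weights <= 0)) {
    stop("weights must be positive and align with the data", call. = FALSE)
  }
  if (is.null(group)) group <- rep("all", n)
  curves <- lapply(split(seq_len(n), group), function(idx) {
    km_one_group(time[idx], event[idx], weights[idx])
  })
  out <- do.call(rbind, lapply(names(curves), function(g) {
    cbind(group = rep(g, nrow(curves[[g]])), curves[[g]], stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  attr(out, "groups") <- names(curves)
  class(out) <- c("wkm", "data.frame")
  out
}

wkm_groups <- function(x) {
  g <- attr(x, "groups")
  if (is.null(g)) unique(x$group) else g
}

km_one_group <- function(time, event, w) {
  dt <- sort(unique(time[event == 1]))
  if (!length(dt)) {
    return(data.frame(time = numeric(0), n_risk = numeric(0), n_event = numeric(0),
                      surv = numeric(0), var = numeric(0), std_err = numeric(0)))
  }
  Y <- vapply(dt, function(t) sum(w[time >= t]), 0)
  Y2 <- vapply(dt, function(t) sum(w[time >= t]^2), 0)
  D <- vapply(dt, function(t) sum(w[time == t & event == 1]), 0)
  lambda <- D / Y
  surv <- cumprod(1 - lambda)
  # weighted Greenwood: squared weights in the numerator; exact classical
  # Greenwood at unit weights
  contrib <- ifelse(lambda < 1, Y2 * lambda / (Y^2 * (1 - lambda)), 0)
  v <- surv^2 * cumsum(contrib)
  data.frame(time = dt, n_risk = Y, n_event = D, surv = surv,
             var = v, std_err = sqrt(v))
}

#' @export
print.wkm <- function(x, digits = 4, ...) {
  cat("Weighted Kaplan-Meier estimate\n")
  for (g in wkm_groups(x)) {
    sub <- x[x$group == g, ]
    cat(sprintf("  group %s: %d event times, final S(t) = %.*f\n",
                g, nrow(sub), digits, if (nrow(sub)) sub$surv[nrow(sub)] else 1))
  }
  invisible(x)
}

#' Survival probabilities at chosen times
#'
#' @param object a `wkm`.
#' @param times evaluation times (default: a short grid over follow-up).
#' @param ... unused.
#' @return data frame of step-function values S(t) per group.
#' @export
summary.wkm <- function(object, times = NULL, ...) {
  if (is.null(times)) times <- pretty(c(0, max(object$time)), 6)
  out <- do.call(rbind, lapply(wkm_groups(object), function(g) {
    sub <- object[object$group == g, ]
    s <- vapply(times, function(t) {
      i <- sub$time <= t
      if (any(i)) sub$surv[max(which(i))] else 1
    }, 0)
    data.frame(group = g, time = times, surv = s)
  }))
  rownames(out) <- NULL
  out
}

#' @export
plot.wkm <- function(x, xlab = "Months", ylab = "Survival probability",
                     col = NULL, conf = FALSE, ...) {
  groups <- unique(x$group)
  if (is.null(col)) col <- seq_along(groups)
  graphics::plot(NA, xlim = c(0, max(x$time)), ylim = c(0, 1),
                 xlab = xlab, ylab = ylab, ...)
  for (i in seq_along(groups)) {
    sub <- x[x$group == groups[i], ]
    graphics::lines(stats::stepfun(sub$time, c(1, sub$surv)), do.points = FALSE,
                    col = col[i])
    if (conf) {
      up <- pmin(1, sub$surv + 1.96 * sub$std_err)
      lo <- pmax(0, sub$surv - 1.96 * sub$std_err)
      graphics::lines(stats::stepfun(sub$time, c(1, up)), do.points = FALSE,
                      col = col[i], lty = 3)
      graphics::lines(stats::stepfun(sub$time, c(1, lo)), do.points = FALSE,
                      col = col[i], lty = 3)
    }
  }
  graphics::legend("bottomleft", legend = groups, col = col, lty = 1, bty = "n")
  invisible(x)
}

#' Export a weighted survival curve as delimited text
#'
#' @param curve a `wkm`.
#' @param path output file path (tab-separated).
#' @return `path`, invisibly.
#' @export
write_survival_curve <- function(curve, path) {
  utils::write.table(as.data.frame(curve), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Weighted log-rank test
#'
#' Two-group log-rank test on weighted risk and event sums. The statistic
#' is U = sum_j (D_1j - Y_1j D_j / Y_j). Because inverse-probability
#' weights are not frequency counts, the variance carries squared weights:
#' V = sum_j lambda_j (1 - lambda_j) * sum_{i at risk} w_i^2 (g_i - p_1j)^2
#' * ntilde_j / (ntilde_j - 1), where lambda_j = D_j / Y_j, p_1j is the
#' weighted proportion at risk in group 1 and ntilde_j = Y_j^2 / Y2_j is
#' the effective (Kish) risk-set size that supplies the small-sample ties
#' correction. At unit weights this reduces exactly to the classical
#' log-rank variance. The statistic is invariant to rescaling all weights
#' by a constant.
#'
#' @param time follow-up times (> 0).
#' @param event 0/1 event indicator.
#' @param weights positive weights (default 1).
#' @param group two-level group indicator; the level sorted last is
#'   "group 1".
#' @return an object of class `wlogrank`: `chisq`, `df`, `p_value`,
#'   `observed`/`expected` weighted event totals per group.
#' @export
weighted_logrank <- function(time, event, weights = NULL, group = NULL) {
  n <- length(time)
  if (is.null(weights)) weights <- rep(1, n)
  g <- as.integer(factor(group))
  if (length(unique(g)) != 2) stop("exactly two non-empty groups are required", call. = FALSE)
  if (any(weights <= 0)) stop("weights must be positive", call. = FALSE)
  g1 <- g == 2
  dt <- sort(unique(time[event == 1]))
  U <- V <- 0
  O1 <- E1 <- 0
  for (t in dt) {
    at <- time >= t
    Y <- sum(weights[at]); Y1 <- sum(weights[at & g1])
    ev <- event == 1 & time == t
    D <- sum(weights[ev]); D1 <- sum(weights[ev & g1])
    p1 <- Y1 / Y
    lambda <- D / Y
    U <- U + (D1 - p1 * D)
    O1 <- O1 + D1; E1 <- E1 + p1 * D
    Y2 <- sum(weights[at]^2)
    ntilde <- Y^2 / Y2
    if (ntilde > 1) {
      ssq <- sum(weights[at]^2 * ((g1[at]) - p1)^2)
      V <- V + lambda * (1 - lambda) * ssq * ntilde / (ntilde - 1)
    }
  }
  chisq <- if (V > 0) U^2 / V else 0
  structure(list(chisq = chisq, df = 1,
                 p_value = stats::pchisq(chisq, 1, lower.tail = FALSE),
                 observed = c(group0 = sum(weights[event == 1 & !g1]), group1 = O1),
                 expected = c(group0 = sum(weights[event == 1]) - E1, group1 = E1)),
            class = "wlogrank")
}

#' @export
print.wlogrank <- function(x, ...) {
  cat(sprintf("Weighted log-rank test: chisq = %.4f on %d df, p = %.4f\n",
              x$chisq, x$df, x$p_value))
  invisible(x)
}
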