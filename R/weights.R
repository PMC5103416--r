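#' Inverse probability of treatment weight
#'
#' w = z/p + (1 - z)/(1 - p): the inverse of the probability of the
#' treatment actually received. Always >= 1.
#'
#' @param z 0/1 treatment indicator (vectorized).
#' @param p propensity score, strictly in (0, 1).
#' @return weight vector.
#' @export
compute_iptw <- function(z, p) {
  if (!is_binary01(z) || anyNA(z)) stop("z must be 0/1", call. = FALSE)
  if (any(!is.finite(p)) || any(p <= 0 | p >= 1)) {
    stop("propensity scores must lie strictly in (0, 1); a score of 0 or 1 would give an infinite weight",
         call. = FALSE)
  }
  z / p + (1 - z) / (1 - p)
}

#' Stabilized inverse probability of treatment weight
#'
#' The IPTW multiplied by the marginal probability of the treatment actually
#' received: z * marginal/p + (1 - z) * (1 - marginal)/(1 - p). Stabilized
#' weights average 1 when the propensity model is correctly specified, so
#' the weighted pseudo-population keeps the original sample size.
#'
#' @param z 0/1 treatment indicator (vectorized).
#' @param p propensity score, strictly in (0, 1).
#' @param marginal marginal treatment probability, strictly in (0, 1).
#' @return weight vector.
#' @export
stabilize_weight <- function(z, p, marginal) {
  if (any(!is.finite(marginal)) || any(marginal <= 0 | marginal >= 1)) {
    stop("marginal probability must lie strictly in (0, 1)", call. = FALSE)
  }
  compute_iptw(z, p) * ifelse(z == 1, marginal, 1 - marginal)
}

#' Total stabilized weight across the two sequential phases
#'
#' Product of the phase-1 and phase-2 stabilized weights for patients who
#' started the first transplant; for non-starters the second-phase weight
#' does not exist and the total equals the phase-1 stabilized weight alone.
#'
#' @param siptw1 phase-1 stabilized weight.
#' @param siptw2 phase-2 stabilized weight, `NA` for ASCT non-starters.
#' @param started_asct 0/1 indicator of starting the first transplant.
#' @return total weight vector.
#' @export
total_weight <- function(siptw1, siptw2, started_asct) {
  if (!is_binary01(started_asct) || anyNA(started_asct)) {
    stop("started_asct must be 0/1", call. = FALSE)
  }
  started <- started_asct == 1
  if (any(started & is.na(siptw2))) {
    stop("siptw2 missing for a patient who started the first transplant", call. = FALSE)
  }
  if (any(!started & !is.na(siptw2))) {
    stop("siptw2 supplied for a patient who never started the first transplant", call. = FALSE)
  }
  ifelse(started, siptw1 * siptw2, siptw1)
}

#' Summary of a weight distribution
#'
#' Mean, sample standard deviation (n - 1 denominator), range, and the
#' count of weights above 2 (extreme weights deserve individual scrutiny).
#'
#' @param weights positive weight vector.
#' @return a `weight_summary` list: `mean`, `sd`, `min`, `max`, `n`,
#'   `n_above_2`.
#' @export
summarize_weights <- function(weights) {
  weights <- weights[!is.na(weights)]
  if (!length(weights)) stop("cannot summarize an empty weight vector", call. = FALSE)
  if (any(weights <= 0)) stop("weights must be positive", call. = FALSE)
  structure(list(mean = mean(weights),
                 sd = if (length(weights) > 1) stats::sd(weights) else 0,
                 min = min(weights), max = max(weights),
                 n = length(weights), n_above_2 = sum(weights > 2)),
            class = "weight_summary")
}

#' @export
print.weight_summary <- function(x, digits = 2, ...) {
  cat(sprintf("%.*f +/- %.*f  range %.*f-%.*f  (n = %d, %d above 2)\n",
              digits, x$mean, digits, x$sd, digits, x$min, digits, x$max,
              x$n, x$n_above_2))
  invisible(x)
}

#' Per-patient weights for the two sequential selection phases
#'
#' Combines fitted propensity scores into the full weight set: phase-wise
#' unstabilized and stabilized weights and the total product. Marginal
#' stabilization probabilities are the observed starting proportions within
#' each phase's at-risk set (all patients for the transplant phase, ASCT
#' starters for the consolidation phase), matching how stabilized weights
#' are computed from trial-flow counts. An optional truncation quantile
#' caps the total weight at that upper quantile (off by default; the
#' analysis this package implements reports extreme weights rather than
#' truncating them).
#'
#' @param cohort cohort `data.frame` with `started_asct` and
#'   `started_consolidation`.
#' @param ps1 fitted probabilities of starting the first transplant
#'   (aligned to `cohort`).
#' @param ps2 fitted probabilities of starting consolidation, `NA` for
#'   non-starters.
#' @param truncation_quantile optional quantile in (0, 1) at which to cap
#'   the total weight; `NULL` (default) disables truncation.
#' @return a `weight_set` data.frame: `id`, `ps1`, `iptw1`, `siptw1`,
#'   `ps2`, `iptw2`, `siptw2`, `tiptw`, `tsiptw`, with the marginal starting
#'   proportions attached as attributes `marginal_p1`, `marginal_p2`.
#' @export
compute_weights <- function(cohort, ps1, ps2, truncation_quantile = NULL) {
  n <- nrow(cohort)
  if (length(ps1) != n || length(ps2) != n) {
    stop("ps1 and ps2 must align with the cohort rows", call. = FALSE)
  }
  z1 <- cohort$started_asct
  started <- z1 == 1
  if (any(is.na(ps2[started]))) stop("ps2 missing for an ASCT starter", call. = FALSE)
  marginal_p1 <- mean(z1)
  if (marginal_p1 <= 0 || marginal_p1 >= 1) {
    stop("all or no patients started the first transplant; weights are undefined", call. = FALSE)
  }
  iptw1 <- compute_iptw(z1, ps1)
  siptw1 <- stabilize_weight(z1, ps1, marginal_p1)
  z2 <- cohort$started_consolidation
  marginal_p2 <- mean(z2[started])
  if (is.na(marginal_p2) || marginal_p2 <= 0 || marginal_p2 >= 1) {
    stop("all or no ASCT starters began consolidation; phase-2 weights are undefined", call. = FALSE)
  }
  iptw2 <- siptw2 <- rep(NA_real_, n)
  iptw2[started] <- compute_iptw(z2[started], ps2[started])
  siptw2[started] <- stabilize_weight(z2[started], ps2[started], marginal_p2)
  tsiptw <- total_weight(siptw1, siptw2, z1)
  tiptw <- ifelse(started, iptw1 * iptw2, iptw1)
  if (!is.null(truncation_quantile)) {
    if (truncation_quantile <= 0 || truncation_quantile >= 1) {
      stop("truncation_quantile must lie in (0, 1)", call. = FALSE)
    }
    cap <- stats::quantile(tsiptw, truncation_quantile, names = FALSE)
    tsiptw <- pmin(tsiptw, cap)
  }
  out <- data.frame(id = if (is.null(cohort$id)) seq_len(n) else cohort$id,
                    ps1 = ps1, iptw1 = iptw1, siptw1 = siptw1,
                    ps2 = ps2, iptw2 = iptw2, siptw2 = siptw2,
                    tiptw = tiptw, tsiptw = tsiptw,
                    stringsAsFactors = FALSE)
  attr(out, "marginal_p1") <- marginal_p1
  attr(out, "marginal_p2") <- marginal_p2
  class(out) <- c("weight_set", "data.frame")
  out
}

#' Three-panel summary of a weight set
#'
#' @param object a `weight_set` from [compute_weights()].
#' @param ... unused.
#' @return named list of [summarize_weights()] results for the unstabilized
#'   and stabilized weights of each phase and of the total product.
#' @export
summary.weight_set <- function(object, ...) {
  structure(list(
    iptw1 = summarize_weights(object$iptw1),
    siptw1 = summarize_weights(object$siptw1),
    iptw2 = summarize_weights(object$iptw2),
    siptw2 = summarize_weights(object$siptw2),
    tiptw = summarize_weights(object$tiptw),
    tsiptw = summarize_weights(object$tsiptw)),
    class = "summary.weight_set",
    marginal_p1 = attr(object, "marginal_p1"),
    marginal_p2 = attr(object, "marginal_p2"))
}

#' @export
print.summary.weight_set <- function(x, ...) {
  cat(sprintf("Marginal starting proportions: phase 1 %.4f, phase 2 %.4f\n",
              attr(x, "marginal_p1"), attr(x, "marginal_p2")))
  cat("A. Starting first transplant\n   IPTW  "); print(x$iptw1)
  cat("   SIPTW "); print(x$siptw1)
  cat("B. Starting consolidation\n   IPTW  "); print(x$iptw2)
  cat("   SIPTW "); print(x$siptw2)
  cat("C. Total product\n   IPTW  "); print(x$tiptw)
  cat("   SIPTW "); print(x$tsiptw)
  invisible(x)
}

#' Export a weight table as delimited text
#'
#' @param weight_set a `weight_set`.
#' @param path output file path (tab-separated).
#' @return `path`, invisibly.
#' @export
write_weight_table <- function(weight_set, path) {
  utils::write.table(as.data.frame(weight_set), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}
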