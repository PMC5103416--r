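#' Inverse logit
#'
#' @param x numeric vector on the log-odds scale.
#' @return probabilities in (0, 1).
#' @keywords internal
expit <- function(x) 1 / (1 + exp(-x))

# clamp probabilities away from 0/1 so inverse weights stay finite;
# returns the vector with an "n_clamped" attribute
clamp_probability <- function(p, eps = 1e-6) {
  n_clamped <- sum(p < eps | p > 1 - eps, na.rm = TRUE)
  out <- pmin(pmax(p, eps), 1 - eps)
  attr(out, "n_clamped") <- n_clamped
  out
}

stop_field <- function(field, msg) {
  stop(sprintf("invalid configuration field '%s': %s", field, msg), call. = FALSE)
}

is_binary01 <- function(x) {
  is.numeric(x) && all(x %in% c(0, 1) | is.na(x))
}

check_probability <- function(p, name, open = FALSE) {
  bad <- if (open) any(p <= 0 | p >= 1) else any(p < 0 | p > 1)
  if (any(!is.finite(p)) || bad) {
    stop_field(name, if (open) "must lie strictly in (0, 1)" else "must lie in [0, 1]")
  }
  invisible(p)
}
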