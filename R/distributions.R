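#' Threshold-lognormal parameter set
#'
#' Bundles the three parameters of the threshold (three-parameter) lognormal
#' law for blood-loss volume V: if V follows this law, log(V - t) is normal
#' with mean `m` and standard deviation `s`, so the support of V is (t, Inf).
#' With `t = 0` this is the ordinary two-parameter lognormal.
#'
#' `m` is the location (mean of log(V - t), in log-mL), `s > 0` the scale
#' (standard deviation of log(V - t)), and `t` the threshold shift in mL.
#' The median of V is `t + exp(m)`.
#'
#' @param m location parameter; single finite number.
#' @param s scale parameter; single strictly positive finite number.
#' @param t threshold parameter in mL; single finite number (default 0).
#' @return An object of class `"lognormal_params"`.
#' @examples
#' lognormal_params(5.58, 0.71, -8.60)  # a fitted Misoprostol-arm triple
#' @export
lognormal_params <- function(m, s, t = 0) {
  for (nm in c("m", "s", "t")) {
    val <- get(nm)
    if (!is.numeric(val) || length(val) != 1L || !is.finite(val))
      stop(sprintf("`%s` must be a single finite number", nm), call. = FALSE)
  }
  if (s <= 0)
    stop("`s` must be strictly positive", call. = FALSE)
  structure(list(m = as.numeric(m), s = as.numeric(s), t = as.numeric(t)),
            class = "lognormal_params")
}

#' Coerce to lognormal_params
#'
#' Accepts an existing `lognormal_params` object or a numeric vector of
#' length 2 (`c(m, s)`, threshold 0) or 3 (`c(m, s, t)`).
#'
#' @param x object to coerce.
#' @return A `lognormal_params` object.
#' @export
as_lognormal_params <- function(x) {
  if (inherits(x, "lognormal_params")) {
    if (x$s <= 0) stop("`s` must be strictly positive", call. = FALSE)
    return(x)
  }
  if (is.numeric(x) && length(x) %in% 2:3)
    return(lognormal_params(x[[1]], x[[2]], if (length(x) == 3L) x[[3]] else 0))
  stop("cannot interpret `params`: supply lognormal_params() or c(m, s[, t])",
       call. = FALSE)
}

#' @export
print.lognormal_params <- function(x, ...) {
  cat(sprintf(
    "threshold-lognormal parameters: m = %.4g, s = %.4g, t = %.4g (median %.4g mL)\n",
    x$m, x$s, x$t, x$t + exp(x$m)))
  invisible(x)
}

#' Threshold-lognormal density
#'
#' Density of blood-loss volume under the threshold lognormal law, i.e. the
#' ordinary lognormal density evaluated at `v - t`. Zero for `v <= t`, so it
#' can be evaluated vectorised over mixed data without error.
#'
#' @param v volumes in mL (any real vector).
#' @param params a [lognormal_params()] object (or numeric `c(m, s[, t])`).
#' @param log if `TRUE` return the log density.
#' @return Numeric vector of densities (1/mL).
#' @export
dlnorm3 <- function(v, params, log = FALSE) {
  p <- as_lognormal_params(params)
  out <- rep(if (log) -Inf else 0, length(v))
  out[is.na(v)] <- NA_real_
  ok <- !is.na(v) & v > p$t
  out[ok] <- stats::dlnorm(v[ok] - p$t, meanlog = p$m, sdlog = p$s, log = log)
  out
}

#' Threshold-lognormal cumulative distribution function
#'
#' @inheritParams dlnorm3
#' @return P(V <= v); 0 for `v <= t`.
#' @export
plnorm3 <- function(v, params) {
  p <- as_lognormal_params(params)
  out <- numeric(length(v))
  out[is.na(v)] <- NA_real_
  ok <- !is.na(v) & v > p$t
  out[ok] <- stats::plnorm(v[ok] - p$t, meanlog = p$m, sdlog = p$s)
  out
}

#' Threshold-lognormal survival function
#'
#' P(V > v), the quantity behind the clinical endpoints: evaluated at 500 mL
#' it is the PPH probability, at 1000 mL the severe-PPH probability. Computed
#' through the standard-normal upper tail directly (not as `1 - plnorm3`) so
#' small tail probabilities keep full relative precision.
#'
#' @inheritParams dlnorm3
#' @return P(V > v); 1 for `v <= t`.
#' @export
slnorm3 <- function(v, params) {
  p <- as_lognormal_params(params)
  out <- rep(1, length(v))
  out[is.na(v)] <- NA_real_
  ok <- !is.na(v) & v > p$t
  out[ok] <- stats::pnorm((log(v[ok] - p$t) - p$m) / p$s, lower.tail = FALSE)
  out
}

#' Threshold-lognormal quantile function
#'
#' Inverse of [plnorm3()]: `t + exp(m + s * qnorm(p))`.
#'
#' @param p probabilities, strictly inside (0, 1).
#' @inheritParams dlnorm3
#' @return Volumes in mL.
#' @export
qlnorm3 <- function(p, params) {
  pr <- as_lognormal_params(params)
  bad <- !is.na(p) & (p <= 0 | p >= 1)
  if (any(bad))
    stop("probabilities must lie strictly inside (0, 1)", call. = FALSE)
  pr$t + exp(pr$m + pr$s * stats::qnorm(p))
}

#' Simulate threshold-lognormal volumes
#'
#' @param n number of draws.
#' @inheritParams dlnorm3
#' @return `n` volumes in mL, all greater than `t`.
#' @export
rlnorm3 <- function(n, params) {
  p <- as_lognormal_params(params)
  p$t + stats::rlnorm(n, meanlog = p$m, sdlog = p$s)
}

#' Standard-normal quantile
#'
#' Convenience wrapper around `qnorm` used in the sample-size arithmetic,
#' e.g. the 0.985 and 0.98 quantiles (2.1701 and 2.0537) that convert severe
#' PPH rates of 1.5% and 2% into log-volume means.
#'
#' @param p probabilities, strictly inside (0, 1).
#' @return z-scores.
#' @export
normal_quantile <- function(p) {
  if (any(!is.na(p) & (p <= 0 | p >= 1)))
    stop("probabilities must lie strictly inside (0, 1)", call. = FALSE)
  stats::qnorm(p)
}
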