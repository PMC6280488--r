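# Tail-probability (PPH / severe-PPH) estimation per arm, by the lognormal
# and by the binomial approach, with 95% confidence intervals.

new_tail_estimate <- function(cutoff, approach, p, ci95, n, arm_label,
                              degenerate = FALSE, note = NULL) {
  ci95 <- pmin(pmax(ci95, 0), 1)
  structure(
    list(cutoff = cutoff, approach = approach, p = p,
         ci95 = c(lower = unname(ci95[1]), upper = unname(ci95[2])),
         width = unname(ci95[2] - ci95[1]), n = n, arm_label = arm_label,
         degenerate = degenerate, note = note),
    class = "tail_estimate")
}

#' @export
print.tail_estimate <- function(x, ...) {
  cat(sprintf("P(V > %g) [%s, arm '%s', n = %d]: %.5f (95%% CI %.5f-%.5f, width %.5f)%s\n",
              x$cutoff, x$approach, x$arm_label, x$n, x$p,
              x$ci95["lower"], x$ci95["upper"], x$width,
              if (x$degenerate) "  [degenerate]" else ""))
  invisible(x)
}

# logit-scale Wald interval around probability p with delta-method variance
logit_ci <- function(p, var_p, level = 0.95) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  if (p <= 0 || p >= 1 || var_p <= 0) return(c(p, p))
  se_l <- sqrt(var_p) / (p * (1 - p))
  stats::plogis(stats::qlogis(p) + c(-1, 1) * z * se_l)
}

#' Tail probability from a fitted lognormal (the "lognormal approach")
#'
#' The event probability P(V > cutoff) is the fitted survival function at the
#' cutoff; since the parameters are maximum-likelihood estimates, so is this
#' probability. Its variance comes from the delta method: the gradient of the
#' survival function with respect to (m, s, t) is propagated through the
#' fit's parameter covariance (including the threshold's uncertainty, which
#' is material). The interval is built on the logit scale and
#' back-transformed so it stays inside (0, 1).
#'
#' @param fit a converged `pph_fit` from [fit_mle_2p()] or [fit_mle_3p()].
#' @param cutoff event cutoff in mL (500 for PPH, 1000 for severe PPH).
#' @param level confidence level.
#' @return A `tail_estimate`.
#' @export
tail_lognormal <- function(fit, cutoff, level = 0.95) {
  if (!inherits(fit, "pph_fit")) stop("`fit` must be a pph_fit", call. = FALSE)
  if (!isTRUE(fit$converged) || is.null(fit$vcov))
    stop("tail_lognormal needs a converged maximum-likelihood fit with a covariance",
         call. = FALSE)
  pr <- fit$params
  p <- slnorm3(cutoff, pr)
  zc <- (log(cutoff - pr$t) - pr$m) / pr$s
  phi <- stats::dnorm(zc)
  grad <- c(m = phi / pr$s,
            s = phi * zc / pr$s,
            t = phi / (pr$s * (cutoff - pr$t)))[seq_len(fit$k)]
  var_p <- drop(t(grad) %*% fit$vcov %*% grad)
  ci <- logit_ci(p, var_p, level)
  new_tail_estimate(cutoff, "lognormal", p, ci, fit$n, fit$arm_label)
}

#' Tail probability from the sample proportion (the "binomial approach")
#'
#' The conventional analysis: the proportion of women whose recorded loss
#' reaches the cutoff. Because recorded volumes heap on round numbers, there
#' is real probability mass exactly at 500 and 1000, so the count uses the
#' clinical ">= cutoff" definition of the event. The default interval is the
#' Wald interval on the logit scale back-transformed (the ML-based interval
#' for a proportion); a plain Wald-on-proportion interval is available via
#' `ci`.
#'
#' @param sample a [blood_loss_sample()] (or numeric vector of volumes).
#' @param cutoff event cutoff in mL.
#' @param ci `"logit"` (default) or `"wald"`.
#' @param level confidence level.
#' @return A `tail_estimate`; zero (or all) events yield a degenerate,
#'   flagged interval rather than an error.
#' @export
tail_binomial <- function(sample, cutoff, ci = c("logit", "wald"),
                          level = 0.95) {
  ci <- match.arg(ci)
  sample <- as_blood_loss_sample(sample)
  v <- sample$volumes
  n <- length(v)
  x <- sum(v >= cutoff)
  p <- x / n
  if (x == 0L || x == n) {
    return(new_tail_estimate(cutoff, "binomial", p, c(p, p), n,
                             sample$arm_label, degenerate = TRUE,
                             note = "no events (or no non-events): interval degenerate"))
  }
  z <- stats::qnorm(1 - (1 - level) / 2)
  bounds <- if (ci == "logit") {
    se_l <- sqrt(1 / x + 1 / (n - x))
    stats::plogis(stats::qlogis(p) + c(-1, 1) * z * se_l)
  } else {
    p + c(-1, 1) * z * sqrt(p * (1 - p) / n)
  }
  new_tail_estimate(cutoff, "binomial", p, bounds, n, sample$arm_label)
}

#' Relative efficiency of the two approaches as a CI width ratio
#'
#' 100 * width(lognormal CI) / width(binomial CI) for the same event in the
#' same arm; values below 100 mean the lognormal approach is the more
#' precise one.
#'
#' @param lognormal_est,binomial_est `tail_estimate`s for the same cutoff
#'   and arm.
#' @return The ratio as a percentage.
#' @export
width_ratio <- function(lognormal_est, binomial_est) {
  for (e in list(lognormal_est, binomial_est))
    if (!inherits(e, "tail_estimate"))
      stop("arguments must be tail_estimate objects", call. = FALSE)
  if (lognormal_est$cutoff != binomial_est$cutoff)
    stop("estimates are for different cutoffs", call. = FALSE)
  if (!identical(lognormal_est$arm_label, binomial_est$arm_label))
    stop("estimates are for different arms", call. = FALSE)
  if (binomial_est$width <= 0)
    stop("binomial interval has zero width", call. = FALSE)
  100 * lognormal_est$width / binomial_est$width
}

#' Ratio of median blood loss between two arms
#'
#' Because the scale of log-volume is stable across studies, comparing arms
#' by their medians is natural: the difference of the log-volume location
#' parameters equals the log of the median ratio on the original scale
#' (thresholds aside). The CI is the normal-theory interval on m1 - m2 (SEs
#' combined in quadrature), exponentiated.
#'
#' @param fit1,fit2 converged `pph_fit`s for the two arms.
#' @param level confidence level.
#' @return List with `ratio`, `ci95`, and the log-scale difference and SE.
#' @export
median_ratio <- function(fit1, fit2, level = 0.95) {
  for (f in list(fit1, fit2))
    if (!inherits(f, "pph_fit") || !isTRUE(f$converged) || is.null(f$se))
      stop("median_ratio needs converged maximum-likelihood fits", call. = FALSE)
  d <- fit1$params$m - fit2$params$m
  se_d <- sqrt(fit1$se[["m"]]^2 + fit2$se[["m"]]^2)
  z <- stats::qnorm(1 - (1 - level) / 2)
  list(ratio = exp(d),
       ci95 = c(lower = exp(d - z * se_d), upper = exp(d + z * se_d)),
       log_diff = d, se_log_diff = se_d)
}

#' Per-arm, per-cutoff estimation table
#'
#' Convenience wrapper producing one row per (arm, cutoff, approach) with the
#' proportion, CI bounds, width, and the lognormal-vs-binomial width ratio.
#'
#' @param samples list of [blood_loss_sample()]s.
#' @param fits list of matching converged `pph_fit`s.
#' @param cutoffs event cutoffs in mL.
#' @return A data.frame shaped like a per-trial proportions table.
#' @export
tail_table <- function(samples, fits, cutoffs = c(500, 1000)) {
  rows <- list()
  for (i in seq_along(samples)) {
    for (cut in cutoffs) {
      bin <- tail_binomial(samples[[i]], cut)
      lgn <- tail_lognormal(fits[[i]], cut)
      wr <- if (bin$width > 0) width_ratio(lgn, bin) else NA_real_
      for (e in list(bin, lgn))
        rows[[length(rows) + 1L]] <- data.frame(
          arm = e$arm_label, cutoff = cut, approach = e$approach,
          proportion = e$p, ci_lower = e$ci95[["lower"]],
          ci_upper = e$ci95[["upper"]], width = e$width,
          width_ratio_pct = if (e$approach == "lognormal") wr else NA_real_)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
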