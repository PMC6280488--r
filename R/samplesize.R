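# Sample-size calculation for a two-arm superiority trial on a
# "blood loss above cutoff" endpoint: the conventional two-proportion
# (binomial) method versus the lognormal-equivalent normal-means method.

#' Specification of a two-arm sample-size problem
#'
#' @param p1 event probability under the control arm.
#' @param p2 event probability under the experimental arm (must be < p1 for
#'   a superiority comparison).
#' @param alpha significance level (one tail's worth when `sided = "one"`).
#' @param power target power.
#' @param sided `"one"` (default, the superiority design) or `"two"`.
#' @param s assumed scale (SD) of log-volume for the lognormal method;
#'   fitted values across trials cluster around 0.7, the default.
#' @param cutoff endpoint cutoff in mL (default 1000, severe PPH). The
#'   lognormal sample size is invariant to it — it cancels in the difference
#'   of the transformed means — but it is carried for the intermediates.
#' @return An object of class `"sample_size_spec"`.
#' @export
sample_size_spec <- function(p1, p2, alpha = 0.05, power = 0.80,
                             sided = c("one", "two"), s = 0.7, cutoff = 1000) {
  sided <- match.arg(sided)
  if (!(is.numeric(p1) && is.numeric(p2) && p2 > 0 && p2 < p1 && p1 < 1))
    stop("need 0 < p2 < p1 < 1 (experimental rate below control rate)",
         call. = FALSE)
  if (!(alpha > 0 && alpha < 0.5)) stop("need 0 < alpha < 0.5", call. = FALSE)
  if (!(power > 0.5 && power < 1)) stop("need 0.5 < power < 1", call. = FALSE)
  if (!(s > 0)) stop("need s > 0", call. = FALSE)
  if (!(cutoff > 0)) stop("need cutoff > 0", call. = FALSE)
  structure(list(p1 = p1, p2 = p2, alpha = alpha, power = power,
                 sided = sided, s = s, cutoff = cutoff),
            class = "sample_size_spec")
}

as_sample_size_spec <- function(x) {
  if (inherits(x, "sample_size_spec")) return(x)
  stop("`spec` must be a sample_size_spec()", call. = FALSE)
}

new_sample_size_result <- function(n_per_group, method, intermediates) {
  structure(list(n_per_group = as.integer(n_per_group),
                 n_total = 2L * as.integer(n_per_group),
                 method = method, intermediates = intermediates),
            class = "sample_size_result")
}

#' @export
print.sample_size_result <- function(x, ...) {
  cat(sprintf("%s method: %d per group, %d total\n",
              x$method, x$n_per_group, x$n_total))
  invisible(x)
}

z_alpha_of <- function(spec) {
  stats::qnorm(1 - if (spec$sided == "one") spec$alpha else spec$alpha / 2)
}

#' Sample size for comparing two proportions (binomial method)
#'
#' Standard normal-approximation formula for the difference of two
#' proportions, pooled variance under the null and unpooled under the
#' alternative, without continuity correction:
#' n/group = (z_(1-a) * sqrt(2*pbar*qbar) + z_power * sqrt(p1 q1 + p2 q2))^2
#'           / (p1 - p2)^2, rounded up.
#' With rates 2% vs 1.5%, one-sided alpha 5% and 80% power this gives 8504
#' per group (17,008 in total).
#'
#' @param spec a [sample_size_spec()].
#' @return A `sample_size_result` with z-quantile intermediates.
#' @export
n_binomial <- function(spec) {
  spec <- as_sample_size_spec(spec)
  za <- z_alpha_of(spec)
  zb <- stats::qnorm(spec$power)
  pbar <- (spec$p1 + spec$p2) / 2
  num <- za * sqrt(2 * pbar * (1 - pbar)) +
    zb * sqrt(spec$p1 * (1 - spec$p1) + spec$p2 * (1 - spec$p2))
  n_real <- (num / (spec$p1 - spec$p2))^2
  new_sample_size_result(ceiling(n_real), "binomial",
                         list(z_alpha = za, z_power = zb, n_real = n_real))
}

#' Log-volume location implied by a tail probability
#'
#' Inverts P(V > cutoff | m, s) = p for the location:
#' m = log(cutoff) - qnorm(1 - p) * s. This converts an event-rate target
#' into a normal-mean target on the log-volume scale, e.g. p = 0.015 at
#' cutoff 1000 with s = 0.7 gives m = 5.3887.
#'
#' @param p tail probability in (0, 1).
#' @param cutoff endpoint cutoff in mL.
#' @param s scale of log-volume.
#' @return The location m.
#' @export
target_location <- function(p, cutoff = 1000, s = 0.7) {
  if (any(p <= 0 | p >= 1))
    stop("`p` must lie strictly inside (0, 1)", call. = FALSE)
  log(cutoff) - stats::qnorm(1 - p) * s
}

#' Sample size by the lognormal-equivalent normal-means method
#'
#' Converts the two event-rate targets into log-volume means via
#' [target_location()] and sizes the two-sample comparison of normal means
#' with known SD s:
#' n/group = 2 * s^2 * (z_(1-a) + z_power)^2 / (m1 - m2)^2, rounded up.
#' The scale cancels (m1 - m2 is proportional to s), so the result depends
#' only on the gap of the normal quantiles of the two rates. For the 2% vs
#' 1.5% example this gives 914 per group, 1828 in total — about 11% of the
#' binomial requirement.
#'
#' @param spec a [sample_size_spec()].
#' @param paper_rounding if `TRUE`, use 4-decimal-place z-quantiles
#'   (2.1701, 2.0537, 1.6449, 0.8416) throughout instead of full precision,
#'   mimicking hand arithmetic with printed tables (gives 913/group, 1826).
#' @return A `sample_size_result`; intermediates record z_alpha, z_power and
#'   the transformed means m1 (for the smaller rate p2) and m2 (for p1).
#' @export
n_lognormal <- function(spec, paper_rounding = FALSE) {
  spec <- as_sample_size_spec(spec)
  r4 <- function(x) if (paper_rounding) round(x, 4) else x
  za <- r4(z_alpha_of(spec))
  zb <- r4(stats::qnorm(spec$power))
  z1 <- r4(stats::qnorm(1 - spec$p2))
  z2 <- r4(stats::qnorm(1 - spec$p1))
  m1 <- r4(log(spec$cutoff) - z1 * spec$s)
  m2 <- r4(log(spec$cutoff) - z2 * spec$s)
  n_real <- 2 * spec$s^2 * (za + zb)^2 / (m1 - m2)^2
  new_sample_size_result(
    ceiling(n_real), "lognormal",
    list(z_alpha = za, z_power = zb, m1 = m1, m2 = m2, n_real = n_real))
}

#' Sample-size savings of the lognormal analysis
#'
#' Ratio of total sample sizes, lognormal over binomial, for the same design
#' spec; the worked 2% vs 1.5% example gives about 0.108.
#'
#' @param binomial,lognormal `sample_size_result`s from the same spec.
#' @return The ratio (dimensionless, < 1 means the lognormal analysis needs
#'   fewer participants).
#' @export
savings_ratio <- function(binomial, lognormal) {
  for (r in list(binomial, lognormal))
    if (!inherits(r, "sample_size_result"))
      stop("arguments must be sample_size_result objects", call. = FALSE)
  lognormal$n_total / binomial$n_total
}
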