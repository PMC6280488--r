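# maximum-likelihood and quantile-matching fitting

test_that("2p MLE has the closed forms and flags degenerate samples", {
  s <- blood_loss_sample(rep(250, 20))
  f <- fit_mle_2p(s)
  expect_false(f$converged)
  expect_true(f$degenerate)
  expect_equal(f$params$m, log(250))

  expect_error(blood_loss_sample(c(400, -5, 300)), "index 2")
})

test_that("2p MLE recovers simulated parameters within Monte Carlo error", {
  n <- 1e5
  set.seed(11)
  v <- rlnorm(n, 5.5, 0.7)
  f <- fit_mle_2p(blood_loss_sample(v))
  expect_lt(abs(f$params$m - 5.5), 3 * 0.7 / sqrt(n))
  expect_lt(abs(f$params$s - 0.7), 3 * 0.7 / sqrt(2 * n))
  expect_equal(f$suffstats$mhat, mean(log(v)))
  expect_equal(f$se[["m"]], f$params$s / sqrt(n))
  expect_equal(f$se[["s"]], f$params$s / sqrt(2 * n))
  # AIC/BIC identities
  expect_equal(f$aic, 2 * 2 - 2 * f$loglik)
  expect_equal(f$bic, 2 * log(n) - 2 * f$loglik)
})

test_that("2p MLE loglik is a local maximum", {
  set.seed(12)
  v <- rlnorm(500, 5.5, 0.7)
  f <- fit_mle_2p(blood_loss_sample(v))
  ll <- function(m, s) sum(dlnorm(v, m, s, log = TRUE))
  for (d in list(c(0.1, 1), c(-0.1, 1), c(0, 1.1), c(0.1, 1.1)))
    expect_gte(f$loglik, ll(f$params$m + d[1], f$params$s * d[2]))
})

test_that("3p MLE recovers published-scale parameters within 3 SE", {
  ps <- c(5.63, 0.63, -47.38)
  set.seed(21)
  v <- rlnorm3(5e4, params_of(ps))
  f <- fit_mle_3p(v)
  expect_true(f$converged)
  est <- c(f$params$m, f$params$s, f$params$t)
  expect_true(all(abs(est - ps) < 3 * f$se))
  # SE of t should be of the order of the published SE (2.55 at trial
  # scale), scaled by sqrt(n_trial / n) ~ sqrt(9000 / 5e4)
  expect_lt(f$se[["t"]], 2.55)
  expect_gt(f$se[["t"]], 0.2)
})

test_that("positive thresholds are fitted as readily as negative ones", {
  ps <- c(5.57, 0.72, 55.14)
  v <- draw_positive(2e4, params_of(ps), seed = 31)
  f <- fit_mle_3p(blood_loss_sample(v))
  expect_true(f$converged)
  expect_gt(f$params$t, 0)
  expect_true(all(abs(c(f$params$m, f$params$s, f$params$t) - ps) < 3 * f$se))
  expect_lt(f$params$t, min(v))
})

test_that("threshold CI covers 0 most of the time when the truth is 2p", {
  reps <- 50
  cover <- 0
  for (r in seq_len(reps)) {
    set.seed(4000 + r)
    v <- rlnorm(1e4, 5.5, 0.7)
    f <- suppressWarnings(fit_mle_3p(v))
    if (!f$converged || f$k < 3) next
    cover <- cover + (f$ci95["t", "lower"] <= 0 && 0 <= f$ci95["t", "upper"])
  }
  expect_gte(cover / reps, 0.85)
})

test_that("3p loglik dominates the nested 2p loglik", {
  for (seed in 1:3) {
    v <- draw_positive(2000, params_of(c(5.5, 0.7, -25)), seed = seed)
    s <- blood_loss_sample(v)
    f2 <- fit_mle_2p(s)
    f3 <- suppressWarnings(fit_mle_3p(s))
    expect_gte(f3$loglik, f2$loglik - 1e-6)
  }
})

test_that("profile optimum matches a brute-force grid search over t", {
  for (seed in 1:3) {
    v <- draw_positive(400, params_of(c(5.5, 0.7, -20)), seed = 100 + seed)
    f <- fit_mle_3p(v, se = FALSE)
    grid <- seq(-200, min(v) - 1e-6 * min(v), by = 0.25)
    pl <- vapply(grid, function(t) pphloss:::profile_loglik_t(v, t),
                 numeric(1))
    expect_lt(abs(f$params$t - grid[which.max(pl)]), 0.25 + 1e-9)
  }
})

test_that("quantile matching round-trips the observational-study fit", {
  probs <- c(0.05, 0.25, 0.50, 0.75, 0.95)
  truth <- lognormal_params(5.47, 0.66, 0)
  spec <- quantile_spec(probs, qlnorm3(probs, truth))
  f <- fit_from_quantiles(spec, "lognormal2p")
  expect_lt(abs(f$params$m - 5.47), 1e-6)
  expect_lt(abs(f$params$s - 0.66), 1e-6)
  expect_lt(f$rss, 1e-8)
  expect_null(f$se)
  expect_true(is.na(f$loglik))

  truth3 <- lognormal_params(5.5, 0.7, -30)
  spec3 <- quantile_spec(probs, qlnorm3(probs, truth3))
  f3 <- fit_from_quantiles(spec3, "lognormal3p")
  expect_lt(abs(f3$params$t - (-30)), 1e-3)
  expect_lt(f3$rss, 1e-6)
})

test_that("two pairs solve the 2p quantile fit in closed form", {
  probs <- c(0.25, 0.9)
  q <- qlnorm3(probs, lognormal_params(5.2, 0.8, 0))
  z <- qnorm(probs)
  s_cf <- (log(q[2]) - log(q[1])) / (z[2] - z[1])
  m_cf <- log(q[1]) - s_cf * z[1]
  f <- fit_from_quantiles(quantile_spec(probs, q), "lognormal2p")
  expect_equal(f$params$m, m_cf, tolerance = 1e-8)
  expect_equal(f$params$s, s_cf, tolerance = 1e-8)
  # fewer pairs than parameters is rejected
  expect_error(fit_from_quantiles(quantile_spec(probs, q), "lognormal3p"),
               "at least 3")
})

test_that("quantile-matching is stable under small perturbations", {
  probs <- c(0.05, 0.25, 0.50, 0.75, 0.95)
  q0 <- qlnorm3(probs, lognormal_params(5.47, 0.66, 0))
  base <- fit_from_quantiles(quantile_spec(probs, q0), "lognormal2p")
  set.seed(55)
  for (r in 1:5) {
    q <- q0 * (1 + runif(5, -0.01, 0.01))
    f <- fit_from_quantiles(quantile_spec(probs, sort(q)), "lognormal2p")
    expect_lt(abs(f$params$m - base$params$m), 0.05)
    expect_lt(abs(f$params$s - base$params$s), 0.05)
  }
})

test_that("model ranking prefers the generating model", {
  # data with a threshold far from 0: 3p must win on AIC
  v <- draw_positive(5000, params_of(c(5.63, 0.63, -47.38)), seed = 61)
  s <- blood_loss_sample(v)
  cmp <- compare_fits(fit_mle_2p(s), suppressWarnings(fit_mle_3p(s)))
  expect_identical(cmp$model[1], "lognormal3p")
  expect_identical(cmp$delta_aic[1], 0)
  # data from t = 0: BIC should usually prefer the smaller model
  wins <- 0
  for (r in 1:10) {
    set.seed(700 + r)
    v0 <- rlnorm(2000, 5.5, 0.7)
    s0 <- blood_loss_sample(v0)
    cmp0 <- compare_fits(fit_mle_2p(s0), suppressWarnings(fit_mle_3p(s0)))
    wins <- wins + (cmp0$bic[cmp0$model == "lognormal2p"] <=
                      cmp0$bic[cmp0$model == "lognormal3p"])
  }
  expect_gte(wins, 6)
  # single input and n mismatch
  one <- compare_fits(fit_mle_2p(s))
  expect_identical(nrow(one), 1L)
  expect_identical(one$delta_aic, 0)
  expect_error(compare_fits(fit_mle_2p(s), fit_mle_2p(blood_loss_sample(v[1:100]))),
               "n mismatch")
})
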