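# sample sizes: binomial two-proportion vs lognormal normal-means methods

test_that("binomial worked example gives 8504 per group, 17008 total", {
  spec <- sample_size_spec(p1 = 0.02, p2 = 0.015, alpha = 0.05,
                           power = 0.80, sided = "one")
  r <- n_binomial(spec)
  expect_identical(r$n_per_group, 8504L)
  expect_identical(r$n_total, 17008L)
  expect_equal(r$intermediates$z_alpha, qnorm(0.95))
})

test_that("lognormal worked example gives the published transformed means and total", {
  spec <- sample_size_spec(0.02, 0.015, s = 0.7, cutoff = 1000)
  r <- n_lognormal(spec)
  expect_equal(round(r$intermediates$m1, 4), 5.3887)
  expect_equal(round(r$intermediates$m2, 4), 5.4701)
  expect_true(r$n_total >= 1828 && r$n_total <= 1832)
  expect_identical(r$n_total, 2L * r$n_per_group)
  # hand arithmetic with 4-dp z tables lands slightly lower still
  r4 <- n_lognormal(spec, paper_rounding = TRUE)
  expect_identical(r4$n_total, 1826L)
  expect_equal(r4$intermediates$z_alpha, 1.6449)
})

test_that("target_location inverts the tail identity", {
  expect_equal(round(target_location(0.015, 1000, 0.7), 4), 5.3887)
  expect_equal(round(target_location(0.02, 1000, 0.7), 4), 5.4701)
  expect_equal(target_location(0.5, 1000, 0.33), log(1000))
  # self-consistency: the location reproduces the tail probability
  m <- target_location(0.03, 500, 0.8)
  expect_equal(slnorm3(500, lognormal_params(m, 0.8, 0)), 0.03,
               tolerance = 1e-12)
})

test_that("lognormal n is invariant to cutoff and scale", {
  base <- n_lognormal(sample_size_spec(0.02, 0.015, s = 0.7, cutoff = 1000))
  alt_cut <- n_lognormal(sample_size_spec(0.02, 0.015, s = 0.7, cutoff = 500))
  alt_s <- n_lognormal(sample_size_spec(0.02, 0.015, s = 1.4, cutoff = 1000))
  expect_identical(base$n_per_group, alt_cut$n_per_group)
  expect_identical(base$n_per_group, alt_s$n_per_group)
})

test_that("binomial n scales like 1/delta^2 and responds to alpha and power", {
  n1 <- n_binomial(sample_size_spec(0.02, 0.015))$n_per_group
  n2 <- n_binomial(sample_size_spec(0.02, 0.0175))$n_per_group
  expect_gt(n2 / n1, 3.5)
  expect_lt(n2 / n1, 4.5)
  expect_gt(n_binomial(sample_size_spec(0.02, 0.015, power = 0.9))$n_per_group,
            n1)
  expect_gt(n_binomial(sample_size_spec(0.02, 0.015, alpha = 0.01))$n_per_group,
            n1)
  expect_gt(n_binomial(sample_size_spec(0.02, 0.015, sided = "two"))$n_per_group,
            n1)
})

test_that("savings ratio reproduces the ~0.108 worked example and stays below 1", {
  spec <- sample_size_spec(0.02, 0.015)
  ratio <- savings_ratio(n_binomial(spec), n_lognormal(spec))
  expect_lt(abs(ratio - 1832 / 17008), 0.01)
  for (p1 in c(0.02, 0.035, 0.05)) for (p2 in c(0.01, 0.015)) {
    sp <- sample_size_spec(p1, p2)
    expect_lt(savings_ratio(n_binomial(sp), n_lognormal(sp)), 1)
  }
})

test_that("both methods deliver approximately the nominal power by simulation", {
  reps <- 2000
  # binomial method: one-sided normal-approximation test at the returned n
  spec <- sample_size_spec(0.05, 0.03)            # smaller n, faster sim
  nb <- n_binomial(spec)$n_per_group
  set.seed(61)
  hits <- replicate(reps, {
    x1 <- rbinom(1, nb, spec$p1)
    x2 <- rbinom(1, nb, spec$p2)
    p1 <- x1 / nb; p2 <- x2 / nb; pb <- (x1 + x2) / (2 * nb)
    z <- (p1 - p2) / sqrt(2 * pb * (1 - pb) / nb)
    z > qnorm(0.95)
  })
  expect_lt(abs(mean(hits) - 0.80), 0.03)

  # lognormal method: two-sample z-test on log-volumes at the returned n
  nl <- n_lognormal(spec)$n_per_group
  m1 <- target_location(spec$p2, 1000, 0.7)
  m2 <- target_location(spec$p1, 1000, 0.7)
  set.seed(62)
  hits_l <- replicate(reps, {
    u1 <- rnorm(nl, m2, 0.7)      # control, larger rate => larger mean
    u2 <- rnorm(nl, m1, 0.7)
    z <- (mean(u1) - mean(u2)) / sqrt(0.7^2 / nl + 0.7^2 / nl)
    z > qnorm(0.95)
  })
  expect_lt(abs(mean(hits_l) - 0.80), 0.03)
})

test_that("degenerate specs are rejected", {
  expect_error(sample_size_spec(0.02, 0.02), "p2 < p1")
  expect_error(sample_size_spec(0.015, 0.02), "p2 < p1")
  expect_error(sample_size_spec(0.02, 0.015, alpha = 0.6), "alpha")
  expect_error(sample_size_spec(0.02, 0.015, power = 0.4), "power")
})
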