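# measurement diagnostics and plot data

test_that("digit preference expects exactly (0.10, 0.02, 0.01) and nests", {
  s <- blood_loss_sample(c(123, 250, 400, 517))
  rep1 <- digit_preference(s)
  expect_identical(rep1$expected_freq, c(0.10, 0.02, 0.01))
  # all multiples of 100: observed all 1
  rep2 <- digit_preference(blood_loss_sample(c(100, 300, 1200)))
  expect_identical(rep2$observed_freq, c(1, 1, 1))
  # continuous data rounded to integer: observed ~ expected
  set.seed(5)
  v <- round(rlnorm(1e5, 5.5, 0.7))
  rep3 <- digit_preference(blood_loss_sample(v[v > 0]))
  for (i in 1:3) {
    p <- rep3$expected_freq[i]
    expect_lt(abs(rep3$observed_freq[i] - p), 3 * sqrt(p * (1 - p) / 1e5))
  }
  # nesting holds on heaped data
  tr <- generate_blood_loss(trial_scenario("misoprostol", n_per_arm = 5000,
                                           seed = 2))
  rep4 <- digit_preference(tr$samples[[1]])
  expect_true(rep4$observed_freq[3] <= rep4$observed_freq[2])
  expect_true(rep4$observed_freq[2] <= rep4$observed_freq[1])
})

test_that("LOD assessment accepts true uniform noise and rejects the lognormal body", {
  set.seed(71)
  body <- rlnorm(2000, 5.5, 0.7)
  uni <- runif(300, 0, 50)
  mixed <- blood_loss_sample(c(uni, body[body >= 50]))
  la <- lod_assess(mixed)
  expect_true(la$flag[la$candidate_lod == 50])
  # un-smeared small values from a lognormal body are not uniform
  set.seed(72)
  v <- rlnorm(50000, 4.4, 0.9)
  lb <- lod_assess(blood_loss_sample(v))
  expect_false(lb$flag[lb$candidate_lod == 50])
  # too few observations below the candidate: skipped with a note
  few <- lod_assess(blood_loss_sample(c(10, 20, 600, 700, 800)))
  expect_true(is.na(few$flag[few$candidate_lod == 50]))
  expect_match(few$note[few$candidate_lod == 50], "skipped")
})

test_that("LOD flag has roughly nominal type-I error on true uniform noise", {
  reps <- 200
  set.seed(73)
  false_alarm <- mean(replicate(reps, {
    x <- c(runif(250, 0, 50), runif(400, 60, 2000))
    la <- lod_assess(blood_loss_sample(x), candidates = 50)
    !la$flag[1]
  }))
  expect_lt(false_alarm, 0.10)
})

test_that("probability plot keeps self-simulated data inside the band", {
  p <- params_of(c(5.58, 0.71, -8.60))
  v <- draw_positive(3000, p, seed = 81)
  f <- fit_mle_3p(blood_loss_sample(v))
  pd <- probability_plot_data(blood_loss_sample(v), f)
  expect_true(!is.unsorted(pd$points$x))
  expect_true(all(pd$points$lower <= pd$points$upper))
  inside <- mean(pd$points$x >= pd$points$lower &
                   pd$points$x <= pd$points$upper)
  expect_gte(inside, 0.95)
})

test_that("LOD smearing pushes sub-50 points outside the probability-plot band", {
  cfg <- synthetic_config(
    list(a = list(params = lognormal_params(5.63, 0.63, -47.38), n = 8000)),
    lod = 50, seed = 82)
  tr <- generate_blood_loss(cfg)
  f <- suppressWarnings(fit_mle_3p(tr$samples$a))
  pd <- probability_plot_data(tr$samples$a, f)
  low <- pd$points$x < 50
  outside_low <- mean(pd$points$x[low] < pd$points$lower[low] |
                        pd$points$x[low] > pd$points$upper[low])
  expect_gt(outside_low, 0.25)
})

test_that("qq data have unit slope for self-simulated data and are deterministic", {
  p <- params_of(c(5.19, 0.83, -22.25))
  v <- draw_positive(1e4, p, seed = 83)
  s <- blood_loss_sample(v)
  f <- fit_mle_3p(s)
  qd <- qq_data(s, f)
  slope <- coef(lm(y ~ x, data = qd$points))[["x"]]
  expect_lt(abs(slope - 1), 0.02)
  expect_identical(qq_data(s, f)$points, qd$points)   # pure function of inputs
})

test_that("cdf overlay bands behave on trial-scale data", {
  p <- params_of(c(5.58, 0.71, -8.60))
  v <- draw_positive(9000, p, seed = 84)
  s <- blood_loss_sample(v)
  f <- fit_mle_3p(s)
  grid <- seq(400, 1400, by = 50)
  ov <- cdf_overlay_data(s, f, grid)
  expect_identical(nrow(ov$points), length(grid))
  with(ov$points, {
    expect_true(all(ecdf_lower <= ecdf & ecdf <= ecdf_upper))
    expect_true(all(fitted_lower <= fitted & fitted <= fitted_upper))
    # the lognormal band is the narrower one across the clinical window
    expect_true(all(fitted_upper - fitted_lower < ecdf_upper - ecdf_lower))
    # both curves inside each other's bands for self-simulated data
    expect_true(mean(fitted >= ecdf_lower & fitted <= ecdf_upper) > 0.9)
  })
  one <- cdf_overlay_data(s, f, 800)
  expect_identical(nrow(one$points), 1L)
})
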