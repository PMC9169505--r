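test_that("the CV-difference calculator reproduces its arithmetic example", {
  # pilot inputs: CV_PRE = 0.0598, CV_ONLINE = 0.367
  r <- n_cv_difference(0.0598, 0.367, alpha = 0.05, power = 0.80)
  expect_equal(r$n, 12)
  # the pieces of the formula
  expect_equal((qnorm(0.975) + qnorm(0.8))^2 * (0.0598^2 + 0.367^2) /
                 (0.367 - 0.0598)^2, 11.4996, tolerance = 1e-4)
  expect_error(n_cv_difference(0.2, 0.2), "infinite")
  # quadrupling the CV separation at fixed cv-square sum shrinks n ~ 4x
  n1 <- n_cv_difference(0.10, 0.30)$n
  n2 <- n_cv_difference(0.05, 0.45)$n   # separation 0.4 vs 0.2, sum ~ similar
  expect_lt(n2, n1)
})

test_that("the repeated-measures calculator reproduces its arithmetic example", {
  # pilot inputs: total variance 0.08731 + 1.09283, icc 0.07398, m = 11
  r <- n_repeated_measures(1.18014, 0.07398, m = 11, delta = 0.4,
                           alpha = 0.05, power = 0.80, groups = 2)
  expect_equal(r$n, 19)
  # icc = 0 reduces to the standard two-mean formula divided by m
  n0 <- n_repeated_measures(1, 0, m = 5, delta = 0.5)$n
  expect_equal(n0, ceiling(2 * (qnorm(0.975) + qnorm(0.8))^2 * 1 / (5 * 0.25)))
  expect_error(n_repeated_measures(1, 0.1, 5, delta = 0), "> 0")
  expect_error(n_repeated_measures(1, 1.2, 5, delta = 0.4), "icc")
})

test_that("the dose-contrast calculator reproduces its arithmetic example", {
  means <- c(5, 4.83, 5, 5.17, 5.17, 5.5, 5.67, 5.67, 5.67, 5.67, 5.83)
  ctr <- c(-4, -4, 0.5, 0.5, 1, 1, 1, 1, 1, 1, 1)
  expect_equal(sum(ctr), 0)
  expect_equal(sum(ctr^2), 39.5)
  expect_equal(sum(ctr * means), 4.945, tolerance = 1e-10)
  r <- n_dose_contrast(means, ctr, sigma2 = 0.547, alpha = 0.05, power = 0.90)
  expect_equal(r$n, 10)
  # scale invariance in the contrasts
  expect_equal(n_dose_contrast(means, 3 * ctr, 0.547, 0.05, 0.90)$n, 10)
  # contrasts orthogonal to the profile have no effect to detect
  expect_error(n_dose_contrast(c(1, 1, 1), c(1, -2, 1), 1), "orthogonal")
})

test_that("all calculators are monotone in power, alpha and effect", {
  powers <- c(0.75, 0.80, 0.90, 0.99)
  alphas <- c(0.01, 0.05, 0.10)
  for (fn in list(
    function(a, p) n_cv_difference(0.0598, 0.367, alpha = a, power = p)$n,
    function(a, p) n_repeated_measures(1.18, 0.074, 11, 0.4, alpha = a, power = p)$n,
    function(a, p) n_dose_contrast(c(5, 5.2, 5.6), c(-1, 0, 1), 0.55,
                                   alpha = a, power = p)$n)) {
    for (a in alphas) {
      expect_true(all(diff(vapply(powers, fn, numeric(1), a = a)) >= 0))
    }
    for (p in powers) {
      expect_true(all(diff(vapply(alphas, fn, numeric(1), p = p)) <= 0))
    }
  }
  # nonincreasing in effect magnitude
  deltas <- c(0.2, 0.4, 0.8)
  ns <- vapply(deltas, function(d) n_repeated_measures(1.18, 0.074, 11, d)$n,
               numeric(1))
  expect_true(all(diff(ns) <= 0))
  # the grid helper lays out the conventional reporting table
  g <- samplesize_grid(n_cv_difference, cv1 = 0.0598, cv2 = 0.367)
  expect_equal(dim(g), c(4L, 3L))
  expect_equal(g["80%", "5%"], 12)
  expect_true(all(apply(g, 2, diff) >= 0))
})

test_that("posterior sample size collapses to the point version on point masses", {
  inputs <- data.frame(cv1 = rep(0.0598, 50), cv2 = rep(0.367, 50))
  ps <- posterior_sample_size(inputs, "cv_difference", alpha = 0.05, power = 0.80)
  expect_equal(ps$median, 12)
  expect_true(all(ps$n_draws == 12))
  expect_equal(ps$excluded_fraction, 0)
  expect_true(all(diff(ps$plan) >= 0))       # sequential plan nondecreasing
})

test_that("posterior sample size is monotone and tracks the draw distribution", {
  set.seed(71)
  # stochastically larger deltas give stochastically smaller n
  d_small <- data.frame(sigma2_total = 1.18, icc = 0.074,
                        delta = runif(400, 0.3, 0.5))
  d_large <- transform(d_small, delta = delta + 0.3)
  ps_s <- posterior_sample_size(d_small, "repeated_measures", m = 11)
  ps_l <- posterior_sample_size(d_large, "repeated_measures", m = 11)
  expect_lt(ps_l$median, ps_s$median)
  expect_true(all(ps_l$plan <= ps_s$plan))
  # sigma2 draws around 1.18: the posterior median n sits near the point value
  sg <- data.frame(sigma2_total = rgamma(2000, shape = 40, rate = 40 / 1.18),
                   icc = 0.07398, delta = 0.4)
  ps_g <- posterior_sample_size(sg, "repeated_measures", m = 11)
  point <- n_repeated_measures(median(sg$sigma2_total), 0.07398, 11, 0.4)$n
  expect_lte(abs(ps_g$median - point), 2)
  # invalid draws are excluded and counted
  bad <- data.frame(sigma2_total = 1.18, icc = 0.074,
                    delta = c(rep(0.4, 30), rep(-1, 10)))
  ps_b <- posterior_sample_size(bad, "repeated_measures", m = 11)
  expect_equal(ps_b$excluded_fraction, 0.25)
})

test_that("the intra-class correlation follows its variance-ratio definition", {
  expect_equal(icc(1, 1), 0.5)
  expect_equal(icc(0, 2), 0)
  expect_equal(icc(0.08731, 1.09283), 0.08731 / (0.08731 + 1.09283))
  expect_error(icc(-1, 2), ">= 0")
})
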