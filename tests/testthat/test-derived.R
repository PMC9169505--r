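test_that("DMin/DMax solve the logistic threshold crossings exactly", {
  # worked example: c=4, f=2, d=1, e=11, delta=0.4
  dd <- dmin_dmax(4, 2, 1, 11, 0.4)
  expect_equal(dd$dmin, 11 - log(4), tolerance = 1e-9)
  expect_equal(dd$dmax, 11 + log(4), tolerance = 1e-9)
  expect_equal(dd$dmin, 9.6137, tolerance = 1e-4)
  expect_equal(dd$dmax, 12.3863, tolerance = 1e-4)
  # against the independent root-finding oracle
  expect_equal(dd$dmin, logistic_time_at(4, 2, 1, 11, 2 + 0.4), tolerance = 1e-8)
  expect_equal(dd$dmax, logistic_time_at(4, 2, 1, 11, 4 - 0.4), tolerance = 1e-8)
  # randomised identity check: G_O(DMin) = f + delta, G_O(DMax) = c - delta
  set.seed(61)
  for (r in 1:50) {
    f <- runif(1, 1, 5); gain <- runif(1, 0.5, 4); c <- f + gain
    d <- runif(1, 0.2, 3); e <- runif(1, 8, 14)
    delta <- runif(1, 0.05, 0.49) * gain / 2
    dd <- dmin_dmax(c, f, d, e, delta)
    gO <- function(j) f + (c - f) / (1 + exp(-d * (j - e)))
    expect_lt(abs(gO(dd$dmin) - (f + delta)), 1e-9)
    expect_lt(abs(gO(dd$dmax) - (c - delta)), 1e-9)
    expect_equal(dd$dmin + dd$dmax, 2 * e, tolerance = 1e-9)  # symmetry about e
  }
  # delta -> (c-f)/2 collapses both times onto the inflection point
  eps <- 1e-9
  dd_lim <- dmin_dmax(4, 2, 1, 11, 1 - eps)
  expect_equal(dd_lim$dmin, 11, tolerance = 1e-6)
  expect_equal(dd_lim$dmax, 11, tolerance = 1e-6)
  expect_error(dmin_dmax(4, 2, 0, 11, 0.4), "d is 0")
  expect_error(dmin_dmax(4, 2, 1, 11, 1.2), "c - f > 2\\*delta")
  expect_error(dmin_dmax(4, 2, 1, 11, -0.1), "> 0")
})

test_that("gain and carry-over are the stated differences, draw by draw", {
  gc <- gain_and_carryover(list(a = 5, c = 4, f = 2, g = 5))
  expect_equal(gc$gain, 2)
  expect_equal(gc$co, 0)
  set.seed(62)
  draws <- list(a = rnorm(500, 5), c = rnorm(500, 4), f = rnorm(500, 2),
                g = rnorm(500, 5))
  gcd <- gain_and_carryover(draws)
  expect_equal(mean(gcd$gain), mean(draws$c) - mean(draws$f))  # linearity
  expect_equal(length(gcd$co), 500L)
})

test_that("minimum clinical efficacy is half the PEI effect in both modes", {
  # descriptive: engineer a mean online displacement of exactly 0.8
  raw_int <- rep(5, 21)
  raw_int[7:16] <- c(4, 4, 4, 4, 4, 4, 4, 4, 5, 5)   # mean online drop 0.8
  df <- do.call(rbind, lapply(1:3, function(s) {
    data.frame(subject = "S01", session = s,
               treatment = c("PEI", "SP", "tP")[s], timepoint = 1:21,
               tlq = raw_int)
  }))
  mce <- minimum_clinical_efficacy(preprocess_tlq(as_tlq_data(df)))
  expect_equal(mce$delta, 0.4)
  expect_equal(mce$provenance, "descriptive")
  # zero PEI effect is flagged
  flat <- df
  flat$tlq <- 5
  expect_error(minimum_clinical_efficacy(preprocess_tlq(as_tlq_data(flat))),
               "non-positive")
  # posterior mode: constant gain 1 at PEI gives a point mass at 0.5
  fake <- make_fake_fit(list("c.Intercept" = 5, "f.Intercept" = 4))
  mp <- minimum_clinical_efficacy(fake)
  expect_equal(mp$delta, 0.5)
  expect_equal(unname(mp$ci), c(0.5, 0.5))
  expect_equal(mp$provenance, "posterior")
})

test_that("individuals control chart reproduces the moving-range arithmetic", {
  cc <- control_chart(c(4, 5, 4, 5, 4))
  expect_equal(cc$center, 4.4)
  expect_equal(cc$lower, 4.4 - 2.66, tolerance = 1e-12)
  expect_equal(cc$upper, 4.4 + 2.66, tolerance = 1e-12)
  expect_length(cc$out_of_limits, 0L)
  const <- control_chart(rep(3, 10))
  expect_equal(const$lower, const$center)
  expect_length(const$out_of_limits, 0L)
  spiked <- control_chart(c(4, 5, 4, 5, 4, 5, 4, 20))
  expect_true(8L %in% spiked$out_of_limits)
  expect_error(control_chart(4), "at least 2")
})

test_that("treatment contrasts match the closed-form Normal oracle", {
  set.seed(63)
  fake <- make_fake_fit(list("c.tP" = rnorm(20000, 0.5, 0.25)))
  tc <- treatment_contrast(fake, c("tP", "PEI"), timepoint = 16, delta = 0.4)
  # at T16 the logistic sits at its plateau, so diff ~ N(0.5, 0.25^2)
  expect_equal(tc$p_greater, 1 - pnorm((0.4 - 0.5) / 0.25), tolerance = 0.02)
  expect_equal(tc$mean, 0.5, tolerance = 0.01)
  # constant difference: probabilities are degenerate
  fixed <- make_fake_fit(list("c.tP" = 1))
  tf <- treatment_contrast(fixed, c("tP", "PEI"), timepoint = 16, delta = 0.4)
  expect_equal(tf$p_greater, 1)
  expect_equal(tf$p_equivalent, 0)
  # identical parameters: difference degenerate at 0
  same <- make_fake_fit(list())
  ts <- treatment_contrast(same, c("SP", "PEI"), timepoint = 12, delta = 0.4)
  expect_equal(ts$mean, 0)
  expect_equal(ts$p_equivalent, 1)
  # P(diff > delta) is nonincreasing in delta
  ps <- vapply(c(0.1, 0.3, 0.5, 0.8), function(dl) {
    treatment_contrast(fake, c("tP", "PEI"), timepoint = 16, delta = dl)$p_greater
  }, numeric(1))
  expect_true(all(diff(ps) <= 0))
  expect_error(treatment_contrast(fake, c("tP", "XX")), "unknown treatment pair")
})

test_that("dose is linear in the probe timeline with onset at T6", {
  expect_equal(dose_at(6, intensity = 2)$dose, 0)
  expect_equal(dose_at(16, intensity = 2)$dose, 40)      # 2 mA x 20 min
  expect_equal(dose_at(16, intensity = 2)$minutes, 20)
  # composition with the DMin example
  dmin <- dmin_dmax(4, 2, 1, 11, 0.4)$dmin
  expect_equal(dose_at(dmin, intensity = 2)$dose, 2 * 2 * (dmin - 6))
  expect_equal(dose_at(dmin, intensity = 2)$dose, 14.455, tolerance = 1e-3)
  # linear in intensity and time
  expect_equal(dose_at(11, intensity = 4)$dose, 2 * dose_at(11, intensity = 2)$dose)
  expect_error(dose_at(4), "precedes stimulation onset")
})

test_that("derived-quantity tables summarise posterior functionals coherently", {
  fit <- tiny_fit()
  dq <- derive_quantities(fit, treatment = "tP")
  expect_setequal(dq$quantity,
                  c("gain", "co", "delta", "dmin", "dmax", "dose_min", "dose_max"))
  expect_true(all(dq$lower <= dq$mean & dq$mean <= dq$upper))
  dmin <- dq$mean[dq$quantity == "dmin"]
  dmax <- dq$mean[dq$quantity == "dmax"]
  expect_lt(dmin, dmax)
  expect_gte(attr(dq, "excluded_fraction"), 0)
  expect_lt(attr(dq, "excluded_fraction"), 0.5)
})
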