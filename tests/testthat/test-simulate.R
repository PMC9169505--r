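test_that("simulated cohorts honour the design schema and determinism", {
  d <- simulate_tlq(6, seed = 4)
  expect_s3_class(d, "tlq_data")
  expect_equal(nrow(d), 378L)                       # 6 x 3 x 21
  expect_equal(nrow(series_table(d)), 18L)
  expect_true(all(d$tlq >= 1 & d$tlq <= 10))
  expect_true(all(d$tlq == round(d$tlq)))
  # Williams crossover: every subject sees all three treatments
  st <- series_table(d)
  for (s in unique(st$subject)) {
    expect_setequal(as.character(st$treatment[st$subject == s]), asb_treatments())
  }
  expect_identical(simulate_tlq(6, seed = 4), d)
  expect_false(identical(simulate_tlq(6, seed = 5)$tlq, d$tlq))
})

test_that("with all variation switched off PEI series are identical and equal the curve", {
  truth <- flat_truth()
  truth$beta[, "Start"] <- 0
  d <- simulate_tlq(6, truth = truth, seed = 6)
  st <- series_table(d)
  pei <- which(st$treatment == "PEI")
  ys <- lapply(pei, function(r) {
    d$y_true[d$subject == st$subject[r] & d$session == st$session[r]]
  })
  for (k in seq_along(ys)[-1]) expect_equal(ys[[k]], ys[[1]])
  # the noiseless transformed trajectory is the mean curve itself
  p <- curve_params(truth$beta, "PEI", start = st$start[pei[1]])
  expect_equal(ys[[1]], mu_curve(1:21, p))
  # and the Likert reconstruction is that curve, inverted and rounded
  raw <- d$tlq[d$subject == st$subject[pei[1]] & d$session == st$session[pei[1]]]
  cont <- invert_transform(ys[[1]], start = st$start[pei[1]])
  expect_equal(raw, pmin(pmax(sign(cont) * floor(abs(cont) + 0.5), 1), 10))
})

test_that("preprocessing the simulated Likert data recovers the latent response", {
  d <- preprocess_tlq(simulate_tlq(10, seed = 8))
  # the transform anchors T1 at the shift constant, so the PRE segment is
  # recovered only up to the per-series offset 5 - y_true(T1); from T6 onward
  # the references are reconstructed values, and the recovery error is the
  # rounding error of the point minus that of its reference (< 1 absolute)
  # wherever the series stays strictly inside the 1-10 scale
  err <- abs(d$y - d$y_true)
  key <- paste(d$subject, d$session)
  interior_series <- vapply(split(d$tlq, key), function(v) all(v > 1 & v < 10),
                            logical(1))
  interior <- interior_series[key] & d$timepoint >= 6
  expect_true(any(interior))
  expect_lt(max(err[interior]), 1 + 1e-9)
  expect_true(mean(err[d$timepoint >= 6] < 0.5) > 0.5)
  # the PRE offset equals 5 minus the latent T1 value, up to rounding
  off <- (5 - d$y_true[d$timepoint == 1])
  err_pre <- abs(d$y[d$timepoint == 3] - d$y_true[d$timepoint == 3] - off)
  expect_lt(max(err_pre[interior_series]), 1 + 1e-9)
  # exact at the series anchor
  expect_true(all(d$y[d$timepoint == 1] == 5))
  # an integer-valued noiseless truth round-trips exactly
  truth <- flat_truth()
  truth$beta[, "Intercept"] <- c(a = 5, b = 0, c = 6, d = 30, e = 11.5,
                                 f = 5, g = 5, h = 50)
  truth$beta[, c("SP", "tP", "Start")] <- 0
  di <- preprocess_tlq(simulate_tlq(2, truth = truth, seed = 9))
  expect_equal(di$y, di$y_true, tolerance = 1e-5)
})

test_that("a large simulated treatment effect shows up at the online plateau", {
  truth <- asb_truth(sigma2 = 0.05, re_sd = c(c = 0, e = 0, f = 0, T = 0),
                     occasion_sd = 0)
  truth$beta[, "Start"] <- 0
  truth$beta["c", "tP"] <- 1
  truth$beta["e", ] <- c(9, 0, 0, 0)
  d <- preprocess_tlq(simulate_tlq(60, truth = truth, seed = 10))
  seg <- segment_of(d$timepoint)
  plateau <- seg == "online" & d$timepoint >= 13   # logistic ~ plateau there
  diff <- mean(d$y[plateau & d$treatment == "tP"]) -
    mean(d$y[plateau & d$treatment == "PEI"])
  expect_equal(diff, 1, tolerance = 0.1)           # the plateau effect
})

test_that("excessive truth values trigger the clamping warning", {
  truth <- asb_truth()
  truth$beta["c", "Intercept"] <- 15                # pushes raws far below 1
  expect_warning(simulate_tlq(4, truth = truth, seed = 11), "clamped")
})

test_that("parameter recovery returns one row per replicate and parameter", {
  rec <- parameter_recovery(reps = 1, n_subjects = 4, seed = 30,
                            chains = 2, iter = 300, burn_in = 150)
  expect_equal(nrow(rec), 32L)                      # 8 quantities x 4 coefficients
  expect_setequal(unique(rec$rep), 1L)
  expect_true(all(c("truth", "estimate", "lower", "upper", "covered") %in% names(rec)))
  expect_equal(attr(rec, "failures"), 0L)
  rs <- recovery_summary(rec)
  expect_equal(nrow(rs), 32L)
  expect_true(all(rs$coverage >= 0 & rs$coverage <= 1))
})

test_that("operating characteristics separate null from large-effect designs", {
  null_truth <- asb_truth()
  null_truth$beta["c", "tP"] <- 0
  null_truth$beta["e", "tP"] <- 0
  big_truth <- asb_truth()
  big_truth$beta["c", "tP"] <- 1.5
  oc <- design_operating_characteristics(
    list(null = list(truth = null_truth, interims = c(8, 14)),
         large = list(truth = big_truth, interims = c(8, 14))),
    reps = 8, delta = 0.4, seed = 20)
  expect_equal(nrow(oc), 2L)
  expect_gt(oc$superiority_rate[oc$scenario == "large"],
            oc$superiority_rate[oc$scenario == "null"])
  # under the null, crossing a 95% credibility bar should stay rare
  expect_lte(oc$superiority_rate[oc$scenario == "null"], 0.25)
  expect_true(all(oc$mean_final_n <= 14))
})
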