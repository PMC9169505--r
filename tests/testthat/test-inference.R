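test_that("Gelman-Rubin follows its closed form and separates mixed from split chains", {
  set.seed(51)
  ch <- rnorm(400)
  # exact duplicate chains: B = 0 so the statistic is sqrt((n-1)/n)
  expect_equal(gelman_rubin(cbind(ch, ch)), sqrt(399 / 400))
  # two long iid chains from one distribution stay below 1.05
  expect_lt(gelman_rubin(cbind(rnorm(5000), rnorm(5000))), 1.05)
  # chains around different locations blow up
  expect_gt(gelman_rubin(cbind(rnorm(2000, 0), rnorm(2000, 10))), 1.2)
  expect_error(gelman_rubin(matrix(rnorm(100), ncol = 1)), "at least 2 chains")
  expect_equal(gelman_rubin(list(ch, ch)), sqrt(399 / 400))
})

test_that("Geweke flags drift but not stationary or constant chains", {
  expect_equal(geweke(rep(2.5, 500))$z, 0)
  set.seed(52)
  g <- geweke(rnorm(5000))
  expect_lt(abs(g$z), 3)
  drift <- rnorm(2000) + seq(0, 5, length.out = 2000)  # 5 sd drift
  expect_lt(geweke(drift)$p_value, 0.01)
  expect_error(geweke(rnorm(1000), frac1 = 0.6, frac2 = 0.6), "overlap")
})

test_that("Heidelberger-Welch passes stationary chains and fails a level shift", {
  set.seed(53)
  hw <- heidelberger_welch(rnorm(2000))
  expect_true(hw$stationarity_pass)
  expect_gt(hw$stationarity_p, 0.05)
  shifted <- c(rnorm(1000), rnorm(1000, 5))
  expect_false(heidelberger_welch(shifted)$stationarity_pass)
  const <- heidelberger_welch(rep(3, 200))
  expect_true(const$halfwidth_pass)
  expect_equal(const$halfwidth_ratio, 0)
  expect_error(heidelberger_welch(rnorm(50)), ">= 100")
})

test_that("posterior summaries report the documented columns and closed forms", {
  d3 <- asb_draws(list(theta = matrix(c(1, 2, 3), 3, 1)))
  s <- summarize_draws(d3)
  expect_equal(s$mean, 2)
  expect_equal(s$se_naive, sd(c(1, 2, 3)) / sqrt(3))
  set.seed(54)
  iid <- asb_draws(list(x = matrix(rnorm(10000), ncol = 1)))
  si <- summarize_draws(iid)
  expect_lt(abs(si$se_timeseries / si$se_naive - 1), 0.2)
  # AR(1) with rho = 0.9 inflates the time-series SE
  ar <- as.numeric(arima.sim(list(ar = 0.9), 10000))
  sa <- summarize_draws(asb_draws(list(x = matrix(ar, ncol = 1))))
  expect_gt(sa$se_timeseries, 2 * sa$se_naive)
  expect_named(s, c("parameter", "mean", "sd", "2.5%", "97.5%",
                    "se_naive", "se_timeseries", "gelman_rubin",
                    "hw_pvalue", "gw_pvalue"))
  # interval bounds bracket the mean for unimodal draws
  expect_lte(si$`2.5%`, si$mean)
  expect_gte(si$`97.5%`, si$mean)
})

test_that("summaries are invariant to chain relabelling", {
  set.seed(55)
  m <- matrix(rnorm(600), 300, 2)
  a <- summarize_draws(asb_draws(list(p = m)))
  b <- summarize_draws(asb_draws(list(p = m[, 2:1])))
  expect_equal(a$mean, b$mean)
  expect_equal(a$sd, b$sd)
  expect_equal(a$gelman_rubin, b$gelman_rubin)
})

test_that("location shifts move only the location-sensitive diagnostics", {
  set.seed(56)
  m <- matrix(rnorm(2000), 1000, 2)
  base <- summarize_draws(asb_draws(list(p = m)))
  shifted <- summarize_draws(asb_draws(list(p = m + 7)))
  expect_equal(shifted$mean, base$mean + 7)
  expect_equal(shifted$gelman_rubin, base$gelman_rubin)
  expect_equal(shifted$gw_pvalue, base$gw_pvalue, tolerance = 1e-8)
  expect_equal(shifted$sd, base$sd)
})

test_that("fitting is reproducible and retains per-chain traces", {
  fit <- tiny_fit()
  dat <- fit$data
  refit <- asb_fit(dat, chains = 2, iter = 500, burn_in = 250, seed = 42)
  expect_identical(fit$draws$draws, refit$draws$draws)   # bit-identical given seed
  expect_equal(fit$draws$meta$chains, 2L)
  expect_equal(dim(fit$draws$draws[["c.Intercept"]]), c(250L, 2L))
  # conversion keeps chains separate for coda
  ml <- as_mcmc_list(fit$draws)
  expect_equal(length(ml), 2L)
  expect_true("sigma2" %in% colnames(ml[[1]]))
  # variance draws are positive in every draw
  expect_true(all(draws_of(fit$draws, "sigma2") > 0))
  expect_true(all(draws_of(fit$draws, "lambda2_c") > 0))
})

test_that("near-noiseless data recover a treatment effect on the plateau", {
  truth <- asb_truth(sigma2 = 0.005, re_sd = c(c = 0, e = 0, f = 0, T = 0),
                     occasion_sd = 0)
  truth$beta[, "Start"] <- 0
  dat <- simulate_tlq(12, truth = truth, seed = 77)
  dat$y <- dat$y_true      # the model-scale response, before Likert rounding
  # a near-degenerate residual variance leaves no room for far-started
  # chains to travel, so initialise close to the prior locations
  fit <- asb_fit(dat, chains = 2, iter = 2000, burn_in = 1000, seed = 77,
                 init_jitter = 0.1)
  est <- mean(draws_of(fit$draws, "c.tP"))
  expect_lt(abs(est - truth$beta["c", "tP"]), 0.1)
})

test_that("a near-deterministic PRE level is recovered within Monte Carlo error", {
  # with tiny noise and no random effects the PRE block pins the level `a`;
  # its posterior must concentrate at the generating value
  truth <- asb_truth(sigma2 = 0.01, re_sd = c(c = 0, e = 0, f = 0, T = 0),
                     occasion_sd = 0)
  truth$beta[, "Start"] <- 0
  dat <- preprocess_tlq(simulate_tlq(8, truth = truth, seed = 13))
  fit <- asb_fit(dat, chains = 2, iter = 600, burn_in = 300, seed = 13)
  expect_lt(abs(mean(draws_of(fit$draws, "a.Intercept")) - 5), 0.1)
  expect_lt(sd(draws_of(fit$draws, "a.Intercept")), 0.2)
})
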