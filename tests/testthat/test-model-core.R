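test_that("each regime of the piecewise mean follows its stated formula", {
  p <- list(a = 5, b = 0.1, c = 4, d = 1, e = 11, f = 2, g = 5, h = 2)
  expect_equal(mu_curve(3, p), 5 + 0.1 * (3 - 5))          # linear PRE
  expect_equal(mu_curve(11, p), 2 + (4 - 2) / 2)           # logistic inflection
  expect_equal(mu_curve(6, p), (5 + 2) / 2)                # transient midpoint
  expect_equal(mu_curve(6, c(p, gammaT = 0.3)), (5 + 2) / 2 + 0.3)
  expect_equal(mu_curve(6, p, transient = "half_a"), 2 + 5 / 2)
  expect_equal(mu_curve(17, p), 4 + (5 - 4) * (1 - exp(-2)))
  expect_equal(mu_curve(17, p), 4.8646647, tolerance = 1e-7)
  # exponential POST approaches g
  expect_equal(mu_curve(21, list(a = 5, b = 0, c = 4, d = 1, e = 11, f = 2,
                                 g = 5, h = 40)), 5, tolerance = 1e-9)
  expect_equal(mu_curve(9, p, occasion = 0.5) - mu_curve(9, p), 0.5)
  expect_error(mu_curve(22, p), "out of range")
  expect_error(mu_curve(0, p), "out of range")
})

test_that("online logistic is monotone in j with limits f and c when d > 0", {
  p <- list(a = 5, b = 0, c = 4.3, d = 0.8, e = 11, f = 2.1, g = 5, h = 1)
  mu <- mu_curve(seq(7, 16, by = 0.25), p)
  expect_true(all(diff(mu) > 0))
  expect_gt(min(mu), p$f)
  expect_lt(max(mu), p$c)
})

test_that("linear predictor composes intercept, treatment dummies and Start", {
  expect_equal(linear_predictor(c(5, 0, 0, 0), "PEI", start = 6), 5)
  # posterior means of the online-plateau row of the pilot summary table
  beta_c <- c(3.2523, 0.5594, 0.6892, 0.4256)
  expect_equal(linear_predictor(beta_c, "SP", start = 0), 3.8117)
  expect_equal(linear_predictor(beta_c, "tP", start = 1), 4.3671)
  expect_equal(linear_predictor(beta_c, "PEI", start = 0, subject_effect = 0.2),
               3.4523)
  expect_error(linear_predictor(beta_c, "sham", 0), "unknown treatment")
})

test_that("log-likelihood matches a brute-force sum of Normal log-densities", {
  dat <- preprocess_tlq(simulate_tlq(3, seed = 5))
  truth <- asb_truth()
  st <- series_table(dat)
  subj <- unique(st$subject)
  set.seed(14)
  params <- list(
    beta = truth$beta,
    gamma_id = list(c = rnorm(3, 0, 0.3), f = rnorm(3, 0, 0.3)),
    gamma_occ = setNames(rnorm(9, 0, 0.2),
                         paste(st$subject, st$session, sep = ".")),
    sigma2 = 0.37)
  ll <- log_likelihood(dat, params)
  # independent brute force: evaluate the curve row by row
  brute <- 0
  for (i in seq_len(nrow(dat))) {
    row <- dat[i, ]
    k <- match(row$subject, subj)
    p <- curve_params(truth$beta, as.character(row$treatment),
                      st$start[st$subject == row$subject & st$session == row$session],
                      c(c = params$gamma_id$c[k], f = params$gamma_id$f[k]))
    m <- mu_curve(row$timepoint, p,
                  occasion = params$gamma_occ[[paste(row$subject, row$session, sep = ".")]])
    brute <- brute + dnorm(row$y, m, sqrt(0.37), log = TRUE)
  }
  expect_equal(ll, brute)
  # a single observation at its mean with variance 1/(2*pi) has log-density 0
  one <- dat[dat$subject == "S01" & dat$session == 1, ]
  p1 <- list(beta = truth$beta, sigma2 = 1 / (2 * pi))
  mu1 <- mu_curve(1, curve_params(truth$beta, as.character(one$treatment[1]),
                                  one$tlq[1]))
  one$y[one$timepoint == 1] <- mu1
  ll_one <- dnorm(mu1, mu1, sqrt(1 / (2 * pi)), log = TRUE)
  expect_equal(ll_one, 0)
  # doubling the dataset doubles the log-likelihood
  dat2 <- rbind(as.data.frame(dat), transform(as.data.frame(dat),
                                              subject = paste0(subject, "b")))
  dat2 <- preprocess_tlq(as_tlq_data(dat2[, c("subject", "session", "treatment",
                                              "timepoint", "tlq")]))
  params2 <- params
  # subjects sort as S01, S01b, S02, ... so effects interleave
  params2$gamma_id <- lapply(params$gamma_id, function(g) rep(g, each = 2))
  occ2 <- params$gamma_occ
  names(occ2) <- sub("^(S\\d+)", "\\1b", names(occ2))
  params2$gamma_occ <- c(params$gamma_occ, occ2)
  expect_equal(log_likelihood(dat2, params2), 2 * ll)
  expect_error(log_likelihood(dat, modifyList(params, list(sigma2 = -1))),
               "positive")
})

test_that("log-prior matches term-by-term evaluation and the posterior adds up", {
  priors <- asb_priors()
  set.seed(3)
  params <- list(beta = priors$beta_mean + matrix(rnorm(32, 0, 0.1), 8, 4),
                 sigma2 = 0.3,
                 lambda2_id = c(c = 0.5, f = 0.2),
                 lambda2_occ = 0.1,
                 gamma_id = list(c = rnorm(4, 0, 0.5), f = rnorm(4, 0, 0.2)),
                 gamma_occ = rnorm(6, 0, 0.3))
  lp <- log_prior(params, priors)
  brute <- sum(dnorm(params$beta, priors$beta_mean, sqrt(priors$beta_var), log = TRUE)) +
    sum(dgamma(1 / c(0.3, 0.1, 0.5, 0.2), 0.001, 0.001, log = TRUE)) +
    sum(dnorm(params$gamma_id$c, 0, sqrt(0.5), log = TRUE)) +
    sum(dnorm(params$gamma_id$f, 0, sqrt(0.2), log = TRUE)) +
    sum(dnorm(params$gamma_occ, 0, sqrt(0.1), log = TRUE))
  expect_equal(lp, brute)
  # coefficients at the prior locations give the sum of the density maxima
  at_mode <- list(beta = priors$beta_mean, sigma2 = 1)
  expect_equal(log_prior(at_mode, priors),
               sum(dnorm(0, 0, sqrt(priors$beta_var), log = TRUE)) +
                 dgamma(1, 0.001, 0.001, log = TRUE))
  # additivity of the joint density
  dat <- preprocess_tlq(simulate_tlq(2, seed = 9))
  params_small <- list(beta = priors$beta_mean, sigma2 = 0.25)
  expect_equal(log_posterior(dat, params_small, priors),
               log_likelihood(dat, params_small) + log_prior(params_small, priors))
})

test_that("with no Start effect and no random effects, same-treatment subjects share curves", {
  truth <- flat_truth()
  truth$beta[, "Start"] <- 0
  dat <- preprocess_tlq(simulate_tlq(6, truth = truth, seed = 2))
  st <- series_table(dat)
  for (trt in asb_treatments()) {
    ys <- lapply(which(st$treatment == trt), function(r) {
      dat$y_true[dat$subject == st$subject[r] & dat$session == st$session[r]]
    })
    for (k in seq_along(ys)[-1]) expect_equal(ys[[k]], ys[[1]])
  }
})
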