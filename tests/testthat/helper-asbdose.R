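# Shared fixtures, built in code.

# the stylised 21-point raw series used across preprocessing tests:
# flat PRE at 6, online drop to 4, partial post rebound
toy_raw <- function() {
  c(6, 6, 6, 6, 6, 6, 5, 5, rep(4, 8), 4, 5, 5, 6, 6)
}

toy_y_expected <- function() {
  c(rep(5, 5), 5, 6, 6, rep(7, 8), 5, 4, 4, 3, 3)
}

# deterministic noise-free truth for exactness checks
flat_truth <- function(...) {
  asb_truth(sigma2 = 0, re_sd = c(c = 0, e = 0, f = 0, T = 0),
            occasion_sd = 0, ...)
}

# one small fit shared by the inference/derived/methods tests (memoised)
.test_env <- new.env(parent = emptyenv())
tiny_fit <- function() {
  if (is.null(.test_env$fit)) {
    dat <- simulate_tlq(5, seed = 42)
    .test_env$fit <- asb_fit(dat, chains = 2, iter = 500, burn_in = 250,
                             seed = 42)
  }
  .test_env$fit
}

# a synthetic "fit" whose posterior draws are fully controlled, for
# closed-form contrast/delta oracles
make_fake_fit <- function(beta_draws, n = 4000L, start = 5) {
  letters8 <- c("a", "b", "c", "d", "e", "f", "g", "h")
  coefs <- c("Intercept", "SP", "tP", "Start")
  base <- c(a = 5, b = 0, c = 5, d = 2, e = 11, f = 4, g = 5, h = 0.2)
  draws <- list()
  for (l in letters8) {
    for (p in coefs) {
      nm <- paste0(l, ".", p)
      v <- if (!is.null(beta_draws[[nm]])) {
        rep_len(beta_draws[[nm]], n)
      } else if (p == "Intercept") {
        rep(base[[l]], n)
      } else {
        rep(0, n)
      }
      draws[[nm]] <- matrix(v, ncol = 1L)
    }
  }
  draws$sigma2 <- matrix(rep(0.2, n), ncol = 1L)
  draws$lambda2_Od <- matrix(rep(0.01, n), ncol = 1L)
  structure(list(
    draws = asb_draws(draws, seed = 1L, iterations = n, burn_in = 0L),
    series = data.frame(subject = "S01", session = 1L,
                        treatment = factor("PEI", levels = asb_treatments()),
                        start = start),
    transient = "midpoint", shift = 5, random = character(0),
    priors = asb_priors()), class = "asb_fit")
}

# independent numeric oracle: solve G_O(j) = target by root finding
logistic_time_at <- function(c, f, d, e, target) {
  gO <- function(j) f + (c - f) / (1 + exp(-d * (j - e)))
  stats::uniroot(function(j) gO(j) - target, c(e - 200, e + 200),
                 tol = 1e-12)$root
}
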