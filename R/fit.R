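#' Fit the hierarchical piecewise dose-response model by MCMC
#'
#' Fits the Bayesian hierarchical nonlinear mixed-effects model for the
#' transformed loudness response: each subject-session series follows the
#' piecewise mean curve of [mu_curve()], every curve quantity a-h carries
#' fixed effects for treatment (PEI reference) and the baseline `Start`
#' covariate, subjects contribute random deviations on a configurable subset
#' of quantities (shared across their sessions), each subject-session has an
#' occasion effect, and observations are conditionally Normal with variance
#' `sigma2`. Sampling runs in JAGS with per-chain seeded RNGs, so results are
#' reproducible bit-for-bit given `seed`.
#'
#' Initial values are the prior locations with seeded jitter; if JAGS fails
#' to initialise (e.g. a divergent starting log-density), the fit retries
#' with fresh jitter up to `retries` times before failing with the original
#' error.
#'
#' @param data a `tlq_data` object; transformed automatically via
#'   [preprocess_tlq()] when column `y` is absent.
#' @param priors an [asb_priors()] object.
#' @param random subject-level random-effect set, a subset of
#'   `c("a","b","c","d","e","f","g","h","T")`. The default `{c, e, f, T}`
#'   covers the quantities whose between-subject variances the pilot analysis
#'   resolved, plus the transient deviation.
#' @param chains number of chains (>= 2 recommended for diagnostics).
#' @param iter total MCMC iterations per chain (burn-in included).
#' @param burn_in iterations discarded per chain (default `iter %/% 2`).
#' @param thin thinning interval.
#' @param seed integer seed controlling initialisation and all chains.
#' @param shift shift constant of the response transform.
#' @param transient transient-bridge reading, see [mu_curve()].
#' @param init_jitter scale of the seeded initialisation jitter, in prior
#'   standard deviations. The default 1 gives overdispersed starts (chains
#'   dropped into different basins expose multimodal posteriors, the regime
#'   the Gelman-Rubin diagnostic presumes); reduce towards 0.1 for
#'   near-degenerate problems (tiny residual variance) where a far-started
#'   chain cannot reach the peaked posterior within the burn-in.
#' @param retries initialisation retries on failure.
#' @param quiet suppress JAGS progress output.
#' @return an object of class `"asb_fit"`: a list with elements `draws`
#'   (an [asb_draws()] object; fixed effects are named like `"c.tP"`,
#'   variances `"sigma2"`, `"lambda2_Od"`, `"lambda2_c"`, ..., random effects
#'   `"gamma_c[subject]"`, occasion effects `"gamma_Od[series]"`), `data`
#'   (the preprocessed data), `priors`, `random`, `transient`, `shift` and
#'   `call`.
#' @seealso [summary.asb_fit()], [derive_quantities()], [simulate_tlq()]
#' @export
asb_fit <- function(data, priors = asb_priors(),
                    random = c("c", "e", "f", "T"),
                    chains = 2L, iter = 2000L, burn_in = iter %/% 2L,
                    thin = 1L, seed = 1L, shift = 5,
                    transient = c("midpoint", "half_a"),
                    init_jitter = 1, retries = 3L, quiet = TRUE) {
  transient <- match.arg(transient)
  stopifnot(inherits(priors, "asb_priors"))
  check_that(is_count(chains) && chains >= 1L, "`chains` must be >= 1")
  check_that(is_count(iter) && is_count(burn_in, 0L) && iter > burn_in,
             "`iter` must exceed `burn_in`")
  check_that(all(random %in% c(curve_letters(), "T")) && !any(duplicated(random)),
             "`random` must be a subset of a-h and 'T'")
  data <- as_tlq_data(data)
  if (is.null(data$y)) data <- preprocess_tlq(data, shift)
  st <- series_table(data)
  check_that(nrow(st) >= 1L, "no series to fit")

  jd <- jags_data(data, st, priors)
  model_string <- jags_model_string(random, transient)
  inits <- jags_inits(priors, chains, seed, init_jitter)

  jm <- NULL
  err <- NULL
  for (try in seq_len(max(1L, retries))) {
    jm <- tryCatch(
      rjags::jags.model(textConnection(model_string), data = jd,
                        inits = inits, n.chains = chains, quiet = quiet),
      error = function(e) {
        err <<- e
        NULL
      })
    if (!is.null(jm)) break
    inits <- jags_inits(priors, chains, seed + 1000L * try, init_jitter)
  }
  if (is.null(jm)) {
    stop("MCMC initialisation failed after ", retries, " retries: ",
         conditionMessage(err), call. = FALSE)
  }
  if (burn_in > 0L) stats::update(jm, burn_in, progress.bar = if (quiet) "none" else "text")

  monitors <- c(paste0("beta_", curve_letters()), "tau", "tauO",
                if (length(random) > 0L) paste0("tau_", random),
                if (length(random) > 0L) paste0("g", random),
                "gOd")
  samp <- rjags::coda.samples(jm, monitors, n.iter = iter - burn_in, thin = thin,
                              progress.bar = if (quiet) "none" else "text")
  draws <- relabel_jags_draws(samp, random, st)
  draws <- asb_draws(draws, seed = seed, iterations = iter,
                     burn_in = burn_in, thinning = thin)
  structure(list(draws = draws, data = data, priors = priors,
                 random = random, transient = transient, shift = shift,
                 series = st, call = match.call()),
            class = "asb_fit")
}

# assemble the data list handed to JAGS
jags_data <- function(data, st, priors) {
  skey <- paste(st$subject, st$session, sep = ".")
  key <- paste(data$subject, data$session, sep = ".")
  sidx <- match(key, skey)
  subj <- unique(st$subject)
  id_s <- match(st$subject, subj)
  j <- data$timepoint
  y <- data$y
  w1 <- j <= 5; w2 <- j == 6; w3 <- j >= 7 & j <= 16; w4 <- j >= 17
  dl <- list(
    ypre = y[w1], spre = sidx[w1], jpre = j[w1], Npre = sum(w1),
    ytrn = y[w2], strn = sidx[w2], Ntrn = sum(w2),
    yonl = y[w3], sonl = sidx[w3], jonl = j[w3], Nonl = sum(w3),
    ypst = y[w4], spst = sidx[w4], jpst = j[w4], Npst = sum(w4),
    S = nrow(st), I = length(subj), id_s = id_s,
    x2 = as.numeric(st$treatment == "SP"),
    x3 = as.numeric(st$treatment == "tP"),
    x4 = st$start,
    prec_shape = priors$prec_shape, prec_rate = priors$prec_rate
  )
  for (r in seq_len(8L)) {
    l <- curve_letters()[r]
    dl[[paste0("m_", l)]] <- priors$beta_mean[r, ]
    dl[[paste0("p_", l)]] <- 1 / priors$beta_var[r, ]
  }
  dl
}

# build the JAGS model source for a given random-effect set
jags_model_string <- function(random, transient) {
  re_term <- function(l) {
    if (l %in% random) sprintf(" + g%s[id_s[q]]", l) else ""
  }
  gT <- if ("T" %in% random) " + gT[id_s[strn[k]]]" else ""
  trn_mean <- if (transient == "midpoint") {
    sprintf("(a[strn[k]]+f[strn[k]])/2%s", gT)
  } else {
    sprintf("f[strn[k]] + a[strn[k]]/2%s", gT)
  }
  quantity_lines <- paste(vapply(curve_letters(), function(l) {
    sprintf("    %s[q] <- beta_%s[1] + beta_%s[2]*x2[q] + beta_%s[3]*x3[q] + beta_%s[4]*x4[q]%s",
            l, l, l, l, l, re_term(l))
  }, character(1)), collapse = "\n")
  prior_lines <- paste(vapply(curve_letters(), function(l) {
    sprintf("    beta_%s[p] ~ dnorm(m_%s[p], p_%s[p])", l, l, l)
  }, character(1)), collapse = "\n")
  re_letters <- setdiff(random, character(0))
  re_lines <- if (length(re_letters) > 0L) {
    paste0("  for (i in 1:I) {\n",
           paste(vapply(re_letters, function(l) {
             sprintf("    g%s[i] ~ dnorm(0, tau_%s)", l, l)
           }, character(1)), collapse = "\n"),
           "\n  }\n",
           paste(vapply(re_letters, function(l) {
             sprintf("  tau_%s ~ dgamma(prec_shape, prec_rate)", l)
           }, character(1)), collapse = "\n"))
  } else ""
  sprintf("
model {
  for (k in 1:Npre) {
    ypre[k] ~ dnorm(a[spre[k]] + b[spre[k]]*(jpre[k]-5) + gOd[spre[k]], tau)
  }
  for (k in 1:Ntrn) {
    ytrn[k] ~ dnorm(%s + gOd[strn[k]], tau)
  }
  for (k in 1:Nonl) {
    yonl[k] ~ dnorm(f[sonl[k]] + (c[sonl[k]]-f[sonl[k]])*ilogit(d[sonl[k]]*(jonl[k]-e[sonl[k]])) + gOd[sonl[k]], tau)
  }
  for (k in 1:Npst) {
    ypst[k] ~ dnorm(c[spst[k]] + (g[spst[k]]-c[spst[k]])*(1-exp(-h[spst[k]]*(jpst[k]-16))) + gOd[spst[k]], tau)
  }
  for (q in 1:S) {
%s
    gOd[q] ~ dnorm(0, tauO)
  }
  for (p in 1:4) {
%s
  }
%s
  tau ~ dgamma(prec_shape, prec_rate)
  tauO ~ dgamma(prec_shape, prec_rate)
}
", trn_mean, quantity_lines, prior_lines, re_lines)
}

# prior locations with seeded overdispersed jitter (one prior sd): chains
# started apart expose multimodal posteriors (e.g. the POST mirror mode)
# instead of collapsing onto whichever mode the first slice move finds,
# which is also what the Gelman-Rubin diagnostic presumes
jags_inits <- function(priors, chains, seed, jitter_sd = 1) {
  with_seed(seed, lapply(seq_len(chains), function(ch) {
    ini <- list(.RNG.name = "base::Mersenne-Twister",
                .RNG.seed = (seed + ch) %% .Machine$integer.max)
    for (r in seq_len(8L)) {
      l <- curve_letters()[r]
      ini[[paste0("beta_", l)]] <-
        priors$beta_mean[r, ] + stats::rnorm(4L, 0, jitter_sd * sqrt(priors$beta_var[r, ]))
    }
    ini
  }))
}

# map JAGS monitor names to the package's parameter names
relabel_jags_draws <- function(samp, random, st) {
  m <- lapply(samp, as.matrix)
  cols <- colnames(m[[1L]])
  nit <- nrow(m[[1L]])
  nch <- length(m)
  subj <- unique(st$subject)
  skey <- paste(st$subject, st$session, sep = ".")
  get_mat <- function(col, transform = identity) {
    out <- vapply(m, function(x) transform(x[, col]), numeric(nit))
    matrix(out, nrow = nit, ncol = nch)
  }
  draws <- list()
  for (l in curve_letters()) {
    for (p in seq_len(4L)) {
      draws[[paste0(l, ".", coef_names()[p])]] <- get_mat(sprintf("beta_%s[%d]", l, p))
    }
  }
  draws[["sigma2"]] <- get_mat("tau", function(v) 1 / v)
  draws[["lambda2_Od"]] <- get_mat("tauO", function(v) 1 / v)
  for (l in random) {
    draws[[paste0("lambda2_", l)]] <- get_mat(paste0("tau_", l), function(v) 1 / v)
    for (i in seq_along(subj)) {
      draws[[sprintf("gamma_%s[%s]", l, subj[i])]] <- get_mat(sprintf("g%s[%d]", l, i))
    }
  }
  for (q in seq_along(skey)) {
    draws[[sprintf("gamma_Od[%s]", skey[q])]] <- get_mat(sprintf("gOd[%d]", q))
  }
  draws
}
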