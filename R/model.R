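#' Piecewise mean curve of the transformed loudness response
#'
#' The session mean follows four regimes indexed by time point j:
#' \deqn{G_P(j) = a + b (j - 5), \quad j = 1,\dots,5}
#' \deqn{G_T = (a + f)/2 + \gamma_T, \quad j = 6}
#' \deqn{G_O(j) = f + (c - f) / (1 + e^{-d (j - e)}), \quad j = 7,\dots,16}
#' \deqn{G_S(j) = c + (g - c) (1 - e^{-h (j - 16)}), \quad j = 17,\dots,21}
#' i.e. a linear pre-stimulation drift ending at level `a`, a transient
#' bridge at stimulation onset, a four-parameter logistic online response
#' rising from floor `f` to plateau `c` with growth intensity `d` and
#' inflection time `e`, and an exponential post-stimulation decay from `c`
#' towards `g` with intensity `h`. The curve is intentionally discontinuous
#' at j = 6 and j = 17. An occasion (subject-session) effect is added
#' throughout.
#'
#' The transient bridge defaults to the midpoint (a+f)/2; set
#' `transient = "half_a"` for the alternative reading f + a/2.
#'
#' @param j time point(s), 1-21 (non-integer values are allowed inside a
#'   segment, e.g. when evaluating the logistic at a derived dose time).
#' @param params named list or vector with elements `a`,`b`,`c`,`d`,`e`,`f`,
#'   `g`,`h` and optionally `gammaT` (transient random deviation, default 0).
#' @param occasion occasion effect added to every time point (default 0).
#' @param transient `"midpoint"` or `"half_a"`.
#' @return numeric vector of mean responses, one per element of `j`.
#' @examples
#' mu_curve(3, list(a = 5, b = 0.1, c = 4, d = 1, e = 11, f = 2, g = 5, h = 2))
#' @export
mu_curve <- function(j, params, occasion = 0, transient = c("midpoint", "half_a")) {
  transient <- match.arg(transient)
  p <- as.list(params)
  for (nm in c("a", "b", "c", "d", "e", "f", "g", "h")) {
    check_that(!is.null(p[[nm]]), "curve parameter '%s' is missing", nm)
  }
  gT <- p$gammaT %||% 0
  check_that(all(j >= 1 & j <= 21), "time point out of range 1-21")
  out <- numeric(length(j))
  pre <- j <= 5
  trn <- j > 5 & j < 7   # the single transient point sits at j = 6
  onl <- j >= 7 & j <= 16
  pst <- j > 16
  out[pre] <- p$a + p$b * (j[pre] - 5)
  out[trn] <- if (transient == "midpoint") (p$a + p$f) / 2 + gT else p$f + p$a / 2 + gT
  out[onl] <- p$f + (p$c - p$f) / (1 + exp(-p$d * (j[onl] - p$e)))
  out[pst] <- p$c + (p$g - p$c) * (1 - exp(-p$h * (j[pst] - 16)))
  out + occasion
}

#' Linear predictor for one curve quantity
#'
#' Each curve quantity q in \{a,...,h\} is modelled as
#' `q_i = beta0 + beta1 SP_i + beta2 tP_i + beta3 Start_i + gamma_q,Id`,
#' with PEI the reference treatment (no indicator) and `Start` the raw
#' response at T1 entering uncentred on its 1-10 scale.
#'
#' @param beta numeric vector of 4 coefficients
#'   (intercept, SP effect, tP effect, Start effect).
#' @param treatment one of `"PEI"`, `"SP"`, `"tP"`.
#' @param start baseline raw response at T1.
#' @param subject_effect subject-level random effect (default 0).
#' @return scalar value of the quantity.
#' @examples
#' linear_predictor(c(3.2523, 0.5594, 0.6892, 0.4256), "SP", start = 0)
#' @export
linear_predictor <- function(beta, treatment, start, subject_effect = 0) {
  check_that(length(beta) == 4L, "`beta` must have 4 coefficients")
  check_that(treatment %in% asb_treatments(), "unknown treatment '%s'", treatment)
  beta[1L] + beta[2L] * (treatment == "SP") + beta[3L] * (treatment == "tP") +
    beta[4L] * start + subject_effect
}

# names used throughout for the 8 curve quantities and 4 covariates
curve_letters <- function() c("a", "b", "c", "d", "e", "f", "g", "h")
coef_names <- function() c("Intercept", "SP", "tP", "Start")

#' Curve parameters implied by fixed effects for one series
#'
#' @param beta 8 x 4 matrix of fixed effects (rows a-h, columns
#'   Intercept/SP/tP/Start).
#' @param treatment treatment label.
#' @param start baseline covariate.
#' @param subject_effects optional named vector of subject random effects,
#'   names among a-h and `"T"` (the transient deviation).
#' @return named list a-h plus `gammaT`, usable as `params` in [mu_curve()].
#' @export
curve_params <- function(beta, treatment, start, subject_effects = NULL) {
  check_that(is.matrix(beta) && all(dim(beta) == c(8L, 4L)),
             "`beta` must be an 8 x 4 matrix")
  se <- setNames(numeric(9L), c(curve_letters(), "T"))
  if (!is.null(subject_effects)) se[names(subject_effects)] <- subject_effects
  p <- lapply(seq_len(8L), function(r) {
    linear_predictor(beta[r, ], treatment, start, se[[curve_letters()[r]]])
  })
  names(p) <- curve_letters()
  p$gammaT <- se[["T"]]
  p
}

# ---- priors ---------------------------------------------------------------

#' Default prior specification
#'
#' Normal priors on every fixed-effect coefficient (second argument a
#' variance) and Gamma(shape, rate) priors on the precisions of all variance
#' components. Defaults: intercept priors N(5, 0.1) for a, N(0, 0.1) for b,
#' N(4, 1) for c, N(2, 0.25) for d, N(11, 1) for e, N(4.5, 2) for f,
#' N(5, 0.1) for g, N(0, 0.1) for h; all treatment effects N(0, 0.25); all
#' Start effects N(0, 0.001); Gamma(0.001, 0.001) on every precision.
#'
#' @param beta_mean,beta_var optional 8 x 4 matrices overriding the Normal
#'   prior locations/variances (rows a-h, columns Intercept/SP/tP/Start).
#' @param prec_shape,prec_rate Gamma hyperparameters for the precision priors.
#' @return an object of class `"asb_priors"`.
#' @export
asb_priors <- function(beta_mean = NULL, beta_var = NULL,
                       prec_shape = 0.001, prec_rate = 0.001) {
  check_that(prec_shape > 0 && prec_rate > 0, "Gamma hyperparameters must be > 0")
  m <- matrix(0, 8L, 4L, dimnames = list(curve_letters(), coef_names()))
  m[, "Intercept"] <- c(a = 5, b = 0, c = 4, d = 2, e = 11, f = 4.5, g = 5, h = 0)
  v <- matrix(0.25, 8L, 4L, dimnames = dimnames(m))
  v[, "Intercept"] <- c(a = 0.1, b = 0.1, c = 1, d = 0.25, e = 1, f = 2, g = 0.1, h = 0.1)
  v[, "Start"] <- 0.001
  if (!is.null(beta_mean)) m[] <- beta_mean
  if (!is.null(beta_var)) v[] <- beta_var
  check_that(all(v > 0), "prior variances must be > 0")
  structure(list(beta_mean = m, beta_var = v,
                 prec_shape = prec_shape, prec_rate = prec_rate),
            class = "asb_priors")
}

#' @export
print.asb_priors <- function(x, ...) {
  cat("fixed-effect priors N(mean, variance):\n")
  tab <- matrix(sprintf("N(%.3g, %.3g)", x$beta_mean, x$beta_var), 8L, 4L,
                dimnames = dimnames(x$beta_mean))
  print(tab, quote = FALSE)
  cat(sprintf("precision priors: Gamma(%.3g, %.3g)\n", x$prec_shape, x$prec_rate))
  invisible(x)
}

# ---- joint density --------------------------------------------------------

# Build the per-observation mean for a full parameter set.
# params: list(beta = 8x4 matrix,
#              gamma_id = named list (letters among a-h,T) of per-subject vectors,
#              gamma_occ = per-series vector (named by subject.session),
#              sigma2 = scalar)
series_mu <- function(data, params, transient = "midpoint") {
  st <- series_table(data)
  subj <- unique(st$subject)
  mu <- numeric(nrow(data))
  key <- paste(data$subject, data$session, sep = ".")
  skey <- paste(st$subject, st$session, sep = ".")
  occ <- params$gamma_occ %||% setNames(numeric(nrow(st)), skey)
  for (r in seq_len(nrow(st))) {
    sel <- key == skey[r]
    se <- vapply(names(params$gamma_id %||% list()), function(l) {
      params$gamma_id[[l]][match(st$subject[r], subj)]
    }, numeric(1))
    p <- curve_params(params$beta, as.character(st$treatment[r]), st$start[r], se)
    mu[sel] <- mu_curve(data$timepoint[sel], p, occasion = occ[[skey[r]]],
                        transient = transient)
  }
  mu
}

#' Log-likelihood of the transformed response
#'
#' Sum over all observations of the Normal log-density of `y` at the
#' piecewise mean with variance `sigma2`.
#'
#' @param data a preprocessed `tlq_data` object containing column `y`
#'   (see [preprocess_tlq()]).
#' @param params list with elements `beta` (8 x 4 fixed-effect matrix),
#'   optionally `gamma_id` (named list of per-subject random-effect vectors,
#'   names among a-h and `"T"`), optionally `gamma_occ` (per-series occasion
#'   effects named `"subject.session"`), and `sigma2` (> 0).
#' @param transient transient-bridge reading, see [mu_curve()].
#' @return scalar log-likelihood.
#' @export
log_likelihood <- function(data, params, transient = "midpoint") {
  data <- as_tlq_data(data)
  check_that(!is.null(data$y), "data must be preprocessed (column `y` missing)")
  check_that(is.numeric(params$sigma2) && params$sigma2 > 0,
             "`sigma2` must be positive")
  mu <- series_mu(data, params, transient)
  sum(stats::dnorm(data$y, mu, sqrt(params$sigma2), log = TRUE))
}

#' Log-prior density
#'
#' Normal log-densities for all 32 fixed-effect coefficients, Gamma
#' log-densities for the precisions of `sigma2`, the occasion variance and
#' each active subject-level variance, plus the N(0, variance) terms of any
#' random effects present in `params`.
#'
#' @param params as in [log_likelihood()], optionally with `lambda2_id`
#'   (named vector of subject-effect variances) and `lambda2_occ`.
#' @param priors an [asb_priors()] object.
#' @return scalar log prior density.
#' @export
log_prior <- function(params, priors = asb_priors()) {
  stopifnot(inherits(priors, "asb_priors"))
  lp <- sum(stats::dnorm(params$beta, priors$beta_mean,
                         sqrt(priors$beta_var), log = TRUE))
  vars <- c(sigma2 = params$sigma2,
            if (!is.null(params$lambda2_occ)) c(lambda2_occ = params$lambda2_occ),
            params$lambda2_id %||% NULL)
  check_that(all(unlist(vars) > 0), "variance components must be positive")
  for (v in vars) {
    lp <- lp + stats::dgamma(1 / v, priors$prec_shape, priors$prec_rate, log = TRUE)
  }
  if (!is.null(params$gamma_id)) {
    for (l in names(params$gamma_id)) {
      lam <- params$lambda2_id[[l]]
      check_that(!is.null(lam), "random effects '%s' present without variance", l)
      lp <- lp + sum(stats::dnorm(params$gamma_id[[l]], 0, sqrt(lam), log = TRUE))
    }
  }
  if (!is.null(params$gamma_occ)) {
    check_that(!is.null(params$lambda2_occ), "occasion effects present without variance")
    lp <- lp + sum(stats::dnorm(params$gamma_occ, 0, sqrt(params$lambda2_occ), log = TRUE))
  }
  lp
}

#' @rdname log_prior
#' @param data,transient passed to [log_likelihood()].
#' @export
log_posterior <- function(data, params, priors = asb_priors(), transient = "midpoint") {
  log_likelihood(data, params, transient) + log_prior(params, priors)
}
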