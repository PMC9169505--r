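# z-quantile pair for a test at level alpha with given power and sidedness
z_pair <- function(alpha, power, sided = 2) {
  check_that(is_prob(alpha) && is_prob(power), "alpha and power must be in (0,1)")
  check_that(sided %in% c(1, 2), "`sided` must be 1 or 2")
  za <- if (sided == 2) stats::qnorm(1 - alpha / 2) else stats::qnorm(1 - alpha)
  zb <- stats::qnorm(power)
  (za + zb)^2
}

#' Intra-class correlation from variance components
#'
#' `rho = sigma0^2 / (sigma0^2 + sigma^2)`, the correlation between repeated
#' measures implied by a random-intercept model with between-subject variance
#' `sigma0^2` and residual variance `sigma^2`.
#'
#' @param sigma2_between between-subject (random-intercept) variance.
#' @param sigma2_resid residual variance.
#' @return the ICC in `[0, 1)`.
#' @examples
#' icc(0.08731, 1.09283)  # ~ 0.07398
#' @export
icc <- function(sigma2_between, sigma2_resid) {
  check_that(sigma2_between >= 0 && sigma2_resid > 0, "variances must be >= 0 / > 0")
  sigma2_between / (sigma2_between + sigma2_resid)
}

#' Sample size from a coefficient-of-variation difference
#'
#' Minimum sample size to resolve the difference between two within-subject
#' coefficients of variation (e.g. the PRE block against the online block of
#' the active control):
#' `n = ceiling( (z_a + z_b)^2 (cv1^2 + cv2^2) / (cv2 - cv1)^2 )`.
#'
#' @param cv1,cv2 the two coefficients of variation (> 0, unequal).
#' @param alpha significance level.
#' @param power target power.
#' @param sided 1 or 2.
#' @return list of class `"samplesize_result"` with `n`, `formula` id and the
#'   echoed inputs.
#' @examples
#' n_cv_difference(0.0598, 0.367, alpha = 0.05, power = 0.80)  # n = 12
#' @export
n_cv_difference <- function(cv1, cv2, alpha = 0.05, power = 0.80, sided = 2) {
  check_that(all(cv1 > 0) && all(cv2 > 0), "CVs must be > 0")
  if (any(cv1 == cv2)) {
    stop("equal CVs give an infinite sample size", call. = FALSE)
  }
  n <- ceiling(z_pair(alpha, power, sided) * (cv1^2 + cv2^2) / (cv2 - cv1)^2)
  structure(list(n = n, formula = "cv_difference",
                 inputs = list(cv1 = cv1, cv2 = cv2, alpha = alpha,
                               power = power, sided = sided)),
            class = "samplesize_result")
}

#' Sample size for a repeated-measures treatment comparison
#'
#' Linear-model-for-repeated-measures formula with compound symmetry:
#' `n = ceiling( groups (z_a + z_b)^2 sigma2 (1 + (m-1) rho) / (m delta^2) )`,
#' where `m` is the number of repeated measures per subject and `rho` the
#' intra-class correlation. With `rho = 0` it reduces to the standard
#' two-mean formula divided by `m`.
#'
#' @param sigma2_total total (marginal) response variance.
#' @param icc intra-class correlation in `[0, 1)`.
#' @param m repeated measures per subject (>= 1).
#' @param delta minimum clinically relevant difference (> 0).
#' @param alpha,power,sided as in [n_cv_difference()].
#' @param groups 1 (paired/single-group) or 2 (two-group comparison).
#' @return a `"samplesize_result"` list.
#' @examples
#' n_repeated_measures(1.18014, 0.07398, m = 11, delta = 0.4)  # n = 19
#' @export
n_repeated_measures <- function(sigma2_total, icc, m, delta,
                                alpha = 0.05, power = 0.80, sided = 2,
                                groups = 2) {
  check_that(all(icc >= 0) && all(icc < 1), "icc must lie in [0, 1)")
  check_that(is_count(m), "`m` must be a positive integer")
  check_that(all(sigma2_total > 0), "sigma2_total must be > 0")
  check_that(groups %in% c(1, 2), "`groups` must be 1 or 2")
  if (any(delta <= 0)) stop("delta must be > 0", call. = FALSE)
  n <- ceiling(groups * z_pair(alpha, power, sided) * sigma2_total *
                 (1 + (m - 1) * icc) / (m * delta^2))
  structure(list(n = n, formula = "repeated_measures",
                 inputs = list(sigma2_total = sigma2_total, icc = icc, m = m,
                               delta = delta, alpha = alpha, power = power,
                               sided = sided, groups = groups)),
            class = "samplesize_result")
}

#' Sample size for a dose-response contrast over the online time points
#'
#' Single-factor contrast test on the online mean profile:
#' `n = ceiling( (z_a + z_b)^2 sigma2 sum(contrast^2) / (sum(contrast * mean))^2 )`.
#' Scaling all contrasts by a constant leaves `n` unchanged.
#'
#' @param means mean responses at the online time points (length 11 on the
#'   default timeline T6-T16).
#' @param contrasts contrast coefficients, same length as `means`, summing
#'   to 0, with `sum(contrasts * means) != 0`.
#' @param sigma2 response variance in the online period.
#' @param alpha,power,sided as in [n_cv_difference()].
#' @return a `"samplesize_result"` list.
#' @examples
#' n_dose_contrast(
#'   means = c(5, 4.83, 5, 5.17, 5.17, 5.5, 5.67, 5.67, 5.67, 5.67, 5.83),
#'   contrasts = c(-4, -4, 0.5, 0.5, 1, 1, 1, 1, 1, 1, 1),
#'   sigma2 = 0.547, alpha = 0.05, power = 0.90)  # n = 10
#' @export
n_dose_contrast <- function(means, contrasts, sigma2,
                            alpha = 0.05, power = 0.80, sided = 2) {
  check_that(length(means) == length(contrasts) && length(means) >= 2L,
             "`means` and `contrasts` must have equal length >= 2")
  check_that(isTRUE(all.equal(sum(contrasts), 0)), "contrasts must sum to 0")
  check_that(sigma2 > 0, "sigma2 must be > 0")
  eff <- sum(contrasts * means)
  if (abs(eff) < sqrt(.Machine$double.eps)) {
    stop("contrasts are orthogonal to the mean profile; effect is 0", call. = FALSE)
  }
  n <- ceiling(z_pair(alpha, power, sided) * sigma2 * sum(contrasts^2) / eff^2)
  structure(list(n = n, formula = "dose_contrast",
                 inputs = list(means = means, contrasts = contrasts,
                               sigma2 = sigma2, alpha = alpha, power = power,
                               sided = sided)),
            class = "samplesize_result")
}

#' @export
print.samplesize_result <- function(x, ...) {
  cat(sprintf("sample size (%s): n = %d\n", x$formula, x$n))
  invisible(x)
}

#' Posterior distribution of a sample size
#'
#' Evaluates a conventional sample-size formula on every posterior draw of
#' its inputs, yielding the posterior distribution of the suggested sample
#' size and a sequential sampling plan (interim sizes at a quantile grid,
#' nondecreasing by construction). Draws violating the formula preconditions
#' are excluded and counted.
#'
#' @param inputs a data frame (or named list of equal-length vectors) with
#'   one row per posterior draw and one column per formula argument, e.g.
#'   `cv1`/`cv2` for `"cv_difference"`; `sigma2_total`/`icc`/`delta` for
#'   `"repeated_measures"` (plus scalars `m`, `groups` passed via `...`);
#'   `sigma2` and optionally a matrix column `means` for `"dose_contrast"`.
#' @param formula which calculator to apply per draw.
#' @param alpha,power,sided test operating characteristics.
#' @param quantile_grid interim quantiles of the sequential plan.
#' @param ... fixed (non-draw) arguments forwarded to the calculator.
#' @return list of class `"samplesize_posterior"` with `n_draws`, `plan`
#'   (named nondecreasing interim sizes), `median`, `excluded_fraction` and
#'   the echoed `formula`.
#' @export
posterior_sample_size <- function(inputs,
                                  formula = c("cv_difference",
                                              "repeated_measures",
                                              "dose_contrast"),
                                  alpha = 0.05, power = 0.80, sided = 2,
                                  quantile_grid = c(0.25, 0.50, 0.75, 0.90),
                                  ...) {
  formula <- match.arg(formula)
  inputs <- as.data.frame(inputs)
  check_that(nrow(inputs) > 0L, "no posterior draws supplied")
  fixed <- list(...)
  one <- function(i) {
    args <- c(as.list(inputs[i, , drop = FALSE]), fixed,
              list(alpha = alpha, power = power, sided = sided))
    fn <- switch(formula,
                 cv_difference = n_cv_difference,
                 repeated_measures = n_repeated_measures,
                 dose_contrast = n_dose_contrast)
    tryCatch(do.call(fn, args)$n, error = function(e) NA_integer_)
  }
  n_draws <- vapply(seq_len(nrow(inputs)), one, numeric(1))
  excluded <- mean(is.na(n_draws))
  n_ok <- n_draws[!is.na(n_draws)]
  check_that(length(n_ok) > 0L, "every draw violated the formula preconditions")
  plan <- stats::quantile(n_ok, quantile_grid, type = 1)
  plan <- stats::setNames(cummax(ceiling(plan)), sprintf("%.0f%%", 100 * quantile_grid))
  structure(list(n_draws = n_ok, plan = plan,
                 median = unname(stats::quantile(n_ok, 0.5, type = 1)),
                 excluded_fraction = excluded, formula = formula),
            class = "samplesize_posterior")
}

#' @export
print.samplesize_posterior <- function(x, ...) {
  cat(sprintf("posterior sample size (%s): median n = %d, %d draws (%.1f%% excluded)\n",
              x$formula, x$median, length(x$n_draws), 100 * x$excluded_fraction))
  cat("sequential plan:\n")
  print(x$plan)
  invisible(x)
}

#' Sample-size table over a power x significance grid
#'
#' Evaluates one calculator over the conventional reporting grid
#' (power 75/80/90/99% by significance 1/5/10%).
#'
#' @param fn one of the `n_*` calculators.
#' @param powers,alphas grid values.
#' @param ... fixed arguments of `fn`.
#' @return matrix of sample sizes, rows powers, columns significance levels.
#' @export
samplesize_grid <- function(fn, powers = c(0.75, 0.80, 0.90, 0.99),
                            alphas = c(0.01, 0.05, 0.10), ...) {
  out <- vapply(alphas, function(a) {
    vapply(powers, function(p) fn(..., alpha = a, power = p)$n, numeric(1))
  }, numeric(length(powers)))
  out <- matrix(out, nrow = length(powers),
                dimnames = list(power = sprintf("%.0f%%", 100 * powers),
                                significance = sprintf("%.0f%%", 100 * alphas)))
  out
}
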