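#' Gelman-Rubin potential scale reduction factor
#'
#' For m >= 2 chains of equal length n, computes
#' `sqrt(((n-1)/n * W + B/n) / W)` with `W` the mean within-chain variance
#' and `B = n * var(chain means)` the between-chain variance. Two identical
#' chains give exactly `sqrt((n-1)/n)` (< 1); values well above 1 indicate
#' non-convergence.
#'
#' @param chains an (iteration x chain) matrix, or a list of equal-length
#'   numeric vectors, holding the draws of one parameter.
#' @return the scalar potential scale reduction factor.
#' @export
gelman_rubin <- function(chains) {
  if (is.list(chains)) {
    lens <- lengths(chains)
    check_that(length(unique(lens)) == 1L, "chains must have equal lengths")
    chains <- do.call(cbind, chains)
  }
  check_that(is.matrix(chains), "`chains` must be a matrix or list of vectors")
  m <- ncol(chains)
  n <- nrow(chains)
  check_that(m >= 2L, "Gelman-Rubin needs at least 2 chains")
  check_that(n >= 2L, "chains too short")
  W <- mean(apply(chains, 2L, stats::var))
  B <- n * stats::var(colMeans(chains))
  if (W == 0) return(if (B == 0) 1 else Inf)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Geweke stationarity diagnostic
#'
#' Compares the mean of the first `frac1` of a chain against the mean of the
#' last `frac2`, standardising by spectral-density-at-zero standard errors;
#' under stationarity the z-score is standard Normal.
#'
#' @param chain numeric vector, one chain of one parameter.
#' @param frac1,frac2 window fractions; must not overlap (`frac1 + frac2 <= 1`).
#' @return list with elements `z` and `p_value` (two-sided).
#' @export
geweke <- function(chain, frac1 = 0.1, frac2 = 0.5) {
  check_that(is.numeric(chain) && length(chain) >= 10L, "chain too short")
  check_that(frac1 > 0 && frac2 > 0 && frac1 + frac2 <= 1,
             "windows overlap: frac1 + frac2 must be <= 1")
  if (stats::var(chain) == 0) {
    return(list(z = 0, p_value = 1))
  }
  z <- unname(coda::geweke.diag(coda::mcmc(chain), frac1 = frac1, frac2 = frac2)$z)
  list(z = z, p_value = 2 * stats::pnorm(-abs(z)))
}

# CDF of the asymptotic Cramer-von Mises distribution (series expansion)
pcramer <- function(q, eps = 1e-5) {
  if (q <= 0) return(0)
  # the 4-term expansion stops converging deep in the tail; the CDF already
  # exceeds 0.9996 at q = 2, so saturate there
  if (q >= 2) return(1)
  total <- 0
  for (k in 0:3) {
    u <- (4 * k + 1)^2 / (16 * q)
    if (u > -log(eps)) next
    z <- gamma(k + 0.5) * sqrt(4 * k + 1) / (gamma(k + 1) * pi^1.5 * sqrt(q))
    total <- total + z * exp(-u) * besselK(u, nu = 0.25)
  }
  min(max(total, 0), 1)
}

# Cramer-von Mises stationarity statistic of one chain segment, using a
# spectral-density-at-zero estimate S0 from the segment's second half
cvm_stationarity_p <- function(x) {
  n <- length(x)
  S0 <- coda::spectrum0.ar(coda::mcmc(x[(n %/% 2):n]))$spec
  if (!is.finite(S0) || S0 <= 0) return(NA_real_)
  B <- (cumsum(x) - seq_len(n) * mean(x)) / sqrt(n * S0)
  1 - pcramer(sum(B^2) / n)
}

#' Heidelberger-Welch stationarity and halfwidth diagnostic
#'
#' Stationarity: a Cramer-von Mises test of the full chain (reported as
#' `stationarity_p`/`stationarity_pass`), followed by the usual iterative
#' schedule that discards initial 10% segments (up to half the chain) until a
#' stationary portion is found (`kept_start`, `converged`). Halfwidth: the
#' 95% interval halfwidth of the retained mean, from its
#' spectral-density-at-zero variance estimate, must not exceed `eps` times
#' the magnitude of the mean.
#'
#' @param chain numeric vector, one chain (length >= 100).
#' @param alpha significance level of the stationarity test.
#' @param eps halfwidth tolerance.
#' @return list with `stationarity_p`, `stationarity_pass` (full chain),
#'   `kept_start`, `converged`, `halfwidth_ratio` and `halfwidth_pass`.
#' @export
heidelberger_welch <- function(chain, alpha = 0.05, eps = 0.1) {
  check_that(is.numeric(chain) && length(chain) >= 100L,
             "Heidelberger-Welch needs a chain of length >= 100")
  n <- length(chain)
  if (stats::var(chain) == 0) {
    return(list(stationarity_p = 1, stationarity_pass = TRUE, kept_start = 1L,
                converged = TRUE, halfwidth_ratio = 0, halfwidth_pass = TRUE))
  }
  p_full <- cvm_stationarity_p(chain)
  kept_start <- NA_integer_
  converged <- FALSE
  for (drop_frac in seq(0, 0.5, by = 0.1)) {
    start <- floor(drop_frac * n) + 1L
    p <- if (drop_frac == 0) p_full else cvm_stationarity_p(chain[start:n])
    if (!is.na(p) && p > alpha) {
      kept_start <- start
      converged <- TRUE
      break
    }
  }
  kept <- if (converged) chain[kept_start:n] else chain
  S0 <- coda::spectrum0.ar(coda::mcmc(kept))$spec
  halfwidth <- stats::qnorm(0.975) * sqrt(S0 / length(kept))
  m <- mean(kept)
  ratio <- if (m == 0) halfwidth else abs(halfwidth / m)
  list(stationarity_p = p_full,
       stationarity_pass = !is.na(p_full) && p_full > alpha,
       kept_start = kept_start, converged = converged,
       halfwidth_ratio = ratio,
       halfwidth_pass = ratio <= eps)
}

#' Posterior summaries with the convergence battery
#'
#' Per parameter: posterior mean, sd, equal-tailed credible interval, naive
#' standard error (sd over the square root of the total number of draws),
#' autocorrelation-adjusted time-series standard error (sd over the square
#' root of the effective sample size), the Gelman-Rubin statistic (NA for a
#' single chain), and the Heidelberger-Welch and Geweke p-values of the first
#' chain.
#'
#' @param draws an [asb_draws()] object.
#' @param level credible level (default 0.95).
#' @param parameters optional character vector restricting the table.
#' @return data frame with one row per parameter and columns `parameter`,
#'   `mean`, `sd`, `lower`, `upper` (the equal-tailed bounds), `se_naive`,
#'   `se_timeseries`, `gelman_rubin`, `hw_pvalue`, `gw_pvalue`.
#' @export
summarize_draws <- function(draws, level = 0.95, parameters = NULL) {
  stopifnot(inherits(draws, "asb_draws"))
  check_that(is_prob(level), "`level` must be in (0,1)")
  nms <- parameters %||% names(draws$draws)
  check_that(all(nms %in% names(draws$draws)), "unknown parameter requested")
  qs <- c((1 - level) / 2, 1 - (1 - level) / 2)
  rows <- lapply(nms, function(p) {
    m <- draws$draws[[p]]
    v <- as.vector(m)
    n_tot <- length(v)
    ess <- tryCatch(
      max(1, sum(vapply(seq_len(ncol(m)), function(ch) {
        unname(coda::effectiveSize(coda::mcmc(m[, ch])))
      }, numeric(1)))),
      error = function(e) n_tot)
    gr <- if (ncol(m) >= 2L) gelman_rubin(m) else NA_real_
    hw <- if (nrow(m) >= 100L) heidelberger_welch(m[, 1L])$stationarity_p else NA_real_
    gw <- if (nrow(m) >= 10L) geweke(m[, 1L])$p_value else NA_real_
    data.frame(parameter = p,
               mean = mean(v), sd = stats::sd(v),
               lower = unname(stats::quantile(v, qs[1L])),
               upper = unname(stats::quantile(v, qs[2L])),
               se_naive = stats::sd(v) / sqrt(n_tot),
               se_timeseries = stats::sd(v) / sqrt(ess),
               gelman_rubin = gr, hw_pvalue = hw, gw_pvalue = gw,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  names(out)[names(out) == "lower"] <- sprintf("%.1f%%", 100 * qs[1L])
  names(out)[names(out) == "upper"] <- sprintf("%.1f%%", 100 * qs[2L])
  rownames(out) <- NULL
  out
}
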