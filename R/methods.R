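#' @export
print.asb_fit <- function(x, ...) {
  st <- x$series
  cat("Bayesian piecewise dose-response model fit\n")
  cat(sprintf("  %d observations, %d series, %d subjects; random effects on {%s}\n",
              nrow(x$data), nrow(st), length(unique(st$subject)),
              paste(x$random, collapse = ",")))
  cat(sprintf("  %d chains x %d iterations (burn-in %d, thinning %d), seed %s\n",
              x$draws$meta$chains, x$draws$meta$iterations,
              x$draws$meta$burn_in, x$draws$meta$thinning, x$draws$meta$seed))
  b <- coef(x)
  cat("posterior mean fixed effects:\n")
  print(round(b, 4))
  invisible(x)
}

#' Posterior mean fixed effects
#' @param object an `asb_fit` object.
#' @param ... unused.
#' @return 8 x 4 matrix of posterior means (rows a-h, columns
#'   Intercept/SP/tP/Start).
#' @export
coef.asb_fit <- function(object, ...) {
  b <- matrix(NA_real_, 8L, 4L, dimnames = list(curve_letters(), coef_names()))
  for (l in curve_letters()) {
    for (p in coef_names()) {
      b[l, p] <- mean(draws_of(object$draws, paste0(l, ".", p)))
    }
  }
  b
}

#' Summarise a model fit
#'
#' Produces the standard reporting table: for every monitored parameter the
#' posterior mean, sd, 95% credible interval, naive and time-series standard
#' errors, and the Gelman-Rubin, Heidelberger-Welch and Geweke diagnostics,
#' with the prior attached to each fixed-effect row. Non-convergence is
#' flagged at a Bonferroni-corrected familywise level
#' (`familywise / number of monitored parameters`).
#'
#' @param object an `asb_fit` object.
#' @param level credible level.
#' @param include `"parameters"` (fixed effects and variance components, the
#'   default) or `"all"` (adds per-subject and per-series random effects).
#' @param familywise familywise significance for convergence flagging.
#' @param ... unused.
#' @return a data frame of class `"summary.asb_fit"` with the columns of
#'   [summarize_draws()] plus `prior` and logical `flagged`.
#' @export
summary.asb_fit <- function(object, level = 0.95,
                            include = c("parameters", "all"),
                            familywise = 0.05, ...) {
  include <- match.arg(include)
  nms <- names(object$draws$draws)
  if (include == "parameters") nms <- nms[!grepl("^gamma_", nms)]
  # order rows like the reporting convention: per-quantity blocks, variances last
  fixed <- as.vector(t(outer(curve_letters(), coef_names(), paste, sep = ".")))
  ord <- c(unlist(lapply(curve_letters(), function(l) {
    c(paste0(l, ".", coef_names()),
      if (paste0("lambda2_", l) %in% nms) paste0("lambda2_", l))
  })), "sigma2", "lambda2_Od")
  nms <- c(intersect(ord, nms), setdiff(nms, ord))
  tab <- summarize_draws(object$draws, level = level, parameters = nms)
  pr <- rep(NA_character_, nrow(tab))
  for (i in seq_len(nrow(tab))) {
    p <- tab$parameter[i]
    if (p %in% fixed) {
      parts <- strsplit(p, ".", fixed = TRUE)[[1L]]
      r <- match(parts[1L], curve_letters())
      cidx <- match(parts[2L], coef_names())
      pr[i] <- sprintf("N(%.4g, %.4g)",
                       object$priors$beta_mean[r, cidx],
                       object$priors$beta_var[r, cidx])
    } else if (grepl("^(sigma2|lambda2)", p)) {
      pr[i] <- sprintf("GA(%.4g, %.4g)", object$priors$prec_shape, object$priors$prec_rate)
    }
  }
  tab <- cbind(tab[, 1L, drop = FALSE], prior = pr, tab[, -1L, drop = FALSE])
  alpha <- familywise / nrow(tab)
  tab$flagged <- (!is.na(tab$gelman_rubin) & tab$gelman_rubin > 1.1) |
    (!is.na(tab$hw_pvalue) & tab$hw_pvalue < alpha) |
    (!is.na(tab$gw_pvalue) & tab$gw_pvalue < alpha)
  class(tab) <- c("summary.asb_fit", "data.frame")
  attr(tab, "level") <- level
  attr(tab, "familywise") <- familywise
  tab
}

#' @export
print.summary.asb_fit <- function(x, digits = 4, ...) {
  cat(sprintf("posterior summaries (%.0f%% credible intervals); %d of %d parameters flagged\n",
              100 * attr(x, "level"), sum(x$flagged), nrow(x)))
  df <- as.data.frame(x)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], round, digits)
  print(df, row.names = FALSE)
  invisible(x)
}

# population curve parameters at a treatment/start, from posterior mean betas
population_params <- function(object, treatment, start) {
  curve_params(coef(object), treatment, start)
}

#' Predict population mean curves
#'
#' Evaluates the posterior-mean population curve (random and occasion effects
#' at zero) for given treatment(s) and baseline.
#'
#' @param object an `asb_fit` object.
#' @param treatment treatment label(s); defaults to all three arms.
#' @param start baseline covariate value; defaults to the mean observed
#'   baseline.
#' @param timepoints time points at which to evaluate.
#' @param ... unused.
#' @return data frame with columns `treatment`, `timepoint`, `mu`.
#' @export
predict.asb_fit <- function(object, treatment = asb_treatments(),
                            start = mean(object$series$start),
                            timepoints = 1:21, ...) {
  out <- do.call(rbind, lapply(treatment, function(trt) {
    p <- population_params(object, trt, start)
    data.frame(treatment = trt, timepoint = timepoints,
               mu = mu_curve(timepoints, p, transient = object$transient))
  }))
  rownames(out) <- NULL
  out
}

#' @export
fitted.asb_fit <- function(object, ...) {
  st <- object$series
  subj <- unique(st$subject)
  skey <- paste(st$subject, st$session, sep = ".")
  gamma_id <- lapply(setNames(object$random, object$random), function(l) {
    vapply(subj, function(s) mean(draws_of(object$draws, sprintf("gamma_%s[%s]", l, s))),
           numeric(1))
  })
  gamma_occ <- setNames(vapply(skey, function(k) {
    mean(draws_of(object$draws, sprintf("gamma_Od[%s]", k)))
  }, numeric(1)), skey)
  params <- list(beta = coef(object), gamma_id = gamma_id, gamma_occ = gamma_occ,
                 sigma2 = mean(draws_of(object$draws, "sigma2")))
  series_mu(object$data, params, object$transient)
}

#' @export
residuals.asb_fit <- function(object, ...) {
  object$data$y - fitted(object)
}

#' Posterior-predictive simulation from a fit
#'
#' Draws `nsim` replicate datasets: for each replicate one posterior draw of
#' the fixed effects and variance components is selected (seeded) and a new
#' cohort of the fitted size is generated through [simulate_tlq()].
#'
#' @param object an `asb_fit` object.
#' @param nsim number of replicate datasets.
#' @param seed integer seed.
#' @param ... unused.
#' @return a list of `tlq_data` objects (length `nsim`).
#' @export
simulate.asb_fit <- function(object, nsim = 1, seed = 1L, ...) {
  n_subjects <- length(unique(object$series$subject))
  total <- object$draws$meta$kept * object$draws$meta$chains
  idx <- with_seed(seed, sample(total, nsim, replace = TRUE))
  lapply(seq_len(nsim), function(s) {
    k <- idx[s]
    beta <- matrix(NA_real_, 8L, 4L, dimnames = list(curve_letters(), coef_names()))
    for (l in curve_letters()) {
      for (p in coef_names()) {
        beta[l, p] <- draws_of(object$draws, paste0(l, ".", p))[k]
      }
    }
    re_sd <- vapply(setNames(object$random, object$random), function(l) {
      sqrt(draws_of(object$draws, paste0("lambda2_", l))[k])
    }, numeric(1))
    truth <- asb_truth(beta = beta, sigma2 = draws_of(object$draws, "sigma2")[k],
                       re_sd = re_sd,
                       occasion_sd = sqrt(draws_of(object$draws, "lambda2_Od")[k]),
                       shift = object$shift)
    simulate_tlq(n_subjects, truth = truth, seed = seed + s)
  })
}

#' Plot posterior mean treatment curves
#'
#' Draws the posterior-mean population curve per treatment over the 21 time
#' points, with the observed transformed responses overlaid as points.
#'
#' @param x an `asb_fit` object.
#' @param show_data overlay observed transformed responses.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.asb_fit <- function(x, show_data = TRUE, ...) {
  pr <- predict(x)
  wide <- vapply(asb_treatments(), function(t) pr$mu[pr$treatment == t], numeric(21L))
  graphics::matplot(1:21, wide, type = "l", lty = 1, lwd = 2,
                    col = c("grey40", "steelblue", "firebrick"),
                    xlab = "time point", ylab = "transformed response", ...)
  if (show_data) {
    cols <- c(PEI = "grey40", SP = "steelblue", tP = "firebrick")
    graphics::points(jitter(x$data$timepoint, 0.3), x$data$y,
                     col = grDevices::adjustcolor(cols[as.character(x$data$treatment)], 0.3),
                     pch = 16, cex = 0.5)
  }
  graphics::abline(v = c(5.5, 6.5, 16.5), lty = 3, col = "grey70")
  graphics::legend("topleft", legend = asb_treatments(), lty = 1, lwd = 2,
                   col = c("grey40", "steelblue", "firebrick"), bty = "n")
  invisible(x)
}
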