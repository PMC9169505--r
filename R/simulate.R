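#' Ground-truth specification for the simulator
#'
#' Bundles the generative parameter values used by [simulate_tlq()]. The
#' defaults describe a pilot-like cohort: flat PRE at level 5, an online
#' logistic rising from the baseline level 5 to a plateau of 5.9 under PEI
#' (gain 0.9, putting the minimum clinical efficacy near 0.4), treatment
#' effects of +0.4 (SP) and +0.7 (tP) on the plateau and -0.5 on the
#' inflection time, a mild post-stimulation decay towards 5.1, residual
#' variance 0.2, subject random effects on \{c, e, f, T\} and a
#' subject-session occasion effect.
#'
#' @param beta 8 x 4 matrix of fixed effects (rows a-h, columns
#'   Intercept/SP/tP/Start).
#' @param sigma2 residual variance (> 0).
#' @param re_sd named vector of subject random-effect standard deviations
#'   (names among a-h, `"T"`); 0/absent disables an effect.
#' @param occasion_sd occasion (subject-session) effect sd.
#' @param shift shift constant of the response transform.
#' @param start_support integer support of the baseline Start distribution
#'   (sampled uniformly).
#' @param transient transient-bridge reading, see [mu_curve()].
#' @return an object of class `"asb_truth"`.
#' @export
asb_truth <- function(beta = NULL, sigma2 = 0.2,
                      re_sd = c(c = 0.3, e = 0.7, f = 0.3, T = 0.2),
                      occasion_sd = 0.2, shift = 5,
                      start_support = 4:8,
                      transient = c("midpoint", "half_a")) {
  transient <- match.arg(transient)
  if (is.null(beta)) {
    beta <- matrix(0, 8L, 4L, dimnames = list(curve_letters(), coef_names()))
    beta[, "Intercept"] <- c(a = 5, b = 0, c = 5.9, d = 2, e = 9, f = 5,
                             g = 5.1, h = 0.2)
    beta["c", "SP"] <- 0.4
    beta["c", "tP"] <- 0.7
    beta["e", "SP"] <- -0.5
    beta["e", "tP"] <- -0.5
  }
  check_that(is.matrix(beta) && all(dim(beta) == c(8L, 4L)),
             "`beta` must be an 8 x 4 matrix")
  dimnames(beta) <- list(curve_letters(), coef_names())
  check_that(sigma2 >= 0 && occasion_sd >= 0 && all(re_sd >= 0),
             "variances must be >= 0")
  check_that(all(names(re_sd) %in% c(curve_letters(), "T")),
             "re_sd names must lie in a-h, T")
  structure(list(beta = beta, sigma2 = sigma2, re_sd = re_sd,
                 occasion_sd = occasion_sd, shift = shift,
                 start_support = start_support, transient = transient),
            class = "asb_truth")
}

#' Simulate a Williams-crossover TLQ dataset
#'
#' Generates a full synthetic cohort from the hierarchical piecewise model:
#' Williams sequences are assigned, subject random effects and per-session
#' occasion effects are drawn, the transformed response is sampled around the
#' piecewise mean curve, and the transformation chain is inverted
#' ([invert_transform()]) to reconstruct raw Likert trajectories, rounding
#' half away from zero and clamping to the 1-10 scale. A warning is recorded
#' when more than 20% of raw values hit the clamp boundary.
#'
#' @param n_subjects number of subjects.
#' @param truth an [asb_truth()] specification.
#' @param seed integer seed; the output is deterministic given the seed.
#' @return a `tlq_data` object (21 rows per subject-session) with an extra
#'   column `y_true`, the simulated transformed response before
#'   rounding/clamping, and attribute `"truth"`.
#' @export
simulate_tlq <- function(n_subjects, truth = asb_truth(), seed = 1L) {
  stopifnot(inherits(truth, "asb_truth"))
  check_that(is_count(n_subjects), "`n_subjects` must be a positive integer")
  seqs <- assign_williams_sequences(n_subjects, seed)
  out <- with_seed(seed + 1L, {
    re_letters <- names(truth$re_sd)[truth$re_sd > 0]
    gid <- lapply(setNames(re_letters, re_letters), function(l) {
      stats::rnorm(n_subjects, 0, truth$re_sd[[l]])
    })
    rows <- vector("list", n_subjects * 3L)
    clamped <- 0L
    for (i in seq_len(n_subjects)) {
      for (ses in 1:3) {
        trt <- seqs[i, ses]
        start <- sample(truth$start_support, 1L)
        se <- vapply(re_letters, function(l) gid[[l]][i], numeric(1))
        p <- curve_params(truth$beta, trt, start,
                          se[setdiff(re_letters, "T")])
        p$gammaT <- if ("T" %in% re_letters) gid[["T"]][i] else 0
        occ <- stats::rnorm(1L, 0, truth$occasion_sd)
        y <- mu_curve(1:21, p, occasion = occ, transient = truth$transient) +
          stats::rnorm(21L, 0, sqrt(truth$sigma2))
        raw <- invert_transform(y, start, truth$shift)
        raw_int <- sign(raw) * floor(abs(raw) + 0.5)  # round half away from zero
        clamped <- clamped + sum(raw_int < 1 | raw_int > 10)
        raw_int <- pmin(pmax(raw_int, 1), 10)
        rows[[(i - 1L) * 3L + ses]] <- data.frame(
          subject = sprintf("S%02d", i), session = ses, treatment = trt,
          timepoint = 1:21, tlq = raw_int, y_true = y, start_true = start,
          stringsAsFactors = FALSE)
      }
    }
    dat <- do.call(rbind, rows)
    if (clamped > 0.2 * nrow(dat)) {
      warning(sprintf("%.1f%% of raw values were clamped to the 1-10 scale; the truth pushes trajectories off-scale",
                      100 * clamped / nrow(dat)), call. = FALSE)
    }
    dat
  })
  ord <- order(out$subject, out$session, out$timepoint)
  dat <- as_tlq_data(out[, c("subject", "session", "treatment", "timepoint", "tlq")])
  dat$y_true <- out$y_true[ord]
  dat$start_true <- out$start_true[ord]
  attr(dat, "truth") <- truth
  dat
}

# flatten an asb_truth's fixed effects to the draw naming scheme
truth_fixed_effects <- function(truth) {
  v <- as.vector(t(truth$beta))
  names(v) <- as.vector(t(outer(curve_letters(), coef_names(), paste, sep = ".")))
  v
}

#' Parameter-recovery experiment
#'
#' Simulates `reps` cohorts from a known truth, fits each with [asb_fit()]
#' and records, per replicate and fixed-effect parameter, the posterior mean,
#' the equal-tailed credible interval at `level`, the bias and whether the
#' interval covers the truth. Fit failures are counted and skipped rather
#' than fatal.
#'
#' With `response = "latent"` (the default) the fit consumes the simulated
#' transformed response itself — the calibration check of the hierarchical
#' model: data drawn from the model, fitted by the model. With
#' `response = "likert"` the fit sees the reconstructed integer scores pushed
#' back through the transformation chain; because that chain anchors T1 at
#' the shift constant (removing the T1 noise realisation and the occasion
#' effect from the PRE segment) and adds rounding error, PRE-segment
#' parameters are structurally misspecified under this mode and nominal
#' coverage is not expected there.
#'
#' @param reps number of replicates.
#' @param n_subjects cohort size per replicate.
#' @param truth an [asb_truth()] specification.
#' @param level credible level of the recovery intervals.
#' @param seed integer seed; replicate r uses `seed + r` throughout.
#' @param response which response the fit consumes, see Details.
#' @param ... passed to [asb_fit()] (chains, iter, burn_in, priors, ...).
#' @return data frame with columns `rep`, `parameter`, `truth`, `estimate`,
#'   `lower`, `upper`, `bias`, `covered`; attribute `"failures"` counts
#'   failed fits. Aggregate with [recovery_summary()].
#' @export
parameter_recovery <- function(reps, n_subjects, truth = asb_truth(),
                               level = 0.90, seed = 1L,
                               response = c("latent", "likert"), ...) {
  check_that(is_count(reps), "`reps` must be >= 1")
  response <- match.arg(response)
  tv <- truth_fixed_effects(truth)
  qs <- c((1 - level) / 2, 1 - (1 - level) / 2)
  failures <- 0L
  rows <- vector("list", reps)
  for (r in seq_len(reps)) {
    dat <- simulate_tlq(n_subjects, truth, seed = seed + r)
    if (response == "latent") {
      # fit the model's own response, with the generating baseline as the
      # Start covariate (the reconstructed T1 score carries the T1 noise
      # realisation, which would correlate covariate and response)
      dat$y <- dat$y_true
      dat$tlq[dat$timepoint == 1L] <- dat$start_true[dat$timepoint == 1L]
    }
    fit <- tryCatch(asb_fit(dat, seed = seed + r, ...),
                    error = function(e) NULL)
    if (is.null(fit)) {
      failures <- failures + 1L
      next
    }
    rec <- do.call(rbind, lapply(names(tv), function(p) {
      d <- draws_of(fit$draws, p)
      q <- stats::quantile(d, qs)
      data.frame(rep = r, parameter = p, truth = unname(tv[p]),
                 estimate = mean(d), lower = unname(q[1L]),
                 upper = unname(q[2L]),
                 bias = mean(d) - unname(tv[p]),
                 covered = q[1L] <= tv[p] && tv[p] <= q[2L],
                 stringsAsFactors = FALSE)
    }))
    rows[[r]] <- rec
  }
  out <- do.call(rbind, rows)
  check_that(!is.null(out), "all fits failed")
  rownames(out) <- NULL
  attr(out, "failures") <- failures
  attr(out, "level") <- level
  out
}

#' @rdname parameter_recovery
#' @param recovery a [parameter_recovery()] result.
#' @return `recovery_summary()`: one row per parameter with mean bias,
#'   mean posterior sd width and coverage proportion.
#' @export
recovery_summary <- function(recovery) {
  agg <- do.call(rbind, lapply(split(recovery, recovery$parameter), function(d) {
    data.frame(parameter = d$parameter[1L], truth = d$truth[1L],
               mean_bias = mean(d$bias),
               mean_width = mean(d$upper - d$lower),
               coverage = mean(d$covered),
               reps = nrow(d), stringsAsFactors = FALSE)
  }))
  rownames(agg) <- NULL
  agg
}

# fast interim analysis: normal-approximation posterior probabilities of the
# three working hypotheses from per-series online-vs-pre contrasts.
normal_interim_analysis <- function(data, delta) {
  data <- if (is.null(data$y)) preprocess_tlq(data) else data
  st <- series_table(data)
  seg <- segment_of(data$timepoint)
  key <- paste(data$subject, data$session, sep = ".")
  skey <- paste(st$subject, st$session, sep = ".")
  eff <- vapply(skey, function(k) {
    sel <- key == k
    mean(data$y[sel & seg == "online"]) - mean(data$y[sel & seg == "pre"])
  }, numeric(1))
  arm <- function(t) eff[st$treatment == t]
  contrast_prob <- function(x1, x0, thresh, two_sided_rope = FALSE) {
    m <- mean(x1) - mean(x0)
    se <- sqrt(stats::var(x1) / length(x1) + stats::var(x0) / length(x0))
    if (!is.finite(se) || se == 0) se <- .Machine$double.eps
    if (two_sided_rope) {
      stats::pnorm(thresh, m, se) - stats::pnorm(-thresh, m, se)
    } else {
      1 - stats::pnorm(thresh, m, se)
    }
  }
  h1 <- contrast_prob(arm("SP"), arm("PEI"), delta, two_sided_rope = TRUE)
  h2 <- contrast_prob(arm("tP"), arm("PEI"), delta)
  # dose-response: slope of the online response on cumulative dose minutes in tP
  tp <- data[data$treatment == "tP" & seg == "online", ]
  dose_prob <- NA_real_
  if (nrow(tp) > 4L) {
    minutes <- 2 * (tp$timepoint - 6)
    fit <- stats::lm(tp$y ~ minutes)
    sl <- summary(fit)$coefficients
    if (nrow(sl) == 2L && is.finite(sl[2L, 2L]) && sl[2L, 2L] > 0) {
      dose_prob <- 1 - stats::pnorm(0, sl[2L, 1L], sl[2L, 2L])
    }
  }
  list(h1_prob = h1, h2_prob = h2, dose_prob = dose_prob)
}

#' Operating characteristics of the adaptive design
#'
#' Simulates complete adaptive runs: per replicate a cohort is generated from
#' the scenario truth, analysed at each interim (default: the fast
#' normal-approximation engine on per-series online-vs-pre contrasts;
#' `method = "mcmc"` runs the full model fit and [treatment_contrast()]), and
#' pushed through [adaptive_decision()] with a valid delta. Reports, per
#' scenario, the rate of stopping for futility, the rate of declaring the
#' active arm superior (a credible H2), and the mean final sample size.
#'
#' @param scenarios named list; each element a list with `truth` (an
#'   [asb_truth()]) and `interims` (increasing cohort sizes).
#' @param reps replicates per scenario.
#' @param delta minimum clinical efficacy used by the analyses.
#' @param threshold credibility threshold.
#' @param seed integer seed.
#' @param method `"normal"` or `"mcmc"`.
#' @param ... passed to [asb_fit()] when `method = "mcmc"`.
#' @return data frame with one row per scenario: `futility_rate`,
#'   `superiority_rate`, `mean_final_n`.
#' @export
design_operating_characteristics <- function(scenarios, reps = 20L, delta = 0.4,
                                             threshold = 0.95, seed = 1L,
                                             method = c("normal", "mcmc"), ...) {
  method <- match.arg(method)
  check_that(is.list(scenarios) && length(scenarios) > 0L, "no scenarios")
  rows <- lapply(seq_along(scenarios), function(sc_i) {
    sc <- scenarios[[sc_i]]
    check_that(!is.null(sc$truth) && !is.null(sc$interims),
               "each scenario needs `truth` and `interims`")
    stopped <- superior <- logical(reps)
    final_n <- numeric(reps)
    for (r in seq_len(reps)) {
      rseed <- seed + 1000L * sc_i + r
      full <- simulate_tlq(max(sc$interims), sc$truth, seed = rseed)
      state <- asb_state(delta)
      state$delta_status <- "valid"
      subj_ids <- unique(full$subject)
      for (n in sc$interims) {
        dat <- full[full$subject %in% subj_ids[seq_len(n)], ]
        class(dat) <- c("tlq_data", "data.frame")
        probs <- if (method == "normal") {
          normal_interim_analysis(dat, delta)
        } else {
          fit <- asb_fit(dat, seed = rseed, ...)
          h2 <- treatment_contrast(fit, c("tP", "PEI"), "online", delta)
          h1 <- treatment_contrast(fit, c("SP", "PEI"), "online", delta)
          list(h1_prob = h1$p_equivalent, h2_prob = h2$p_greater,
               dose_prob = NA_real_)
        }
        dec <- adaptive_decision(state, probs$h1_prob, probs$h2_prob,
                                 probs$dose_prob, threshold)
        state <- dec$state
        final_n[r] <- n
        if (startsWith(dec$action, "stop")) {
          stopped[r] <- TRUE
          break
        }
        if (probs$h2_prob >= threshold) {
          superior[r] <- TRUE
          break
        }
      }
    }
    data.frame(scenario = names(scenarios)[sc_i] %||% as.character(sc_i),
               futility_rate = mean(stopped),
               superiority_rate = mean(superior),
               mean_final_n = mean(final_n),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
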