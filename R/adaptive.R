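# normal-approximation Bayes factor for equality of two posterior means.
# BF01 = N(d; 0, se) / N(d; 0, sqrt(se^2 + tau^2)): the observed mean
# difference d (with uncertainty se from both posteriors) under the point
# null against a Normal alternative of scale tau.
bf01_mean_difference <- function(m1, s1, m2, s2, prior_scale = 5) {
  d <- m1 - m2
  se <- sqrt(s1^2 + s2^2)
  if (se == 0) {
    return(if (d == 0) Inf else 0)
  }
  exp(stats::dnorm(d, 0, se, log = TRUE) -
        stats::dnorm(d, 0, sqrt(se^2 + prior_scale^2), log = TRUE))
}

#' Uncertainty reduction between successive interim posteriors
#'
#' Quantifies the information gained between interim stages for one quantity:
#' (1) the expected values of the two posteriors are compared with a
#' normal-approximation Bayes factor (equivalent when `BF01 > bf_threshold`);
#' (2) equal-tailed credible-interval lengths `L_prev` and `L_curr` are
#' computed at `level`; (3) `R = L_curr / L_prev` and
#' `UR = (1 - R) * 100` percent. With `method = "cv"` the posterior
#' coefficients of variation replace the interval lengths. In regular
#' accrual, UR shrinks towards zero as interim sample sizes grow (for a
#' Normal mean it follows the `1/sqrt(n)` law).
#'
#' @param prev,curr numeric vectors of posterior draws of the quantity at
#'   stages i-1 and i.
#' @param level credible level of the interval lengths.
#' @param method `"length"` (interval lengths) or `"cv"` (coefficients of
#'   variation).
#' @param bf_threshold equivalence threshold on BF01 (default 3, substantial
#'   evidence).
#' @param prior_scale scale of the Normal alternative in the Bayes factor, on
#'   the quantity's own scale.
#' @return list with `equivalent`, `bf01`, `L_prev`, `L_curr`, `R`, `UR`.
#' @export
uncertainty_reduction <- function(prev, curr, level = 0.95,
                                  method = c("length", "cv"),
                                  bf_threshold = 3, prior_scale = 5) {
  method <- match.arg(method)
  check_that(length(prev) > 0L && length(curr) > 0L, "empty posterior draws")
  bf <- bf01_mean_difference(mean(prev), stats::sd(prev) %|NA|% 0,
                             mean(curr), stats::sd(curr) %|NA|% 0,
                             prior_scale = prior_scale)
  qs <- c((1 - level) / 2, 1 - (1 - level) / 2)
  len <- function(x) {
    if (method == "length") {
      unname(diff(stats::quantile(x, qs)))
    } else {
      check_that(mean(x) != 0, "coefficient of variation undefined at mean 0")
      abs(stats::sd(x) / mean(x))
    }
  }
  L_prev <- len(prev)
  L_curr <- len(curr)
  if (L_prev == 0) {
    stop("uncertainty reduction undefined: previous-stage interval has length 0",
         call. = FALSE)
  }
  R <- L_curr / L_prev
  list(equivalent = bf >= bf_threshold, bf01 = bf,
       L_prev = L_prev, L_curr = L_curr, R = R, UR = (1 - R) * 100)
}

`%|NA|%` <- function(a, b) if (is.na(a)) b else a

#' Adaptive trial state
#'
#' Tracks the trial through its seamless stages: the delta status
#' (`processed_uncertain` while the minimum clinical efficacy is still being
#' confirmed, `processed_credible` after an in-margin update replaced it,
#' `valid` once confirmed), the current interim label (N3 during delta
#' confirmation, N4/N5/N6 for the hypothesis and dose interims), the working
#' delta, and an append-only decision log.
#'
#' @param delta initial (anterior) minimum clinical efficacy.
#' @return an object of class `"asb_state"`.
#' @export
asb_state <- function(delta = 0.4) {
  check_that(is.numeric(delta) && delta > 0, "delta must be > 0")
  structure(list(stage = "exploratory",
                 delta_status = "processed_uncertain",
                 delta = delta,
                 interim = "N3",
                 log = data.frame(event = character(0), detail = character(0),
                                  stringsAsFactors = FALSE)),
            class = "asb_state")
}

state_log <- function(state, event, detail) {
  state$log <- rbind(state$log,
                     data.frame(event = event, detail = detail,
                                stringsAsFactors = FALSE))
  state
}

#' @export
print.asb_state <- function(x, ...) {
  cat(sprintf("adaptive state: stage %s, delta %s (%.4g), next interim %s\n",
              x$stage, x$delta_status, x$delta, x$interim))
  if (nrow(x$log) > 0L) {
    cat("decision log:\n")
    for (i in seq_len(nrow(x$log))) {
      cat(sprintf("  %d. [%s] %s\n", i, x$log$event[i], x$log$detail[i]))
    }
  }
  invisible(x)
}

#' Update the processed delta at an interim
#'
#' Implements the three delta-confirmation outcomes. Writing `L` for the
#' credible-interval length of the new delta posterior and `margin` for the
#' desired credibility margin (default: half the working delta):
#' (1) the new posterior is not within the margin (`L > margin`) -- the
#' anterior delta remains acceptable and recruitment continues with N3
#' interims; (2) within margin and the difference from the anterior delta is
#' significant (`BF01 < 1/bf_threshold`) -- the updated delta replaces the
#' anterior one, downstream margins and sample sizes must be re-adapted, and
#' recruitment continues with adapted N3 interims; (3) within margin and the
#' difference is insignificant (`BF01 > bf_threshold`, with intermediate
#' evidence treated the same way) -- the delta becomes valid and the
#' confirmation stage ends.
#'
#' @param state an [asb_state()] object.
#' @param prev_delta,new_delta posterior draws of delta at the previous and
#'   current interim.
#' @param margin_fraction desired credibility margin as a fraction of the
#'   working delta.
#' @param level credible level of the margin check.
#' @param bf_threshold,prior_scale Bayes-factor settings, see
#'   [uncertainty_reduction()].
#' @return the updated `asb_state`.
#' @export
processed_delta_update <- function(state, prev_delta, new_delta,
                                   margin_fraction = 0.5, level = 0.95,
                                   bf_threshold = 3, prior_scale = 5) {
  stopifnot(inherits(state, "asb_state"))
  check_that(length(prev_delta) > 0L && length(new_delta) > 0L,
             "empty delta posteriors")
  qs <- c((1 - level) / 2, 1 - (1 - level) / 2)
  L <- unname(diff(stats::quantile(new_delta, qs)))
  margin <- margin_fraction * abs(state$delta)
  bf <- bf01_mean_difference(mean(prev_delta), stats::sd(prev_delta) %|NA|% 0,
                             mean(new_delta), stats::sd(new_delta) %|NA|% 0,
                             prior_scale = prior_scale)
  if (L > margin) {
    state$delta_status <- "processed_uncertain"
    state$interim <- "N3"
    return(state_log(state, "delta_interim",
                     sprintf("new delta CI length %.4g exceeds margin %.4g; anterior delta %.4g retained; continue N3",
                             L, margin, state$delta)))
  }
  if (bf < 1 / bf_threshold) {
    state$delta <- mean(new_delta)
    state$delta_status <- "processed_credible"
    state$interim <- "N3"
    return(state_log(state, "delta_interim",
                     sprintf("significant in-margin update (BF01 %.3g); delta replaced by %.4g; margins and sample sizes re-adapted; continue adapted N3",
                             bf, state$delta)))
  }
  state$delta_status <- "valid"
  state$stage <- "confirmatory"
  return(state_log(state, "delta_interim",
                   sprintf("insignificant in-margin update (BF01 %.3g); delta %.4g valid; confirmation stage ends",
                           bf, state$delta)))
}

#' Adaptive decision at a hypothesis interim
#'
#' Encodes the study roadmap as a pure function of the current state and the
#' posterior probabilities of the three working hypotheses: H1 (sham-plus-PEI
#' is equivalent to PEI alone), H2 (active stimulation plus PEI is superior
#' to PEI beyond delta) and Dose (a dose-response relationship exists).
#' Probabilities are credible when they reach `threshold` (and credibly
#' against when below `1 - threshold`).
#'
#' Outcomes with a valid delta: credible evidence against H2 stops the study
#' (active stimulation indistinct from the active control); credible H2
#' together with credible Dose defines the minimum/maximum effective dose and
#' adapts to the multisession confirmatory study; credible evidence for H1
#' eliminates the PEI-alone session; credible H2 with partial Dose continues
#' with N6 interims; partial H2 with partial Dose continues with N5 interims;
#' otherwise the hypothesis interims continue with N4. While delta is merely
#' processed, every conclusion carries a certainty ratio (the reported
#' posterior probability) and recruitment continues with N3 interims.
#'
#' @param state an [asb_state()] object.
#' @param h1_prob posterior probability of H1 equivalence
#'   (`P(|mu_SP - mu_PEI| < delta)`).
#' @param h2_prob posterior probability of H2 superiority
#'   (`P(mu_tP - mu_PEI > delta)`).
#' @param dose_prob posterior probability of the dose-response relationship;
#'   `NA` when no dose analysis was run (then no dose action is taken).
#' @param threshold credibility threshold (default 0.95).
#' @return list with `action`, `next_interim`, `note`, and the updated
#'   `state`.
#' @export
adaptive_decision <- function(state, h1_prob, h2_prob, dose_prob = NA_real_,
                              threshold = 0.95) {
  stopifnot(inherits(state, "asb_state"))
  probs <- c(h1_prob, h2_prob, dose_prob)
  check_that(all(is.na(probs) | (probs >= 0 & probs <= 1)),
             "probabilities must lie in [0,1]")
  check_that(is_prob(threshold), "`threshold` must be in (0,1)")
  if (!is.na(dose_prob) && state$delta_status == "processed_uncertain" &&
      nrow(state$log) == 0L) {
    stop("inconsistent state: dose decision requested before any delta processing",
         call. = FALSE)
  }
  decide <- function(action, next_interim, note) {
    st <- state_log(state, "hypothesis_interim", sprintf("%s (%s)", action, note))
    st$interim <- next_interim
    list(action = action, next_interim = next_interim, note = note, state = st)
  }
  if (state$delta_status != "valid") {
    return(decide("continue",
                  "N3",
                  sprintf("delta still processed; conclusions carry certainty ratios (H1 %.3f, H2 %.3f); recruitment continues with N3 interims",
                          h1_prob, h2_prob)))
  }
  if (h2_prob <= 1 - threshold) {
    return(decide("stop: tP not different from PEI", "none",
                  sprintf("credible evidence against H2 (P = %.3f); the study ends", h2_prob)))
  }
  h2_credible <- h2_prob >= threshold
  dose_credible <- !is.na(dose_prob) && dose_prob >= threshold
  dose_rejected <- !is.na(dose_prob) && dose_prob <= 1 - threshold
  if (h2_credible && dose_credible) {
    return(decide("define min/max dose; adapt to multisession study", "confirmatory",
                  sprintf("valid delta with credible H2 (%.3f) and credible Dose (%.3f)",
                          h2_prob, dose_prob)))
  }
  if (h2_credible && dose_rejected) {
    return(decide("no dose-response relationship", "N4",
                  sprintf("credible H2 (%.3f) but credible evidence against Dose (%.3f)",
                          h2_prob, dose_prob)))
  }
  if (h1_prob >= threshold) {
    return(decide("adapt: eliminate PEI session", "N4",
                  sprintf("credible evidence for H1 equivalence (P = %.3f); SP is similar to PEI", h1_prob)))
  }
  if (h2_credible) {
    return(decide("continue", "N6",
                  sprintf("credible H2 (%.3f) with partial Dose; recruitment continues with N6 interims", h2_prob)))
  }
  if (!is.na(dose_prob)) {
    return(decide("continue", "N5",
                  sprintf("partial H2 (%.3f) and partial Dose (%.3f); recruitment continues with N5 interims",
                          h2_prob, dose_prob)))
  }
  decide("continue", "N4",
         sprintf("partial H1 (%.3f) / H2 (%.3f); recruitment continues with N4 interims",
                 h1_prob, h2_prob))
}
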