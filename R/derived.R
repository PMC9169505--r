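#' Online gain and trial carry-over
#'
#' `Gain = c - f` is the potential gain of the mean response during the
#' online period; `CO = g - a` is the potential carry-over within the trial
#' (POST minimum relative to the PRE endpoint).
#'
#' @param params named list/vector with elements `c`, `f`, `g`, `a` (extra
#'   elements ignored). Vectors are accepted element-wise, so posterior draws
#'   can be pushed through directly.
#' @return list with numeric `gain` and `co`.
#' @export
gain_and_carryover <- function(params) {
  p <- as.list(params)
  check_that(!is.null(p$c) && !is.null(p$f) && !is.null(p$g) && !is.null(p$a),
             "need curve quantities a, c, f, g")
  list(gain = p$c - p$f, co = p$g - p$a)
}

#' Minimum and maximum effective time points of the online logistic
#'
#' The logistic online curve first differs from its floor by the minimum
#' clinical efficacy `delta` at
#' `DMin = e - (1/d) log((c - f - delta)/delta)` and last differs from its
#' plateau by `delta` at
#' `DMax = e + (1/d) log((c - f - delta)/delta)`, so that
#' `G_O(DMin) = f + delta` and `G_O(DMax) = c - delta`, and
#' `DMin + DMax = 2 e`.
#'
#' @param c,f,d,e logistic parameters (plateau, floor, growth intensity,
#'   inflection time); vectors are accepted element-wise.
#' @param delta minimum clinical efficacy, must satisfy `0 < delta` and
#'   `c - f > 2 delta`.
#' @return list with numeric `dmin` and `dmax`.
#' @export
dmin_dmax <- function(c, f, d, e, delta) {
  check_that(all(d != 0), "undefined dose times: growth intensity d is 0")
  if (any(delta <= 0)) {
    stop("undefined dose times: delta must be > 0 (got ",
         min(delta), ")", call. = FALSE)
  }
  if (any(c - f <= 2 * delta)) {
    stop("undefined dose times: need gain c - f > 2*delta (violated: c - f = ",
         signif(min(c - f), 4), " vs 2*delta = ", signif(max(2 * delta), 4), ")",
         call. = FALSE)
  }
  w <- log((c - f - delta) / delta) / d
  list(dmin = e - w, dmax = e + w)
}

#' Minimum clinical efficacy (delta)
#'
#' Delta is 50% of the observed effectiveness of the active control (PEI).
#' In descriptive mode it is half the displacement of the mean online
#' transformed response from the mean PRE transformed response across the PEI
#' series. In posterior mode it is the distribution of half the PEI online
#' gain (`0.5 * (c - f)` at PEI covariates) across posterior draws.
#'
#' @param x a preprocessed `tlq_data` object (descriptive mode) or an
#'   `asb_fit` (posterior mode).
#' @param level credible level for the posterior-mode interval.
#' @param start baseline covariate at which to evaluate posterior-mode gain;
#'   defaults to the mean observed baseline.
#' @return list with `delta` (point value: the descriptive delta or the
#'   posterior mean), `provenance` (`"descriptive"` or `"posterior"`), and in
#'   posterior mode `draws` and `ci`.
#' @export
minimum_clinical_efficacy <- function(x, level = 0.95, start = NULL) {
  if (inherits(x, "asb_fit")) {
    start <- start %||% mean(x$series$start)
    cpei <- draws_of(x$draws, "c.Intercept") + draws_of(x$draws, "c.Start") * start
    fpei <- draws_of(x$draws, "f.Intercept") + draws_of(x$draws, "f.Start") * start
    d <- 0.5 * (cpei - fpei)
    qs <- stats::quantile(d, c((1 - level) / 2, 1 - (1 - level) / 2))
    if (mean(d) <= 0) {
      stop("estimated PEI effect is non-positive; delta undefined", call. = FALSE)
    }
    return(list(delta = mean(d), provenance = "posterior",
                draws = d, ci = unname(qs)))
  }
  x <- as_tlq_data(x)
  check_that(!is.null(x$y), "descriptive mode needs preprocessed data (column `y`)")
  pei <- x[x$treatment == "PEI", ]
  check_that(nrow(pei) > 0L, "no PEI series present")
  seg <- segment_of(pei$timepoint)
  displacement <- mean(pei$y[seg == "online"]) - mean(pei$y[seg == "pre"])
  if (displacement <= 0) {
    stop("observed PEI effect is non-positive; delta undefined", call. = FALSE)
  }
  list(delta = 0.5 * displacement, provenance = "descriptive")
}

#' Individuals control chart with natural limits
#'
#' Shewhart individuals chart: centre line at the mean, natural limits at
#' `mean +/- k * mean moving range` (the conventional individuals-chart
#' constant k = 2.66 by default). Points outside the limits signal
#' fundamental changes in expected behaviour rather than random variation.
#'
#' @param values ordered numeric observations (>= 2).
#' @param k moving-range multiplier.
#' @return list with `center`, `lower`, `upper`, `moving_range` (its mean)
#'   and `out_of_limits` (integer indices).
#' @export
control_chart <- function(values, k = 2.66) {
  check_that(is.numeric(values) && length(values) >= 2L,
             "need at least 2 values for a control chart")
  mr <- mean(abs(diff(values)))
  center <- mean(values)
  lower <- center - k * mr
  upper <- center + k * mr
  list(center = center, lower = lower, upper = upper, moving_range = mr,
       out_of_limits = which(values < lower | values > upper))
}

#' Posterior treatment contrast at a time point or period
#'
#' Per posterior draw, evaluates the population mean curve for both
#' treatments at the requested time point (or averaged over a named period)
#' and summarises the difference `t1 - t2`: posterior mean, equal-tailed
#' interval, the superiority probability `P(diff > delta)` and the
#' equivalence (ROPE) probability `P(|diff| < delta)`.
#'
#' @param fit an `asb_fit` object.
#' @param pair character vector of two treatments, contrast is
#'   `pair[1] - pair[2]`.
#' @param timepoint a numeric time point, or one of `"pre"`, `"online"`,
#'   `"post"` to average the curve over that period.
#' @param delta minimum clinical efficacy.
#' @param start baseline covariate (cancels in the contrast since both arms
#'   share the Start coefficient; kept for completeness).
#' @param level credible level.
#' @return list with `mean`, `ci`, `p_greater`, `p_equivalent`, `draws`.
#' @export
treatment_contrast <- function(fit, pair = c("tP", "PEI"), timepoint = "online",
                               delta = 0.4, start = NULL, level = 0.95) {
  stopifnot(inherits(fit, "asb_fit"))
  check_that(length(pair) == 2L && all(pair %in% asb_treatments()),
             "unknown treatment pair: %s", paste(pair, collapse = ","))
  start <- start %||% mean(fit$series$start)
  jj <- if (is.character(timepoint)) {
    check_that(timepoint %in% names(segment_scheme()$segments),
               "unknown period '%s'", timepoint)
    segment_scheme()$segments[[timepoint]]
  } else {
    check_that(all(timepoint >= 1 & timepoint <= 21), "time point out of range")
    timepoint
  }
  total <- fit$draws$meta$kept * fit$draws$meta$chains
  bd <- lapply(setNames(curve_letters(), curve_letters()), function(l) {
    vapply(coef_names(), function(p) draws_of(fit$draws, paste0(l, ".", p)),
           numeric(total))
  })
  curve_at <- function(trt, k) {
    p <- lapply(bd, function(m) {
      m[k, "Intercept"] + m[k, "SP"] * (trt == "SP") +
        m[k, "tP"] * (trt == "tP") + m[k, "Start"] * start
    })
    mean(mu_curve(jj, p, transient = fit$transient))
  }
  d <- vapply(seq_len(total), function(k) {
    curve_at(pair[1L], k) - curve_at(pair[2L], k)
  }, numeric(1))
  qs <- stats::quantile(d, c((1 - level) / 2, 1 - (1 - level) / 2))
  list(mean = mean(d), ci = unname(qs),
       p_greater = mean(d > delta),
       p_equivalent = mean(abs(d) < delta),
       draws = d)
}

#' Stimulation dose at a probe time point
#'
#' Dose is intensity times elapsed stimulation time (mA minutes), evaluated
#' at the probe timestamp. On the default session timeline the online probes
#' are spaced 2 minutes apart with stimulation onset at T6, so
#' `minutes = spacing * (timepoint - onset)` and a full 2 mA session reaches
#' 2 x 20 = 40 mA min at T16.
#'
#' @param timepoint model time point (may be fractional, e.g. a DMin/DMax).
#' @param intensity stimulation intensity in mA (default 2).
#' @param spacing minutes between online probes (default 2).
#' @param onset time point of stimulation onset (default 6).
#' @return list with `intensity` (mA), `minutes` and `dose` (mA min).
#' @export
dose_at <- function(timepoint, intensity = 2, spacing = 2, onset = 6) {
  check_that(all(intensity >= 0) && spacing > 0, "invalid timeline")
  if (any(timepoint < onset)) {
    stop("time point precedes stimulation onset (T", onset, ")", call. = FALSE)
  }
  minutes <- spacing * (timepoint - onset)
  list(intensity = intensity, minutes = minutes, dose = intensity * minutes)
}

#' Posterior derived dose-response quantities for one treatment
#'
#' Pushes every posterior draw through the Table-of-derived-quantities map:
#' online gain `c - f`, carry-over `g - a`, the minimum/maximum effective
#' time points [dmin_dmax()] at the supplied (or posterior PEI) delta, and
#' the corresponding minimum/maximum effective doses via [dose_at()]. Draws
#' violating the DMin/DMax precondition (gain not exceeding `2 delta`, or
#' `d = 0`) are excluded and the exclusion fraction reported.
#'
#' @param fit an `asb_fit` object.
#' @param treatment treatment arm to evaluate (default `"tP"`).
#' @param delta minimum clinical efficacy; default takes the posterior delta
#'   from [minimum_clinical_efficacy()] draw by draw.
#' @param start baseline covariate; defaults to the mean observed baseline.
#' @param intensity,spacing,onset dose timeline, see [dose_at()].
#' @param level credible level.
#' @return data frame with one row per quantity (`gain`, `co`, `delta`,
#'   `dmin`, `dmax`, `dose_min`, `dose_max`) and columns `mean`, `sd`,
#'   `lower`, `upper`; attribute `"excluded_fraction"` gives the share of
#'   draws dropped by the DMin/DMax preconditions.
#' @export
derive_quantities <- function(fit, treatment = "tP", delta = NULL, start = NULL,
                              intensity = 2, spacing = 2, onset = 6,
                              level = 0.95) {
  stopifnot(inherits(fit, "asb_fit"))
  check_that(treatment %in% asb_treatments(), "unknown treatment '%s'", treatment)
  start <- start %||% mean(fit$series$start)
  total <- fit$draws$meta$kept * fit$draws$meta$chains
  at <- function(l) {
    draws_of(fit$draws, paste0(l, ".Intercept")) +
      draws_of(fit$draws, paste0(l, ".SP")) * (treatment == "SP") +
      draws_of(fit$draws, paste0(l, ".tP")) * (treatment == "tP") +
      draws_of(fit$draws, paste0(l, ".Start")) * start
  }
  a <- at("a"); cc <- at("c"); d <- at("d"); e <- at("e")
  f <- at("f"); g <- at("g")
  gain <- cc - f
  co <- g - a
  deltas <- if (is.null(delta)) {
    0.5 * ((draws_of(fit$draws, "c.Intercept") + draws_of(fit$draws, "c.Start") * start) -
           (draws_of(fit$draws, "f.Intercept") + draws_of(fit$draws, "f.Start") * start))
  } else {
    rep_len(delta, total)
  }
  ok <- deltas > 0 & (gain > 2 * deltas) & d != 0 & gain > 0
  w <- log((gain[ok] - deltas[ok]) / deltas[ok]) / d[ok]
  dmin <- e[ok] - w
  dmax <- e[ok] + w
  # dose times outside the stimulation window are excluded alongside
  in_win <- dmin >= onset & dmax <= 16
  dose_min <- intensity * spacing * (dmin[in_win] - onset)
  dose_max <- intensity * spacing * (dmax[in_win] - onset)
  qs <- c((1 - level) / 2, 1 - (1 - level) / 2)
  row <- function(name, v) {
    data.frame(quantity = name, mean = mean(v), sd = stats::sd(v),
               lower = unname(stats::quantile(v, qs[1L])),
               upper = unname(stats::quantile(v, qs[2L])),
               stringsAsFactors = FALSE)
  }
  out <- rbind(row("gain", gain), row("co", co), row("delta", deltas),
               row("dmin", dmin), row("dmax", dmax),
               row("dose_min", dose_min), row("dose_max", dose_max))
  attr(out, "excluded_fraction") <- 1 - sum(in_win) / total
  attr(out, "treatment") <- treatment
  out
}
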