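#' Segment scheme of the 21-point session
#'
#' Time points partition into PRE (1-5, no stimulation), a transient bridge
#' point (6, stimulation onset), ONLINE (7-16, one probe after each of the
#' ten picture blocks under stimulation) and POST (17-21, after stimulation).
#' Detrending references each point against the starting point of its
#' segment: PRE against T1, the online block (T6-T16) against T5, POST
#' against T16.
#'
#' @return a list with elements `segments` (named list of time-point vectors)
#'   and `refs` (named integer vector of detrending reference time points for
#'   the pre, online and post blocks).
#' @export
segment_scheme <- function() {
  list(
    segments = list(pre = 1:5, transient = 6L, online = 7:16, post = 17:21),
    refs = c(pre = 1L, online = 5L, post = 16L)
  )
}

#' Segment membership of time points
#' @param j integer time point(s) in 1-21.
#' @return character vector: `"pre"`, `"transient"`, `"online"` or `"post"`.
#' @export
segment_of <- function(j) {
  check_that(all(j >= 1 & j <= 21), "time points must lie in 1-21")
  out <- character(length(j))
  out[j <= 5] <- "pre"
  out[j == 6] <- "transient"
  out[j >= 7 & j <= 16] <- "online"
  out[j >= 17] <- "post"
  out
}

#' Detrend a raw 21-point series against segment references
#'
#' Computes the cumulative variation of each time point against the starting
#' point (reference) of its segment: `d_j = raw_j - raw_T1` for j in 1-5,
#' `d_j = raw_j - raw_T5` for j in 6-16 and `d_j = raw_j - raw_T16` for j in
#' 17-21.
#'
#' @param raw numeric vector of 21 raw responses ordered by time point.
#' @param scheme segment scheme, see [segment_scheme()].
#' @return numeric vector of 21 detrended values.
#' @export
detrend <- function(raw, scheme = segment_scheme()) {
  check_that(length(raw) == 21L && !anyNA(raw), "`raw` must be 21 complete values")
  d <- numeric(21L)
  d[1:5] <- raw[1:5] - raw[scheme$refs[["pre"]]]
  d[6:16] <- raw[6:16] - raw[scheme$refs[["online"]]]
  d[17:21] <- raw[17:21] - raw[scheme$refs[["post"]]]
  d
}

#' Reverse and shift a detrended series
#'
#' Reverses the detrended response so that larger values mean greater
#' reduction in perceived loudness ("the more, the better"), then shifts it
#' to the positive axis: `Y_j = shift - d_j`. With the default shift of 5
#' the series sits at 5 at each segment reference.
#'
#' @param detrended numeric vector of 21 detrended values.
#' @param shift shift constant (default 5, matching the prior centring of the
#'   PRE-end level).
#' @return numeric vector Y of 21 transformed values.
#' @export
reverse_shift <- function(detrended, shift = 5) {
  check_that(length(detrended) == 21L, "`detrended` must have 21 values")
  shift - detrended
}

#' Transform raw TLQ data to the modelled response
#'
#' Applies the full chain [detrend()] then [reverse_shift()] per series and
#' appends the result as column `y`. The transform operates on each session
#' independently; there is no cross-session normalisation.
#'
#' @param x a `tlq_data` object (see [as_tlq_data()]).
#' @param shift shift constant.
#' @return `x` with an added numeric column `y` and attribute `"shift"`.
#' @export
preprocess_tlq <- function(x, shift = 5) {
  x <- as_tlq_data(x)
  x$y <- NA_real_
  key <- interaction(x$subject, x$session, drop = TRUE)
  for (k in levels(key)) {
    sel <- key == k
    raw <- x$tlq[sel][order(x$timepoint[sel])]
    x$y[sel][order(x$timepoint[sel])] <- reverse_shift(detrend(raw), shift)
  }
  attr(x, "shift") <- shift
  x
}

#' Invert the transformation chain
#'
#' Reconstructs the raw series from the transformed response, the shift
#' constant, and the baseline `start` (the raw value at T1). The inversion is
#' exact and proceeds segment by segment: `raw_j = raw_ref + (shift - Y_j)`,
#' where the references are T1 (pre block, anchored at `start`), the
#' reconstructed T5 (online block) and the reconstructed T16 (post block).
#' Used by the simulator to turn model-scale trajectories into Likert scores.
#'
#' @param y numeric vector of 21 transformed values.
#' @param start raw response at time point 1.
#' @param shift shift constant used in the forward transform.
#' @return numeric vector of 21 raw (continuous, unrounded) values.
#' @export
invert_transform <- function(y, start, shift = 5) {
  check_that(length(y) == 21L && !anyNA(y), "`y` must be 21 complete values")
  raw <- numeric(21L)
  raw[1:5] <- start + (shift - y[1:5])
  raw[6:16] <- raw[5L] + (shift - y[6:16])
  raw[17:21] <- raw[16L] + (shift - y[17:21])
  raw
}
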