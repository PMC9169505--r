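#' Treatment arms and Williams sequences
#'
#' The trial compares three treatments: `PEI` (positive emotion induction
#' alone, the active control and reference level), `SP` (sham stimulation
#' concurrent with PEI) and `tP` (active HD-tDCS concurrent with PEI).
#'
#' @return `asb_treatments()` returns the treatment levels in their fixed
#'   reference order. `williams_orderings()` returns the six period orderings
#'   of the three treatments used by the Williams crossover design (the union
#'   of two mutually orthogonal 3x3 Latin squares, i.e. all six permutations),
#'   as a 6 x 3 character matrix in a fixed lexicographic enumeration.
#' @examples
#' williams_orderings()
#' @export
asb_treatments <- function() c("PEI", "SP", "tP")

#' @rdname asb_treatments
#' @export
williams_orderings <- function() {
  trt <- asb_treatments()
  perms <- rbind(
    c(1L, 2L, 3L), c(1L, 3L, 2L),
    c(2L, 1L, 3L), c(2L, 3L, 1L),
    c(3L, 1L, 2L), c(3L, 2L, 1L)
  )
  m <- matrix(trt[perms], nrow = 6L, ncol = 3L,
              dimnames = list(sequence = 1:6, period = paste0("period", 1:3)))
  m
}

#' Assign Williams-design treatment sequences
#'
#' Randomly assigns each subject one of the six Williams orderings of
#' \{PEI, SP, tP\}, balanced so that the per-ordering counts differ by at
#' most one across the cohort. Deterministic given `seed`.
#'
#' @param n_subjects number of subjects (>= 1).
#' @param seed integer seed.
#' @return an `n_subjects` x 3 character matrix of treatments by period, with
#'   attribute `"sequence"` giving the ordering index (1-6) per subject.
#' @examples
#' assign_williams_sequences(6, seed = 1)
#' @export
assign_williams_sequences <- function(n_subjects, seed) {
  check_that(is_count(n_subjects), "`n_subjects` must be a positive integer")
  ord <- williams_orderings()
  idx <- with_seed(seed, {
    base <- rep(1:6, times = n_subjects %/% 6L)
    extra <- if (n_subjects %% 6L > 0L) sample(6L, n_subjects %% 6L) else integer(0)
    sample(c(base, extra))
  })
  out <- ord[idx, , drop = FALSE]
  rownames(out) <- paste0("subject", seq_len(n_subjects))
  attr(out, "sequence") <- idx
  out
}

# ---- TLQ long-format data -------------------------------------------------

#' Validate and classify long-format TLQ data
#'
#' The canonical exchange format is a long table with one row per observation
#' and columns `subject`, `session` (1-3), `treatment` (PEI/SP/tP),
#' `timepoint` (1-21) and `tlq` (integer Likert score 1-10); an optional
#' `minutes` column carries elapsed-minute probe timestamps. Each
#' subject-session series must contain all 21 time points exactly once, a
#' subject's sessions must carry distinct treatments, and the per-series
#' baseline `Start` is the raw response at time point 1.
#'
#' @param x a data frame in the long format above.
#' @return `x`, sorted by subject, session and timepoint, with class
#'   `"tlq_data"` prepended.
#' @seealso [read_tlq_long()], [series_table()]
#' @export
as_tlq_data <- function(x) {
  check_that(is.data.frame(x), "TLQ data must be a data frame")
  required <- c("subject", "session", "treatment", "timepoint", "tlq")
  missing_cols <- setdiff(required, names(x))
  check_that(length(missing_cols) == 0L,
             "TLQ data lacks column(s): %s", paste(missing_cols, collapse = ", "))
  x <- as.data.frame(x)
  x$subject <- as.character(x$subject)
  x$session <- as.integer(x$session)
  x$timepoint <- as.integer(x$timepoint)
  x$tlq <- as.numeric(x$tlq)

  bad_trt <- !(x$treatment %in% asb_treatments())
  if (any(bad_trt)) {
    i <- which(bad_trt)[1L]
    stop(sprintf("unknown treatment label '%s' (subject %s, session %s, timepoint %s)",
                 x$treatment[i], x$subject[i], x$session[i], x$timepoint[i]),
         call. = FALSE)
  }
  x$treatment <- factor(as.character(x$treatment), levels = asb_treatments())

  bad_sess <- is.na(x$session) | x$session < 1L | x$session > 3L
  if (any(bad_sess)) {
    i <- which(bad_sess)[1L]
    stop(sprintf("session index out of 1-3 (subject %s, row %d)", x$subject[i], i),
         call. = FALSE)
  }
  bad_tlq <- is.na(x$tlq) | x$tlq < 1 | x$tlq > 10
  if (any(bad_tlq)) {
    i <- which(bad_tlq)[1L]
    stop(sprintf("tlq outside 1-10 (subject %s, session %d, timepoint %d: %s)",
                 x$subject[i], x$session[i], x$timepoint[i], x$tlq[i]),
         call. = FALSE)
  }
  bad_tp <- is.na(x$timepoint) | x$timepoint < 1L | x$timepoint > 21L
  if (any(bad_tp)) {
    i <- which(bad_tp)[1L]
    stop(sprintf("timepoint outside 1-21 (subject %s, session %d: %s)",
                 x$subject[i], x$session[i], x$timepoint[i]),
         call. = FALSE)
  }

  key <- interaction(x$subject, x$session, drop = TRUE)
  for (k in levels(key)) {
    rows <- x[key == k, ]
    tp <- sort(rows$timepoint)
    dup <- unique(tp[duplicated(tp)])
    if (length(dup) > 0L) {
      stop(sprintf("duplicate timepoint(s) %s in series subject %s, session %d",
                   paste(dup, collapse = ", "), rows$subject[1L], rows$session[1L]),
           call. = FALSE)
    }
    miss <- setdiff(1:21, tp)
    if (length(miss) > 0L) {
      stop(sprintf("series subject %s, session %d is missing timepoint(s) %s",
                   rows$subject[1L], rows$session[1L], paste(miss, collapse = ", ")),
           call. = FALSE)
    }
    if (length(unique(rows$treatment)) != 1L) {
      stop(sprintf("series subject %s, session %d mixes treatment labels",
                   rows$subject[1L], rows$session[1L]), call. = FALSE)
    }
  }
  # sessions of one subject must carry distinct treatments
  st <- unique(x[, c("subject", "session", "treatment")])
  for (s in unique(st$subject)) {
    trt <- st$treatment[st$subject == s]
    check_that(length(trt) <= 3L && !any(duplicated(trt)),
               "subject %s repeats a treatment across sessions", s)
  }

  x <- x[order(x$subject, x$session, x$timepoint), , drop = FALSE]
  rownames(x) <- NULL
  class(x) <- c("tlq_data", "data.frame")
  x
}

#' Read and write long-format TLQ data
#'
#' `read_tlq_long()` reads a delimited text file with header columns
#' `subject,session,treatment,timepoint,tlq` (optionally `minutes`),
#' validates it (see [as_tlq_data()]) and returns a `tlq_data` object.
#' `write_tlq_long()` writes one back out as CSV.
#'
#' @param path file path.
#' @param x a `tlq_data` object (or validatable data frame).
#' @return `read_tlq_long()`: a `tlq_data` data frame; `write_tlq_long()`:
#'   `path`, invisibly.
#' @export
read_tlq_long <- function(path) {
  check_that(file.exists(path), "file not found: %s", path)
  as_tlq_data(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname read_tlq_long
#' @export
write_tlq_long <- function(x, path) {
  x <- as_tlq_data(x)
  utils::write.csv(as.data.frame(x), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Per-series summary of a TLQ dataset
#'
#' One row per subject-session series with its treatment and the baseline
#' covariate `start`, the raw response at time point 1 (the model's `Start`
#' predictor).
#'
#' @param x a `tlq_data` object.
#' @return data frame with columns `subject`, `session`, `treatment`, `start`.
#' @export
series_table <- function(x) {
  x <- as_tlq_data(x)
  first <- x[x$timepoint == 1L, c("subject", "session", "treatment", "tlq")]
  names(first)[4L] <- "start"
  rownames(first) <- NULL
  first
}

#' @export
print.tlq_data <- function(x, ...) {
  st <- series_table(x)
  cat(sprintf("TLQ dataset: %d observations, %d series, %d subjects\n",
              nrow(x), nrow(st), length(unique(x$subject))))
  cat("treatment series counts:",
      paste(sprintf("%s=%d", levels(st$treatment), table(st$treatment)), collapse = ", "),
      "\n")
  print(utils::head(as.data.frame(x), 6L))
  if (nrow(x) > 6L) cat("...\n")
  invisible(x)
}
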