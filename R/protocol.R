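#' Default emotional Stroop word lists
#'
#' Six tinnitus-descriptor (emotional) words and six neutral words matched on
#' syllables, length and frequency of use in Portuguese.
#'
#' @return `est_words()`: list with character vectors `neutral` and
#'   `emotional`, each of length 6.
#' @export
est_words <- function() {
  list(neutral = c("Garrafa", "Banheiro", "Luz", "Antigo", "Milho", "Patio"),
       emotional = c("Cigarra", "Campainha", "Tom", "Apito", "Grilo", "Radio"))
}

# fixed response-key map of the Stroop task
est_key_map <- function() {
  c(green = "Z", yellow = "X", blue = "N", red = "M")
}

#' Synthetic picture catalog
#'
#' Generates a synthetic valence/arousal catalog shaped like a normative
#' picture database rating table (9-point valence `Vr` and arousal `Ar`
#' scales): `n_neutral` pictures with 4 < Vr < 6 and Ar < 6, and
#' `n_positive` with Vr > 6, of which `n_hav` also have Ar > 6 (the
#' high-arousal-valence stratum). No real picture ratings are reproduced.
#'
#' @param n_neutral,n_positive,n_hav stratum sizes.
#' @param seed integer seed.
#' @return data frame with columns `id`, `valence`, `arousal`.
#' @export
make_picture_catalog <- function(n_neutral = 100L, n_positive = 100L,
                                 n_hav = 45L, seed = 1L) {
  check_that(n_hav <= n_positive, "`n_hav` cannot exceed `n_positive`")
  with_seed(seed, {
    val_n <- stats::runif(n_neutral, 4.1, 5.9)
    aro_n <- stats::runif(n_neutral, 1.5, 5.5)
    val_p <- stats::runif(n_positive, 6.1, 8.9)
    aro_p <- c(stats::runif(n_hav, 6.1, 8.5),
               stats::runif(n_positive - n_hav, 2, 5.9))
    data.frame(
      id = sprintf("pic%03d", seq_len(n_neutral + n_positive)),
      valence = c(val_n, val_p),
      arousal = c(aro_n, aro_p),
      stringsAsFactors = FALSE)
  })
}

#' Compile a session schedule
#'
#' Lays out the canonical session timeline with its 21 loudness probes. PRE:
#' probe T1, resting-state block 1, T2, Stroop task 1, T3, resting-state
#' block 2, T4, then the pre-stimulation baseline T5. ONLINE: T6 at picture
#' block onset, then one probe after each of the ten 2-minute picture blocks
#' (T7-T16). POST: T17, resting-state block 3, T18, Stroop task 2, T19,
#' resting-state block 4, T20, and the closing probe T21. Active (`tP`)
#' sessions add 20 minutes of 2 mA stimulation with 30 s ramps starting at
#' the online onset; sham (`SP`) sessions ramp up and immediately back down.
#'
#' @param session_type `"PEI"`, `"SP"` or `"tP"`.
#' @param block_minutes nominal picture-block duration (minutes); also the
#'   online probe spacing.
#' @param est_minutes Stroop-task duration (minutes).
#' @param stim_minutes active stimulation duration (minutes).
#' @param ramp_seconds ramp-up/-down duration (seconds).
#' @return data frame of class `"session_schedule"` with columns `kind`
#'   (`TLQ`, `rs_block`, `PEI_block`, `EST`, `stim_on`, `stim_off`), `label`,
#'   `start_min` and `duration_min`; event times strictly increasing.
#' @export
build_session_schedule <- function(session_type = c("PEI", "SP", "tP"),
                                   block_minutes = 2, est_minutes = 10,
                                   stim_minutes = 20, ramp_seconds = 30) {
  session_type <- match.arg(session_type)
  ev <- list()
  t <- 0
  tlq_min <- 0.25  # probe response slot
  add <- function(kind, label, dur) {
    ev[[length(ev) + 1L]] <<- data.frame(kind = kind, label = label,
                                         start_min = t, duration_min = dur,
                                         stringsAsFactors = FALSE)
    t <<- t + dur
  }
  tlq_i <- 0L
  tlq <- function() {
    tlq_i <<- tlq_i + 1L
    add("TLQ", sprintf("T%d", tlq_i), tlq_min)
  }
  # PRE
  tlq(); add("rs_block", "rs1", block_minutes)
  tlq(); add("EST", "EST1", est_minutes)
  tlq(); add("rs_block", "rs2", block_minutes)
  tlq()  # T4
  tlq()  # T5, pre-stimulation baseline
  # ONLINE: stimulation events bracket the ten picture blocks
  if (session_type == "tP") {
    add("stim_on", "ramp_up", ramp_seconds / 60)
  } else if (session_type == "SP") {
    add("stim_on", "sham_ramp_up", ramp_seconds / 60)
    add("stim_off", "sham_ramp_down", ramp_seconds / 60)
  }
  tlq()  # T6 at online onset, dose 0
  for (b in 1:10) {
    add("PEI_block", sprintf("PEI%d", b), block_minutes - tlq_min)
    tlq()  # T7..T16
  }
  if (session_type == "tP") {
    add("stim_off", "ramp_down", ramp_seconds / 60)
  }
  # POST
  tlq(); add("rs_block", "rs3", block_minutes)
  tlq(); add("EST", "EST2", est_minutes)
  tlq(); add("rs_block", "rs4", block_minutes)
  tlq()  # T20
  tlq()  # T21
  out <- do.call(rbind, ev)
  out$session_type <- session_type
  class(out) <- c("session_schedule", "data.frame")
  out
}

#' Build picture-block playlists from a catalog
#'
#' Resting-state blocks each hold 20 neutral pictures (4 < Vr < 6, Ar < 6).
#' The ten online picture blocks form two consecutive runs of five; within
#' each run the full 100-picture positive pool (Vr > 6) is used without
#' replacement, every block starting with 4 high-arousal-valence pictures
#' (Vr > 6 and Ar > 6) followed by 16 positive pictures. Each slot is 5 s
#' plus a 500 ms cue. Deterministic given `seed`.
#'
#' @param catalog data frame with columns `id`, `valence`, `arousal`.
#' @param seed integer seed.
#' @return data frame with columns `block_kind` (`rs`/`PEI`), `block`, `run`,
#'   `slot`, `id`, `stratum` (`neutral`/`HAV`/`HV`), `onset_s`,
#'   `duration_s`, `cue_ms`.
#' @export
build_picture_blocks <- function(catalog, seed = 1L) {
  check_that(all(c("id", "valence", "arousal") %in% names(catalog)),
             "catalog needs columns id, valence, arousal")
  check_that(all(catalog$valence >= 1 & catalog$valence <= 9) &&
               all(catalog$arousal >= 1 & catalog$arousal <= 9),
             "ratings must lie in [1, 9]")
  neutral <- catalog$id[catalog$valence > 4 & catalog$valence < 6 & catalog$arousal < 6]
  positive <- catalog$id[catalog$valence > 6]
  hav <- catalog$id[catalog$valence > 6 & catalog$arousal > 6]
  if (length(neutral) < 80L) {
    stop("insufficient neutral-eligible pictures (4<Vr<6, Ar<6): need 80, have ",
         length(neutral), call. = FALSE)
  }
  if (length(positive) < 100L) {
    stop("insufficient positive-eligible pictures (Vr>6): need 100, have ",
         length(positive), call. = FALSE)
  }
  if (length(hav) < 40L) {
    stop("insufficient high-arousal-valence pictures (Vr>6, Ar>6): need 40, have ",
         length(hav), call. = FALSE)
  }
  with_seed(seed, {
    # the 100-picture positive pool keeps at least 40 high-arousal pictures
    # so each 5-block run can seed its blocks with 4 fresh HAV slots
    hav_in <- sample(hav, 40L)
    pool <- c(hav_in, sample(setdiff(positive, hav_in), 60L))
    hav_pool <- intersect(pool, hav)
    rs_ids <- matrix(sample(neutral, 80L), nrow = 20L)  # 4 blocks x 20
    rows <- list()
    slot_s <- 5 + 0.5
    for (b in 1:4) {
      rows[[length(rows) + 1L]] <- data.frame(
        block_kind = "rs", block = sprintf("rs%d", b), run = NA_integer_,
        slot = 1:20, id = rs_ids[, b], stratum = "neutral",
        onset_s = (0:19) * slot_s, duration_s = 5, cue_ms = 500,
        stringsAsFactors = FALSE)
    }
    for (run in 1:2) {
      hav_run <- sample(hav_pool, 20L)          # 4 per block x 5 blocks
      hv_run <- sample(setdiff(pool, hav_run))  # remaining 80, 16 per block
      for (b in 1:5) {
        ids <- c(hav_run[(b - 1L) * 4L + 1:4], hv_run[(b - 1L) * 16L + 1:16])
        rows[[length(rows) + 1L]] <- data.frame(
          block_kind = "PEI", block = sprintf("PEI%d", (run - 1L) * 5L + b),
          run = run, slot = 1:20, id = ids,
          stratum = c(rep("HAV", 4L), rep("HV", 16L)),
          onset_s = (0:19) * slot_s, duration_s = 5, cue_ms = 500,
          stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, rows)
  })
}

#' Build the emotional Stroop trial sequence
#'
#' Each of the 12 words (6 neutral, 6 emotional) appears 4 times in random
#' order with a random ink colour, and every word trial is followed by two
#' consecutive XXXX-string trials, giving 24 + 24 word trials and 96 XXXX
#' trials -- 144 in total. Responses use the fixed key map Z = green,
#' X = yellow, N = blue, M = red; stimuli show for up to 4 s with a 500 ms
#' cue.
#'
#' @param neutral_words,emotional_words character vectors of exactly 6 words.
#' @param seed integer seed.
#' @return data frame with columns `trial`, `stimulus`, `category`
#'   (`neutral`/`emotional`/`xxxx`), `color`, `key`, `max_s`, `cue_ms`.
#' @export
build_est_sequence <- function(neutral_words = est_words()$neutral,
                               emotional_words = est_words()$emotional,
                               seed = 1L) {
  check_that(length(neutral_words) == 6L && length(emotional_words) == 6L,
             "need exactly 6 neutral and 6 emotional words")
  keys <- est_key_map()
  with_seed(seed, {
    words <- c(rep(neutral_words, 4L), rep(emotional_words, 4L))
    cat_w <- c(rep("neutral", 24L), rep("emotional", 24L))
    ord <- sample(48L)
    words <- words[ord]
    cat_w <- cat_w[ord]
    stim <- character(0)
    categ <- character(0)
    for (k in seq_len(48L)) {
      stim <- c(stim, words[k], "XXXX", "XXXX")
      categ <- c(categ, cat_w[k], "xxxx", "xxxx")
    }
    color <- sample(names(keys), 144L, replace = TRUE)
    data.frame(trial = 1:144, stimulus = stim, category = categ,
               color = color, key = unname(keys[color]),
               max_s = 4, cue_ms = 500, stringsAsFactors = FALSE)
  })
}
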