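# Three-phase adaptive SRT staircase, implemented as a pure state machine
# (no audio): 5 dB steps until >= 4 sentences and a first reversal, 2 dB
# steps until >= 4 more sentences and a track SE below 1 dB, then 1 dB
# steps until the 20-sentence list is exhausted.

#' Adaptive track settings
#'
#' @param start_snr_db nominal SNR of the first sentence (dB; default 0).
#' @param steps_db step sizes for phases 1-3 in dB (default 5, 2, 1).
#' @param se_threshold_db phase-2 to phase-3 transition threshold on the
#'   track standard error (sample SD of phase-2 presented levels divided
#'   by sqrt(n); default 1 dB).
#' @param min_phase_sentences minimum scored sentences in phases 1 and 2
#'   before their transition criteria are evaluated (default 4, 4).
#' @param scoring_rule sentence-level correctness rule that drives the
#'   up/down decision: `"majority"` (>= 2 of 3 keywords, default) or
#'   `"all"` (all keywords).
#' @param n_keywords keywords per sentence (default 3).
#' @param escalation_step_db level increase when the first sentence is not
#'   repeated completely correctly (default 5 dB).
#' @param max_escalations safety cap on first-sentence replays.
#' @param n_sentences list length (default 20).
#' @param noise_level_dba nominal masker level, carried as metadata only.
#' @return A list of class `track_settings`.
#' @export
track_settings <- function(start_snr_db = 0, steps_db = c(5, 2, 1),
                           se_threshold_db = 1,
                           min_phase_sentences = c(4, 4),
                           scoring_rule = c("majority", "all"),
                           n_keywords = 3,
                           escalation_step_db = 5, max_escalations = 12,
                           n_sentences = 20, noise_level_dba = 70) {
  scoring_rule <- match.arg(scoring_rule)
  stopifnot(length(steps_db) == 3, all(steps_db > 0),
            se_threshold_db > 0, length(min_phase_sentences) == 2,
            n_keywords >= 1, n_sentences >= 1)
  structure(list(start_snr_db = start_snr_db, steps_db = as.numeric(steps_db),
                 se_threshold_db = se_threshold_db,
                 min_phase_sentences = as.integer(min_phase_sentences),
                 scoring_rule = scoring_rule, n_keywords = as.integer(n_keywords),
                 escalation_step_db = escalation_step_db,
                 max_escalations = as.integer(max_escalations),
                 n_sentences = as.integer(n_sentences),
                 noise_level_dba = noise_level_dba),
            class = "track_settings")
}

#' Sentence-level correctness from keyword scores
#'
#' Converts a keyword count into the binary decision that drives the
#' staircase. The default `"majority"` rule scores a sentence correct when
#' a strict majority of its keywords (>= 2 of 3) was repeated; `"all"`
#' requires every keyword, as used by tests scored sentence-by-sentence.
#'
#' @param k_correct keywords repeated correctly (0 to `n_keywords`).
#' @param rule `"majority"` or `"all"`.
#' @param n_keywords keywords per sentence (default 3).
#' @return Logical vector.
#' @export
#' @examples
#' sentence_correct(2)            # TRUE  (majority)
#' sentence_correct(2, "all")     # FALSE
sentence_correct <- function(k_correct, rule = c("majority", "all"),
                             n_keywords = 3) {
  rule <- match.arg(rule)
  if (any(k_correct < 0 | k_correct > n_keywords))
    stop(sprintf("`k_correct` must lie in 0..%d", n_keywords))
  if (rule == "majority") k_correct > n_keywords / 2 else k_correct == n_keywords
}

#' Start an adaptive SRT track
#'
#' Prepares a running track over a 20-sentence list. The first sentence is
#' presented at the starting SNR (0 dB nominal); its adjusted level adds
#' the sentence's normalization offset. Feed responses with
#' [step_track()]; extract the threshold with [compute_srt()].
#'
#' @param list_sentences data.frame with one row per list sentence, columns
#'   `sentence_id` and `offset_db`, in presentation order.
#' @param settings a [track_settings()] object.
#' @return An object of class `srt_track` with `status = "running"`.
#' @export
start_track <- function(list_sentences, settings = track_settings()) {
  stop_if_not_df_with(list_sentences, c("sentence_id", "offset_db"),
                      "list_sentences")
  stopifnot(inherits(settings, "track_settings"))
  if (nrow(list_sentences) != settings$n_sentences)
    stop(sprintf("list has %d sentences; track requires %d",
                 nrow(list_sentences), settings$n_sentences))
  cap <- settings$n_sentences + settings$max_escalations
  structure(list(
    settings = settings,
    sentence_id = list_sentences$sentence_id,
    offset_db = as.numeric(list_sentences$offset_db),
    # presentation log (preallocated; n_pres rows valid)
    n_pres = 0L,
    log_sentence = integer(cap), log_phase = integer(cap),
    log_nominal = numeric(cap), log_adjusted = numeric(cap),
    log_k = integer(cap), log_correct = logical(cap),
    log_replay = logical(cap),
    # staircase state
    sent_idx = 1L, phase = 1L, nominal = settings$start_snr_db,
    first_resolved = FALSE, n_escalations = 0L,
    n_phase1 = 0L, n_phase2 = 0L,
    phase2_sum = 0, phase2_sumsq = 0,
    last_direction = NA_integer_, n_reversals = 0L,
    n_scored = 0L, all_correct_so_far = TRUE,
    status = "running"
  ), class = "srt_track")
}

#' Advance an adaptive track by one scored response
#'
#' Records the response to the pending presentation and prepares the next
#' one. While the first sentence is unresolved, a response short of fully
#' correct replays it at +5 dB (an escalation replay: it consumes no new
#' list sentence and is excluded from phase counting and the SRT). Once
#' underway, the nominal SNR moves down after a correct sentence and up
#' after an incorrect one, by the step size of the phase of the sentence
#' being placed. Phase transitions are evaluated after every scored
#' sentence: phase 1 to 2 after at least 4 phase-1 sentences and one
#' reversal (a change of up/down direction between consecutive
#' adjustments); phase 2 to 3 after at least 4 phase-2 sentences once the
#' SE of the phase-2 presented levels drops below 1 dB. The track
#' completes when the last list sentence has been scored, whether or not
#' phase 3 was reached.
#'
#' @param track a running `srt_track`.
#' @param k_correct number of keywords repeated correctly for the pending
#'   presentation (0 to `n_keywords`).
#' @return The updated `srt_track`.
#' @export
step_track <- function(track, k_correct) {
  stopifnot(inherits(track, "srt_track"))
  if (track$status != "running") stop("cannot step a completed track")
  st <- track$settings
  if (length(k_correct) != 1 || is.na(k_correct) ||
      k_correct < 0 || k_correct > st$n_keywords)
    stop(sprintf("`k_correct` must be a single value in 0..%d", st$n_keywords))
  k <- as.integer(k_correct)

  i <- track$n_pres + 1L
  is_replay <- track$sent_idx == 1L && !track$first_resolved &&
    track$n_escalations > 0L
  correct <- sentence_correct(k, st$scoring_rule, st$n_keywords)
  track$log_sentence[i] <- track$sentence_id[track$sent_idx]
  track$log_phase[i] <- track$phase
  track$log_nominal[i] <- track$nominal
  track$log_adjusted[i] <- track$nominal + track$offset_db[track$sent_idx]
  track$log_k[i] <- k
  track$log_correct[i] <- correct
  track$log_replay[i] <- is_replay
  track$n_pres <- i

  if (!track$first_resolved) {
    # first sentence: escalate until repeated completely correctly
    if (k < st$n_keywords) {
      track$n_escalations <- track$n_escalations + 1L
      if (track$n_escalations > st$max_escalations)
        stop("first sentence never repeated correctly within the escalation cap")
      track$nominal <- track$nominal + st$escalation_step_db
      return(track)
    }
    track$first_resolved <- TRUE
    correct <- TRUE
  }

  # the resolved presentation counts toward its phase
  if (track$phase == 1L) track$n_phase1 <- track$n_phase1 + 1L
  if (track$phase == 2L) {
    track$n_phase2 <- track$n_phase2 + 1L
    track$phase2_sum <- track$phase2_sum + track$nominal
    track$phase2_sumsq <- track$phase2_sumsq + track$nominal^2
  }

  # restart heuristic: measurements are conventionally restarted when the
  # first four sentences are all repeated correctly; srtkit warns instead
  # of restarting (the condition is rare under the standard start level)
  track$n_scored <- track$n_scored + 1L
  track$all_correct_so_far <- track$all_correct_so_far && correct
  if (track$n_scored == 4L && track$all_correct_so_far)
    warning("first four sentences repeated correctly; a restart is conventionally recommended",
            call. = FALSE)

  dir <- if (correct) -1L else 1L
  if (!is.na(track$last_direction) && dir != track$last_direction)
    track$n_reversals <- track$n_reversals + 1L
  track$last_direction <- dir

  next_phase <- track$phase
  if (track$phase == 1L && track$n_phase1 >= st$min_phase_sentences[1] &&
      track$n_reversals >= 1L) {
    next_phase <- 2L
  } else if (track$phase == 2L && track$n_phase2 >= st$min_phase_sentences[2]) {
    n <- track$n_phase2
    var <- (track$phase2_sumsq - track$phase2_sum^2 / n) / (n - 1)
    se <- sqrt(max(var, 0) / n)
    if (se < st$se_threshold_db) next_phase <- 3L
  }

  if (track$sent_idx >= st$n_sentences) {
    track$status <- "complete"
    return(track)
  }
  track$nominal <- track$nominal + dir * st$steps_db[next_phase]
  track$phase <- next_phase
  track$sent_idx <- track$sent_idx + 1L
  track
}

#' Presentation log of a track
#'
#' @param x an `srt_track`.
#' @param ... unused.
#' @return data.frame with one row per presentation: `index`,
#'   `sentence_id`, `phase`, `nominal_snr_db`, `adjusted_snr_db`,
#'   `k_correct`, `correct`, `is_escalation_replay`.
#' @export
as.data.frame.srt_track <- function(x, ...) {
  n <- x$n_pres
  data.frame(
    index = seq_len(n),
    sentence_id = x$log_sentence[seq_len(n)],
    phase = x$log_phase[seq_len(n)],
    nominal_snr_db = x$log_nominal[seq_len(n)],
    adjusted_snr_db = x$log_adjusted[seq_len(n)],
    k_correct = x$log_k[seq_len(n)],
    correct = x$log_correct[seq_len(n)],
    is_escalation_replay = x$log_replay[seq_len(n)]
  )
}

#' Speech reception threshold of a completed track
#'
#' The SRT is the mean of the nominal (unadjusted, pre-offset) SNRs of the
#' phase-2 and phase-3 presentations; the SE is the sample SD of the same
#' levels divided by sqrt(n). Phase-1 sentences and first-sentence
#' escalation replays are excluded.
#'
#' @param track a completed `srt_track`.
#' @return List with `srt_db`, `se_db`, and `n` (presentations used).
#' @export
compute_srt <- function(track) {
  stopifnot(inherits(track, "srt_track"))
  if (track$status != "complete")
    stop("track is not complete; keep stepping it")
  log <- as.data.frame(track)
  use <- log$phase >= 2L & !log$is_escalation_replay
  if (!any(use))
    stop(paste("track never left phase 1 (no reversal or too few sentences);",
               "no SRT is defined -- consider re-measuring"))
  levels <- log$nominal_snr_db[use]
  n <- length(levels)
  se <- if (n > 1) stats::sd(levels) / sqrt(n) else NA_real_
  list(srt_db = mean(levels), se_db = se, n = n)
}

#' @export
print.srt_track <- function(x, ...) {
  cat(sprintf("Adaptive SRT track [%s]: %d presentations, phase %d\n",
              x$status, x$n_pres, x$phase))
  if (x$status == "complete") {
    res <- tryCatch(compute_srt(x), error = function(e) NULL)
    if (!is.null(res))
      cat(sprintf("  SRT %.2f dB SNR (SE %.2f dB, n = %d)\n",
                  res$srt_db, res$se_db, res$n))
    else cat("  no SRT (track never left phase 1)\n")
  }
  invisible(x)
}

#' @export
plot.srt_track <- function(x, ...) {
  log <- as.data.frame(x)
  plot(log$index, log$nominal_snr_db, type = "b",
       pch = ifelse(log$correct, 19, 1),
       col = c("grey40", "steelblue", "darkorange")[log$phase],
       xlab = "presentation", ylab = "nominal SNR (dB)", ...)
  graphics::legend("topright", legend = c("phase 1", "phase 2", "phase 3"),
                   col = c("grey40", "steelblue", "darkorange"), pch = 19,
                   bty = "n")
  invisible(x)
}
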