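# Virtual-listener simulation layer: synthetic corpus generator, keyword
# response model, counterbalanced session plans, and whole-study
# simulation, so every construction and validation stage can be exercised
# without audio or human data.

#' Synthetic-corpus distribution parameters
#'
#' Defaults emulate a psychoacoustically characterized sentence corpus:
#' midpoints normal around -4.8 dB SNR, sentence slopes normal around
#' 13 %/dB (sentence-level non-adaptive characterization slopes run
#' shallower than adaptively measured test slopes), log-normal fit MSEs,
#' high naturalness with occasional low-scoring sentences, small
#' discomfort fractions with a heavy-ish tail, and a quality flag that is
#' almost always set. Each distribution leaves a small configurable
#' fraction of sentences violating the corresponding retention criterion.
#'
#' @param midpoint_mean_db,midpoint_sd_db midpoint distribution (dB SNR).
#' @param slope_mean,slope_sd slope distribution (%/dB); draws are not
#'   truncated, so the tails supply out-of-bounds violators.
#' @param mse_meanlog,mse_sdlog log-normal MSE parameters (%^2 scale).
#' @param naturalness_mean,naturalness_sd naturalness score distribution,
#'   clamped to the 1-7 scale.
#' @param discomfort_shape1,discomfort_shape2 Beta parameters for the
#'   discomfort fraction.
#' @param quality_p probability that a sentence passes playback-quality
#'   screening.
#' @return Named list of parameters.
#' @export
corpus_params <- function(midpoint_mean_db = -4.8, midpoint_sd_db = 1.5,
                          slope_mean = 13, slope_sd = 4.5,
                          mse_meanlog = log(200), mse_sdlog = 0.6,
                          naturalness_mean = 5.8, naturalness_sd = 0.5,
                          discomfort_shape1 = 0.6, discomfort_shape2 = 12,
                          quality_p = 0.97) {
  stopifnot(midpoint_sd_db >= 0, slope_sd >= 0, quality_p >= 0, quality_p <= 1)
  list(midpoint_mean_db = midpoint_mean_db, midpoint_sd_db = midpoint_sd_db,
       slope_mean = slope_mean, slope_sd = slope_sd,
       mse_meanlog = mse_meanlog, mse_sdlog = mse_sdlog,
       naturalness_mean = naturalness_mean, naturalness_sd = naturalness_sd,
       discomfort_shape1 = discomfort_shape1,
       discomfort_shape2 = discomfort_shape2, quality_p = quality_p)
}

#' Generate a synthetic sentence-metadata corpus
#'
#' Draws `10 * n_per_template` sentence records (templates 1-10) from the
#' distributions in [corpus_params()], in the schema consumed by
#' [apply_filters()]. Deterministic under `seed`.
#'
#' @param n_per_template sentences per template (default 120, which at the
#'   default parameters comfortably clears the 88-per-template floor
#'   needed for 44 lists after filtering).
#' @param params a [corpus_params()] list.
#' @param seed integer seed; `NULL` uses the current RNG stream.
#' @return data.frame with columns `sentence_id`, `template_id`,
#'   `midpoint_db`, `slope_pct_per_db`, `mse_pct2`, `naturalness_mean`,
#'   `discomfort_fraction`, `quality_ok`.
#' @export
generate_synthetic_corpus <- function(n_per_template = 120,
                                      params = corpus_params(),
                                      seed = NULL) {
  stopifnot(n_per_template >= 1)
  p <- params
  n <- 10L * as.integer(n_per_template)
  with_seed(seed, {
    data.frame(
      sentence_id = seq_len(n),
      template_id = rep(1:10, each = n_per_template),
      midpoint_db = stats::rnorm(n, p$midpoint_mean_db, p$midpoint_sd_db),
      slope_pct_per_db = stats::rnorm(n, p$slope_mean, p$slope_sd),
      mse_pct2 = stats::rlnorm(n, p$mse_meanlog, p$mse_sdlog),
      naturalness_mean = pmin(7, pmax(1, stats::rnorm(n, p$naturalness_mean,
                                                      p$naturalness_sd))),
      discomfort_fraction = stats::rbeta(n, p$discomfort_shape1,
                                         p$discomfort_shape2),
      quality_ok = stats::runif(n) < p$quality_p
    )
  })
}

#' Virtual listeners
#'
#' A virtual listener deviates from the corpus reference by an individual
#' SRT shift (its effective psychometric midpoint is
#' `reference + srt_shift_db`) and scales every sentence slope by
#' `slope_scale`. The default between-listener SD of 0.5 dB echoes the
#' between-subject spread typical of normal-hearing cohorts.
#'
#' @param n number of listeners.
#' @param srt_shift_sd_db SD of the individual SRT shifts (dB).
#' @param slope_scale common multiplier on sentence slopes (> 0).
#' @param seed integer seed; `NULL` uses the current RNG stream.
#' @return data.frame with `listener_id`, `srt_shift_db`, `slope_scale`.
#' @export
virtual_listeners <- function(n, srt_shift_sd_db = 0.5, slope_scale = 1,
                              seed = NULL) {
  stopifnot(n >= 1, srt_shift_sd_db >= 0, slope_scale > 0)
  with_seed(seed, data.frame(
    listener_id = seq_len(n),
    srt_shift_db = stats::rnorm(n, 0, srt_shift_sd_db),
    slope_scale = slope_scale
  ))
}

#' Simulate a keyword response
#'
#' The three keywords of a sentence are scored as independent Bernoulli
#' draws with success probability given by the sentence's logistic
#' psychometric function evaluated at the level the listener actually
#' hears (`nominal + offset`), shifted by the listener's individual SRT
#' shift and with the slope scaled by the listener's slope factor. For a
#' normalized sentence (`offset = midpoint - reference`) the probability
#' depends on the nominal SNR only through
#' `nominal - (reference + srt_shift)`.
#'
#' @param nominal_snr_db nominal (pre-offset) presentation SNR (dB).
#' @param offset_db the sentence's normalization offset (dB).
#' @param midpoint_db the sentence's intrinsic psychometric midpoint (dB).
#' @param slope the sentence's slope (%/dB).
#' @param srt_shift_db listener SRT shift (dB; default 0).
#' @param slope_scale listener slope multiplier (default 1).
#' @param n_keywords keywords per sentence (default 3).
#' @return Integer count of keywords repeated correctly (uses the current
#'   RNG stream).
#' @export
simulate_keyword_response <- function(nominal_snr_db, offset_db, midpoint_db,
                                      slope, srt_shift_db = 0,
                                      slope_scale = 1, n_keywords = 3) {
  p <- logistic_p(nominal_snr_db + offset_db,
                  midpoint_db + srt_shift_db, slope * slope_scale)
  stats::rbinom(1L, n_keywords, p)
}

#' Counterbalanced session plan
#'
#' Splits the lists across participants in pairs: for each consecutive
#' pair of participants a seeded random permutation of all lists is drawn,
#' the first half becoming participant A's test lists (in that order) and
#' the second half participant B's, so every pair jointly covers all
#' lists. Each participant's training lists are drawn from the complement
#' of their own test set. With 20 participants and 44 lists every list is
#' tested exactly 10 times.
#'
#' @param n_participants even number of participants (default 20).
#' @param n_lists even number of lists (default 44).
#' @param n_training training lists per participant (default 2).
#' @param seed integer seed; `NULL` uses the current RNG stream.
#' @return data.frame with one row per presentation: `participant_id`,
#'   `pair_index`, `presentation_order` (1..`n_training + n_lists/2`),
#'   `list_id`, `is_training`.
#' @export
make_session_plan <- function(n_participants = 20, n_lists = 44,
                              n_training = 2, seed = NULL) {
  if (n_participants %% 2 != 0) stop("`n_participants` must be even")
  if (n_lists %% 2 != 0) stop("`n_lists` must be even")
  half <- n_lists %/% 2
  if (n_training > half) stop("more training lists than the complement holds")
  with_seed(seed, {
    rows <- vector("list", n_participants)
    for (pair in seq_len(n_participants / 2)) {
      perm <- sample.int(n_lists)
      halves <- list(perm[seq_len(half)], perm[half + seq_len(half)])
      for (side in 1:2) {
        pid <- 2L * (pair - 1L) + side
        test_lists <- halves[[side]]
        complement <- halves[[3L - side]]
        training <- sample(complement, n_training)
        rows[[pid]] <- data.frame(
          participant_id = pid, pair_index = pair,
          presentation_order = seq_len(n_training + half),
          list_id = c(training, test_lists),
          is_training = rep(c(TRUE, FALSE), c(n_training, half))
        )
      }
    }
    do.call(rbind, rows)
  })
}

#' Simulate one adaptive track for a virtual listener
#'
#' Runs the full three-phase staircase of [step_track()], drawing keyword
#' responses from [simulate_keyword_response()].
#'
#' @param list_sentences data.frame with `sentence_id`, `offset_db`,
#'   `midpoint_db`, `slope_pct_per_db` for one list, in presentation
#'   order.
#' @param srt_shift_db listener SRT shift (dB).
#' @param slope_scale listener slope multiplier.
#' @param settings a [track_settings()] object.
#' @param seed integer seed; `NULL` uses the current RNG stream.
#' @return A completed `srt_track`.
#' @export
simulate_track <- function(list_sentences, srt_shift_db = 0, slope_scale = 1,
                           settings = track_settings(), seed = NULL) {
  stop_if_not_df_with(list_sentences,
                      c("sentence_id", "offset_db", "midpoint_db",
                        "slope_pct_per_db"), "list_sentences")
  with_seed(seed, {
    track <- start_track(list_sentences, settings)
    nk <- settings$n_keywords
    mids <- list_sentences$midpoint_db + srt_shift_db
    slopes <- list_sentences$slope_pct_per_db * slope_scale
    offs <- list_sentences$offset_db
    # a virtual listener cannot be restarted, so the restart advisory
    # (first four sentences correct) is muffled here
    withCallingHandlers(
      while (track$status == "running") {
        i <- track$sent_idx
        p <- 1 / (1 + exp(-4 * (slopes[i] / 100) *
                            (track$nominal + offs[i] - mids[i])))
        track <- step_track(track, stats::rbinom(1L, nk, p))
      },
      warning = function(w) {
        if (grepl("restart is conventionally recommended",
                  conditionMessage(w)))
          invokeRestart("muffleWarning")
      }
    )
    track
  })
}

#' Simulate a complete normative study
#'
#' Runs every session in a counterbalanced plan: each participant
#' completes their training and test tracks in presentation order, with
#' per-track RNG streams derived from the master seed, the participant and
#' the presentation order (so re-running one session reproduces its
#' tracks exactly). An optional linear learning drift moves each
#' listener's effective midpoint by `drift_db_per_order` dB per
#' measurement, for power checks of the training-effect analysis.
#'
#' @param list_set a `sentence_lists` object from [optimize_lists()] (or
#'   [read_list_csv()]; needs `slope_pct_per_db` and `midpoint_db`
#'   columns, present whenever the lists were built by the optimizer).
#' @param listeners data.frame from [virtual_listeners()]; by default
#'   drawn internally (`n_participants` listeners, SD 0.5 dB).
#' @param plan session plan from [make_session_plan()]; by default drawn
#'   internally.
#' @param n_participants used when `listeners`/`plan` are defaulted.
#' @param drift_db_per_order learning drift in dB per measurement
#'   (negative = improvement; default 0).
#' @param settings a [track_settings()] object.
#' @param seed master seed (integer).
#' @param keep_logs retain per-track presentation logs (needed by
#'   [posthoc_slopes()]).
#' @return An object of class `srt_study`: list with `results` (one row
#'   per track: `participant_id`, `presentation_order`, `list_id`,
#'   `is_training`, `srt_db`, `se_db`, `n_phase23`) and, when
#'   `keep_logs`, `logs` (named list of presentation logs).
#' @export
simulate_study <- function(list_set, listeners = NULL, plan = NULL,
                           n_participants = 20, drift_db_per_order = 0,
                           settings = track_settings(), seed = 1,
                           keep_logs = FALSE) {
  stopifnot(inherits(list_set, "sentence_lists"))
  lists_df <- list_set$lists
  stop_if_not_df_with(lists_df, c("list_number", "sentence_id", "offset_db",
                                  "midpoint_db", "slope_pct_per_db"),
                      "list_set$lists")
  if (is.null(listeners))
    listeners <- virtual_listeners(n_participants, seed = derive_seed(seed, 0, 1))
  if (is.null(plan))
    plan <- make_session_plan(nrow(listeners), list_set$n_lists,
                              seed = derive_seed(seed, 0, 2))
  if (!all(plan$participant_id %in% listeners$listener_id))
    stop("session plan references unknown listeners")
  if (!all(plan$list_id %in% lists_df$list_number))
    stop("session plan references lists absent from the list set")

  by_list <- split(lists_df, lists_df$list_number)
  n_rows <- nrow(plan)
  srt <- se <- numeric(n_rows)
  n23 <- integer(n_rows)
  logs <- if (keep_logs) vector("list", n_rows) else NULL
  for (r in seq_len(n_rows)) {
    pid <- plan$participant_id[r]
    ord <- plan$presentation_order[r]
    li <- listeners[listeners$listener_id == pid, ]
    shift <- li$srt_shift_db + drift_db_per_order * (ord - 1)
    track <- simulate_track(by_list[[as.character(plan$list_id[r])]],
                            srt_shift_db = shift,
                            slope_scale = li$slope_scale,
                            settings = settings,
                            seed = derive_seed(seed, pid, ord))
    res <- compute_srt(track)
    srt[r] <- res$srt_db; se[r] <- res$se_db; n23[r] <- res$n
    if (keep_logs) logs[[r]] <- as.data.frame(track)
  }
  results <- data.frame(
    participant_id = plan$participant_id,
    presentation_order = plan$presentation_order,
    list_id = plan$list_id, is_training = plan$is_training,
    srt_db = srt, se_db = se, n_phase23 = n23
  )
  if (keep_logs)
    names(logs) <- sprintf("p%02d_o%02d", plan$participant_id,
                           plan$presentation_order)
  structure(list(results = results, logs = logs, listeners = listeners,
                 plan = plan, seed = seed,
                 drift_db_per_order = drift_db_per_order),
            class = "srt_study")
}

#' @export
print.srt_study <- function(x, ...) {
  r <- x$results
  cat(sprintf("Simulated SRT study: %d participants x %d measurements\n",
              length(unique(r$participant_id)),
              max(r$presentation_order)))
  test <- r[!r$is_training, ]
  cat(sprintf("  grand mean SRT (test lists): %.2f dB SNR (SD %.2f dB)\n",
              mean(test$srt_db), stats::sd(test$srt_db)))
  invisible(x)
}
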