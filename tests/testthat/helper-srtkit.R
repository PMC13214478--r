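# Shared fixtures, all built in code.

# A normalized 20-sentence list with identical psychometrics; offsets 0.
flat_list <- function(midpoint_db = -4.8, slope = 18.5, n = 20) {
  data.frame(sentence_id = seq_len(n), offset_db = 0,
             midpoint_db = midpoint_db, slope_pct_per_db = slope)
}

# Drive a track with a scripted sequence of keyword counts.
run_scripted <- function(list_sentences, ks, settings = track_settings()) {
  track <- start_track(list_sentences, settings)
  for (k in ks) {
    if (track$status != "running") break
    track <- step_track(track, k)
  }
  track
}

# Hand-built completed track carrying a given per-presentation log; only
# the fields compute_srt() consumes are populated.
fake_track <- function(phase, nominal, replay = rep(FALSE, length(phase))) {
  n <- length(phase)
  structure(list(
    settings = track_settings(), n_pres = n,
    log_sentence = seq_len(n), log_phase = as.integer(phase),
    log_nominal = as.numeric(nominal), log_adjusted = as.numeric(nominal),
    log_k = rep(3L, n), log_correct = rep(TRUE, n), log_replay = replay,
    status = "complete", phase = max(phase), sent_idx = n
  ), class = "srt_track")
}

# A retained, trimmed synthetic corpus plus its normalization reference.
retained_corpus <- function(n_per_template = 120, seed = 11) {
  flt <- apply_filters(generate_synthetic_corpus(n_per_template, seed = seed))
  trim_by_offset(flt$retained)
}

# Small corpus with exactly 4 sentences per template (for exhaustive
# optimizer enumeration), distinct midpoints and slopes.
toy_corpus <- function(seed = 42) {
  withr::with_seed(seed, data.frame(
    sentence_id = 1:40,
    template_id = rep(1:10, each = 4),
    midpoint_db = rnorm(40, -4.8, 1.2),
    slope_pct_per_db = rnorm(40, 13, 3)
  ))
}

# Directly simulated SRT table from the mixed model (no staircase):
# srt = intercept + drift * order + participant effect + residual.
direct_srt_table <- function(n_participants = 20, n_orders = 24,
                             intercept = -5.3, drift = 0,
                             participant_sd = 0.5, residual_sd = 0.7) {
  grid <- expand.grid(participant_id = seq_len(n_participants),
                      presentation_order = seq_len(n_orders))
  u <- rnorm(n_participants, 0, participant_sd)
  grid$srt_db <- intercept + drift * grid$presentation_order +
    u[grid$participant_id] + rnorm(nrow(grid), 0, residual_sd)
  grid$list_id <- ((grid$presentation_order - 1) %% 44) + 1
  grid$is_training <- grid$presentation_order <= 2
  grid
}
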