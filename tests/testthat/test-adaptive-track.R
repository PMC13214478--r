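test_that("sentence correctness rules match keyword counts", {
  expect_true(sentence_correct(3))
  expect_true(sentence_correct(2))
  expect_false(sentence_correct(1))
  expect_false(sentence_correct(0))
  expect_true(sentence_correct(3, "all"))
  expect_false(sentence_correct(2, "all"))
  expect_error(sentence_correct(4), "0..3")
})

test_that("tracks start at 0 dB nominal with the sentence offset applied", {
  lst <- flat_list()
  lst$offset_db[1] <- 2.7
  track <- start_track(lst)
  expect_equal(track$status, "running")
  expect_equal(track$n_pres, 0)
  expect_equal(track$nominal, 0)
  track <- step_track(track, 3)
  log <- as.data.frame(track)
  expect_equal(log$nominal_snr_db[1], 0)
  expect_equal(log$adjusted_snr_db[1], 2.7)
  expect_error(start_track(flat_list(n = 19)), "20")
})

test_that("the first sentence escalates in 5 dB increments until fully correct", {
  track <- run_scripted(flat_list(), c(0, 2, 3, 3))
  log <- as.data.frame(track)
  # attempts at 0, +5, +10; replays flagged and not consuming list sentences
  expect_equal(log$nominal_snr_db[1:3], c(0, 5, 10))
  expect_equal(log$sentence_id[1:3], rep(1, 3))
  expect_equal(log$is_escalation_replay[1:3], c(FALSE, TRUE, TRUE))
  # k = 2 is majority-correct for the staircase but not "completely correct"
  expect_true(log$correct[2])
  # after resolution the staircase proceeds downward in 5 dB steps
  expect_equal(log$nominal_snr_db[4], 5)
  expect_equal(log$sentence_id[4], 2)
  # a fully correct first sentence never replays
  t2 <- run_scripted(flat_list(), c(3, 3))
  expect_equal(as.data.frame(t2)$nominal_snr_db[2], -5)
})

test_that("phases advance per the 5/2/1 schedule with reversal and SE gates", {
  st <- track_settings(start_snr_db = 1)
  # s1@1 ok, s2@-4 ok, s3@-9 wrong (reversal), s4@-4 ok -> phase 2 opens
  # s5@-6 wrong, s6@-4 ok, s7@-6 wrong, s8@-4 ok: phase-2 levels
  # {-6,-4,-6,-4}, SE = sd/2 = 0.577 < 1 -> phase 3, 1 dB steps
  track <- run_scripted(flat_list(), c(3, 3, 0, 3, 0, 3, 0, 3, 3),
                        settings = st)
  log <- as.data.frame(track)
  expect_equal(log$phase[1:9], c(1, 1, 1, 1, 2, 2, 2, 2, 3))
  expect_equal(log$nominal_snr_db[5:9], c(-6, -4, -6, -4, -5))
  p2 <- log$nominal_snr_db[log$phase == 2]
  expect_equal(sd(p2) / sqrt(4), 0.5773503, tolerance = 1e-6)
})

test_that("a fully correct start triggers the restart advisory, not a restart", {
  expect_warning(run_scripted(flat_list(), rep(3, 4)),
                 "restart is conventionally recommended")
  # a single early miss silences it
  expect_no_warning(run_scripted(flat_list(), c(3, 0, 3, 3, 3, 3)))
})

test_that("phase 1 persists without a reversal however many sentences pass", {
  track <- suppressWarnings(run_scripted(flat_list(), rep(3, 12)))
  log <- as.data.frame(track)
  expect_true(all(log$phase == 1))
  expect_equal(log$nominal_snr_db, seq(0, by = -5, length.out = 12))
})

test_that("phase sequence is monotone and steps match the phase size", {
  for (seed in 1:12) {
    track <- simulate_track(flat_list(), srt_shift_db = 0.3, seed = seed)
    log <- as.data.frame(track)
    expect_true(all(diff(log$phase[!log$is_escalation_replay]) >= 0))
    # keep one row per scored sentence: for sentence 1 that is the
    # resolving (last) presentation, after any escalation replays
    scored <- log[log$sentence_id != 1 | log$index == max(log$index[log$sentence_id == 1]), ]
    steps <- abs(diff(scored$nominal_snr_db))
    # the adjustment into each sentence uses that sentence's phase step
    expect_equal(steps, c(5, 2, 1)[scored$phase[-1]])
    expect_true(track$status == "complete")
    expect_equal(sum(!log$is_escalation_replay), 20)
  }
})

test_that("the SRT averages unadjusted phase-2/3 levels only", {
  tr <- fake_track(phase = c(1, 1, 2, 2, 2, 2, 3, 3),
                   nominal = c(0, -5, -4, -6, -5, -5, -6, -6))
  res <- compute_srt(tr)
  expect_equal(res$srt_db, -16 / 3)
  expect_equal(res$se_db, sd(c(-4, -6, -5, -5, -6, -6)) / sqrt(6))
  expect_equal(res$se_db, 0.3333333, tolerance = 1e-6)
  expect_equal(res$n, 6)

  const <- fake_track(phase = c(1, 2, 2, 2), nominal = c(0, -5, -5, -5))
  expect_equal(compute_srt(const)$srt_db, -5)
  expect_equal(compute_srt(const)$se_db, 0)

  # translation equivariance
  shifted <- fake_track(phase = c(1, 1, 2, 2, 2, 2, 3, 3),
                        nominal = c(0, -5, -4, -6, -5, -5, -6, -6) + 1.5)
  expect_equal(compute_srt(shifted)$srt_db, res$srt_db + 1.5)
  expect_equal(compute_srt(shifted)$se_db, res$se_db)

  stuck <- fake_track(phase = rep(1, 5), nominal = seq(0, -20, by = -5))
  expect_error(compute_srt(stuck), "never left phase 1")
})

test_that("the SRT ignores sentence offsets entirely", {
  lst <- flat_list()
  withr::with_seed(8, lst$offset_db <- rnorm(20, 0, 1.5))
  lst$midpoint_db <- -4.8 + lst$offset_db  # normalized sentences
  base <- simulate_track(lst, seed = 303)
  log <- as.data.frame(base)
  expect_true(any(log$adjusted_snr_db != log$nominal_snr_db))
  expect_equal(log$adjusted_snr_db - log$nominal_snr_db,
               lst$offset_db[match(log$sentence_id, lst$sentence_id)])
  # perturbing offsets (and midpoints in step, keeping normalization)
  # leaves the response stream and hence the SRT unchanged
  lst2 <- lst
  lst2$offset_db <- lst$offset_db + 0.9
  lst2$midpoint_db <- lst$midpoint_db + 0.9
  alt <- simulate_track(lst2, seed = 303)
  expect_equal(compute_srt(alt)$srt_db, compute_srt(base)$srt_db)
})

test_that("completed tracks refuse further input", {
  track <- simulate_track(flat_list(), seed = 1)
  expect_equal(track$status, "complete")
  expect_error(step_track(track, 3), "completed")
})
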