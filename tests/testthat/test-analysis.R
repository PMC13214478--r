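test_that("list equivalence reports per-list means, deviations and spread", {
  res <- data.frame(
    participant_id = rep(1:2, 2), presentation_order = rep(3:4, each = 2),
    list_id = rep(c(10, 20), each = 2), is_training = FALSE,
    srt_db = c(-5, -5, -6, -6))
  eq <- list_equivalence(res)
  expect_equal(eq$grand_mean_db, -5.5)
  expect_equal(eq$per_list$normalized_db, c(0.5, -0.5))
  expect_equal(eq$max_pairwise_diff_db, 1.0)
  # all-equal SRTs: zero deviations and spread
  res0 <- res; res0$srt_db <- -5.3
  eq0 <- list_equivalence(res0)
  expect_equal(eq0$per_list$normalized_db, c(0, 0))
  expect_equal(eq0$grand_sd_db, 0)
  # permuting rows changes nothing
  eqp <- list_equivalence(res[sample(4), ])
  expect_equal(eqp$per_list, eq$per_list)
  # absent lists are reported, not dropped
  eqm <- list_equivalence(res, all_lists = c(10, 20, 30))
  expect_equal(eqm$per_list$n[eqm$per_list$list_id == 30], 0)
  expect_true(is.nan(eqm$per_list$mean_srt_db[eqm$per_list$list_id == 30]))
})

test_that("training rows never enter list-equivalence or within-subject stats", {
  res <- direct_srt_table(n_participants = 6, n_orders = 10)
  with_tr <- res
  without_tr <- res[!res$is_training, ]
  expect_equal(list_equivalence(with_tr)$per_list,
               list_equivalence(without_tr)$per_list)
  expect_equal(within_subject_stats(with_tr)$per_participant,
               within_subject_stats(without_tr)$per_participant)
})

test_that("within-subject stats average the per-participant SDs", {
  res <- data.frame(
    participant_id = rep(1:2, each = 2), presentation_order = rep(3:4, 2),
    list_id = 1:4, is_training = FALSE,
    srt_db = c(-5, -6, -4, -4))
  ws <- within_subject_stats(res)
  expect_equal(ws$per_participant$sd_srt_db, c(sqrt(0.5), 0))
  expect_equal(ws$avg_within_subject_sd_db, sqrt(0.5) / 2)
  # relabeling participants leaves the average unchanged
  res2 <- res; res2$participant_id <- 3 - res2$participant_id
  expect_equal(within_subject_stats(res2)$avg_within_subject_sd_db,
               ws$avg_within_subject_sd_db)
  expect_error(within_subject_stats(res[c(1, 3, 4), ]), "fewer than 2")
})

test_that("order F-test holds its size under the null", {
  withr::with_seed(400, {
    pvals <- replicate(500, {
      res <- direct_srt_table(drift = 0)
      training_effect(res)$p_value
    })
  })
  expect_lte(mean(pvals < 0.05), 0.08)
})

test_that("mixed model recovers injected drift and variance components", {
  withr::with_seed(401, {
    fits <- replicate(200, {
      res <- direct_srt_table(drift = -0.02, participant_sd = 0.5,
                              residual_sd = 0.7)
      fit <- training_effect(res)
      c(fit$order_slope_db, fit$var_participant_db2)
    })
  })
  expect_lt(abs(mean(fits[1, ]) - (-0.02)), 0.005)
  expect_lt(abs(mean(fits[2, ]) - 0.25) / 0.25, 0.5)
})

test_that("excluding training drops the first orders from the fit", {
  withr::with_seed(12, res <- direct_srt_table(drift = -0.05))
  with_tr <- training_effect(res, include_training = TRUE)
  without_tr <- training_effect(res, include_training = FALSE)
  expect_equal(with_tr$n_obs, 480)
  expect_equal(without_tr$n_obs, 440)
  expect_equal(with_tr$df[2], 478)
  expect_equal(without_tr$df[2], 438)
  expect_true(with_tr$significant)
  expect_true(all(with_tr$ci95[1] <= with_tr$order_slope_db,
                  with_tr$order_slope_db <= with_tr$ci95[2]))
})

test_that("balanced data with no participant effect reduces to ordinary least squares", {
  withr::with_seed(55, res <- direct_srt_table(n_participants = 8,
                                               n_orders = 12, drift = -0.04,
                                               participant_sd = 0,
                                               residual_sd = 0.5))
  fit <- training_effect(res)
  ols <- lm(srt_db ~ presentation_order, data = res)
  expect_equal(unname(coef(fit)), unname(coef(ols)), tolerance = 1e-6)
})

test_that("post hoc slope fits track the generating slope with the known finite-track bias", {
  # Per-track least-squares slope estimates from short adaptive tracks are
  # upward-biased (sampling concentrates near the midpoint and the
  # 3-keyword proportions are coarse), so the grand average is checked
  # against the generating slope only up to that bias, and the estimator
  # is additionally required to discriminate between slope regimes.
  trm <- retained_corpus(40, seed = 14)
  grand <- vapply(c(10, 18.5), function(s_true) {
    corpus <- trm$corpus
    corpus$slope_pct_per_db <- s_true
    ls <- optimize_lists(corpus, 8, n_iter = 3, seed = 5)
    study <- simulate_study(ls, n_participants = 20, seed = 77,
                            keep_logs = TRUE)
    ps <- posthoc_slopes(study)
    expect_equal(ps$n_tracks, 20 * 6)
    expect_lt(ps$n_excluded / ps$n_tracks, 0.2)
    # upward, bounded bias: the skewed per-track estimates pull the mean
    # above the generating slope but not beyond ~60%
    expect_gt(ps$grand_mean_slope, s_true - 3)
    expect_lt(ps$grand_mean_slope, 1.6 * s_true)
    conv <- ps$per_track$slope_pct_per_db[ps$per_track$converged]
    expect_lt(abs(stats::median(conv) - s_true) / s_true, 0.35)
    ps$grand_mean_slope
  }, numeric(1))
  expect_gt(grand[2], grand[1])
})

test_that("the slope grand average is invariant to track ordering", {
  study <- local({
    trm <- retained_corpus(30, seed = 9)
    ls <- optimize_lists(trm$corpus, 4, n_iter = 2, seed = 5)
    simulate_study(ls, n_participants = 4, seed = 3, keep_logs = TRUE)
  })
  ps <- posthoc_slopes(study)
  ps2 <- posthoc_slopes(rev(study$logs))
  expect_equal(ps2$grand_mean_slope, ps$grand_mean_slope)
})

test_that("uninformative tracks are excluded from slope averaging, not imputed", {
  good <- data.frame(nominal_snr_db = seq(-10, 0),
                     k_correct = c(0, 0, 0, 1, 1, 2, 2, 3, 3, 3, 3))
  flat <- data.frame(nominal_snr_db = rep(c(-6, -5, -4), 3), k_correct = 3)
  ps <- posthoc_slopes(list(a = good, b = flat))
  expect_equal(ps$n_excluded, 1)
  expect_false(ps$per_track$converged[ps$per_track$track == "b"])
  expect_error(posthoc_slopes(list(only = flat)), "non-convergent")
})
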