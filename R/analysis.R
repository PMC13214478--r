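# Validation statistics: list equivalence, within-subject variability,
# post hoc psychometric slopes, and the mixed-effects training-effect
# analysis.

results_from <- function(results) {
  if (inherits(results, "srt_study")) results <- results$results
  stop_if_not_df_with(results, c("participant_id", "presentation_order",
                                 "list_id", "is_training", "srt_db"),
                      "results")
  results
}

#' List-equivalence report
#'
#' Per-list mean SRT and SD over participants (test measurements only),
#' the grand mean (mean of list means) and its SD, normalized deviations
#' (list mean minus grand mean), and the maximum pairwise difference
#' between list means. Lists named in `all_lists` but absent from the
#' results are reported with `n = 0` and `NaN` statistics rather than
#' dropped.
#'
#' @param results a `srt_study` or its `results` data.frame.
#' @param all_lists optional vector of list ids that should appear.
#' @return A list of class `list_equivalence`: `per_list` (data.frame
#'   `list_id`, `n`, `mean_srt_db`, `sd_srt_db`, `normalized_db`),
#'   `grand_mean_db`, `grand_sd_db`, `max_pairwise_diff_db`,
#'   `mean_within_list_sd_db`.
#' @export
list_equivalence <- function(results, all_lists = NULL) {
  r <- results_from(results)
  r <- r[!r$is_training, , drop = FALSE]
  ids <- sort(unique(c(r$list_id, all_lists)))
  if (length(ids) < 2) stop("need at least 2 lists")
  per <- do.call(rbind, lapply(ids, function(id) {
    v <- r$srt_db[r$list_id == id]
    data.frame(list_id = id, n = length(v),
               mean_srt_db = if (length(v)) mean(v) else NaN,
               sd_srt_db = if (length(v) > 1) stats::sd(v) else NaN)
  }))
  present <- per$n > 0
  if (sum(present) < 2) stop("need at least 2 lists with results")
  grand <- mean(per$mean_srt_db[present])
  per$normalized_db <- per$mean_srt_db - grand
  structure(list(
    per_list = per,
    grand_mean_db = grand,
    grand_sd_db = stats::sd(per$mean_srt_db[present]),
    max_pairwise_diff_db = diff(range(per$mean_srt_db[present])),
    mean_within_list_sd_db = mean(per$sd_srt_db[per$n > 1]),
    grand_mean_all_measurements_db = mean(r$srt_db),
    grand_mean_by_participant_db =
      mean(tapply(r$srt_db, r$participant_id, mean))
  ), class = "list_equivalence")
}

#' @export
print.list_equivalence <- function(x, ...) {
  cat(sprintf("List equivalence over %d lists\n", nrow(x$per_list)))
  cat(sprintf("  grand mean SRT %.2f dB SNR (SD of list means %.2f dB)\n",
              x$grand_mean_db, x$grand_sd_db))
  cat(sprintf("  max pairwise list difference %.2f dB; mean within-list SD %.2f dB\n",
              x$max_pairwise_diff_db, x$mean_within_list_sd_db))
  invisible(x)
}

#' Within-subject SRT statistics
#'
#' Mean and SD of the test-list SRTs for each participant (training
#' excluded), and the average within-subject SD (unweighted mean of the
#' per-participant SDs).
#'
#' @param results a `srt_study` or its `results` data.frame.
#' @return List with `per_participant` (data.frame `participant_id`, `n`,
#'   `mean_srt_db`, `sd_srt_db`) and `avg_within_subject_sd_db`.
#' @export
within_subject_stats <- function(results) {
  r <- results_from(results)
  r <- r[!r$is_training, , drop = FALSE]
  per <- do.call(rbind, lapply(split(r, r$participant_id), function(df) {
    if (nrow(df) < 2)
      stop(sprintf("participant %s has fewer than 2 test measurements",
                   df$participant_id[1]))
    data.frame(participant_id = df$participant_id[1], n = nrow(df),
               mean_srt_db = mean(df$srt_db), sd_srt_db = stats::sd(df$srt_db))
  }))
  rownames(per) <- NULL
  list(per_participant = per,
       avg_within_subject_sd_db = mean(per$sd_srt_db))
}

#' Training-effect mixed model
#'
#' Fits the linear mixed-effects model
#' `srt ~ 1 + presentation_order + (1 | participant)` by REML
#' ([lme4::lmer()]) and tests the presentation-order coefficient with a
#' marginal F-test. Degrees of freedom follow the residual convention
#' (observations minus the 2 fixed-effect parameters), which is also used
#' for the 95% confidence interval on the order slope. With
#' `include_training = TRUE` (the default) all measurements enter with
#' their session order 1..24; otherwise the training rows are dropped and
#' the original order codes retained.
#'
#' @param results a `srt_study` or its `results` data.frame.
#' @param include_training include the training measurements.
#' @param alpha significance level for the F-test report (default 0.05).
#' @return An object of class `training_effect`: `intercept_db`,
#'   `order_slope_db` (dB per measurement), `order_se_db`, `ci95`,
#'   `f_value`, `df`, `p_value`, `significant`, `var_participant_db2`,
#'   `var_residual_db2`, `n_obs`, `converged`, and the underlying `fit`.
#' @export
training_effect <- function(results, include_training = TRUE, alpha = 0.05) {
  r <- results_from(results)
  if (!include_training) r <- r[!r$is_training, , drop = FALSE]
  if (length(unique(r$participant_id)) < 2)
    stop("need at least 2 participants")
  if (length(unique(r$presentation_order)) < 3)
    stop("need at least 3 presentation orders")
  r$participant_id <- factor(r$participant_id)
  messages <- character()
  fit <- withCallingHandlers(
    lme4::lmer(srt_db ~ presentation_order + (1 | participant_id),
               data = r, REML = TRUE),
    warning = function(w) {
      messages <<- c(messages, conditionMessage(w))
      invokeRestart("muffleWarning")
    },
    message = function(m) {
      messages <<- c(messages, conditionMessage(m))
      invokeRestart("muffleMessage")
    }
  )
  cf <- lme4::fixef(fit)
  vc <- as.data.frame(lme4::VarCorr(fit))
  se <- sqrt(diag(as.matrix(stats::vcov(fit))))
  est <- unname(cf["presentation_order"])
  se_order <- unname(se[2])
  n <- nrow(r)
  df2 <- n - 2L
  f <- (est / se_order)^2
  p <- stats::pf(f, 1, df2, lower.tail = FALSE)
  ci <- est + c(-1, 1) * stats::qt(1 - alpha / 2, df2) * se_order
  conv <- !any(grepl("failed to converge|unable to evaluate", messages))
  structure(list(
    intercept_db = unname(cf["(Intercept)"]),
    order_slope_db = est, order_se_db = se_order, ci95 = ci,
    f_value = f, df = c(1L, df2), p_value = p,
    significant = p < alpha, alpha = alpha,
    var_participant_db2 = vc$vcov[vc$grp == "participant_id"],
    var_residual_db2 = vc$vcov[vc$grp == "Residual"],
    n_obs = n, include_training = include_training,
    converged = conv, messages = messages, fit = fit
  ), class = "training_effect")
}

#' @export
print.training_effect <- function(x, ...) {
  cat("Training-effect mixed model: srt ~ order + (1 | participant)\n")
  cat(sprintf("  %s training measurements; n = %d\n",
              if (x$include_training) "including" else "excluding", x$n_obs))
  cat(sprintf("  order effect %.4f dB/measurement [%.4f, %.4f]\n",
              x$order_slope_db, x$ci95[1], x$ci95[2]))
  cat(sprintf("  F(%d,%d) = %.2f, p = %.4g (%ssignificant at alpha = %.2f)\n",
              x$df[1], x$df[2], x$f_value, x$p_value,
              if (x$significant) "" else "not ", x$alpha))
  cat(sprintf("  variance: participant %.4f dB^2, residual %.4f dB^2\n",
              x$var_participant_db2, x$var_residual_db2))
  if (!x$converged) cat("  [estimation flagged as non-converged]\n")
  invisible(x)
}

#' @export
coef.training_effect <- function(object, ...) {
  c(intercept_db = object$intercept_db,
    order_slope_db = object$order_slope_db)
}

#' Post hoc psychometric slopes per track
#'
#' Refits the logistic psychometric function to every track's presentation
#' log (nominal SNR versus proportion of keywords correct, all scored
#' presentations) with [fit_psychometric()], and averages the slopes over
#' the convergent fits. Non-convergent fits are excluded and counted, not
#' imputed.
#'
#' @param study an `srt_study` simulated with `keep_logs = TRUE`, or a
#'   list of per-track presentation logs (data.frames with
#'   `nominal_snr_db` and `k_correct`).
#' @return List with `per_track` (data.frame `track`, `slope_pct_per_db`,
#'   `midpoint_db`, `converged`), `grand_mean_slope`, `n_tracks`,
#'   `n_excluded`.
#' @export
posthoc_slopes <- function(study) {
  logs <- if (inherits(study, "srt_study")) study$logs else study
  if (is.null(logs) || !length(logs))
    stop("no presentation logs; simulate with keep_logs = TRUE")
  fits <- lapply(logs, function(log) {
    fit_psychometric(data.frame(snr_db = log$nominal_snr_db,
                                k_correct = log$k_correct))
  })
  nm <- names(logs)
  if (is.null(nm)) nm <- as.character(seq_along(logs))
  per <- data.frame(
    track = nm,
    slope_pct_per_db = vapply(fits, function(f) f$slope, numeric(1)),
    midpoint_db = vapply(fits, function(f) f$midpoint_db, numeric(1)),
    converged = vapply(fits, function(f) f$converged, logical(1))
  )
  rownames(per) <- NULL
  if (!any(per$converged)) stop("all post hoc fits were non-convergent")
  list(per_track = per,
       grand_mean_slope = mean(per$slope_pct_per_db[per$converged]),
       n_tracks = nrow(per), n_excluded = sum(!per$converged))
}
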