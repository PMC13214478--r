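# Corpus retention rules: linguistic/quality criteria, psychometric
# bounds, and the offset-magnitude trim that caps normalization gains.

#' Tukey fence cutoffs
#'
#' Outlier fences at 1.5 interquartile ranges beyond the quartiles, with
#' quartiles computed by linear interpolation ([stats::quantile()] type 7).
#'
#' @param values numeric vector (>= 4 values).
#' @param k fence multiplier (1.5 = the conventional outlier rule).
#' @return Named numeric vector `c(low, high)`.
#' @export
#' @examples
#' iqr_cutoffs(c(1, 2, 3, 4))  # low -0.5, high 5.5
iqr_cutoffs <- function(values, k = 1.5) {
  values <- values[!is.na(values)]
  if (length(values) < 4) stop("need at least 4 values for quartile fences")
  q <- stats::quantile(values, c(0.25, 0.75), names = FALSE, type = 7)
  iqr <- q[2] - q[1]
  c(low = q[1] - k * iqr, high = q[2] + k * iqr)
}

#' Sentence retention criteria
#'
#' Bundles the cutoffs used by [apply_filters()]. Defaults are the
#' configuration of the reference Danish corpus: playback quality required;
#' discomfort reported by strictly less than 25% of raters; mean
#' naturalness of at least 4.5 on the 7-point scale; psychometric midpoint
#' strictly inside (-9.2, -0.5) dB SNR; slope strictly inside (0, 33.5)
#' %/dB; and fit MSE below 897 squared percentage points. The
#' psychometric cutoffs are configuration values (originally derived from
#' quartile fences on the real corpus, see [iqr_cutoffs()]); they are not
#' recomputed from the data being filtered.
#'
#' `mse_direction` controls the sense of the MSE rule: `"below"` retains
#' `mse < mse_bound` (upper-outlier removal, the default), `"above"`
#' retains `mse > mse_bound`.
#'
#' @param midpoint_range open interval for the midpoint (dB SNR).
#' @param slope_range open interval for the slope (%/dB).
#' @param mse_bound MSE cutoff in squared percentage points.
#' @param mse_direction `"below"` or `"above"` (see Details).
#' @param naturalness_min inclusive minimum mean naturalness (1-7).
#' @param discomfort_max strict maximum discomfort proportion (0-1).
#' @param quality_required require the playback-quality flag.
#' @param max_abs_offset_db cap on normalization offsets, used by
#'   [trim_by_offset()].
#' @return An object of class `filter_criteria`.
#' @export
filter_criteria <- function(midpoint_range = c(-9.2, -0.5),
                            slope_range = c(0, 33.5),
                            mse_bound = 897,
                            mse_direction = c("below", "above"),
                            naturalness_min = 4.5,
                            discomfort_max = 0.25,
                            quality_required = TRUE,
                            max_abs_offset_db = 3) {
  mse_direction <- match.arg(mse_direction)
  stopifnot(length(midpoint_range) == 2L, midpoint_range[1] < midpoint_range[2],
            length(slope_range) == 2L, slope_range[1] < slope_range[2],
            is.finite(mse_bound), naturalness_min >= 1, naturalness_min <= 7,
            discomfort_max >= 0, discomfort_max <= 1, max_abs_offset_db > 0)
  structure(
    list(midpoint_range = as.numeric(midpoint_range),
         slope_range = as.numeric(slope_range),
         mse_bound = as.numeric(mse_bound), mse_direction = mse_direction,
         naturalness_min = as.numeric(naturalness_min),
         discomfort_max = as.numeric(discomfort_max),
         quality_required = isTRUE(quality_required),
         max_abs_offset_db = as.numeric(max_abs_offset_db)),
    class = "filter_criteria"
  )
}

corpus_cols <- c("sentence_id", "template_id", "midpoint_db",
                 "slope_pct_per_db", "mse_pct2", "naturalness_mean",
                 "discomfort_fraction", "quality_ok")

#' Apply sentence retention criteria to a corpus table
#'
#' Retains the sentences that satisfy every criterion in `criteria`:
#' playback quality, discomfort strictly below the maximum, naturalness at
#' or above the minimum, midpoint and slope strictly inside their open
#' intervals, and the MSE rule. Rejections are attributed to the first
#' failing criterion in that order, so the per-criterion counts plus the
#' retained count always sum to the input count.
#'
#' @param corpus data.frame with columns `sentence_id`, `template_id`,
#'   `midpoint_db`, `slope_pct_per_db`, `mse_pct2`, `naturalness_mean`,
#'   `discomfort_fraction`, `quality_ok`.
#' @param criteria a [filter_criteria()] object.
#' @return A list of class `corpus_filter` with elements `retained` (the
#'   surviving rows, input order preserved), `rejections` (named integer
#'   vector of first-failure counts), and `n_input`.
#' @export
apply_filters <- function(corpus, criteria = filter_criteria()) {
  stop_if_not_df_with(corpus, corpus_cols, "corpus")
  stopifnot(inherits(criteria, "filter_criteria"))
  for (col in corpus_cols) {
    bad <- which(is.na(corpus[[col]]))
    if (length(bad))
      stop(sprintf("missing `%s` for sentence_id %s", col,
                   paste(corpus$sentence_id[bad], collapse = ", ")))
  }
  mse_ok <- if (criteria$mse_direction == "below")
    corpus$mse_pct2 < criteria$mse_bound else corpus$mse_pct2 > criteria$mse_bound
  checks <- list(
    quality = !criteria$quality_required | as.logical(corpus$quality_ok),
    discomfort = corpus$discomfort_fraction < criteria$discomfort_max,
    naturalness = corpus$naturalness_mean >= criteria$naturalness_min,
    midpoint = corpus$midpoint_db > criteria$midpoint_range[1] &
      corpus$midpoint_db < criteria$midpoint_range[2],
    slope = corpus$slope_pct_per_db > criteria$slope_range[1] &
      corpus$slope_pct_per_db < criteria$slope_range[2],
    mse = mse_ok
  )
  fail_first <- rep(NA_character_, nrow(corpus))
  for (nm in names(checks)) {
    hit <- is.na(fail_first) & !checks[[nm]]
    fail_first[hit] <- nm
  }
  keep <- is.na(fail_first)
  rejections <- vapply(names(checks),
                       function(nm) sum(fail_first == nm, na.rm = TRUE),
                       integer(1))
  structure(
    list(retained = corpus[keep, , drop = FALSE],
         rejections = rejections, n_input = nrow(corpus),
         criteria = criteria),
    class = "corpus_filter"
  )
}

#' @export
print.corpus_filter <- function(x, ...) {
  cat(sprintf("Corpus filter: %d of %d sentences retained\n",
              nrow(x$retained), x$n_input))
  rej <- x$rejections[x$rejections > 0]
  if (length(rej))
    cat("  rejected (first failing criterion):",
        paste(sprintf("%s=%d", names(rej), rej), collapse = ", "), "\n")
  invisible(x)
}

#' Trim sentences by normalization-offset magnitude
#'
#' Computes the mean midpoint of the retained corpus and removes sentences
#' whose midpoint lies more than `max_abs_offset_db` from it, which caps
#' the level offsets that sentence normalization will later apply. The
#' pre-trim mean is returned as the normalization reference (a single pass
#' suffices when trimming barely moves the mean; `iterate = TRUE` repeats
#' until the mean moves by less than `tol` dB).
#'
#' @param corpus data.frame with at least `sentence_id` and `midpoint_db`.
#' @param max_abs_offset_db offset cap in dB (default 3).
#' @param iterate repeat trim/re-mean until stable.
#' @param tol mean-shift tolerance (dB) for `iterate = TRUE`.
#' @return List with `corpus` (survivors), `reference_mean_db` (the mean
#'   used for the final trim), `n_removed`, and `passes`.
#' @export
trim_by_offset <- function(corpus, max_abs_offset_db = 3, iterate = FALSE,
                           tol = 0.05) {
  stop_if_not_df_with(corpus, c("sentence_id", "midpoint_db"), "corpus")
  if (nrow(corpus) == 0) stop("empty corpus")
  n0 <- nrow(corpus)
  passes <- 0L
  repeat {
    passes <- passes + 1L
    ref <- mean(corpus$midpoint_db)
    keep <- abs(corpus$midpoint_db - ref) <= max_abs_offset_db
    if (!any(keep)) stop("all sentences trimmed; offset cap too tight")
    done <- all(keep) || !iterate ||
      abs(mean(corpus$midpoint_db[keep]) - ref) < tol
    corpus <- corpus[keep, , drop = FALSE]
    if (done) break
  }
  list(corpus = corpus, reference_mean_db = ref,
       n_removed = n0 - nrow(corpus), passes = passes)
}
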