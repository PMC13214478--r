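# Logistic psychometric model: functional form, least-squares fitting,
# and sentence normalization offsets.

#' Construct a logistic psychometric function
#'
#' A psychometric function maps presentation SNR (dB) to the probability of
#' a correct response. The parameterization used throughout srtkit is
#' \deqn{p(x) = \frac{1}{1 + \exp(-4 (s/100) (x - m))}}{
#'       p(x) = 1 / (1 + exp(-4 (s/100) (x - m)))}
#' where \eqn{m} (`midpoint_db`) is the inflection point -- the SNR at
#' which \eqn{p = 0.5} -- and \eqn{s} (`slope`) is the derivative of the
#' percent-correct curve at the inflection point, in %/dB. The factor 4
#' makes `slope` exactly that derivative, so the two parameters are the
#' quantities audiologists report (e.g. an 18.5 %/dB sentence test slope).
#'
#' @param midpoint_db inflection point in dB SNR.
#' @param slope slope at the inflection point in %/dB; must be positive
#'   and finite.
#' @param mse mean squared error of a fit that produced the parameters, in
#'   squared percentage points; `NA` for an exactly specified function.
#' @param converged logical; `FALSE` marks a non-convergent fit whose
#'   parameters should not be trusted.
#' @return An object of class `psychfun`.
#' @seealso [logistic_p()], [fit_psychometric()]
#' @export
#' @examples
#' pf <- psychometric_function(-4.8, 13)
#' predict(pf, snr_db = c(-10, -4.8, 0))
psychometric_function <- function(midpoint_db, slope, mse = NA_real_,
                                  converged = TRUE) {
  stopifnot(is.numeric(midpoint_db), length(midpoint_db) == 1L,
            is.numeric(slope), length(slope) == 1L, is.finite(slope))
  if (isTRUE(converged) && !is.finite(midpoint_db))
    stop("`midpoint_db` must be finite")
  if (!is.na(mse) && mse < 0) stop("`mse` must be non-negative")
  structure(
    list(midpoint_db = as.numeric(midpoint_db), slope = as.numeric(slope),
         mse = as.numeric(mse), converged = isTRUE(converged)),
    class = "psychfun"
  )
}

#' Logistic psychometric probability
#'
#' Evaluates the logistic psychometric function (see
#' [psychometric_function()] for the parameterization) at one or more SNRs.
#'
#' @param snr_db numeric vector of SNRs in dB; must be finite.
#' @param midpoint_db inflection point (dB SNR), or a `psychfun` object in
#'   which case `slope` is ignored.
#' @param slope slope at the inflection point in %/dB (> 0).
#' @return Probabilities in \[0, 1\], same length as `snr_db`.
#' @export
#' @examples
#' logistic_p(-4.8, midpoint_db = -4.8, slope = 13)  # 0.5 by definition
logistic_p <- function(snr_db, midpoint_db, slope) {
  if (inherits(midpoint_db, "psychfun")) {
    slope <- midpoint_db$slope
    midpoint_db <- midpoint_db$midpoint_db
  }
  if (!is.numeric(snr_db) || any(!is.finite(snr_db)))
    stop("`snr_db` must be finite numeric")
  stopifnot(length(midpoint_db) == 1L, length(slope) == 1L)
  if (!is.finite(slope) || slope <= 0) stop("`slope` must be positive")
  1 / (1 + exp(-4 * (slope / 100) * (snr_db - midpoint_db)))
}

#' @export
print.psychfun <- function(x, ...) {
  cat("Logistic psychometric function\n")
  cat(sprintf("  midpoint: %.3f dB SNR\n", x$midpoint_db))
  cat(sprintf("  slope:    %.3f %%/dB at midpoint\n", x$slope))
  if (!is.na(x$mse)) cat(sprintf("  fit MSE:  %.2f %%^2\n", x$mse))
  if (!x$converged) cat("  [non-convergent fit; parameters unreliable]\n")
  invisible(x)
}

#' @export
coef.psychfun <- function(object, ...) {
  c(midpoint_db = object$midpoint_db, slope = object$slope)
}

#' @param object,newdata,... standard `predict` arguments; `newdata` or
#'   `snr_db` supplies the SNRs.
#' @param snr_db SNRs (dB) at which to evaluate the curve.
#' @rdname psychometric_function
#' @export
predict.psychfun <- function(object, newdata = NULL, snr_db = NULL, ...) {
  x <- if (!is.null(snr_db)) snr_db
  else if (is.data.frame(newdata)) newdata$snr_db
  else newdata
  if (is.null(x)) stop("supply `snr_db` (or `newdata`)")
  logistic_p(x, object)
}

#' @param x a `psychfun`.
#' @rdname psychometric_function
#' @export
plot.psychfun <- function(x, ...) {
  grid <- seq(x$midpoint_db - 10, x$midpoint_db + 10, length.out = 201)
  plot(grid, 100 * logistic_p(grid, x), type = "l",
       xlab = "SNR (dB)", ylab = "correct (%)", ...)
  graphics::abline(h = 50, v = x$midpoint_db, lty = 3)
  invisible(x)
}

#' Fit a logistic psychometric function by least squares
#'
#' Fits the two-parameter logistic of [psychometric_function()] to
#' percent-correct data by damped iterative least squares
#' (Levenberg-Marquardt via [minpack.lm::nlsLM()]), with multiple starting
#' midpoints spread over the observed SNR range for robustness on the
#' short (<= 25 point) trial series produced by single adaptive tracks.
#' The response is percent correct per presentation (0-100), so the
#' reported `mse` is in squared percentage points.
#'
#' Trials with no information about the midpoint -- all responses fully
#' correct or fully wrong -- yield a flagged non-convergent result
#' (`converged = FALSE`) rather than spurious parameters.
#'
#' @param trials a data.frame with column `snr_db` and either
#'   `pct_correct` (0-100) or `k_correct` (+ optional `n_keywords`,
#'   default 3) from which percent correct is computed per presentation.
#' @return A `psychfun` with fields `mse`, `converged`, `n_trials`.
#' @export
#' @examples
#' snr <- seq(-12, 0)
#' trials <- data.frame(snr_db = snr,
#'                      pct_correct = 100 * logistic_p(snr, -4.8, 13))
#' fit_psychometric(trials)
fit_psychometric <- function(trials) {
  stop_if_not_df_with(trials, "snr_db", "trials")
  x <- as.numeric(trials$snr_db)
  if (any(!is.finite(x))) stop("`snr_db` must be finite")
  if ("pct_correct" %in% names(trials)) {
    y <- as.numeric(trials$pct_correct)
    if (any(y < 0 | y > 100)) stop("`pct_correct` must lie in [0, 100]")
  } else if ("k_correct" %in% names(trials)) {
    n_kw <- if ("n_keywords" %in% names(trials)) trials$n_keywords else 3
    k <- trials$k_correct
    if (any(k < 0 | k > n_kw)) stop("`k_correct` must lie in [0, n_keywords]")
    y <- 100 * as.numeric(k) / as.numeric(n_kw)
  } else {
    stop("`trials` needs a `pct_correct` or `k_correct` column")
  }
  if (length(unique(x)) < 3)
    stop("need at least 3 distinct SNR levels to fit a psychometric function")

  n <- length(y)
  if (all(y == y[1])) {
    # no transition observed: midpoint unidentifiable
    fn <- psychometric_function(NA_real_, 1e-6, mse = 0, converged = FALSE)
    fn$n_trials <- n
    return(fn)
  }

  sse_of <- function(m, s) sum((y - 100 / (1 + exp(-4 * (s / 100) * (x - m))))^2)
  rng <- range(x)
  starts_m <- unique(c(seq(rng[1], rng[2], length.out = 5),
                       stats::weighted.mean(x, w = pmax(1e-6, 1 - abs(y / 100 - 0.5)))))
  starts_s <- c(5, 15, 30)
  best <- NULL
  for (m0 in starts_m) for (s0 in starts_s) {
    fit <- tryCatch(
      suppressWarnings(minpack.lm::nlsLM(
        y ~ 100 / (1 + exp(-4 * (s / 100) * (x - m))),
        start = list(m = m0, s = s0),
        lower = c(m = rng[1] - 20, s = 1e-3),
        upper = c(m = rng[2] + 20, s = 200),
        control = minpack.lm::nls.lm.control(maxiter = 200)
      )),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    cf <- stats::coef(fit)
    sse <- sse_of(cf[["m"]], cf[["s"]])
    if (is.null(best) || sse < best$sse - 1e-12)
      best <- list(m = cf[["m"]], s = cf[["s"]], sse = sse)
  }
  if (is.null(best)) {
    fn <- psychometric_function(NA_real_, 1e-6, mse = NA_real_,
                                converged = FALSE)
    fn$n_trials <- n
    return(fn)
  }
  # A midpoint far outside the sampled range or a slope pinned at a bound
  # means the data did not constrain the curve.
  conv <- best$m > rng[1] - 15 && best$m < rng[2] + 15 &&
    best$s > 2e-3 && best$s < 199
  fn <- psychometric_function(best$m, best$s, mse = best$sse / n,
                              converged = conv)
  fn$n_trials <- n
  fn
}

#' Sentence normalization offsets
#'
#' The per-sentence level offset that aligns each sentence's psychometric
#' midpoint with a reference: `offset_i = midpoint_i - reference_mean`.
#' Applying a level gain of `offset_i` dB to sentence `i` shifts its
#' effective midpoint onto `reference_mean` (a gain of `g` dB moves the
#' midpoint by `-g` dB), so positive offsets boost hard sentences.
#'
#' @param midpoints_db numeric vector of sentence midpoints (dB SNR).
#' @param reference_mean_db the reference midpoint (dB SNR), typically the
#'   corpus mean.
#' @return Numeric vector of offsets in dB.
#' @export
#' @examples
#' compute_offsets(c(-2.1, -4.8), reference_mean_db = -4.8)  # +2.7, 0
compute_offsets <- function(midpoints_db, reference_mean_db) {
  if (any(!is.finite(midpoints_db)) || !is.finite(reference_mean_db))
    stop("midpoints and reference must be finite")
  as.numeric(midpoints_db) - as.numeric(reference_mean_db)
}
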