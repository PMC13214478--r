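# Sorting sentences into psychometrically equivalent lists: middle-out
# pairing by offset, random pair-to-list assignment, and best-of-N
# minimization of a between-list dispersion cost.

#' Maximum number of lists supported by a corpus
#'
#' With a fixed number of sentences per template in every list, the
#' scarcest template limits the list count:
#' `floor(min(counts) / per_list_per_template)`.
#'
#' @param per_template_counts integer vector of available sentences per
#'   template.
#' @param per_list_per_template sentences of each template per list
#'   (default 2).
#' @return Integer list count.
#' @export
#' @examples
#' max_list_count(rep(88, 10))  # 44
max_list_count <- function(per_template_counts, per_list_per_template = 2) {
  stopifnot(all(per_template_counts >= 0), per_list_per_template >= 1)
  as.integer(floor(min(per_template_counts) / per_list_per_template))
}

#' Pair sentences of one template middle-out by offset
#'
#' Sorts the sentences of a single template by normalization offset and
#' pairs them from the middle outward, so each pair couples a relatively
#' easy sentence with a comparably hard one: with sorted offsets
#' `s_1..s_2m`, pair of rank `j - 1` is `(s_(m-j+1), s_(m+j))`; rank 0 is
#' the innermost (near-zero-offset) pair and the last pair holds the most
#' extreme offsets. When more than `2 * n_pairs` sentences are available,
#' `2 * n_pairs` are first drawn uniformly at random (using the current
#' RNG stream).
#'
#' @param records data.frame with `sentence_id` and `offset_db` (one
#'   template's sentences).
#' @param n_pairs number of pairs to form.
#' @return data.frame with columns `rank`, `id_low`, `id_high`,
#'   `offset_low`, `offset_high` (low/high by offset).
#' @export
pair_by_offset <- function(records, n_pairs) {
  stop_if_not_df_with(records, c("sentence_id", "offset_db"), "records")
  m <- as.integer(n_pairs)
  if (nrow(records) < 2L * m)
    stop(sprintf("need at least %d sentences to form %d pairs; have %d",
                 2L * m, m, nrow(records)))
  if (nrow(records) > 2L * m) {
    take <- sample.int(nrow(records), 2L * m)
    records <- records[take, , drop = FALSE]
  }
  ord <- order(records$offset_db, records$sentence_id)
  records <- records[ord, , drop = FALSE]
  j <- seq_len(m)
  lo <- m - j + 1L
  hi <- m + j
  data.frame(
    rank = j - 1L,
    id_low = records$sentence_id[lo],
    id_high = records$sentence_id[hi],
    offset_low = records$offset_db[lo],
    offset_high = records$offset_db[hi]
  )
}

#' Randomly distribute template pairs across lists
#'
#' For each template, a random permutation (current RNG stream) assigns
#' its pairs to the lists, one pair per list, so both members of a pair
#' land in the same list and extreme offsets are balanced both across and
#' within lists.
#'
#' @param pairs_by_template named list (one element per template) of
#'   data.frames as returned by [pair_by_offset()], each with exactly
#'   `n_lists` rows.
#' @param n_lists number of lists.
#' @return data.frame with columns `list_number`, `template_id`,
#'   `sentence_id`, `pair_rank`.
#' @export
assign_pairs_to_lists <- function(pairs_by_template, n_lists) {
  L <- as.integer(n_lists)
  out <- vector("list", length(pairs_by_template))
  tmpl_ids <- names(pairs_by_template)
  if (is.null(tmpl_ids)) tmpl_ids <- as.character(seq_along(pairs_by_template))
  for (i in seq_along(pairs_by_template)) {
    pairs <- pairs_by_template[[i]]
    if (nrow(pairs) != L)
      stop(sprintf("template %s has %d pairs; expected %d",
                   tmpl_ids[i], nrow(pairs), L))
    perm <- sample.int(L)
    out[[i]] <- data.frame(
      list_number = rep(perm, each = 2L),
      template_id = as.integer(tmpl_ids[i]),
      sentence_id = as.vector(rbind(pairs$id_low, pairs$id_high)),
      pair_rank = rep(pairs$rank, each = 2L)
    )
  }
  res <- do.call(rbind, out)
  res[order(res$list_number, res$template_id, res$pair_rank), ,
      drop = FALSE]
}

#' Between-list dispersion cost
#'
#' The equivalence cost of a candidate list arrangement: a weighted sum of
#' the standard deviation (sample SD, n-1 denominator by default) over
#' lists of the per-list mean slope and of the per-list mean offset, with
#' equal unit weights by default.
#'
#' @param assignment data.frame with `list_number`, `slope_pct_per_db`,
#'   `offset_db` (one row per sentence entry).
#' @param weights numeric `c(slope, offset)` weights.
#' @param sd_denominator `"n-1"` (sample SD, default) or `"n"`.
#' @return The cost (non-negative scalar).
#' @export
list_cost <- function(assignment, weights = c(slope = 1, offset = 1),
                      sd_denominator = c("n-1", "n")) {
  stop_if_not_df_with(assignment,
                      c("list_number", "slope_pct_per_db", "offset_db"),
                      "assignment")
  sd_denominator <- match.arg(sd_denominator)
  mean_slope <- tapply(assignment$slope_pct_per_db, assignment$list_number, mean)
  mean_offset <- tapply(assignment$offset_db, assignment$list_number, mean)
  if (length(mean_slope) < 2)
    stop("cost needs at least 2 lists (SD over lists undefined)")
  sdev <- function(v) {
    s <- stats::sd(v)
    if (sd_denominator == "n") s * sqrt((length(v) - 1) / length(v)) else s
  }
  as.numeric(weights[1] * sdev(mean_slope) + weights[2] * sdev(mean_offset))
}

#' Sort a corpus into equivalent sentence lists
#'
#' Repeats the pseudo-randomized sort `n_iter` times and keeps the
#' arrangement with the lowest between-list dispersion cost. Each
#' iteration: (1) per template, subsample `2 * n_lists` sentences (when
#' more are available) and pair them middle-out by offset
#' ([pair_by_offset()]); (2) randomly distribute pairs across lists
#' ([assign_pairs_to_lists()]); (3) recompute the reference mean midpoint
#' over the selected sentences and recalculate every offset against it;
#' (4) score the arrangement with [list_cost()]. Ties in cost keep the
#' earliest iteration; the whole procedure is reproducible bit-for-bit
#' under `seed`.
#'
#' @param corpus data.frame of retained sentences (columns `sentence_id`,
#'   `template_id`, `midpoint_db`, `slope_pct_per_db`); offsets are
#'   derived internally from midpoints.
#' @param n_lists number of lists to build; must not exceed
#'   [max_list_count()] of the corpus.
#' @param n_iter number of randomized sorts (default 1000).
#' @param seed integer seed; `NULL` uses the current RNG stream.
#' @param weights,sd_denominator passed to [list_cost()].
#' @param per_list_per_template sentences of each template per list.
#' @return An object of class `sentence_lists`: a list with `lists` (the
#'   winning assignment: `list_number`, `sentence_id`, `template_id`,
#'   `offset_db`, `slope_pct_per_db`, `midpoint_db`), `reference_mean_db`,
#'   `cost`, `iteration`, `n_lists`, `seed`, and `log` (per-iteration
#'   costs).
#' @export
optimize_lists <- function(corpus, n_lists, n_iter = 1000, seed = NULL,
                           weights = c(slope = 1, offset = 1),
                           sd_denominator = c("n-1", "n"),
                           per_list_per_template = 2) {
  stop_if_not_df_with(corpus, c("sentence_id", "template_id", "midpoint_db",
                                "slope_pct_per_db"), "corpus")
  sd_denominator <- match.arg(sd_denominator)
  L <- as.integer(n_lists)
  counts <- table(corpus$template_id)
  feasible <- max_list_count(as.integer(counts), per_list_per_template)
  if (L > feasible)
    stop(sprintf(
      "corpus supports at most %d lists (%d per template per list); %d requested",
      feasible, per_list_per_template, L))
  if (per_list_per_template != 2)
    stop("only 2 sentences per template per list is supported")
  split_corpus <- split(corpus, corpus$template_id)
  # pairing sorts by offset, and offset is midpoint minus a constant, so
  # pre-pairing offsets can be computed against any provisional reference
  prov_ref <- mean(corpus$midpoint_db)

  run <- function() {
    best <- NULL
    log_cost <- numeric(n_iter)
    for (it in seq_len(n_iter)) {
      pairs_by_template <- lapply(split_corpus, function(df) {
        df$offset_db <- df$midpoint_db - prov_ref
        pair_by_offset(df, L)
      })
      asg <- assign_pairs_to_lists(pairs_by_template, L)
      idx <- match(asg$sentence_id, corpus$sentence_id)
      asg$midpoint_db <- corpus$midpoint_db[idx]
      asg$slope_pct_per_db <- corpus$slope_pct_per_db[idx]
      ref <- mean(asg$midpoint_db)
      asg$offset_db <- compute_offsets(asg$midpoint_db, ref)
      cost <- list_cost(asg, weights, sd_denominator)
      log_cost[it] <- cost
      if (is.null(best) || cost < best$cost)
        best <- list(assignment = asg, reference_mean_db = ref,
                     cost = cost, iteration = it)
    }
    best$log <- log_cost
    best
  }
  best <- with_seed(seed, run())

  structure(
    list(lists = best$assignment[, c("list_number", "sentence_id",
                                     "template_id", "offset_db",
                                     "slope_pct_per_db", "midpoint_db",
                                     "pair_rank")],
         reference_mean_db = best$reference_mean_db,
         cost = best$cost, iteration = best$iteration,
         n_lists = L, seed = seed, log = best$log),
    class = "sentence_lists"
  )
}

#' @export
print.sentence_lists <- function(x, ...) {
  cat(sprintf("Sentence lists: %d lists x %d sentences\n",
              x$n_lists, nrow(x$lists) / x$n_lists))
  cat(sprintf("  reference midpoint: %.3f dB SNR\n", x$reference_mean_db))
  if (!is.null(x$cost))
    cat(sprintf("  dispersion cost: %.4f (iteration %d of %d)\n",
                x$cost, x$iteration, length(x$log)))
  cat(sprintf("  offset range: [%.2f, %.2f] dB\n",
              min(x$lists$offset_db), max(x$lists$offset_db)))
  invisible(x)
}

#' @export
summary.sentence_lists <- function(object, ...) {
  per_list <- do.call(rbind, lapply(split(object$lists, object$lists$list_number),
    function(df) data.frame(
      list_number = df$list_number[1], n = nrow(df),
      mean_slope = mean(df$slope_pct_per_db),
      mean_offset = mean(df$offset_db)
    )))
  rownames(per_list) <- NULL
  per_list
}
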