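# CSV readers/writers for the pipeline's tables. Every file srtkit writes
# starts with a single `#` provenance comment (tool version, seed, config
# hash) which all readers skip; CSVs use comma separators and dot
# decimals.

write_table_with_provenance <- function(df, path, seed = NA,
                                        extra = character()) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(provenance_line(seed, extra), con)
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

read_table_skip_provenance <- function(path) {
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Read / write a corpus metadata CSV
#'
#' Columns: `sentence_id`, `template_id`, `midpoint_db`,
#' `slope_pct_per_db`, `mse_pct2`, `naturalness_mean`,
#' `discomfort_fraction`, `quality_ok`. Column aliases `slope` and `mse`
#' are accepted on read.
#'
#' @param corpus data.frame in the corpus schema.
#' @param path file path.
#' @param seed seed recorded in the provenance line.
#' @return `read_corpus_csv`: the corpus data.frame; `write_corpus_csv`:
#'   the path, invisibly.
#' @export
write_corpus_csv <- function(corpus, path, seed = NA) {
  stop_if_not_df_with(corpus, corpus_cols, "corpus")
  write_table_with_provenance(corpus[, corpus_cols], path, seed,
                              sprintf("config=%s", config_hash(corpus_cols)))
}

#' @rdname write_corpus_csv
#' @export
read_corpus_csv <- function(path) {
  df <- read_table_skip_provenance(path)
  aliases <- c(slope = "slope_pct_per_db", mse = "mse_pct2")
  for (a in names(aliases))
    if (a %in% names(df) && !(aliases[[a]] %in% names(df)))
      names(df)[names(df) == a] <- aliases[[a]]
  stop_if_not_df_with(df, corpus_cols, "corpus file")
  df$quality_ok <- as.logical(df$quality_ok)
  df
}

#' Read / write list-definition CSVs
#'
#' The deposited list-definition format: columns `list_number`,
#' `sentence_number`, `offset_db`, with offsets serialized to one decimal
#' place (full precision is a property of the in-memory `sentence_lists`
#' object, not of the interchange file). An optional `template_id` column
#' is carried through when present; on read, the aliases `list`,
#' `sentence`, `sentence_id`, `template`, `offset` are accepted.
#' `write_list_csv` followed by `read_list_csv` and a second write
#' produces a byte-identical file.
#'
#' Validation on read: every list must have exactly `n_per_list` rows
#' (default 20), no `(list, sentence)` row may repeat, no sentence may
#' appear in two lists, and offsets must be numeric; violations name the
#' offending list or row.
#'
#' @param list_set a `sentence_lists` object (or a data.frame with the
#'   list columns).
#' @param path file path.
#' @param n_per_list required list length on read (default 20; `NA` skips
#'   the check).
#' @return `read_list_csv`: a `sentence_lists` object (with
#'   `reference_mean_db` recovered from the provenance line when present);
#'   `write_list_csv`: the path, invisibly.
#' @export
write_list_csv <- function(list_set, path) {
  df <- if (inherits(list_set, "sentence_lists")) list_set$lists else list_set
  stop_if_not_df_with(df, c("list_number", "sentence_id", "offset_db"),
                      "list_set")
  out <- data.frame(list_number = df$list_number,
                    sentence_number = df$sentence_id)
  if ("template_id" %in% names(df)) out$template_id <- df$template_id
  out$offset_db <- sprintf("%.1f", round(df$offset_db, 1))
  extra <- character()
  if (inherits(list_set, "sentence_lists")) {
    extra <- c(sprintf("reference_mean_db=%.6f", list_set$reference_mean_db),
               sprintf("config=%s", config_hash(list_set$n_lists)))
    seed <- if (is.null(list_set$seed)) NA else list_set$seed
  } else seed <- NA
  write_table_with_provenance(out, path, seed, extra)
}

#' @rdname write_list_csv
#' @export
read_list_csv <- function(path, n_per_list = 20) {
  first <- readLines(path, n = 1L)
  ref <- NA_real_
  seed <- NULL
  if (startsWith(first, "#")) {
    m <- regmatches(first, regexec("reference_mean_db=([-0-9.eE+]+)", first))[[1]]
    if (length(m) == 2) ref <- as.numeric(m[2])
    m <- regmatches(first, regexec("seed=([-0-9]+)", first))[[1]]
    if (length(m) == 2) seed <- as.integer(m[2])
  }
  df <- read_table_skip_provenance(path)
  aliases <- c(list = "list_number", sentence = "sentence_number",
               sentence_id = "sentence_number", template = "template_id",
               offset = "offset_db")
  for (a in names(aliases))
    if (a %in% names(df) && !(aliases[[a]] %in% names(df)))
      names(df)[names(df) == a] <- aliases[[a]]
  stop_if_not_df_with(df, c("list_number", "sentence_number", "offset_db"),
                      "list file")
  if (!is.numeric(df$offset_db))
    stop("non-numeric offsets in list file")
  key <- paste(df$list_number, df$sentence_number)
  if (anyDuplicated(key))
    stop(sprintf("duplicate (list, sentence) row: %s", key[duplicated(key)][1]))
  if (anyDuplicated(df$sentence_number))
    stop(sprintf("sentence %s appears in more than one list",
                 df$sentence_number[duplicated(df$sentence_number)][1]))
  if (!is.na(n_per_list)) {
    sizes <- table(df$list_number)
    bad <- names(sizes)[sizes != n_per_list]
    if (length(bad))
      stop(sprintf("list_number %s has %d rows; expected %d",
                   bad[1], sizes[[bad[1]]], n_per_list))
  }
  lists <- data.frame(list_number = df$list_number,
                      sentence_id = df$sentence_number)
  if ("template_id" %in% names(df)) lists$template_id <- df$template_id
  lists$offset_db <- df$offset_db
  structure(list(lists = lists, reference_mean_db = ref, cost = NULL,
                 iteration = NULL, n_lists = length(unique(df$list_number)),
                 seed = seed, log = NULL),
            class = "sentence_lists")
}

#' Read / write a study-results CSV
#'
#' Long-format table of one row per SRT measurement: `participant_id`,
#' `presentation_order`, `list_id`, `is_training`, `srt_db`, `se_db`,
#' `n_phase23` (and `slope_pct_per_db` when present).
#'
#' @param results an `srt_study` or its `results` data.frame.
#' @param path file path.
#' @param seed seed recorded in the provenance line.
#' @return `read_study_csv`: the results data.frame; `write_study_csv`:
#'   the path, invisibly.
#' @export
write_study_csv <- function(results, path, seed = NA) {
  if (inherits(results, "srt_study")) {
    if (is.na(seed)) seed <- results$seed
    results <- results$results
  }
  stop_if_not_df_with(results, c("participant_id", "presentation_order",
                                 "list_id", "is_training", "srt_db"),
                      "results")
  write_table_with_provenance(results, path, seed)
}

#' @rdname write_study_csv
#' @export
read_study_csv <- function(path) {
  df <- read_table_skip_provenance(path)
  stop_if_not_df_with(df, c("participant_id", "presentation_order",
                            "list_id", "is_training", "srt_db"),
                      "study file")
  df$is_training <- as.logical(df$is_training)
  df
}

#' Read / write an adaptive-track log CSV
#'
#' One row per presentation, in the schema of [as.data.frame.srt_track()].
#'
#' @param track an `srt_track` or its log data.frame.
#' @param path file path.
#' @return `read_track_csv`: the log data.frame; `write_track_csv`: the
#'   path, invisibly.
#' @export
write_track_csv <- function(track, path) {
  log <- if (inherits(track, "srt_track")) as.data.frame(track) else track
  stop_if_not_df_with(log, c("index", "sentence_id", "phase",
                             "nominal_snr_db", "adjusted_snr_db",
                             "k_correct", "correct", "is_escalation_replay"),
                      "track log")
  write_table_with_provenance(log, path)
}

#' @rdname write_track_csv
#' @export
read_track_csv <- function(path) {
  df <- read_table_skip_provenance(path)
  df$correct <- as.logical(df$correct)
  df$is_escalation_replay <- as.logical(df$is_escalation_replay)
  df
}
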