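# Run configuration: one YAML file drives the whole pipeline.

#' Default run configuration
#'
#' A nested list with the settings of every pipeline stage: `seed`,
#' `filter` (the [filter_criteria()] cutoffs), `optimizer` (`n_lists`,
#' `n_iter`, cost `weights`, `sd_denominator`), `track` (the
#' [track_settings()] fields), and `study` (`n_participants`,
#' `n_training`, listener model). Serializable to and from YAML with
#' [write_run_config()] / [read_run_config()]; unknown keys in a config
#' file are rejected.
#'
#' @return Nested named list.
#' @export
default_run_config <- function() {
  list(
    seed = 1L,
    filter = list(
      midpoint_min_db = -9.2, midpoint_max_db = -0.5,
      slope_min = 0, slope_max = 33.5,
      mse_bound = 897, mse_direction = "below",
      naturalness_min = 4.5, discomfort_max = 0.25,
      quality_required = TRUE, max_abs_offset_db = 3
    ),
    optimizer = list(
      n_lists = 44L, n_iter = 1000L,
      weight_slope = 1, weight_offset = 1, sd_denominator = "n-1"
    ),
    track = list(
      start_snr_db = 0, steps_db = c(5, 2, 1), se_threshold_db = 1,
      scoring_rule = "majority", n_keywords = 3L,
      escalation_step_db = 5, n_sentences = 20L, noise_level_dba = 70
    ),
    study = list(
      n_participants = 20L, n_training = 2L,
      listener_srt_sd_db = 0.5, listener_slope_scale = 1
    )
  )
}

check_known_keys <- function(cfg, ref, path = "") {
  unknown <- setdiff(names(cfg), names(ref))
  if (length(unknown))
    stop(sprintf("unknown config key(s): %s",
                 paste0(path, unknown, collapse = ", ")), call. = FALSE)
  for (nm in names(cfg))
    if (is.list(ref[[nm]]) && !is.null(names(ref[[nm]])))
      check_known_keys(as.list(cfg[[nm]]), ref[[nm]],
                       paste0(path, nm, "."))
  invisible(TRUE)
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && !is.null(names(base[[nm]])) &&
        is.list(override[[nm]]))
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    else base[[nm]] <- override[[nm]]
  }
  base
}

#' @param path YAML file path.
#' @rdname default_run_config
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg)) cfg <- list()
  ref <- default_run_config()
  check_known_keys(cfg, ref)
  merge_config(ref, cfg)
}

#' @param config a config list (missing keys filled from the defaults).
#' @rdname default_run_config
#' @export
write_run_config <- function(config, path) {
  check_known_keys(config, default_run_config())
  yaml::write_yaml(config, path)
  invisible(path)
}

#' Build stage objects from a run config
#'
#' @param config a run-config list.
#' @return List with `criteria` ([filter_criteria()]) and `settings`
#'   ([track_settings()]).
#' @export
config_objects <- function(config) {
  f <- config$filter
  t <- config$track
  list(
    criteria = filter_criteria(
      midpoint_range = c(f$midpoint_min_db, f$midpoint_max_db),
      slope_range = c(f$slope_min, f$slope_max),
      mse_bound = f$mse_bound, mse_direction = f$mse_direction,
      naturalness_min = f$naturalness_min,
      discomfort_max = f$discomfort_max,
      quality_required = f$quality_required,
      max_abs_offset_db = f$max_abs_offset_db
    ),
    settings = track_settings(
      start_snr_db = t$start_snr_db, steps_db = t$steps_db,
      se_threshold_db = t$se_threshold_db,
      scoring_rule = t$scoring_rule, n_keywords = t$n_keywords,
      escalation_step_db = t$escalation_step_db,
      n_sentences = t$n_sentences, noise_level_dba = t$noise_level_dba
    )
  )
}
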