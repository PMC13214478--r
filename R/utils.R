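# Internal helpers: seeding, hashing, provenance.

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG
# state. seed = NULL leaves the current stream untouched.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# Deterministic per-track seed below 2^31, derived from (master seed,
# participant, presentation order) so that re-running one session does not
# perturb the RNG stream of any other track.
derive_seed <- function(master, participant, order) {
  m <- 2147483647
  s <- (abs(as.numeric(master)) %% 100000) * 1000003 +
    as.numeric(participant) * 10007 + as.numeric(order) * 101
  as.integer(s %% m)
}

# Tiny FNV-style hash of an R object's deparsed form; used only to stamp
# output files with a config fingerprint. bitwXor works on 32-bit signed
# ints, so the accumulator is split into 16-bit halves.
config_hash <- function(x) {
  txt <- paste(deparse(x), collapse = " ")
  bytes <- utf8ToInt(txt)
  h <- 2166136261
  for (b in bytes) {
    h <- (h * 16777619) %% 4294967296
    lo <- bitwXor(as.integer(h %% 65536), as.integer(b))
    h <- (h %/% 65536) * 65536 + lo
  }
  sprintf("%08x", h)
}

pkg_version <- function() {
  as.character(utils::packageVersion("srtkit"))
}

# Every file srtkit writes starts with one comment line that readers skip.
provenance_line <- function(seed = NA, extra = character()) {
  parts <- c(
    sprintf("# srtkit %s", pkg_version()),
    sprintf("seed=%s", ifelse(is.na(seed), "NA", format(seed))),
    extra
  )
  paste(parts, collapse = " | ")
}

stop_if_not_df_with <- function(x, cols, what) {
  if (!is.data.frame(x))
    stop(sprintf("`%s` must be a data.frame", what), call. = FALSE)
  missing <- setdiff(cols, names(x))
  if (length(missing))
    stop(sprintf("`%s` is missing column(s): %s", what,
                 paste(missing, collapse = ", ")), call. = FALSE)
  invisible(x)
}
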