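# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so simulation functions are
#' deterministic without disturbing the caller's RNG stream.
#' @noRd
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("`seed` must be a single integer", call. = FALSE)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Deterministic per-component substream seed derived from a master seed.
# Kept below 2^31 so it is always a valid R integer.
substream_seed <- function(seed, component) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  offsets <- c(baseline = 1L, assign = 2L, noise = 3L, signature = 4L,
               prognostic = 5L, stage = 6L, permute = 7L)
  off <- if (is.character(component)) {
    if (!component %in% names(offsets))
      stop("unknown substream component: ", component, call. = FALSE)
    offsets[[component]]
  } else as.integer(component)
  as.integer((abs(as.numeric(seed)) * 97L + off * 7919) %% (2^31 - 1))
}

# Stop with a classed condition so callers and the CLI can map error
# families to exit codes (config vs data/format errors).
stop_config <- function(...) {
  stop(errorCondition(paste0(...), class = c("acidep_config_error", "error")))
}
stop_format <- function(...) {
  stop(errorCondition(paste0(...), class = c("acidep_format_error", "error")))
}

assert_fraction <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    stop_config("`", name, "` must be a single number in [0, 1]")
  invisible(x)
}
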