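## Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 0 && x == floor(x)
}

#' @keywords internal
check_range <- function(x, lo, hi, what, lo_open = FALSE, hi_open = FALSE) {
  bad <- if (lo_open) x <= lo else x < lo
  bad <- bad | if (hi_open) x >= hi else x > hi
  if (any(bad, na.rm = TRUE))
    stopf("%s must lie in %s%g, %g%s; offending value %g", what,
          if (lo_open) "(" else "[", lo, hi, if (hi_open) ")" else "]",
          x[which(bad)[1L]])
  invisible(x)
}

## Deterministic per-stage seed derivation from one master seed.
## Kept well below 2^31 so it is always a valid R integer seed.
stage_seed <- function(seed, stage) {
  (as.integer(seed) %% 1000000L) * 1000L + as.integer(stage)
}

## Two-sided p from a t statistic.
t_pvalue <- function(t, df) 2 * stats::pt(abs(t), df = df, lower.tail = FALSE)
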