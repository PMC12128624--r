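# Shared constants and small helpers.

# Muscles recorded by surface EMG (bilateral).
EMG_MUSCLES <- c("TA", "GAM", "SOL", "PL", "RF", "VL", "ST")

# Muscle groups targeted by the stimulation suit.
FES_MUSCLES <- c("quadriceps", "hamstrings", "gluteii",
                 "tibialis_anterior", "gastrocnemius")

SIDES <- c("left", "right")

side_suffix <- function(side) c(left = "L", right = "R")[[side]]

channel_label <- function(muscle, side) paste0(muscle, "_", side_suffix(side))

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

assert_scalar_num <- function(x, name, lower = -Inf, upper = Inf,
                              open_lower = FALSE, open_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stopf("'%s' must be a single finite number", name)
  lo_ok <- if (open_lower) x > lower else x >= lower
  hi_ok <- if (open_upper) x < upper else x <= upper
  if (!lo_ok || !hi_ok)
    stopf("'%s' = %g is outside the allowed range %s%g, %g%s", name, x,
          if (open_lower) "(" else "[", lower, upper,
          if (open_upper) ")" else "]")
  invisible(x)
}

# Linear interpolation of the first upward crossing of `level` by `x(t)`.
first_crossing <- function(t, x, level) {
  above <- x >= level
  i <- which(!above[-length(x)] & above[-1])
  if (length(i) == 0L) {
    if (all(above)) return(t[1])
    return(NA_real_)
  }
  i <- i[1]
  t[i] + (level - x[i]) * (t[i + 1] - t[i]) / (x[i + 1] - x[i])
}
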