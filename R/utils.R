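# Internal helpers shared across the package.

#' Round half away from zero
#'
#' Base `round()` rounds halves to even; printed odds denominators and count
#' tables here follow the conventional "half away from zero" rule instead.
#'
#' @param x numeric vector.
#' @param digits integer number of decimal places.
#' @return numeric vector rounded half away from zero.
#' @keywords internal
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# stop() with a classed condition so callers (and the CLI) can distinguish
# validation failures from I/O failures.
abort_validation <- function(msg, call. = FALSE) {
  cond <- structure(
    class = c("polyscreen_validation_error", "error", "condition"),
    list(message = msg, call = if (isTRUE(call.)) sys.call(-1) else NULL)
  )
  stop(cond)
}

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         closed_lower = TRUE, closed_upper = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort_validation(sprintf("`%s` must be a single finite number", name))
  }
  lo_ok <- if (closed_lower) x >= lower else x > lower
  hi_ok <- if (closed_upper) x <= upper else x < upper
  if (!lo_ok || !hi_ok) {
    abort_validation(sprintf(
      "`%s` = %g is outside %s%g, %g%s", name, x,
      if (closed_lower) "[" else "(", lower, upper,
      if (closed_upper) "]" else ")"
    ))
  }
  invisible(x)
}

check_count <- function(x, name, lower = 0) {
  check_number(x, name, lower = lower)
  if (x != round(x)) {
    abort_validation(sprintf("`%s` must be a whole number, got %g", name, x))
  }
  invisible(as.numeric(x))
}

# Round a vector of non-negative expected counts to integers whose sum equals
# `total`, repairing by largest remainder (ties broken by position).
allocate_integer_counts <- function(expected, total) {
  stopifnot(all(expected >= 0), total >= 0)
  rounded <- round_half_up(expected)
  gap <- total - sum(rounded)
  if (gap != 0) {
    frac <- expected - floor(expected)
    ord <- if (gap > 0) {
      order(-(frac - 0.5), seq_along(expected))
    } else {
      order(frac - 0.5, seq_along(expected))
    }
    i <- 0L
    step <- sign(gap)
    while (gap != 0) {
      i <- i + 1L
      idx <- ord[((i - 1L) %% length(expected)) + 1L]
      if (rounded[idx] + step >= 0) {
        rounded[idx] <- rounded[idx] + step
        gap <- gap - step
      }
    }
  }
  rounded
}
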