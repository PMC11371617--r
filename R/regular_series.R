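#' Regularly sampled univariate series with an explicit missing mask
#'
#' A `regular_series` holds one numeric channel on a uniform time grid.
#' Slot `i` (1-based) covers the half-open interval
#' `[start + (i-1)*step, start + i*step)`; its label is the interval start.
#' Missing slots carry `NA` in `values` and `TRUE` in `missing_mask`; the two
#' encodings are kept consistent by construction.
#'
#' @param start `POSIXct` (UTC) timestamp of the first slot.
#' @param step sampling interval in seconds (positive scalar).
#' @param values numeric vector; `NA` marks missing slots.
#' @param missing_mask optional logical vector; defaults to `is.na(values)`.
#'   Supplying a mask that flags a finite value as missing blanks that value.
#' @param label free-text channel label.
#' @return An object of class `regular_series`.
#' @examples
#' s <- regular_series(as.POSIXct("2023-01-01", tz = "UTC"), 60,
#'                     c(61, NA, 63), label = "hr")
#' series_times(s)
#' @export
regular_series <- function(start, step, values, missing_mask = NULL,
                           label = "") {
  if (!inherits(start, "POSIXct")) {
    start <- as.POSIXct(start, tz = "UTC")
  }
  step <- as.numeric(step)
  stopifnot(length(step) == 1L, is.finite(step), step > 0)
  values <- as.numeric(values)
  if (length(values) < 1L) {
    stop("a regular_series needs at least one slot", call. = FALSE)
  }
  if (is.null(missing_mask)) {
    missing_mask <- is.na(values)
  }
  missing_mask <- as.logical(missing_mask)
  if (length(missing_mask) != length(values)) {
    stop("values and missing_mask must have equal length", call. = FALSE)
  }
  missing_mask <- missing_mask | is.na(values)
  values[missing_mask] <- NA_real_
  if (any(!is.finite(values) & !missing_mask)) {
    stop("non-missing values must be finite", call. = FALSE)
  }
  structure(
    list(start = start, step = step, values = values,
         missing_mask = missing_mask, label = as.character(label)[1L]),
    class = "regular_series"
  )
}

#' @export
length.regular_series <- function(x) length(x$values)

#' Slot timestamps of a regular series
#'
#' @param series a [regular_series()].
#' @return `POSIXct` vector of slot start times.
#' @export
series_times <- function(series) {
  stopifnot(inherits(series, "regular_series"))
  series$start + series$step * (seq_along(series$values) - 1L)
}

#' @export
print.regular_series <- function(x, ...) {
  n <- length(x$values)
  cat(sprintf(
    "<regular_series> %s\n  %d slots @ %gs from %s, %d missing (%.1f%%)\n",
    if (nzchar(x$label)) x$label else "(unlabelled)",
    n, x$step, format(x$start, "%Y-%m-%d %H:%M:%S", tz = "UTC"),
    sum(x$missing_mask), 100 * mean(x$missing_mask)))
  invisible(x)
}

# internal: error with a condition class so callers/tests can be precise
bi_stop <- function(class, fmt, ...) {
  msg <- sprintf(fmt, ...)
  stop(structure(class = c(class, "binimpute_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}
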