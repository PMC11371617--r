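#' @title Day-by-clock-slot grids, clock-anchored gaps and bin windows
#' @description Helpers that reshape a [regular_series()] into a matrix with
#'   one row per calendar day and one column per within-day clock slot, the
#'   layout in which "impute a day's gap from the same clock time of other
#'   days" is natural.  Durations exposed to the user (gap span, bin size)
#'   are in minutes; the grid step stays in seconds.
#' @name daygrid
NULL

# parse "HH:MM" / "HH:MM:SS" to seconds since midnight
clock_to_seconds <- function(clock) {
  if (is.numeric(clock)) return(as.numeric(clock))
  p <- strsplit(as.character(clock), ":", fixed = TRUE)[[1L]]
  if (!length(p) %in% c(2L, 3L) || anyNA(suppressWarnings(as.numeric(p)))) {
    bi_stop("binimpute_format_error", "cannot parse clock time '%s'", clock)
  }
  p <- as.numeric(p)
  p[1L] * 3600 + p[2L] * 60 + if (length(p) == 3L) p[3L] else 0
}

seconds_to_clock <- function(sec) {
  sprintf("%02d:%02d", as.integer(sec) %/% 3600L,
          (as.integer(sec) %% 3600L) %/% 60L)
}

new_daygrid <- function(day_labels, slot_seconds, step, values, mask) {
  stopifnot(nrow(values) == length(day_labels),
            ncol(values) == length(slot_seconds),
            identical(dim(values), dim(mask)))
  values[mask] <- NA_real_
  structure(
    list(day_labels = day_labels, slot_seconds = slot_seconds,
         step = step, values = values, missing_mask = mask),
    class = "daygrid"
  )
}

#' @export
print.daygrid <- function(x, ...) {
  cat(sprintf(
    "<daygrid> %d days x %d slots @ %gs (%s .. %s), %d missing cells\n",
    nrow(x$values), ncol(x$values), x$step,
    format(x$day_labels[1L]), format(x$day_labels[length(x$day_labels)]),
    sum(x$missing_mask)))
  invisible(x)
}

#' @export
dim.daygrid <- function(x) dim(x$values)

#' Reshape a series into a day-by-clock-slot grid
#'
#' Cuts the series into whole calendar days (rows) by clock slot (columns).
#' Only days whose full set of slots lies inside the series range are
#' eligible; with `require_complete` a day must in addition have no missing
#' slot — mirroring the protocol of selecting complete days before deleting
#' data from them.  When more eligible days exist than `n_days`, that many
#' are drawn uniformly without replacement using `selection_seed`; the
#' returned rows are always in chronological order.
#'
#' @param series a [regular_series()] whose step divides 24 h.
#' @param require_complete admit only fully observed days (default `TRUE`).
#' @param n_days number of days to keep; `NULL` keeps all eligible days.
#' @param selection_seed integer seed for the uniform day draw.
#' @return A `daygrid`.
#' @export
build_daygrid <- function(series, require_complete = TRUE, n_days = NULL,
                          selection_seed = 1L) {
  stopifnot(inherits(series, "regular_series"))
  step <- series$step
  if (86400 %% step != 0) {
    bi_stop("binimpute_alignment_error",
            "step %gs does not divide 24 h", step)
  }
  t_per_day <- as.integer(86400 / step)
  times <- series_times(series)
  day <- as.Date(times, tz = "UTC")
  sec <- as.numeric(times) %% 86400
  slot_col <- as.integer(round(sec / step)) + 1L
  tab <- table(day)
  full_days <- as.Date(names(tab)[tab == t_per_day])
  if (!length(full_days)) {
    bi_stop("binimpute_insufficient_data",
            "series covers no whole calendar day")
  }
  rows <- lapply(full_days, function(d) {
    i <- which(day == d)
    i[order(slot_col[i])]
  })
  vals <- do.call(rbind, lapply(rows, function(i) series$values[i]))
  mask <- do.call(rbind, lapply(rows, function(i) series$missing_mask[i]))
  eligible <- if (require_complete) which(rowSums(mask) == 0L)
              else seq_along(full_days)
  if (is.null(n_days)) n_days <- length(eligible)
  if (length(eligible) < n_days) {
    bi_stop("binimpute_insufficient_data",
            "need %d eligible days but only %d available",
            n_days, length(eligible))
  }
  keep <- if (length(eligible) > n_days) {
    with_local_seed(selection_seed,
                    sort(sample(eligible, n_days, replace = FALSE)))
  } else {
    eligible
  }
  new_daygrid(full_days[keep], (seq_len(t_per_day) - 1L) * step, step,
              vals[keep, , drop = FALSE], mask[keep, , drop = FALSE])
}

# run expr under a private RNG state, restoring the caller's afterwards
with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

#' Define a clock-anchored missing span
#'
#' @param start_clock within-day clock time (`"HH:MM"`, `"HH:MM:SS"`, or
#'   seconds since midnight) at which the gap starts.
#' @param span_minutes gap length in minutes; the interval is end-exclusive,
#'   so a 5-minute gap starting 03:22 covers slots 03:22 .. 03:26 on a
#'   1-minute grid.
#' @param target_day row index of the day the gap is placed on.
#' @return A `gap_spec`.
#' @export
gap_spec <- function(start_clock, span_minutes, target_day = 1L) {
  start_sec <- clock_to_seconds(start_clock)
  span_sec <- span_minutes * 60
  stopifnot(span_sec > 0, start_sec >= 0)
  if (start_sec + span_sec > 86400) {
    bi_stop("binimpute_alignment_error",
            "gap %s + %g min crosses midnight",
            seconds_to_clock(start_sec), span_minutes)
  }
  structure(list(start_sec = start_sec, span_sec = span_sec,
                 target_day = as.integer(target_day)),
            class = "gap_spec")
}

#' Slot indices covered by a gap
#'
#' @param grid a `daygrid`.
#' @param gap a [gap_spec()].
#' @return Integer vector of 1-based column indices (slot 1 is midnight).
#' @export
gap_slots <- function(grid, gap) {
  stopifnot(inherits(grid, "daygrid"), inherits(gap, "gap_spec"))
  step <- grid$step
  if (gap$start_sec %% step != 0 || gap$span_sec %% step != 0) {
    bi_stop("binimpute_alignment_error",
            "gap at %s (%g s) is not aligned to the %gs grid",
            seconds_to_clock(gap$start_sec), gap$span_sec, step)
  }
  first <- as.integer(gap$start_sec / step) + 1L
  n <- as.integer(gap$span_sec / step)
  if (first + n - 1L > ncol(grid$values)) {
    bi_stop("binimpute_alignment_error", "gap extends past the day end")
  }
  seq.int(first, first + n - 1L)
}

#' Delete a gap from its target day
#'
#' Marks the gap cells of the target day missing and returns both the masked
#' grid and the deleted true values (in slot order) for later scoring.  All
#' gap cells must currently be observed; no other cell is touched.
#'
#' @inheritParams gap_slots
#' @return List with elements `grid` (masked copy) and `truth` (numeric).
#' @export
mask_gap <- function(grid, gap) {
  slots <- gap_slots(grid, gap)
  d <- gap$target_day
  if (d < 1L || d > nrow(grid$values)) {
    bi_stop("binimpute_config_error", "target_day %d out of range", d)
  }
  if (any(grid$missing_mask[d, slots])) {
    bi_stop("binimpute_precondition_error",
            "gap cells on day %d are already missing", d)
  }
  truth <- grid$values[d, slots]
  out <- grid
  out$missing_mask[d, slots] <- TRUE
  out$values[d, slots] <- NA_real_
  list(grid = out, truth = truth)
}

#' Bin window of a given width around a gap
#'
#' The window is centred on the gap: the surplus width beyond the gap is
#' split as evenly as possible, the odd extra slot going *before* the gap,
#' and the window is clipped (not shifted) at the day boundaries, so a
#' window near midnight can be narrower than requested.  A bin of 24 h (or
#' more) always covers the whole day — the no-binning baseline.
#'
#' @inheritParams gap_slots
#' @param bin_minutes window width in minutes; at least the gap span.
#' @return A `bin_window` with 1-based `first_slot`/`last_slot` (inclusive).
#' @export
make_bin_window <- function(grid, gap, bin_minutes) {
  stopifnot(inherits(grid, "daygrid"))
  bin_sec <- bin_minutes * 60
  if (bin_sec < gap$span_sec) {
    bi_stop("binimpute_config_error",
            "bin size %g min is smaller than the gap span %g min",
            bin_minutes, gap$span_sec / 60)
  }
  if (bin_sec %% grid$step != 0) {
    bi_stop("binimpute_alignment_error",
            "bin size %g min is not a multiple of the %gs step",
            bin_minutes, grid$step)
  }
  slots <- gap_slots(grid, gap)
  if (bin_sec >= 86400) {            # whole-day baseline: the full grid
    return(structure(list(bin_minutes = bin_minutes, first_slot = 1L,
                          last_slot = ncol(grid$values)),
                     class = "bin_window"))
  }
  n_bin <- as.integer(bin_sec / grid$step)
  surplus <- n_bin - length(slots)
  before <- ceiling(surplus / 2)
  after <- surplus - before
  first <- max(1L, slots[1L] - before)
  last <- min(ncol(grid$values), slots[length(slots)] + after)
  structure(list(bin_minutes = bin_minutes, first_slot = as.integer(first),
                 last_slot = as.integer(last)),
            class = "bin_window")
}

#' Restrict a grid to a bin window's columns
#'
#' All days are kept; masks are preserved.  With a 24-h window this is the
#' identity — the whole-day grid used as the no-binning baseline.
#'
#' @param grid a `daygrid`.
#' @param window a [make_bin_window()] result.
#' @return A `daygrid` over the window columns.
#' @export
extract_bin_matrix <- function(grid, window) {
  stopifnot(inherits(grid, "daygrid"), inherits(window, "bin_window"))
  cols <- seq.int(window$first_slot, window$last_slot)
  new_daygrid(grid$day_labels, grid$slot_seconds[cols], grid$step,
              grid$values[, cols, drop = FALSE],
              grid$missing_mask[, cols, drop = FALSE])
}

#' The standard ladder of bin sizes
#'
#' Returns the benchmark ladder 1, 2, 3, 4, 5, 10, 15, 30, 45 minutes and
#' 1–6 hours, filtered to widths at least the gap span (a 5-minute gap
#' starts at the 5-minute bin, a 15-minute gap at the 15-minute bin).
#'
#' @param span_minutes gap span in minutes.
#' @return Ascending numeric vector of bin sizes in minutes.
#' @export
standard_bin_sizes <- function(span_minutes = 1) {
  sizes <- c(1, 2, 3, 4, 5, 10, 15, 30, 45, 60 * (1:6))
  sizes[sizes >= span_minutes]
}
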