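#' Load a generic timestamped-value CSV onto a uniform grid
#'
#' Reads a long-format CSV with one timestamp column (ISO-8601, naive local
#' time interpreted as UTC) and one numeric value column, and places it on the
#' uniform grid running from the first to the last timestamp at `step`
#' seconds.  Grid slots absent from the file, and rows whose value cell is
#' empty or not numeric, are flagged missing.
#'
#' @param path CSV file path (header row, RFC-4180).
#' @param timestamp_column,value_column column names.
#' @param step grid interval in seconds; must divide every gap between
#'   consecutive timestamps.
#' @param label channel label for the result; defaults to `value_column`.
#' @return A [regular_series()].
#' @export
load_value_csv <- function(path, timestamp_column = "timestamp",
                           value_column = "value", step,
                           label = value_column) {
  if (!file.exists(path)) {
    bi_stop("binimpute_io_error", "file not found: %s", path)
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character", check.names = FALSE)
  for (col in c(timestamp_column, value_column)) {
    if (!col %in% names(df)) {
      bi_stop("binimpute_config_error",
              "column '%s' not in file (has: %s)", col,
              paste(names(df), collapse = ", "))
    }
  }
  ts_raw <- df[[timestamp_column]]
  ts <- parse_timestamps(ts_raw)
  bad <- which(is.na(ts))
  if (length(bad)) {
    bi_stop("binimpute_format_error",
            "unparseable timestamp '%s' at data line %d",
            ts_raw[bad[1L]], bad[1L])
  }
  if (anyDuplicated(ts)) {
    d <- ts_raw[which(duplicated(ts))[1L]]
    bi_stop("binimpute_duplicate_error", "duplicate timestamp '%s'", d)
  }
  ord <- order(ts)
  ts <- ts[ord]
  vals_raw <- df[[value_column]][ord]
  offs <- as.numeric(difftime(ts, ts[1L], units = "secs"))
  if (any(abs(offs %% step) > 1e-6)) {
    i <- which(abs(offs %% step) > 1e-6)[1L]
    bi_stop("binimpute_alignment_error",
            "timestamp %s is not aligned to the %gs grid",
            format(ts[i], tz = "UTC"), step)
  }
  n <- as.integer(round(offs[length(offs)] / step)) + 1L
  values <- rep(NA_real_, n)
  idx <- as.integer(round(offs / step)) + 1L
  suppressWarnings(num <- as.numeric(vals_raw))
  num[!nzchar(trimws(vals_raw))] <- NA_real_
  values[idx] <- num
  regular_series(ts[1L], step, values, label = label)
}

# ISO-8601-ish timestamp parsing that yields NA (never an R error) for
# unparseable entries, so errors can name the offending line
parse_timestamps <- function(x) {
  fmts <- c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS",
            "%Y-%m-%dT%H:%M", "%Y-%m-%d %H:%M", "%Y-%m-%d")
  out <- .POSIXct(rep(NA_real_, length(x)), tz = "UTC")
  for (f in fmts) {
    todo <- is.na(out)
    if (!any(todo)) break
    out[todo] <- as.POSIXct(strptime(x[todo], f, tz = "UTC"))
  }
  out
}

#' Load the household smart-meter file dialect
#'
#' Parses the semicolon-separated minute-level format of the public household
#' electric power consumption file: header
#' `Date;Time;Global_active_power;...`, dates as `d/m/yyyy`, times as
#' `hh:mm:ss`, and `?` marking missing cells.  The selected channel is placed
#' on a 1-minute grid from the first to the last record.
#'
#' @param path file path.
#' @param channel channel (column) name, e.g. `"Global_active_power"`.
#' @return A 1-min [regular_series()].
#' @export
load_power_file <- function(path, channel = "Global_active_power") {
  if (!file.exists(path)) {
    bi_stop("binimpute_io_error", "file not found: %s", path)
  }
  df <- utils::read.csv(path, sep = ";", stringsAsFactors = FALSE,
                        colClasses = "character", check.names = FALSE)
  if (!all(c("Date", "Time") %in% names(df))) {
    bi_stop("binimpute_format_error",
            "expected a 'Date;Time;...' header, got: %s",
            paste(names(df), collapse = ";"))
  }
  if (!channel %in% names(df)) {
    bi_stop("binimpute_config_error",
            "unknown channel '%s' (file has: %s)", channel,
            paste(setdiff(names(df), c("Date", "Time")), collapse = ", "))
  }
  ts <- as.POSIXct(paste(df$Date, df$Time), tz = "UTC",
                   format = "%d/%m/%Y %H:%M:%S")
  bad <- which(is.na(ts))
  if (length(bad)) {
    bi_stop("binimpute_format_error",
            "malformed Date/Time '%s %s' at data line %d",
            df$Date[bad[1L]], df$Time[bad[1L]], bad[1L])
  }
  vals_raw <- df[[channel]]
  vals_raw[vals_raw == "?"] <- NA
  suppressWarnings(num <- as.numeric(vals_raw))
  ord <- order(ts)
  ts <- ts[ord]; num <- num[ord]
  offs <- as.numeric(difftime(ts, ts[1L], units = "secs"))
  if (any(abs(offs %% 60) > 1e-6)) {
    bi_stop("binimpute_alignment_error",
            "records are not on a 1-min grid")
  }
  if (anyDuplicated(offs)) {
    bi_stop("binimpute_duplicate_error", "duplicate Date/Time record")
  }
  n <- as.integer(round(offs[length(offs)] / 60)) + 1L
  values <- rep(NA_real_, n)
  values[as.integer(round(offs / 60)) + 1L] <- num
  regular_series(ts[1L], 60, values, label = channel)
}

#' Resample a series to a coarser uniform grid
#'
#' Aggregates each half-open target interval `[t, t + target_step)` with the
#' chosen reduction over its non-missing source samples (e.g. 5-second heart
#' rate to 1-minute means).  A target slot with no non-missing source sample
#' is missing.
#'
#' @param series a [regular_series()].
#' @param target_step new interval in seconds; integer multiple of
#'   `series$step`.
#' @param fun reduction over non-missing samples: `"mean"` (default) or
#'   `"median"`.
#' @return A [regular_series()] at `target_step`.
#' @export
resample_to_step <- function(series, target_step,
                             fun = c("mean", "median")) {
  stopifnot(inherits(series, "regular_series"))
  fun <- match.arg(fun)
  ratio <- target_step / series$step
  if (abs(ratio - round(ratio)) > 1e-9 || ratio < 1) {
    bi_stop("binimpute_resample_error",
            "target step %gs is not an integer multiple of source step %gs",
            target_step, series$step)
  }
  ratio <- as.integer(round(ratio))
  if (ratio == 1L) return(series)
  grp <- (seq_along(series$values) - 1L) %/% ratio
  red <- if (fun == "mean") {
    function(v) mean(v, na.rm = TRUE)
  } else {
    function(v) stats::median(v, na.rm = TRUE)
  }
  agg <- vapply(split(series$values, grp), red, numeric(1L))
  agg[is.nan(agg)] <- NA_real_
  regular_series(series$start, target_step, as.numeric(agg),
                 label = series$label)
}

#' Write a series as a timestamped-value CSV
#'
#' Inverse of [load_value_csv()]: ISO-8601 timestamps, one row per grid slot,
#' missing slots written with an empty value cell so the round trip
#' reproduces grid, values and mask exactly.
#'
#' @param series a [regular_series()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_value_csv <- function(series, path) {
  stopifnot(inherits(series, "regular_series"))
  ts <- format(series_times(series), "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  val <- ifelse(series$missing_mask, "",
                formatC(series$values, digits = 15, format = "g"))
  ok <- tryCatch({
    utils::write.csv(data.frame(timestamp = ts, value = val),
                     path, row.names = FALSE, quote = FALSE)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) bi_stop("binimpute_io_error", "cannot write to %s", path)
  invisible(path)
}
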