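#' Root-mean-square error
#'
#' `sqrt(mean((actual - imputed)^2))` over two equal-length finite vectors.
#'
#' @param actual,imputed numeric vectors of equal nonzero length.
#' @return Non-negative scalar; zero iff the vectors are identical.
#' @export
rmse <- function(actual, imputed) {
  if (length(actual) != length(imputed) || length(actual) == 0L) {
    bi_stop("binimpute_contract_error",
            "rmse needs equal nonzero lengths (got %d and %d)",
            length(actual), length(imputed))
  }
  if (!all(is.finite(actual)) || !all(is.finite(imputed))) {
    bi_stop("binimpute_contract_error", "rmse inputs must be finite")
  }
  sqrt(mean((actual - imputed)^2))
}

#' Score one day's gap imputation from a bin window
#'
#' Deletes the gap from its target day (all other days stay fully observed),
#' cuts the bin window of the requested width, runs the imputer on the
#' windowed matrix, and scores the imputed gap cells against the deleted
#' truth with [rmse()].  The input grid is not modified.
#'
#' @param grid a `daygrid` in which the gap cells are observed.
#' @param gap a [gap_spec()] naming the target day.
#' @param algorithm imputer short name (see [impute_by_name()]).
#' @param bin_minutes window width in minutes; 1440 is the whole-day
#'   (no-binning) baseline.
#' @param params named list of imputer arguments.
#' @return One-row data frame: `day`, `algorithm`, `bin_size_minutes`,
#'   `gap_start`, `gap_span_minutes`, `rmse`.
#' @export
evaluate_day <- function(grid, gap, algorithm, bin_minutes,
                         params = list()) {
  masked <- mask_gap(grid, gap)
  window <- make_bin_window(masked$grid, gap, bin_minutes)
  sub <- extract_bin_matrix(masked$grid, window)
  res <- impute_by_name(sub, algorithm, params)
  local_cols <- gap_slots(grid, gap) - window$first_slot + 1L
  imputed <- res$filled[gap$target_day, local_cols]
  data.frame(day = grid$day_labels[gap$target_day],
             algorithm = as.character(algorithm),
             bin_size_minutes = bin_minutes,
             gap_start = seconds_to_clock(gap$start_sec),
             gap_span_minutes = gap$span_sec / 60,
             rmse = rmse(masked$truth, imputed))
}

#' Sweep bin sizes and algorithms over every day
#'
#' Places the same clock-anchored gap on each day in turn (one day masked at
#' a time), evaluates every `(day, algorithm, bin size)` combination with
#' [evaluate_day()], and appends the whole-day baseline records
#' (`baseline_bin` minutes, default 1440).
#'
#' @param grid a fully observed `daygrid`.
#' @param gap_start gap clock time (`"HH:MM"`).
#' @param span_minutes gap length in minutes.
#' @param algorithms character vector of imputer names.
#' @param bin_minutes bin widths in minutes; default
#'   [standard_bin_sizes()] for the span.
#' @param params named list of imputer arguments shared by all runs.
#' @param baseline_bin baseline width in minutes (default 1440 = 24 h).
#' @return A `sweep_result`: list with `records` (tidy data frame) and
#'   `baseline_bin`.
#' @export
sweep_bins <- function(grid, gap_start, span_minutes, algorithms = "em",
                       bin_minutes = standard_bin_sizes(span_minutes),
                       params = list(), baseline_bin = 1440) {
  stopifnot(inherits(grid, "daygrid"))
  sizes <- sort(unique(c(bin_minutes, baseline_bin)))
  recs <- vector("list", nrow(grid$values) * length(algorithms) *
                   length(sizes))
  i <- 0L
  for (d in seq_len(nrow(grid$values))) {
    gap <- gap_spec(gap_start, span_minutes, target_day = d)
    for (alg in algorithms) {
      for (b in sizes) {
        i <- i + 1L
        recs[[i]] <- evaluate_day(grid, gap, alg, b, params)
      }
    }
  }
  structure(list(records = do.call(rbind, recs),
                 baseline_bin = baseline_bin),
            class = "sweep_result")
}

#' @export
print.sweep_result <- function(x, ...) {
  cat(sprintf("<sweep_result> %d records: %d days x {%s} x %d bin sizes\n",
              nrow(x$records), length(unique(x$records$day)),
              paste(unique(x$records$algorithm), collapse = ", "),
              length(unique(x$records$bin_size_minutes))))
  invisible(x)
}

sweep_pair <- function(result, algorithm, bin_minutes) {
  r <- result$records
  binned <- r[r$algorithm == algorithm & r$bin_size_minutes == bin_minutes, ]
  base <- r[r$algorithm == algorithm &
              r$bin_size_minutes == result$baseline_bin, ]
  days <- sort(unique(r$day))
  if (!all(days %in% binned$day) || !all(days %in% base$day)) {
    bi_stop("binimpute_contract_error",
            "missing binned or baseline records for algorithm '%s', bin %g",
            algorithm, bin_minutes)
  }
  list(days = days,
       binned = binned$rmse[match(days, binned$day)],
       baseline = base$rmse[match(days, base$day)])
}

#' Count days on which a bin beats the whole-day baseline
#'
#' Number of days whose binned RMSE is *strictly* below the baseline RMSE
#' for the given algorithm; ties do not count as improved.
#'
#' @param result a [sweep_bins()] result.
#' @param algorithm imputer name.
#' @param bin_minutes bin width in minutes.
#' @return Integer count in `[0, n_days]`.
#' @export
days_improved <- function(result, algorithm, bin_minutes) {
  p <- sweep_pair(result, algorithm, bin_minutes)
  sum(p$binned < p$baseline)
}

#' Days-improved summary over every algorithm and bin size
#'
#' @param result a [sweep_bins()] result.
#' @return Data frame: `algorithm`, `bin_size_minutes`, `days_improved`,
#'   `n_days` (baseline rows are omitted).
#' @export
days_improved_table <- function(result) {
  r <- result$records
  combos <- unique(r[r$bin_size_minutes != result$baseline_bin,
                     c("algorithm", "bin_size_minutes")])
  combos <- combos[order(combos$algorithm, combos$bin_size_minutes), ]
  n_days <- length(unique(r$day))
  combos$days_improved <- vapply(seq_len(nrow(combos)), function(i) {
    days_improved(result, combos$algorithm[i], combos$bin_size_minutes[i])
  }, numeric(1L))
  combos$n_days <- n_days
  rownames(combos) <- NULL
  combos[, c("algorithm", "bin_size_minutes", "days_improved", "n_days")]
}

#' Within-window data fluctuation of one day
#'
#' Sample standard deviation (denominator `n - 1`) of the day's observed
#' values inside the bin window — the dispersion measure used to explain
#' when cross-day binned imputation helps.
#'
#' @param grid a `daygrid`.
#' @param window a [make_bin_window()] result.
#' @param day row index.
#' @param type `"sd"` (default) or `"cv"` (coefficient of variation).
#' @return Non-negative scalar.
#' @export
fluctuation <- function(grid, window, day, type = c("sd", "cv")) {
  type <- match.arg(type)
  cols <- seq.int(window$first_slot, window$last_slot)
  v <- grid$values[day, cols]
  v <- v[!grid$missing_mask[day, cols]]
  if (length(v) < 2L) {
    bi_stop("binimpute_contract_error",
            "fluctuation needs >= 2 observed cells (day %d has %d)",
            day, length(v))
  }
  s <- stats::sd(v)
  if (type == "cv") s / mean(v) else s
}

#' Split per-day fluctuation by improvement status
#'
#' Partitions the sweep's days into those where the given `(algorithm, bin)`
#' strictly beat the baseline and those where it did not, and returns each
#' group's per-day within-window fluctuation (box-plot-ready) with group
#' medians.  An empty group yields an empty sample, not an error.
#'
#' @param result a [sweep_bins()] result.
#' @param grid the original (unmasked) `daygrid` the sweep ran on.
#' @param gap_template a [gap_spec()] giving the gap clock time and span
#'   (its target day is ignored).
#' @param algorithm imputer name.
#' @param bin_minutes bin width whose window defines the fluctuation region.
#' @return List: `improved`, `not_improved` (named numeric vectors of
#'   per-day fluctuation), `medians` (length-2 named vector).
#' @export
fluctuation_split <- function(result, grid, gap_template, algorithm,
                              bin_minutes) {
  p <- sweep_pair(result, algorithm, bin_minutes)
  window <- make_bin_window(grid, gap_template, bin_minutes)
  fl <- vapply(seq_along(p$days), function(i) {
    d <- which(grid$day_labels == p$days[i])[1L]
    fluctuation(grid, window, d)
  }, numeric(1L))
  names(fl) <- as.character(p$days)
  improved <- p$binned < p$baseline
  list(improved = fl[improved],
       not_improved = fl[!improved],
       medians = c(improved = stats::median(fl[improved]),
                   not_improved = stats::median(fl[!improved])))
}

#' Write / read the tidy sweep records CSV
#'
#' Schema: `day,algorithm,bin_size_minutes,gap_start,gap_span_minutes,rmse`;
#' the baseline bin is stored in a header comment so the round trip restores
#' the full `sweep_result`.
#'
#' @param result a [sweep_bins()] result.
#' @param path output CSV path.
#' @return `path` invisibly (writer); a `sweep_result` (reader).
#' @export
write_sweep_csv <- function(result, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# baseline_bin=%g", result$baseline_bin), con)
  utils::write.csv(result$records, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_sweep_csv
#' @export
read_sweep_csv <- function(path) {
  first <- readLines(path, n = 1L)
  baseline <- if (grepl("^# baseline_bin=", first)) {
    as.numeric(sub("^# baseline_bin=", "", first))
  } else 1440
  records <- utils::read.csv(path, comment.char = "#",
                             stringsAsFactors = FALSE)
  records$day <- as.Date(records$day)
  structure(list(records = records, baseline_bin = baseline),
            class = "sweep_result")
}
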