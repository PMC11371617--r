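#' Configuration for the synthetic diurnal generator
#'
#' The generator emulates the statistical shape the binned-imputation method
#' assumes: a smooth diurnal mean profile shared by all days, a day-level
#' random offset, optional activity "bursts" confined to an active clock
#' window (3-4 p.m. by default), optional slow within-day drift uncorrelated
#' across days, and white observation noise.  Defaults mirror a 30-day,
#' 1-minute-resolution wearable heart-rate setting with a quiet inactive
#' period at 3-4 a.m. (no bursts there by construction).
#'
#' @param n_days number of generated days (>= 2; default 30).
#' @param step sampling interval in seconds (default 60; must divide 24 h).
#' @param baseline mean level, e.g. resting-ish heart rate in bpm
#'   (default 65).
#' @param circadian_amplitude cosine amplitude of the diurnal profile
#'   (default 10 bpm).
#' @param circadian_phase clock time of the diurnal peak (default
#'   `"16:00"`).
#' @param day_offset_sd SD of the per-day level offset `a_d` (default 3).
#' @param noise_sd SD of the white noise (default 2).
#' @param active_window clock interval holding activity bursts (default
#'   `c("15:00", "16:00")`).
#' @param active_burst_rate burst events per hour inside the active window
#'   (default 10).
#' @param active_burst_amplitude peak excursion per burst (default 15 bpm).
#' @param active_burst_halflife burst decay half-life in minutes
#'   (default 5).
#' @param drift_sd stationary SD of a slow within-day drift, modelled as a
#'   mean-reverting Ornstein-Uhlenbeck (AR(1)) process independent across
#'   days (default 0 = off).  Turning it on makes whole-day windows
#'   misleading — the drift is full rank across days, so a wide-window
#'   covariance cannot learn it from a handful of days — while narrow
#'   windows, inside which the drift is nearly constant, stay informative.
#' @param drift_tau drift correlation time in minutes (default 120).
#' @param seed integer master seed; each day uses its own stream derived
#'   from `(seed, day)` so adding days never perturbs earlier ones.
#' @return A `synthetic_config` list (clock fields converted to seconds).
#' @export
synthetic_config <- function(n_days = 30L, step = 60, baseline = 65,
                             circadian_amplitude = 10,
                             circadian_phase = "16:00",
                             day_offset_sd = 3, noise_sd = 2,
                             active_window = c("15:00", "16:00"),
                             active_burst_rate = 10,
                             active_burst_amplitude = 15,
                             active_burst_halflife = 5,
                             drift_sd = 0, drift_tau = 120, seed = 1L) {
  stopifnot(n_days >= 2L, 86400 %% step == 0,
            day_offset_sd >= 0, noise_sd >= 0, active_burst_rate >= 0,
            active_burst_amplitude >= 0, active_burst_halflife > 0,
            drift_sd >= 0, drift_tau > 0, circadian_amplitude >= 0)
  structure(list(
    n_days = as.integer(n_days), step = step, baseline = baseline,
    circadian_amplitude = circadian_amplitude,
    phase_sec = clock_to_seconds(circadian_phase),
    day_offset_sd = day_offset_sd, noise_sd = noise_sd,
    active_start = clock_to_seconds(active_window[1L]),
    active_end = clock_to_seconds(active_window[2L]),
    active_burst_rate = active_burst_rate,
    active_burst_amplitude = active_burst_amplitude,
    active_burst_halflife = active_burst_halflife,
    drift_sd = drift_sd, drift_tau = drift_tau, seed = as.integer(seed)),
    class = "synthetic_config")
}

#' Deterministic diurnal mean profile
#'
#' `m(t) = baseline + amplitude * cos(2 * pi * (t - phase) / 24 h)`: the
#' profile peaks at `circadian_phase` and troughs 12 h away.
#'
#' @param config a [synthetic_config()].
#' @param t_sec clock time(s) in seconds since midnight.
#' @return Numeric vector of mean levels.
#' @export
diurnal_mean <- function(config, t_sec) {
  config$baseline + config$circadian_amplitude *
    cos(2 * pi * (t_sec - config$phase_sec) / 86400)
}

day_stream_seed <- function(seed, d) {
  as.integer((as.double(seed) * 10007 + as.double(d) * 9973) %% 2147483647)
}

# one day's burst component: homogeneous Poisson events inside the active
# window, each decaying as amplitude * 2^(-minutes since event / halflife)
burst_component <- function(config, slot_sec) {
  hours <- (config$active_end - config$active_start) / 3600
  n_ev <- stats::rpois(1L, config$active_burst_rate * hours)
  events <- sort(stats::runif(n_ev, config$active_start, config$active_end))
  b <- numeric(length(slot_sec))
  for (s in events) {
    dt_min <- (slot_sec - s) / 60
    on <- dt_min >= 0
    b[on] <- b[on] + config$active_burst_amplitude *
      2^(-dt_min[on] / config$active_burst_halflife)
  }
  list(values = b, events = events)
}

generate_structured <- function(config, profile, truncate_at_zero) {
  Tn <- as.integer(86400 / config$step)
  slot_sec <- (seq_len(Tn) - 1L) * config$step
  m <- profile(slot_sec)
  vals <- matrix(NA_real_, config$n_days, Tn)
  offsets <- numeric(config$n_days)
  bursts <- vector("list", config$n_days)
  drift_par <- vector("list", config$n_days)
  for (d in seq_len(config$n_days)) {
    row <- with_local_seed(day_stream_seed(config$seed, d), {
      a_d <- stats::rnorm(1L, 0, config$day_offset_sd)
      bc <- burst_component(config, slot_sec)
      drift <- numeric(Tn)
      dp <- NULL
      if (config$drift_sd > 0) {
        # stationary AR(1): z_1 ~ N(0,1), z_t = rho z_{t-1} + sqrt(1-rho^2) e
        rho <- exp(-config$step / (config$drift_tau * 60))
        z <- as.numeric(stats::filter(
          c(stats::rnorm(1L), sqrt(1 - rho^2) * stats::rnorm(Tn - 1L)),
          rho, method = "recursive"))
        drift <- config$drift_sd * z
        dp <- c(rho = rho)
      }
      eps <- stats::rnorm(Tn, 0, config$noise_sd)
      list(x = m + a_d + bc$values + drift + eps, a_d = a_d,
           events = bc$events, dp = dp)
    })
    x <- row$x
    if (truncate_at_zero) x <- pmax(x, 0)
    vals[d, ] <- x
    offsets[d] <- row$a_d
    bursts[[d]] <- row$events
    drift_par[[d]] <- row$dp
  }
  grid <- new_daygrid(as.Date("2023-01-01") + seq_len(config$n_days) - 1L,
                      slot_sec, config$step, vals,
                      matrix(FALSE, config$n_days, Tn))
  truth <- list(profile = m, day_offsets = offsets, burst_times = bursts,
                drift = drift_par, config = config)
  list(grid = grid, truth = truth)
}

#' Generate a heart-rate-like day grid
#'
#' `x[d, t] = m(t) + a_d + b_d(t) + drift_d(t) + eps[d, t]` with the cosine
#' diurnal profile of [diurnal_mean()].  Fully seed-deterministic; no
#' missing cells.
#'
#' @param config a [synthetic_config()].
#' @return List with `grid` (a `daygrid`) and `truth` (profile, per-day
#'   offsets, burst event times, drift parameters) for parameter-recovery
#'   checks.
#' @export
generate_heart_like <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  generate_structured(config, function(t) diurnal_mean(config, t),
                      truncate_at_zero = FALSE)
}

#' Generate a household-power-like day grid
#'
#' Same structural model as [generate_heart_like()] but with a two-level
#' step profile for the daily mean — a low overnight plateau and a higher
#' daytime plateau between `day_start` and `day_end` — bursts standing in
#' for appliance events, and values truncated at 0 from below.
#'
#' @param config a [synthetic_config()]; see [power_config()] for defaults
#'   on a kW-like scale.
#' @param low,high plateau levels (kW-like; defaults 0.3 and 1.5).
#' @param day_start,day_end clock limits of the daytime plateau (defaults
#'   `"07:00"`, `"23:00"`).
#' @return As [generate_heart_like()].
#' @export
generate_power_like <- function(config = power_config(), low = 0.3,
                                high = 1.5, day_start = "07:00",
                                day_end = "23:00") {
  stopifnot(inherits(config, "synthetic_config"))
  s0 <- clock_to_seconds(day_start)
  s1 <- clock_to_seconds(day_end)
  profile <- function(t) ifelse(t >= s0 & t < s1, high, low)
  generate_structured(config, profile, truncate_at_zero = TRUE)
}

#' Default generator settings on a power-consumption-like scale
#'
#' @param ... overrides passed to [synthetic_config()].
#' @return A `synthetic_config`.
#' @export
power_config <- function(...) {
  defaults <- list(n_days = 30L, step = 60, baseline = 0,
                   circadian_amplitude = 0, day_offset_sd = 0.05,
                   noise_sd = 0.08, active_window = c("15:00", "16:00"),
                   active_burst_rate = 4, active_burst_amplitude = 1,
                   active_burst_halflife = 10, drift_sd = 0, seed = 1L)
  over <- list(...)
  defaults[names(over)] <- over
  do.call(synthetic_config, defaults)
}

#' Flatten a generated day grid into a regular series
#'
#' Concatenates the grid's rows into one [regular_series()] so the
#' file-based pipeline (CSV in, CSV out) can be exercised end to end.
#'
#' @param grid a `daygrid` with consecutive day labels.
#' @param label channel label.
#' @return A [regular_series()].
#' @export
daygrid_to_series <- function(grid, label = "synthetic") {
  stopifnot(inherits(grid, "daygrid"))
  start <- as.POSIXct(paste(grid$day_labels[1L], "00:00:00"), tz = "UTC")
  span <- as.integer(grid$day_labels[length(grid$day_labels)] -
                       grid$day_labels[1L]) + 1L
  Tn <- ncol(grid$values)
  vals <- rep(NA_real_, span * Tn)          # days absent from the grid stay
  mask <- rep(TRUE, span * Tn)              # missing in the flat series
  for (d in seq_len(nrow(grid$values))) {
    off <- as.integer(grid$day_labels[d] - grid$day_labels[1L]) * Tn
    vals[off + seq_len(Tn)] <- grid$values[d, ]
    mask[off + seq_len(Tn)] <- grid$missing_mask[d, ]
  }
  regular_series(start, grid$step, vals, mask, label = label)
}
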