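# Builders for small synthetic sessions used across test files.

# Minute grid starting at `start` (clock time on 2000-01-01) of length n.
grid_times <- function(start = "07:00", n = 120L, day = "2000-01-01") {
  as.POSIXct(paste(day, start), tz = "UTC") + 60 * (seq_len(n) - 1L)
}

make_session <- function(start = "07:00", n = 120L, ee = 1.2,
                         activity = 2000, meals = list(), condition = "") {
  calorimetry_session(grid_times(start, n),
                      rep_len(ee, n), rep_len(activity, n),
                      meals = meals, condition = condition)
}

# A 33-h chamber-style grid (22:00 to 07:00 two days later), matching the
# standard protocol span so all named periods resolve.
make_chamber_session <- function(ee, activity, meals = list(),
                                 condition = "three-meal") {
  n <- 1980L
  calorimetry_session(grid_times("22:00", n), rep_len(ee, n),
                      rep_len(activity, n), meals = meals,
                      condition = condition)
}

# Independent, deliberately naive windowed mean for oracle checks: average of
# activity[t+lag-hw .. t+lag+hw] clipped to the series, NA if empty.
naive_integrated <- function(activity, at, hw, lag) {
  n <- length(activity)
  vapply(at, function(t) {
    lo <- max(1L, t + lag - hw)
    hi <- min(n, t + lag + hw)
    if (t + lag + hw < 1L || t + lag - hw > n) return(NA_real_)
    mean(activity[lo:hi])
  }, numeric(1))
}

flat_params <- function(seed, noise_sd = 0, ...) {
  simulation_params(seed = seed, noise_sd = noise_sd, circadian_amplitude = 0,
                    sleep_dip_fraction = 0, ...)
}
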