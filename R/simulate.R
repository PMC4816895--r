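#' Parameters of the synthetic chamber simulator
#'
#' Defines the latent world a simulated 33-h chamber stay is drawn from:
#' a circadian basal curve with a multiplicative sleep dip, a gamma-shaped
#' postprandial TEF response per meal, NEAT driven by smoothed accelerometer
#' activity through a known integration kernel, and additive measurement
#' noise. Defaults emulate a sedentary chamber protocol (lights out
#' 23:00-07:00, meals 08:00/12:00/19:00): 24-h EE about 1850 kcal, 24-h mean
#' activity about 3500 counts/min, sleep activity near-constant around 2250
#' counts/min, and a NEAT share of waking EE near 10%.
#'
#' @param basal_kcal_min Waking basal EE level (kcal/min).
#' @param sleep_dip_fraction Multiplicative basal reduction during sleep.
#' @param circadian_amplitude Amplitude (kcal/min) of a 24-h cosine on basal,
#'   peaking late afternoon (16:00).
#' @param meals Data frame with columns `time` ("HH:MM"), `kcal`,
#'   `tef_fraction` (in `[0, 0.25]`), `response_shape`, `response_scale`
#'   (minutes), `label`.
#' @param neat_slope kcal/min of NEAT per count/min of integrated activity
#'   above its minimum.
#' @param neat_kernel_half_width,neat_kernel_lag The true integration kernel
#'   (minutes) through which activity drives NEAT.
#' @param activity_base Constant waking activity floor (counts/min).
#' @param sleep_activity Near-constant sleep activity level (counts/min);
#'   sleep activity carries no jitter (near-zero variance).
#' @param activity_jitter_sd SD (counts/min) of the small Gaussian jitter a
#'   seated subject shows on top of the waking floor — postural sway and
#'   fidgeting register even at "rest".
#' @param burst_rate Activity bursts per waking hour.
#' @param burst_magnitude Peak burst amplitude (counts/min), jittered
#'   uniformly by +/-30% per burst; bursts decay linearly over a 4-12 min
#'   compact support.
#' @param rest_window Optional `c(start, end)` clock times of a window in
#'   which bursts are suppressed, or `NULL` (default): chamber protocols ask
#'   subjects to sit before breakfast but seated subjects still fidget, and
#'   published baselines show pre-breakfast EE well above the NEAT-free
#'   level, so by default the pre-breakfast window gets ordinary waking
#'   activity.
#' @param noise_sd SD of additive Gaussian EE noise (kcal/min).
#' @param noise_ar1 AR(1) coefficient of the noise (0 = white, the default).
#' @param start,duration_min Session start clock time and length (default
#'   22:00, 1980 min = 33 h).
#' @param sleep_start,sleep_end Sleep period clock times.
#' @param seed Integer RNG seed; every random draw derives from it.
#' @return Object of class `simulation_params`.
#' @export
simulation_params <- function(basal_kcal_min = 1.14,
                              sleep_dip_fraction = 0.08,
                              circadian_amplitude = 0.05,
                              meals = data.frame(
                                time = c("08:00", "12:00", "19:00"),
                                kcal = c(689, 761, 741),
                                tef_fraction = c(0.060, 0.065, 0.070),
                                response_shape = 2,
                                response_scale = 60,
                                label = c("breakfast", "lunch", "dinner"),
                                stringsAsFactors = FALSE),
                              neat_slope = 8e-5,
                              neat_kernel_half_width = 7L,
                              neat_kernel_lag = 0L,
                              activity_base = 3100,
                              sleep_activity = 2250,
                              activity_jitter_sd = 30,
                              burst_rate = 6,
                              burst_magnitude = 2000,
                              rest_window = NULL,
                              noise_sd = 0.05,
                              noise_ar1 = 0,
                              start = "22:00",
                              duration_min = 1980L,
                              sleep_start = "23:00",
                              sleep_end = "07:00",
                              seed = 1L) {
  p <- structure(as.list(environment()), class = "simulation_params")
  validate_simulation_params(p)
  p
}

validate_simulation_params <- function(p) {
  rates <- c(p$basal_kcal_min, p$sleep_dip_fraction, p$circadian_amplitude,
             p$neat_slope, p$activity_base, p$sleep_activity,
             p$activity_jitter_sd, p$burst_rate,
             p$burst_magnitude, p$noise_sd, p$meals$kcal)
  if (any(!is.finite(rates)) || any(rates < 0))
    stop("all simulator rates and levels must be finite and >= 0",
         call. = FALSE)
  if (any(p$meals$tef_fraction < 0 | p$meals$tef_fraction > 0.25))
    stop("tef_fraction must lie in [0, 0.25]", call. = FALSE)
  if (p$neat_kernel_half_width < 0)
    stop("neat_kernel_half_width must be >= 0", call. = FALSE)
  if (p$duration_min < 60)
    stop("duration_min too short for a chamber stay", call. = FALSE)
  invisible(p)
}

# Discrete, truncated-and-renormalized gamma response: mass at minute
# offsets 0..359 after the meal. Truncation keeps the component's integral
# exactly tef_fraction * kcal inside the session.
tef_response_mass <- function(shape, scale, horizon = 360L) {
  tau <- seq_len(horizon)
  m <- stats::pgamma(tau, shape = shape, scale = scale) -
    stats::pgamma(tau - 1, shape = shape, scale = scale)
  m / sum(m)
}

#' Simulate a chamber session with known latent components
#'
#' Generates a minute-resolution session whose EE is built as
#' `basal + TEF + NEAT + noise`:
#' * basal: circadian cosine around `basal_kcal_min`, multiplied by
#'   `1 - sleep_dip_fraction` during sleep;
#' * TEF: per meal, `tef_fraction * kcal` spread over a gamma-shaped
#'   response (mass beyond 6 h truncated and renormalized);
#' * activity: an exactly constant waking base plus Poisson-timed bursts
#'   with compact (4-12 min, linear-decay) support, suppressed during sleep
#'   and during the pre-breakfast rest window; near-constant during sleep;
#'   rounded to whole counts;
#' * NEAT: `neat_slope` times the rise of kernel-integrated activity above
#'   its session minimum — the same linear model the NEAT-removal estimator
#'   assumes, with a known kernel;
#' * noise: Gaussian, optionally AR(1).
#'
#' EE is floored at 0.05 kcal/min; floor events are counted in the ground
#' truth (`n_floored`) and absorbed into its noise component so the four
#' ground-truth components always sum to the emitted EE bit-exactly.
#'
#' @param params A [simulation_params()].
#' @return List with `session` (a [calorimetry_session()]) and `truth`, a
#'   `ground_truth` list holding the `basal`, `tef`, `neat`, `noise` minute
#'   series, the per-meal TEF component matrix `tef_by_meal`, the true
#'   per-meal fractions, and the NEAT share of waking EE.
#' @export
simulate_session <- function(params = simulation_params()) {
  validate_simulation_params(params)
  set.seed(params$seed)
  n <- as.integer(params$duration_min)
  start_day <- as.POSIXct("2000-01-01", tz = "UTC")
  time <- start_day + parse_hm(params$start) * 60 + 60 * (seq_len(n) - 1L)
  mod <- minute_of_day(time)

  in_clock_window <- function(s_hm, e_hm) {
    if (s_hm < e_hm) mod >= s_hm & mod < e_hm else mod >= s_hm | mod < e_hm
  }
  asleep <- in_clock_window(parse_hm(params$sleep_start),
                            parse_hm(params$sleep_end))
  resting <- if (is.null(params$rest_window)) rep(FALSE, n) else
    in_clock_window(parse_hm(params$rest_window[1L]),
                    parse_hm(params$rest_window[2L]))

  # --- activity -------------------------------------------------------------
  activity <- ifelse(asleep, params$sleep_activity, params$activity_base)
  awake <- which(!asleep)
  if (params$activity_jitter_sd > 0)
    activity[awake] <- activity[awake] +
      stats::rnorm(length(awake), 0, params$activity_jitter_sd)
  burstable <- which(!asleep & !resting)
  n_bursts <- stats::rpois(1L, params$burst_rate * length(burstable) / 60)
  if (n_bursts > 0 && length(burstable) > 0) {
    starts <- sample(burstable, n_bursts, replace = TRUE)
    for (s in starts) {
      d <- sample(4:12, 1L)
      amp <- params$burst_magnitude * stats::runif(1L, 0.7, 1.3)
      span <- s:min(n, s + d - 1L)
      activity[span] <- activity[span] + amp * (1 - (seq_along(span) - 1L) / d)
    }
  }
  activity <- pmax(0, round(activity))

  # --- basal ----------------------------------------------------------------
  hours <- mod / 60
  basal <- params$basal_kcal_min +
    params$circadian_amplitude * cos(2 * pi * (hours - 16) / 24)
  basal[asleep] <- basal[asleep] * (1 - params$sleep_dip_fraction)

  # --- TEF ------------------------------------------------------------------
  nm <- nrow(params$meals)
  tef_by_meal <- matrix(0, n, nm,
                        dimnames = list(NULL, params$meals$label))
  meal_idx <- integer(nm)
  for (j in seq_len(nm)) {
    mi <- which(mod == parse_hm(params$meals$time[j]))[1L]
    if (is.na(mi)) stop("meal time ", params$meals$time[j],
                        " not on the session grid", call. = FALSE)
    meal_idx[j] <- mi
    mass <- tef_response_mass(params$meals$response_shape[j],
                              params$meals$response_scale[j])
    span <- mi:min(n, mi + length(mass) - 1L)
    tef_by_meal[span, j] <- params$meals$tef_fraction[j] *
      params$meals$kcal[j] * mass[seq_along(span)]
  }
  tef <- rowSums(tef_by_meal)

  # --- NEAT -----------------------------------------------------------------
  kernel <- integration_spec(params$neat_kernel_half_width,
                             params$neat_kernel_lag)
  a_int <- integrate_activity(activity, kernel)
  neat <- params$neat_slope * (a_int - min(a_int, na.rm = TRUE))
  neat[is.na(neat)] <- 0

  # --- noise and assembly ---------------------------------------------------
  eps <- stats::rnorm(n, 0, params$noise_sd)
  if (params$noise_ar1 != 0 && params$noise_sd > 0)
    eps <- as.numeric(stats::filter(eps, params$noise_ar1, method = "recursive"))
  comp_sum <- basal + tef + neat      # same association order as the
  ee_raw <- comp_sum + eps            # component-sum invariant checks
  floored <- ee_raw < 0.05
  ee <- pmax(ee_raw, 0.05)
  noise <- eps
  noise[floored] <- ee[floored] - comp_sum[floored]   # absorb floor events
  if (any(floored))
    message(sum(floored), " EE sample(s) floored at 0.05 kcal/min")

  meals <- lapply(seq_len(nm), function(j)
    meal_event(params$meals$time[j], params$meals$kcal[j],
               params$meals$label[j]))
  session <- calorimetry_session(time, ee, activity, meals = meals,
                                 condition = if (nm >= 3) "three-meal"
                                 else if (nm == 2) "two-meal" else "custom")
  waking <- !asleep
  truth <- structure(list(
    basal = basal, tef = tef, neat = neat, noise = noise,
    tef_by_meal = tef_by_meal, meal_idx = meal_idx,
    true_tef_fraction = stats::setNames(params$meals$tef_fraction,
                                        params$meals$label),
    neat_waking_share = sum(neat[waking]) / sum(ee[waking]),
    n_floored = sum(floored), kernel = kernel,
    params = params), class = "ground_truth")
  list(session = session, truth = truth)
}

#' Simulate a clock-paired fed/fasted session pair
#'
#' The fasted (no-breakfast) session shares every random draw — basal,
#' activity, NEAT and noise — with the fed one; its EE simply lacks the
#' breakfast TEF component, and its meal list drops breakfast. This is the
#' idealized paired design behind the delta-EE reference method.
#'
#' @param params A [simulation_params()] whose first meal is the breakfast
#'   to withhold.
#' @return List with `fed`, `fasted` (sessions) and `truth` (of the fed
#'   session).
#' @export
simulate_pair <- function(params = simulation_params()) {
  sim <- simulate_session(params)
  tr <- sim$truth
  ee_fasted <- pmax(sim$session$ee - tr$tef_by_meal[, 1L], 0.05)
  fasted <- calorimetry_session(sim$session$time, ee_fasted,
                                sim$session$activity,
                                meals = sim$session$meals[-1L],
                                condition = "two-meal")
  list(fed = sim$session, fasted = fasted, truth = tr)
}

#' Estimator recovery experiment on simulated sessions
#'
#' Runs the simulator across seeds, applies the requested morning-TEF
#' estimators to each (paired) session, and reports per-seed estimates and
#' errors against the ground-truth TEF energy accumulated *inside the
#' analysis window* (as a % of breakfast energy). Windowed truth is the
#' right recovery oracle here: the estimators measure the postprandial rise
#' within the window, and the simulated response deliberately carries mass
#' beyond it.
#'
#' @param params Base [simulation_params()]; seed `i` of `n_seeds` runs with
#'   `seed = params$seed + i - 1`.
#' @param n_seeds Number of simulated subjects.
#' @param estimators Subset of
#'   `c("delta_ee", "schutz_rmr", "schutz_smr", "neat_free")`.
#' @param p Analysis [period()] (default morning 08:00-12:00).
#' @param config Config list (grids, pre-breakfast window).
#' @return List with `runs` (long data frame: seed, estimator, estimate,
#'   truth, error — all in TEF percentage points) and `summary` (per
#'   estimator: bias, RMSE, SD of error).
#' @export
recovery_experiment <- function(params = simulation_params(), n_seeds = 20L,
                                estimators = c("delta_ee", "schutz_rmr",
                                               "schutz_smr", "neat_free"),
                                p = period("08:00", "12:00", "morning"),
                                config = default_config()) {
  estimators <- match.arg(estimators, several.ok = TRUE)
  rows <- list()
  for (i in seq_len(n_seeds)) {
    params_i <- params
    params_i$seed <- params$seed + (i - 1L)
    pair <- simulate_pair(params_i)
    fed <- pair$fed
    intake <- fed$meals[[1L]]$energy_kcal
    idx <- period_indices(fed, p)
    truth_pct <- 100 * sum(pair$truth$tef_by_meal[idx, 1L]) / intake
    est_one <- function(est) switch(
      est,
      delta_ee   = tef_delta_ee(fed, pair$fasted, p, intake)$tef_percent,
      schutz_rmr = suppressWarnings(
        tef_schutz(fed, p, baseline_rmr(fed), intake, "rmr"))$tef_percent,
      schutz_smr = suppressWarnings(
        tef_schutz(fed, p, baseline_smr(fed), intake, "smr"))$tef_percent,
      neat_free  = suppressWarnings(
        tef_original(fed, p, intake, config))$tef_percent)
    for (est in estimators)
      rows[[length(rows) + 1L]] <- data.frame(
        seed = params_i$seed, estimator = est,
        estimate = est_one(est), truth = truth_pct,
        stringsAsFactors = FALSE)
  }
  runs <- do.call(rbind, rows)
  runs$error <- runs$estimate - runs$truth
  summary <- do.call(rbind, lapply(split(runs, runs$estimator), function(d)
    data.frame(estimator = d$estimator[1L], n = nrow(d),
               bias = mean(d$error), rmse = sqrt(mean(d$error^2)),
               sd_error = stats::sd(d$error), stringsAsFactors = FALSE)))
  rownames(summary) <- NULL
  list(runs = runs, summary = summary)
}
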