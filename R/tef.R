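#' A single TEF estimate
#'
#' @param method One of `"delta_ee"`, `"schutz_rmr"`, `"schutz_smr"`,
#'   `"neat_free"`.
#' @param period The [period()] over which TEF was accumulated.
#' @param tef_kcal Accumulated TEF, kcal.
#' @param intake_kcal Energy intake used as the denominator, kcal.
#' @param baseline_kcal_min The subtracted baseline, kcal/min.
#' @param ee0_kcal_min Regression intercept (intercept methods only).
#' @param degenerate Propagated degenerate-fit flag.
#' @param meal Meal label for per-meal estimates.
#' @return Object of class `tef_result`; `tef_percent` is
#'   `100 * tef_kcal / intake_kcal`.
#' @export
tef_result <- function(method, period, tef_kcal, intake_kcal,
                       baseline_kcal_min, ee0_kcal_min = NA_real_,
                       degenerate = FALSE, meal = NA_character_) {
  if (!is.finite(intake_kcal) || intake_kcal <= 0)
    stop("intake_kcal must be positive", call. = FALSE)
  structure(list(method = method, period = period,
                 tef_kcal = tef_kcal,
                 tef_percent = 100 * tef_kcal / intake_kcal,
                 intake_kcal = intake_kcal,
                 baseline_kcal_min = baseline_kcal_min,
                 ee0_kcal_min = ee0_kcal_min,
                 degenerate = degenerate, meal = meal),
            class = "tef_result")
}

#' @export
print.tef_result <- function(x, ...) {
  cat(sprintf("<tef_result %s%s [%s]: %.1f kcal = %.1f%% of %.0f kcal%s>\n",
              x$method, if (!is.na(x$meal)) paste0(":", x$meal) else "",
              x$period$name, x$tef_kcal, x$tef_percent, x$intake_kcal,
              if (x$degenerate) ", DEGENERATE" else ""))
  invisible(x)
}

#' @export
as.data.frame.tef_result <- function(x, ...) {
  data.frame(method = x$method, meal = x$meal, period = x$period$name,
             tef_kcal = x$tef_kcal, tef_percent = x$tef_percent,
             intake_kcal = x$intake_kcal,
             baseline_kcal_min = x$baseline_kcal_min,
             ee0_kcal_min = x$ee0_kcal_min, degenerate = x$degenerate,
             stringsAsFactors = FALSE)
}

#' Resting metabolic rate: mean pre-breakfast EE
#'
#' The RMR baseline is the average energy expenditure over the seated
#' pre-breakfast rest window (07:15-07:45 by default). Note that it includes
#' whatever NEAT occurs in that window.
#'
#' @param session A [calorimetry_session()].
#' @param p The pre-breakfast [period()].
#' @return kcal/min.
#' @export
baseline_rmr <- function(session, p = period("07:15", "07:45", "pre_breakfast")) {
  mean(slice_session(session, p)$ee)
}

#' Sleeping metabolic rate: mean EE over the sleep period
#'
#' @param session A [calorimetry_session()].
#' @param p The sleep [period()] (23:00-07:00 by default, spanning midnight;
#'   exactly 480 samples).
#' @return kcal/min.
#' @export
baseline_smr <- function(session, p = period("23:00", "07:00", "sleep")) {
  mean(slice_session(session, p)$ee)
}

#' Preprandial NEAT-free baseline
#'
#' Mean of the NEAT-free EE series over the pre-breakfast window, using a
#' NEAT model fitted on that window itself. This is the baseline of the
#' NEAT-removal TEF method; it is never above [baseline_rmr()] because the
#' subtracted NEAT is non-negative.
#'
#' @param ee_free NEAT-free EE values over the pre-breakfast window (the
#'   period slice of [ee_free_series()]).
#' @return kcal/min.
#' @export
baseline_preprandial_free <- function(ee_free) mean(ee_free)

#' TEF as the fed-minus-fasted EE difference (delta-EE)
#'
#' The reference ("gold standard") estimate: the difference in energy
#' expenditure between a fed and a time-matched fasted session, accumulated
#' over the analysis period (a left Riemann sum at 1-min resolution).
#'
#' @param fed,fasted [calorimetry_session()]s covering `p` on clock-aligned
#'   grids.
#' @param p Analysis [period()] (morning 08:00-12:00 in the standard design).
#' @param intake_kcal Energy content of the meal(s) whose TEF is measured.
#' @return A [tef_result()].
#' @export
tef_delta_ee <- function(fed, fasted, p, intake_kcal) {
  a <- slice_session(fed, p)
  b <- slice_session(fasted, p)
  if (length(a$ee) != length(b$ee) ||
      any(minute_of_day(a$time) != minute_of_day(b$time)))
    stop("fed and fasted sessions are not clock-aligned over period '",
         p$name, "'", call. = FALSE)
  tef_result("delta_ee", p, sum(a$ee - b$ee), intake_kcal,
             baseline_kcal_min = mean(b$ee))
}

#' Regression intercept of EE on instantaneous activity (EE0)
#'
#' OLS intercept of minute EE on raw (non-integrated) activity counts over a
#' period: the energy expenditure extrapolated to zero activity.
#'
#' @inheritParams tef_delta_ee
#' @param session A [calorimetry_session()].
#' @return Intercept, kcal/min.
#' @export
ee0_intercept <- function(session, p) {
  s <- slice_session(session, p)
  if (stats::sd(s$activity) == 0)
    stop("zero activity variance over period '", p$name,
         "'; EE0 intercept undefined", call. = FALSE)
  slope <- stats::cov(s$activity, s$ee) / stats::var(s$activity)
  mean(s$ee) - slope * mean(s$activity)
}

#' TEF from an intercept and a baseline
#'
#' The elementary intercept-method arithmetic:
#' `tef_kcal = (ee0 - baseline) * duration_min`, and
#' `tef_percent = 100 * tef_kcal / intake_kcal`. Exposed separately so
#' published worked examples (printed EE0, RMR/SMR, window length) can be
#' reproduced without the underlying minute data.
#'
#' @param ee0_kcal_min Regression intercept, kcal/min.
#' @param baseline_kcal_min RMR or SMR baseline, kcal/min.
#' @param duration_min Accumulation window length, minutes.
#' @param intake_kcal Intake denominator, kcal.
#' @return List with `tef_kcal` and `tef_percent`.
#' @examples
#' tef_from_components(1.461, 1.195, 900, 2668) # 239.4 kcal
#' @export
tef_from_components <- function(ee0_kcal_min, baseline_kcal_min, duration_min,
                                intake_kcal) {
  tef_kcal <- (ee0_kcal_min - baseline_kcal_min) * duration_min
  list(tef_kcal = tef_kcal, tef_percent = 100 * tef_kcal / intake_kcal)
}

#' TEF by the activity-regression intercept method
#'
#' Estimates TEF as the rise of the zero-activity intercept EE0 (over the
#' postprandial period) above a resting or sleeping baseline:
#' `(EE0 - baseline) * duration`. Negative estimates are returned as-is with
#' a warning — they are a documented failure mode of this method, not an
#' error.
#'
#' @inheritParams tef_delta_ee
#' @param session The fed [calorimetry_session()].
#' @param baseline_kcal_min Baseline from [baseline_rmr()] or
#'   [baseline_smr()].
#' @param baseline One of `"rmr"`, `"smr"` — names the method variant in the
#'   result.
#' @return A [tef_result()] with `ee0_kcal_min` filled in.
#' @export
tef_schutz <- function(session, p, baseline_kcal_min, intake_kcal,
                       baseline = c("rmr", "smr")) {
  baseline <- match.arg(baseline)
  ee0 <- ee0_intercept(session, p)
  dur <- period_duration(session, p)
  tef_kcal <- (ee0 - baseline_kcal_min) * dur
  if (tef_kcal < 0)
    warning(sprintf("negative TEF estimate (%.1f kcal) from the %s-baseline ",
                    tef_kcal, toupper(baseline)),
            "intercept method", call. = FALSE)
  tef_result(paste0("schutz_", baseline), p, tef_kcal, intake_kcal,
             baseline_kcal_min = baseline_kcal_min, ee0_kcal_min = ee0)
}

#' TEF by NEAT removal (lag-optimized integrated activity)
#'
#' The four-step NEAT-removal pipeline:
#' 1. On the pre-breakfast window and on the postprandial analysis period
#'    *separately*, grid-search the integration window/lag maximizing the
#'    Pearson correlation of EE with integrated activity, and fit the linear
#'    NEAT model there.
#' 2. Construct the NEAT series of each fit (activity-driven EE above the
#'    period's lowest integrated activity) and subtract it from EE.
#' 3. Take the preprandial baseline as the mean NEAT-free EE over the
#'    pre-breakfast window (its own fit).
#' 4. Accumulate `EE_free(t) - baseline` over the analysis period.
#'
#' Because the two windows are fitted separately there is a deliberate
#' discontinuity in the NEAT-free series at breakfast; no re-levelling is
#' applied. Constant activity over either window degrades gracefully: NEAT
#' is zero there (flagged `degenerate`) and the estimate reduces to the
#' plain postprandial area above the raw pre-breakfast mean.
#'
#' @inheritParams tef_delta_ee
#' @param session The fed [calorimetry_session()].
#' @param config A config list from [default_config()] / [load_config()];
#'   supplies the pre-breakfast window and the search grids.
#' @param details If `TRUE`, attach the two `neat_fit`s, the baseline and
#'   the NEAT-free period series as attribute `"details"`.
#' @return A [tef_result()].
#' @export
tef_original <- function(session, p, intake_kcal, config = default_config(),
                         details = FALSE) {
  g <- config_grids(config)
  pre_p <- config_period(config, "pre_breakfast")
  pre_idx <- period_indices(session, pre_p)
  post_idx <- period_indices(session, p)

  pre_fit <- fit_neat_safe(session$ee, session$activity, pre_idx,
                           g$w, g$lag, g$statistic)
  post_fit <- fit_neat_safe(session$ee, session$activity, post_idx,
                            g$w, g$lag, g$statistic)

  pre_neat <- suppressWarnings(neat_series(pre_fit, session$activity))
  post_neat <- suppressWarnings(neat_series(post_fit, session$activity))
  pre_free <- ee_free_series(session$ee, pre_neat)[pre_idx]
  post_free <- ee_free_series(session$ee, post_neat)[post_idx]
  baseline <- baseline_preprandial_free(pre_free)

  res <- tef_result("neat_free", p, sum(post_free - baseline), intake_kcal,
                    baseline_kcal_min = baseline,
                    degenerate = pre_fit$degenerate || post_fit$degenerate)
  if (details)
    attr(res, "details") <- list(pre_fit = pre_fit, post_fit = post_fit,
                                 baseline = baseline, ee_free = post_free,
                                 idx = post_idx)
  res
}

#' Per-meal TEF by NEAT removal
#'
#' Accumulates the NEAT-free EE above the preprandial baseline over
#' `[meal time, meal time + horizon)` for each meal, normalized by that
#' meal's energy content. By default the NEAT model fitted once on the full
#' waking period is reused for every meal window (`refit_per_meal = TRUE`
#' refits on each 4-h window instead), and the baseline is the pre-breakfast
#' NEAT-free mean for all meals (`per_meal_baseline = TRUE` uses the mean of
#' the 30 min before each meal instead).
#'
#' @param session A [calorimetry_session()] with at least one meal.
#' @param config Config list; supplies grids, the pre-breakfast window and
#'   the waking period (chosen by the session's meal schedule: the waking
#'   window starts at the first meal).
#' @param horizon_min Accumulation horizon per meal, minutes (default 240).
#' @param refit_per_meal Refit the NEAT model on each meal window.
#' @param per_meal_baseline Use a 30-min preprandial window before each meal
#'   as that meal's baseline.
#' @return List of [tef_result()]s, one per meal.
#' @export
per_meal_tef <- function(session, config = default_config(),
                         horizon_min = 240L, refit_per_meal = FALSE,
                         per_meal_baseline = FALSE) {
  if (!length(session$meals)) stop("session has no meals", call. = FALSE)
  g <- config_grids(config)
  n <- length(session$time)

  pre_p <- config_period(config, "pre_breakfast")
  pre_idx <- period_indices(session, pre_p)
  pre_fit <- fit_neat_safe(session$ee, session$activity, pre_idx,
                           g$w, g$lag, g$statistic)
  pre_free <- ee_free_series(session$ee,
                             suppressWarnings(neat_series(pre_fit,
                                                          session$activity)))
  baseline_pre <- baseline_preprandial_free(pre_free[pre_idx])

  # waking fit spans first meal .. 23:00 (the standard waking window when
  # breakfast is present, 12:00-23:00 when it is not)
  first_meal <- session$meals[[which.min(vapply(session$meals, function(m)
    meal_index(session, m), integer(1)))]]
  waking_p <- period(first_meal$time, "23:00", "waking")
  waking_idx <- period_indices(session, waking_p)
  waking_fit <- fit_neat_safe(session$ee, session$activity, waking_idx,
                              g$w, g$lag, g$statistic)

  lapply(session$meals, function(m) {
    mi <- meal_index(session, m)
    if (mi + horizon_min - 1L > n)
      stop("horizon after meal '", m$label, "' extends past the session end",
           call. = FALSE)
    idx <- mi:(mi + horizon_min - 1L)
    fit <- if (refit_per_meal)
      fit_neat_safe(session$ee, session$activity, idx, g$w, g$lag, g$statistic)
    else waking_fit
    free <- ee_free_series(session$ee,
                           suppressWarnings(neat_series(fit, session$activity)))
    baseline <- if (per_meal_baseline) {
      bidx <- max(1L, mi - 30L):(mi - 1L)
      mean(free[bidx])
    } else baseline_pre
    tef_result("neat_free", period(m$time,
                                   format(session$time[min(idx[length(idx)] + 1L, n)], "%H:%M"),
                                   paste0(m$label, "+", horizon_min, "min")),
               sum(free[idx] - baseline), m$energy_kcal,
               baseline_kcal_min = baseline,
               degenerate = pre_fit$degenerate || fit$degenerate,
               meal = m$label)
  })
}
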