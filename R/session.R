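#' A meal event on the session's minute grid
#'
#' @param time Clock time `"HH:MM"` at which the meal starts.
#' @param energy_kcal Energy content of the meal in kcal; must be > 0
#'   (a 0-kcal "meal" has no TEF denominator).
#' @param label Free-text label, e.g. `"breakfast"`.
#' @return An object of class `meal_event`.
#' @export
meal_event <- function(time, energy_kcal, label = "") {
  parse_hm(time)
  if (!is.numeric(energy_kcal) || length(energy_kcal) != 1L ||
      !is.finite(energy_kcal) || energy_kcal <= 0)
    stop("meal energy_kcal must be a single positive number (got ",
         energy_kcal, ")", call. = FALSE)
  structure(list(time = time, energy_kcal = as.numeric(energy_kcal), label = label),
            class = "meal_event")
}

#' Construct a calorimetry chamber session
#'
#' A session is one continuous chamber stay: aligned minute series of energy
#' expenditure (kcal/min) and triaxial accelerometer activity (counts/min),
#' plus the meal schedule. The grid must be complete: consecutive timestamps
#' differ by exactly one minute, and no gaps or duplicates are permitted —
#' every downstream window assumes a complete minute grid.
#'
#' @param time `POSIXct` timestamps, strictly increasing on a 1-min grid.
#' @param ee Energy expenditure, kcal/min, non-negative, same length as `time`.
#' @param activity Accelerometer counts/min, non-negative, same length.
#' @param meals List of [meal_event()]s; each meal time must occur within the
#'   session span.
#' @param condition Free-text condition label, e.g. `"three-meal"`.
#' @return An object of class `calorimetry_session`.
#' @export
calorimetry_session <- function(time, ee, activity, meals = list(),
                                condition = "") {
  time <- as.POSIXct(time, tz = "UTC")
  n <- length(time)
  if (n < 2L) stop("session needs at least 2 samples", call. = FALSE)
  if (length(ee) != n || length(activity) != n)
    stop("timestamps, ee and activity must have equal length (",
         n, ", ", length(ee), ", ", length(activity), ")", call. = FALSE)
  dt <- diff(as.numeric(time))
  if (any(dt == 0))
    stop("duplicate timestamp at ", format(time[which(dt == 0)[1L] + 1L]),
         call. = FALSE)
  if (any(dt != 60))
    stop("gap at ", format(time[which(dt != 60)[1L]] + 60),
         ": timestamps must be on a complete 1-min grid", call. = FALSE)
  if (anyNA(ee) || any(!is.finite(ee)))
    stop("ee contains missing or non-finite values", call. = FALSE)
  if (anyNA(activity) || any(!is.finite(activity)))
    stop("activity contains missing or non-finite values", call. = FALSE)
  if (any(ee < 0))
    stop("negative ee at ", format(time[which(ee < 0)[1L]]), call. = FALSE)
  if (any(activity < 0))
    stop("negative activity at ", format(time[which(activity < 0)[1L]]),
         call. = FALSE)
  meals <- lapply(meals, function(m) {
    if (!inherits(m, "meal_event")) m <- do.call(meal_event, as.list(m))
    m
  })
  s <- structure(list(time = time, ee = as.numeric(ee),
                      activity = as.numeric(activity),
                      meals = meals, condition = condition),
                 class = "calorimetry_session")
  for (m in meals) meal_index(s, m)   # errors if a meal is outside the span
  s
}

#' @keywords internal
meal_index <- function(session, meal) {
  i <- which(minute_of_day(session$time) == parse_hm(meal$time))[1L]
  if (is.na(i))
    stop("meal '", meal$label, "' at ", meal$time,
         " lies outside the session span", call. = FALSE)
  i
}

#' @export
print.calorimetry_session <- function(x, ...) {
  n <- length(x$time)
  cat(sprintf("<calorimetry_session: %d min (%s to %s)%s>\n", n,
              format(x$time[1L], "%Y-%m-%d %H:%M"),
              format(x$time[n], "%H:%M"),
              if (nzchar(x$condition)) paste0(", ", x$condition) else ""))
  if (length(x$meals))
    cat("  meals:", paste(vapply(x$meals, function(m)
      sprintf("%s %s (%.0f kcal)", m$label, m$time, m$energy_kcal), ""),
      collapse = ", "), "\n")
  cat(sprintf("  ee: mean %.3f kcal/min; activity: mean %.0f counts/min\n",
              mean(x$ee), mean(x$activity)))
  invisible(x)
}

#' @export
length.calorimetry_session <- function(x) length(x$time)

#' Energy expenditure from gas exchange and urinary nitrogen (Weir)
#'
#' Computes minute energy expenditure from oxygen consumption, carbon dioxide
#' production and the urinary nitrogen excretion rate:
#' `EE = 3.941 * vo2 + 1.106 * vco2 - 2.17 * n_rate` (kcal/min with vo2 and
#' vco2 in L/min and n_rate in g/min). The coefficients are the de-facto
#' standard Weir values and are overridable for sensitivity analysis.
#'
#' A respiratory quotient (vco2/vo2) outside (0.6, 1.3) is physiologically
#' implausible and is flagged with a warning; a negative computed EE is an
#' error (inconsistent inputs), never silently returned.
#'
#' @param vo2 O2 consumption rate, L/min, >= 0 (vectorised).
#' @param vco2 CO2 production rate, L/min, >= 0.
#' @param n_rate Urinary nitrogen excretion rate, g/min, >= 0. A 24-h urine
#'   collection of N grams corresponds to `N / 1440` g/min.
#' @param coef Length-3 numeric: coefficients of vo2, vco2, n_rate.
#' @return Energy expenditure, kcal/min.
#' @examples
#' weir_ee(0.25, 0.20)            # 1.20645 kcal/min
#' weir_ee(0.25, 0.20, 12 / 1440) # protein correction for 12 g N/day
#' @export
weir_ee <- function(vo2, vco2, n_rate = 0, coef = c(3.941, 1.106, -2.17)) {
  if (any(vo2 < 0) || any(vco2 < 0) || any(n_rate < 0))
    stop("gas exchange rates and n_rate must be non-negative", call. = FALSE)
  if (length(coef) != 3L) stop("coef must have length 3", call. = FALSE)
  rq_ok <- vo2 == 0 | (vco2 / vo2 > 0.6 & vco2 / vo2 < 1.3)
  if (!all(rq_ok))
    warning(sum(!rq_ok), " sample(s) with respiratory quotient outside ",
            "(0.6, 1.3)", call. = FALSE)
  ee <- coef[1L] * vo2 + coef[2L] * vco2 + coef[3L] * n_rate
  if (any(ee < 0))
    stop("Weir equation produced negative energy expenditure; ",
         "inputs are inconsistent", call. = FALSE)
  ee
}

#' Read a chamber session from a delimited text file
#'
#' Expects a CSV with header `timestamp,ee_kcal_min,activity_counts`, or the
#' gas-exchange variant `timestamp,vo2_l_min,vco2_l_min,activity_counts` from
#' which EE is derived via [weir_ee()] with a session-level constant nitrogen
#' rate. Lines starting with `#` (run metadata written by [write_session()])
#' are skipped. Timestamps are ISO-8601.
#'
#' Gaps in the minute grid are a hard error by default; with
#' `fill_gaps = "linear"` gaps of at most `max_gap` minutes are filled by
#' explicit linear interpolation of ee and activity (logged via `message()`),
#' longer gaps remain an error.
#'
#' @param path File path.
#' @param schema Optional named character vector mapping the standard column
#'   names (`timestamp`, `ee_kcal_min`, `vo2_l_min`, `vco2_l_min`,
#'   `activity_counts`) to the names used in the file.
#' @param n_rate Constant urinary nitrogen rate (g/min) used when EE is
#'   computed from gas columns.
#' @param fill_gaps `"none"` (default: gaps are an error) or `"linear"`.
#' @param max_gap Largest gap (minutes) that `fill_gaps = "linear"` will fill.
#' @param meals Optional list of [meal_event()]s to attach.
#' @param condition Condition label to attach.
#' @return A [calorimetry_session()].
#' @export
read_session <- function(path, schema = NULL, n_rate = 0,
                         fill_gaps = c("none", "linear"), max_gap = 5,
                         meals = list(), condition = "") {
  fill_gaps <- match.arg(fill_gaps)
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  col <- function(std) {
    nm <- if (!is.null(schema) && std %in% names(schema)) schema[[std]] else std
    if (nm %in% names(df)) df[[nm]] else NULL
  }
  ts_raw <- col("timestamp")
  if (is.null(ts_raw)) stop("no timestamp column in ", path, call. = FALSE)
  time <- as.POSIXct(ts_raw, tz = "UTC",
                     tryFormats = c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%dT%H:%M",
                                    "%Y-%m-%d %H:%M:%OS", "%Y-%m-%d %H:%M"))
  if (anyNA(time))
    stop("unparseable timestamp at row ", which(is.na(time))[1L], call. = FALSE)
  activity <- col("activity_counts")
  if (is.null(activity)) stop("no activity_counts column in ", path, call. = FALSE)
  ee <- col("ee_kcal_min")
  if (is.null(ee)) {
    vo2 <- col("vo2_l_min"); vco2 <- col("vco2_l_min")
    if (is.null(vo2) || is.null(vco2))
      stop("need either an ee_kcal_min column or vo2_l_min + vco2_l_min in ",
           path, call. = FALSE)
    ee <- weir_ee(vo2, vco2, n_rate)
  }
  dup <- duplicated(time)
  if (any(dup))
    stop("duplicate timestamp at ", format(time[which(dup)[1L]]), call. = FALSE)
  if (fill_gaps == "linear") {
    dt <- diff(as.numeric(time)) / 60
    if (any(dt > 1)) {
      big <- which(dt > max_gap + 1)
      if (length(big))
        stop("gap of ", dt[big[1L]] - 1, " min at ",
             format(time[big[1L]] + 60), " exceeds max_gap = ", max_gap,
             call. = FALSE)
      full <- seq(time[1L], time[length(time)], by = 60)
      filled <- sum(dt[dt > 1] - 1)
      message("filling ", filled, " missing minute(s) by linear interpolation")
      ee <- stats::approx(as.numeric(time), ee, xout = as.numeric(full))$y
      activity <- stats::approx(as.numeric(time), activity,
                                xout = as.numeric(full))$y
      time <- full
    }
  }
  calorimetry_session(time, ee, activity, meals = meals, condition = condition)
}

#' Write a session to CSV
#'
#' Emits the standard `timestamp,ee_kcal_min,activity_counts` layout, with
#' optional `#`-prefixed metadata comment lines (tool version, seed, config
#' hash) that [read_session()] skips. Values are written in full precision so
#' that a read/write round trip is exact.
#'
#' @param session A [calorimetry_session()].
#' @param path Output path.
#' @param comments Character vector of metadata lines (without the `#`).
#' @return `path`, invisibly.
#' @export
write_session <- function(session, path, comments = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  for (cm in comments) writeLines(paste0("# ", cm), con)
  writeLines("timestamp,ee_kcal_min,activity_counts", con)
  writeLines(sprintf("%s,%s,%s",
                     format(session$time, "%Y-%m-%dT%H:%M:%S"),
                     formatC(session$ee, digits = 17, format = "g"),
                     formatC(session$activity, digits = 17, format = "g")),
             con)
  invisible(path)
}

#' Advance the energy-expenditure series relative to activity
#'
#' Whole-room calorimeters respond with a delay of a couple of minutes;
#' measured EE is therefore advanced (shifted earlier) by `minutes` relative
#' to the timestamps and the activity series. The trailing `minutes` samples
#' have no advanced EE and are dropped: all series are truncated to the
#' common support rather than padded, so no fabricated samples enter any
#' regression.
#'
#' @param session A [calorimetry_session()].
#' @param minutes Non-negative integer shift; default 2 (the validated
#'   chamber response time).
#' @return A shorter [calorimetry_session()].
#' @export
advance_ee <- function(session, minutes = 2L) {
  minutes <- as.integer(minutes)
  if (minutes < 0L) stop("minutes must be >= 0", call. = FALSE)
  n <- length(session$time)
  if (minutes >= n)
    stop("advance of ", minutes, " min >= session length ", n, call. = FALSE)
  if (minutes == 0L) return(session)
  keep <- seq_len(n - minutes)
  calorimetry_session(session$time[keep],
                      session$ee[keep + minutes],
                      session$activity[keep],
                      meals = session$meals, condition = session$condition)
}

#' Extract the EE and activity samples of a period
#'
#' @param session A [calorimetry_session()].
#' @param p A [period()]; must lie within the session span.
#' @return List with `time`, `ee`, `activity` (the samples in `[start, end)`)
#'   and `idx`, the indices into the full session.
#' @export
slice_session <- function(session, p) {
  idx <- period_indices(session, p)
  list(time = session$time[idx], ee = session$ee[idx],
       activity = session$activity[idx], idx = idx)
}
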