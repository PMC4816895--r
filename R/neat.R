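#' Specification of an activity integration window
#'
#' The delayed and prolonged energetic cost of movement means minute EE
#' correlates better with activity aggregated over a moving window than with
#' instantaneous counts. An integration spec is the pair (half-width `w`,
#' lag `L`): integrated activity at minute `t` is the windowed statistic of
#' raw counts over timestamps in `[t + L - w, t + L + w]`.
#'
#' @param half_width Window half-width in minutes, integer >= 0. The search
#'   grid used in practice is 0..30.
#' @param lag Lag in minutes, integer; positive means the window is centred
#'   after the EE sample. Practical grid -20..20.
#' @return An object of class `integration_spec`.
#' @export
integration_spec <- function(half_width, lag = 0L) {
  hw <- as.integer(half_width); lg <- as.integer(lag)
  if (is.na(hw) || hw < 0L) stop("half_width must be an integer >= 0", call. = FALSE)
  if (is.na(lg)) stop("lag must be an integer", call. = FALSE)
  structure(list(half_width = hw, lag = lg), class = "integration_spec")
}

#' @export
print.integration_spec <- function(x, ...) {
  cat(sprintf("<integration_spec: half_width %d min, lag %+d min>\n",
              x$half_width, x$lag))
  invisible(x)
}

# Windowed statistic of `activity` evaluated at positions `at` (indices into
# the full series). Windows are truncated at the series boundaries; a window
# with no overlap yields NA. `cs` is c(0, cumsum(activity)), passed in by
# callers that evaluate many specs on the same series.
integrate_at <- function(activity, at, half_width, lag,
                         statistic = "mean", cs = NULL) {
  n <- length(activity)
  if (is.null(cs)) cs <- c(0, cumsum(activity))
  lo <- at + lag - half_width
  hi <- at + lag + half_width
  out <- rep(NA_real_, length(at))
  ok <- hi >= 1L & lo <= n
  lo <- pmax(lo[ok], 1L)
  hi <- pmin(hi[ok], n)
  tot <- cs[hi + 1L] - cs[lo]
  out[ok] <- if (statistic == "mean") tot / (hi - lo + 1L) else tot
  out
}

#' Integrate an activity series over a moving window
#'
#' Computes integrated physical activity: for each minute `t`, the mean (or
#' sum) of raw counts over `[t + lag - half_width, t + lag + half_width]`.
#' Windows are truncated to the samples that exist, so boundary minutes use
#' shorter windows rather than being discarded; a minute whose window lies
#' entirely outside the series is returned as `NA` and excluded from any
#' downstream correlation or regression.
#'
#' The default statistic is the windowed mean: Pearson correlation is
#' invariant to the choice and the NEAT series is too (the fitted slope
#' compensates), while the mean keeps units of counts/min and makes truncated
#' boundary windows comparable to full ones.
#'
#' @param activity Numeric series on a complete minute grid.
#' @param spec An [integration_spec()].
#' @param statistic `"mean"` (default) or `"sum"`.
#' @return Numeric series of the same length as `activity`.
#' @examples
#' integrate_activity(c(0, 0, 60, 0, 0), integration_spec(1)) # 0 20 20 20 0
#' @export
integrate_activity <- function(activity, spec, statistic = c("mean", "sum")) {
  statistic <- match.arg(statistic)
  stopifnot(inherits(spec, "integration_spec"))
  integrate_at(activity, seq_along(activity), spec$half_width, spec$lag,
               statistic)
}

# Pearson r over complete pairs; NA when either side is constant.
safe_cor <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 2L) return(NA_real_)
  x <- x[ok]; y <- y[ok]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y)
}

#' Grid-search the integration window maximizing correlation with EE
#'
#' Exhaustively evaluates every (half-width, lag) pair on the supplied grids,
#' computing the Pearson correlation between `ee(t)` and integrated activity
#' at `t` for `t` in the period, and returns the pair with the highest `r`.
#' Integration windows draw on the full series (samples outside the period
#' inform windows near its edges); only the correlation is restricted to the
#' period. Run once per analysis period — the optimum is period-specific.
#'
#' Ties (exact equality of `r`) are broken toward the most parsimonious,
#' physiologically causal spec: smallest half-width, then smallest `|lag|`,
#' then non-positive lag before positive.
#'
#' @param ee Full-session EE series (kcal/min).
#' @param activity Full-session activity series (counts/min), same length.
#' @param idx Integer indices of the analysis period (e.g. from
#'   [period_indices()]).
#' @param w_grid,lag_grid Integer grids to search; defaults 0..30 and -20..20.
#' @param statistic Passed to the integration, `"mean"` or `"sum"`.
#' @param min_pairs Minimum complete pairs required at every grid point.
#' @return List of class `integration_opt` with elements `spec` (the argmax
#'   [integration_spec()]), `r` (the maximal correlation), and `grid` (a
#'   data frame of `half_width`, `lag`, `r` for the whole search, for
#'   inspection or dumping).
#' @export
optimize_integration <- function(ee, activity, idx, w_grid = 0:30,
                                 lag_grid = -20:20,
                                 statistic = c("mean", "sum"),
                                 min_pairs = 10L) {
  statistic <- match.arg(statistic)
  if (length(ee) != length(activity))
    stop("ee and activity must be aligned", call. = FALSE)
  if (stats::sd(activity[idx]) == 0)
    stop("zero activity variance over the period; cannot optimize integration",
         call. = FALSE)
  grid <- expand.grid(half_width = as.integer(w_grid),
                      lag = as.integer(lag_grid))
  # preference order for tie-breaking
  grid <- grid[order(grid$half_width, abs(grid$lag), grid$lag), ]
  cs <- c(0, cumsum(activity))
  ee_p <- ee[idx]
  r <- vapply(seq_len(nrow(grid)), function(i) {
    a <- integrate_at(activity, idx, grid$half_width[i], grid$lag[i],
                      statistic, cs)
    if (sum(!is.na(a)) < min_pairs)
      stop("fewer than ", min_pairs, " valid paired samples at grid point (",
           grid$half_width[i], ", ", grid$lag[i], ")", call. = FALSE)
    safe_cor(ee_p, a)
  }, numeric(1))
  grid$r <- r
  if (all(is.na(r)))
    stop("correlation undefined over the whole grid (constant EE or ",
         "integrated activity)", call. = FALSE)
  # argmax with the documented tie-break: the grid is already in preference
  # order, and ties within 1e-12 of the max count as exact
  best <- which(r >= max(r, na.rm = TRUE) - 1e-12)[1L]
  if (abs(r[best]) < 0.2)
    warning(sprintf("weak EE-activity coupling: best |r| = %.3f < 0.2",
                    abs(r[best])), call. = FALSE)
  structure(list(spec = integration_spec(grid$half_width[best], grid$lag[best]),
                 r = r[best],
                 grid = grid[order(grid$half_width, grid$lag), ]),
            class = "integration_opt")
}

#' @export
print.integration_opt <- function(x, ...) {
  cat(sprintf("<integration_opt: half_width %d, lag %+d, r = %.4f (grid of %d)>\n",
              x$spec$half_width, x$spec$lag, x$r, nrow(x$grid)))
  invisible(x)
}

#' Fit the linear NEAT model over a period
#'
#' Ordinary least squares of `ee(t)` on integrated activity over the period.
#' The fit records the slope (kcal/min per count/min), intercept, Pearson
#' `r`, and the period minimum of integrated activity, which serves as the
#' zero-NEAT reference: NEAT is the activity-driven EE *above the quietest
#' minute of the period*. A non-positive slope contradicts the assumed
#' positive EE-activity dependency and sets the `degenerate` flag (NEAT is
#' then taken as identically zero downstream).
#'
#' @inheritParams optimize_integration
#' @param spec The [integration_spec()] to use (typically from
#'   [optimize_integration()]).
#' @return Object of class `neat_fit` with fields `spec`, `idx`, `slope`,
#'   `intercept`, `r`, `min_integrated_activity`, `degenerate`, `statistic`.
#' @export
fit_neat <- function(ee, activity, idx, spec, statistic = c("mean", "sum")) {
  statistic <- match.arg(statistic)
  stopifnot(inherits(spec, "integration_spec"))
  if (stats::sd(activity[idx]) == 0)
    stop("zero activity variance over the period; cannot fit NEAT model",
         call. = FALSE)
  a <- integrate_at(activity, idx, spec$half_width, spec$lag, statistic)
  ok <- !is.na(a)
  if (sum(ok) < 3L) stop("too few valid samples for the NEAT fit", call. = FALSE)
  x <- a[ok]; y <- ee[idx][ok]
  if (stats::sd(x) == 0)
    stop("zero activity variance over the period; cannot fit NEAT model",
         call. = FALSE)
  slope <- stats::cov(x, y) / stats::var(x)
  intercept <- mean(y) - slope * mean(x)
  r <- safe_cor(x, y)
  if (is.na(r)) r <- 0   # constant EE: no linear dependency, degenerate below
  structure(list(spec = spec, idx = idx, slope = slope, intercept = intercept,
                 r = r, min_integrated_activity = min(x),
                 degenerate = slope <= 0, statistic = statistic),
            class = "neat_fit")
}

# Degenerate-tolerant variant used by the NEAT-free TEF pipeline: constant
# activity over the period degrades gracefully to a NEAT == 0 fit instead of
# erroring, so the estimate reduces to the plain postprandial area.
fit_neat_safe <- function(ee, activity, idx, w_grid, lag_grid,
                          statistic = "mean") {
  if (stats::sd(activity[idx]) == 0) {
    warning("constant activity over the period: NEAT model degenerate, ",
            "NEAT set to 0", call. = FALSE)
    return(structure(list(spec = integration_spec(0L, 0L), idx = idx,
                          slope = 0, intercept = mean(ee[idx]), r = NA_real_,
                          min_integrated_activity = activity[idx][1L],
                          degenerate = TRUE, statistic = statistic),
                     class = "neat_fit"))
  }
  opt <- optimize_integration(ee, activity, idx, w_grid, lag_grid, statistic)
  fit <- fit_neat(ee, activity, idx, opt$spec, statistic)
  if (fit$degenerate)
    warning("non-positive EE-activity slope: NEAT model degenerate, ",
            "NEAT set to 0", call. = FALSE)
  fit
}

#' @export
print.neat_fit <- function(x, ...) {
  cat(sprintf(
    "<neat_fit: slope %.3g kcal/min per count, intercept %.3f, r = %.3f%s>\n",
    x$slope, x$intercept, x$r, if (x$degenerate) ", DEGENERATE" else ""))
  invisible(x)
}

#' Nonexercise activity thermogenesis series implied by a fit
#'
#' `NEAT(t) = slope * (A_int(t) - min_integrated_activity)`, clipped below at
#' zero: NEAT is the EE attributable to the rise of integrated activity above
#' its lowest value in the fitting period. For a degenerate fit the series is
#' identically zero (with a warning): the estimate then reduces to the raw
#' postprandial area, and the flag propagates so users can see that.
#'
#' @param fit A `neat_fit`.
#' @param activity Full-session activity series (same series the fit's
#'   indices refer to).
#' @return NEAT series, kcal/min, `NA` where integrated activity is undefined.
#' @export
neat_series <- function(fit, activity) {
  stopifnot(inherits(fit, "neat_fit"))
  if (fit$degenerate) {
    warning("degenerate NEAT fit: returning an all-zero NEAT series",
            call. = FALSE)
    return(rep(0, length(activity)))
  }
  a <- integrate_at(activity, seq_along(activity), fit$spec$half_width,
                    fit$spec$lag, fit$statistic)
  pmax(0, fit$slope * (a - fit$min_integrated_activity))
}

#' Energy expenditure free from NEAT
#'
#' @param ee EE series (kcal/min).
#' @param neat NEAT series from [neat_series()], same length.
#' @return `ee - neat`, elementwise.
#' @export
ee_free_series <- function(ee, neat) {
  if (length(ee) != length(neat))
    stop("ee and neat series are misaligned (lengths ", length(ee), " and ",
         length(neat), ")", call. = FALSE)
  ee - neat
}
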