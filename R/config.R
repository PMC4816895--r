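#' Default run configuration
#'
#' Bundles the protocol constants used throughout: the named analysis
#' periods, the integration search grids, the calorimetric coefficients and
#' EE advance, and the simulator defaults. The defaults encode the standard
#' 33-h chamber protocol: lights out 23:00-07:00, breakfast 08:00, lunch
#' 12:00, dinner 19:00; resting metabolic rate window 07:15-07:45; morning
#' analysis window 08:00-12:00; waking window 08:00-23:00 (12:00-23:00 for a
#' session without breakfast).
#'
#' @return A nested list with sections `periods`, `integration`,
#'   `calorimetry` and `simulate`.
#' @export
default_config <- function() {
  list(
    periods = list(
      pre_breakfast   = list(start = "07:15", end = "07:45"),
      morning         = list(start = "08:00", end = "12:00"),
      waking          = list(start = "08:00", end = "23:00"),
      waking_two_meal = list(start = "12:00", end = "23:00"),
      sleep           = list(start = "23:00", end = "07:00")
    ),
    integration = list(
      half_width_max = 30L,
      lag_min = -20L,
      lag_max = 20L,
      statistic = "mean"
    ),
    calorimetry = list(
      weir_coef = c(3.941, 1.106, -2.17),
      advance_min = 2L
    ),
    simulate = unclass(simulation_params())
  )
}

#' @keywords internal
config_period <- function(config, name) {
  p <- config$periods[[name]]
  if (is.null(p)) stop("no period named '", name, "' in config", call. = FALSE)
  period(p$start, p$end, name)
}

#' @keywords internal
config_grids <- function(config) {
  list(w = 0:config$integration$half_width_max,
       lag = config$integration$lag_min:config$integration$lag_max,
       statistic = config$integration$statistic)
}

merge_config <- function(base, override, path = "") {
  for (key in names(override)) {
    here <- if (nzchar(path)) paste0(path, ".", key) else key
    if (!key %in% names(base))
      stop("unknown config key: ", here, call. = FALSE)
    if (is.list(base[[key]]) && is.list(override[[key]]) &&
        !is.null(names(base[[key]]))) {
      base[[key]] <- merge_config(base[[key]], override[[key]], here)
    } else {
      base[[key]] <- override[[key]]
    }
  }
  base
}

#' Load a run configuration from a JSON file
#'
#' Reads overrides from a JSON file with the same nesting as
#' [default_config()] and merges them over the defaults. Unknown keys are an
#' error (they are almost always typos); an integration grid wider than the
#' standard search range (half-width 0..30, lag -20..20) is accepted with a
#' warning. With `path = NULL` the pure defaults are returned.
#'
#' @param path Path to a JSON config file, or `NULL` for defaults.
#' @param quiet Suppress the echo of effective values.
#' @return A config list as from [default_config()].
#' @export
load_config <- function(path = NULL, quiet = TRUE) {
  cfg <- default_config()
  if (!is.null(path)) {
    override <- jsonlite::read_json(path, simplifyVector = TRUE)
    cfg <- merge_config(cfg, override)
  }
  if (cfg$integration$half_width_max > 30L ||
      cfg$integration$lag_min < -20L || cfg$integration$lag_max > 20L)
    warning("integration grid exceeds the standard search range ",
            "(half-width 0..30, lag -20..20)", call. = FALSE)
  if (cfg$integration$half_width_max < 0L ||
      cfg$integration$lag_min > cfg$integration$lag_max)
    stop("malformed integration grid", call. = FALSE)
  if (!cfg$integration$statistic %in% c("mean", "sum"))
    stop("integration.statistic must be 'mean' or 'sum'", call. = FALSE)
  if (!quiet) {
    flat <- unlist(cfg)
    for (k in names(flat)) message("config: ", k, " = ", flat[[k]])
  }
  cfg
}

# Order-independent content hash of a config, for output provenance lines.
# Not cryptographic; just stable across sessions of the same R version.
config_hash <- function(config) {
  js <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA)
  bytes <- utf8ToInt(js)
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}
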