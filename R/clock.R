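#' @keywords internal
#' Parse a "HH:MM" clock time into minutes past midnight.
parse_hm <- function(x) {
  if (length(x) != 1L || !is.character(x) || !grepl("^[0-2]?[0-9]:[0-5][0-9]$", x))
    stop("clock time must be a single \"HH:MM\" string, got: ",
         deparse(substitute(x)), " = ", paste(x, collapse = ","), call. = FALSE)
  parts <- as.integer(strsplit(x, ":", fixed = TRUE)[[1L]])
  if (parts[1L] > 23L) stop("hour out of range in clock time ", x, call. = FALSE)
  parts[1L] * 60L + parts[2L]
}

#' Minutes past midnight for each timestamp.
#' @keywords internal
minute_of_day <- function(times) {
  lt <- as.POSIXlt(times, tz = "UTC")
  lt$hour * 60L + lt$min
}

#' Define an analysis period by wall-clock boundaries
#'
#' A period is a half-open clock interval `[start, end)` on a session's
#' 1-minute grid, so a "4 h" period such as 08:00-12:00 contains exactly
#' 240 samples. `end` may be clock-earlier than `start` (e.g. the sleep
#' period 23:00-07:00), in which case the period spans midnight. Periods are
#' resolved against a concrete session by [period_indices()]: `start` maps to
#' its first occurrence in the session, `end` to the first occurrence after
#' `start`.
#'
#' @param start,end Clock times, `"HH:MM"`.
#' @param name Optional label (e.g. `"morning"`).
#' @return An object of class `tef_period`.
#' @examples
#' period("08:00", "12:00", "morning")
#' period("23:00", "07:00", "sleep")   # spans midnight
#' @export
period <- function(start, end, name = NULL) {
  s <- parse_hm(start)
  e <- parse_hm(end)
  if (s == e) stop("degenerate period: start == end (", start, ")", call. = FALSE)
  structure(list(start = start, end = end, name = name %||% paste0(start, "-", end)),
            class = "tef_period")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.tef_period <- function(x, ...) {
  cat(sprintf("<period %s: %s to %s)\n", x$name, x$start, x$end))
  invisible(x)
}

#' Resolve a period to integer sample indices of a session
#'
#' @param session A [calorimetry_session()].
#' @param p A [period()].
#' @return Integer vector of indices into the session's minute grid covering
#'   `[start, end)`.
#' @export
period_indices <- function(session, p) {
  stopifnot(inherits(p, "tef_period"))
  mod <- minute_of_day(session$time)
  s_hm <- parse_hm(p$start)
  e_hm <- parse_hm(p$end)
  si <- which(mod == s_hm)[1L]
  if (is.na(si))
    stop("period '", p$name, "' outside session span: start ", p$start,
         " never occurs", call. = FALSE)
  after <- which(mod == e_hm & seq_along(mod) > si)
  n <- length(mod)
  if (length(after) == 0L) {
    # allow a period ending exactly at the sample after the last timestamp
    if ((mod[n] + 1L) %% 1440L == e_hm) {
      ei <- n + 1L
    } else {
      stop("period '", p$name, "' outside session span: end ", p$end,
           " never occurs after its start", call. = FALSE)
    }
  } else {
    ei <- after[1L]
  }
  si:(ei - 1L)
}

#' @keywords internal
period_duration <- function(session, p) length(period_indices(session, p))
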