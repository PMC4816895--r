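#' Bland-Altman agreement between two sets of paired estimates
#'
#' Computes the paired differences `d_i = a_i - b_i`, their mean (the bias),
#' sample SD (n-1 denominator), and the limits of agreement
#' `mean +/- 1.96 * SD`.
#'
#' @param a,b Numeric vectors of paired estimates (same subjects, same
#'   order), length >= 2.
#' @return Object of class `bland_altman` with `mean_diff`, `sd_diff`,
#'   `loa_low`, `loa_high`, `pairs`, and the per-pair `means`/`diffs` for
#'   plotting.
#' @examples
#' bland_altman(c(1, 2, 3), c(0, 0, 0)) # mean_diff 2, LoA 2 -/+ 1.96
#' @export
bland_altman <- function(a, b) {
  if (length(a) != length(b))
    stop("a and b must be paired (lengths ", length(a), " and ", length(b),
         ")", call. = FALSE)
  if (length(a) < 2L)
    stop("Bland-Altman needs at least 2 pairs", call. = FALSE)
  d <- a - b
  m <- mean(d)
  s <- stats::sd(d)
  structure(list(mean_diff = m, sd_diff = s,
                 loa_low = m - 1.96 * s, loa_high = m + 1.96 * s,
                 pairs = length(d), means = (a + b) / 2, diffs = d),
            class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("<bland_altman: n = %d, mean diff %.3f, LoA [%.3f, %.3f]>\n",
              x$pairs, x$mean_diff, x$loa_low, x$loa_high))
  invisible(x)
}

#' Bland-Altman plot
#'
#' Scatter of pair differences against pair means with a solid mean-difference
#' line and dashed limits of agreement.
#'
#' @param x A [bland_altman()] result.
#' @param ... Passed to [plot()].
#' @export
plot.bland_altman <- function(x, ...) {
  graphics::plot(x$means, x$diffs, xlab = "Mean of methods",
                 ylab = "Difference between methods", ...)
  graphics::abline(h = x$mean_diff)
  graphics::abline(h = c(x$loa_low, x$loa_high), lty = 2)
  invisible(x)
}

#' @keywords internal
format_mean_sd_range <- function(x, digits = 1) {
  s <- if (length(x) > 1L) stats::sd(x) else 0
  fmt <- paste0("%.", digits, "f")
  sprintf(paste0(fmt, " ± ", fmt, " [", fmt, "–", fmt, "]"),
          mean(x), s, min(x), max(x))
}

#' Group summary of TEF results, mean +/- SD [range]
#'
#' Summarizes a collection of [tef_result()]s (or a data frame with
#' `method`, `tef_percent`, `tef_kcal`, optional `condition`) per
#' method/condition group: n, mean, sample SD (reported as 0 with a flag
#' when n = 1), min and max, plus a formatted `mean +/- SD [range]` string
#' at 1 decimal for percentages.
#'
#' @param results List of `tef_result`s or an equivalent data frame.
#' @param value Column to summarize, `"tef_percent"` (default) or
#'   `"tef_kcal"`.
#' @return Data frame, one row per group.
#' @export
summary_table <- function(results, value = c("tef_percent", "tef_kcal")) {
  value <- match.arg(value)
  if (!is.data.frame(results))
    results <- do.call(rbind, lapply(results, as.data.frame))
  if (is.null(results$condition)) results$condition <- ""
  key <- interaction(results$method, results$condition, drop = TRUE)
  out <- do.call(rbind, lapply(split(results, key), function(d) {
    v <- d[[value]]
    data.frame(method = d$method[1L], condition = d$condition[1L],
               n = length(v), mean = mean(v),
               sd = if (length(v) > 1L) stats::sd(v) else 0,
               min = min(v), max = max(v),
               single = length(v) == 1L,
               formatted = format_mean_sd_range(
                 v, digits = if (value == "tef_percent") 1 else 3),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  if (any(out$single))
    warning("group(s) with n = 1: SD reported as 0", call. = FALSE)
  out
}
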