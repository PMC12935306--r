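#' Doubling time from an OD600 growth series
#'
#' Fits `log2(OD600) ~ time` by least squares over the exponential-phase
#' window; the doubling time is the reciprocal slope. With
#' `window = "auto"`, candidate windows are contiguous runs of at least
#' `min_points` points whose fit has a positive slope, R-squared of at
#' least `r2_min`, and no point deviating from the line by more than
#' `max_residual` log2 units (the residual bound rejects windows that drag
#' in lag or plateau points, which can leave R-squared high when the
#' exponential span is wide). The longest such window is used, ties broken
#' by R-squared; when no window qualifies, the best positive-slope window
#' is used. The fit is exact on noiseless exponentials for any sampling
#' grid.
#'
#' @param times numeric vector of times (min), strictly increasing.
#' @param od600 positive OD600 readings, same length.
#' @param window `"auto"` or a numeric `c(t_start, t_end)` time range.
#' @param r2_min R-squared acceptance level for the automatic window
#'   (default 0.99).
#' @param max_residual largest tolerated deviation of any point from the
#'   fitted line, in log2 units (default 0.15, about a tenth of a
#'   doubling).
#' @param min_points minimum points in a window (default 3).
#' @return list of class `growth_fit`: `doubling_time_min`, `slope`
#'   (log2 units per min), `r_squared`, `window` (`c(t_start, t_end)`),
#'   `n_points`.
#' @export
fit_doubling_time <- function(times, od600, window = "auto", r2_min = 0.99,
                              max_residual = 0.15, min_points = 3L) {
  stopifnot(length(times) == length(od600), length(times) >= 3L)
  if (any(diff(times) <= 0)) stop("times must be strictly increasing", call. = FALSE)
  if (any(od600 <= 0)) stop("od600 values must be positive", call. = FALSE)
  y <- log2(od600)

  fit_window <- function(idx) {
    t <- times[idx]; yy <- y[idx]
    sxx <- sum((t - mean(t))^2)
    slope <- sum((t - mean(t)) * (yy - mean(yy))) / sxx
    resid <- yy - (mean(yy) + slope * (t - mean(t)))
    sst <- sum((yy - mean(yy))^2)
    r2 <- if (sst <= 0) 0 else 1 - sum(resid^2) / sst
    list(slope = slope, r2 = r2, n = length(idx),
         max_resid = max(abs(resid)), t_range = range(t))
  }

  if (is.numeric(window)) {
    idx <- which(times >= window[1] & times <= window[2])
    if (length(idx) < min_points) {
      stop("fewer than ", min_points, " points in the requested window",
           call. = FALSE)
    }
    best <- fit_window(idx)
  } else {
    n <- length(times)
    best <- NULL
    for (i in seq_len(n - min_points + 1L)) {
      for (j in seq(i + min_points - 1L, n)) {
        f <- fit_window(i:j)
        if (f$slope <= 0) next
        f$ok <- f$r2 >= r2_min && f$max_resid <= max_residual
        better <- if (is.null(best)) {
          TRUE
        } else if (f$ok != best$ok) {
          f$ok
        } else if (f$ok) {
          f$n > best$n || (f$n == best$n && f$r2 > best$r2)
        } else {
          f$r2 > best$r2
        }
        if (better) best <- f
      }
    }
  }
  if (is.null(best) || best$slope <= 0) {
    stop("no growth detected", call. = FALSE)
  }
  structure(list(doubling_time_min = 1 / best$slope, slope = best$slope,
                 r_squared = best$r2, window = best$t_range,
                 n_points = best$n), class = "growth_fit")
}
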