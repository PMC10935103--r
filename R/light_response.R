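#' Five-day window index within a year
#'
#' Calendar-anchored, non-overlapping 5-day windows starting January 1.
#' Windows 1-72 are 5 days; window 73 absorbs the year-end remainder (days
#' 361 to the last day of the year: 5 days in common years, 6 in leap
#' years), so every year yields exactly 73 windows that partition it.
#'
#' @param dates Date vector.
#' @return integer window index in 1..73.
#' @export
window_index <- function(dates) {
  doy <- as.integer(format(dates, "%j"))
  pmin(((doy - 1L) %/% 5L) + 1L, 73L)
}

#' Window boundary table for one year
#'
#' @param year calendar year.
#' @return data frame with `window`, `window_start`, `window_end` (73 rows).
#' @export
year_windows <- function(year) {
  jan1 <- as.Date(sprintf("%d-01-01", year))
  dec31 <- as.Date(sprintf("%d-12-31", year))
  start <- jan1 + 5L * (0:72)
  end <- c(start[-1] - 1L, dec31)
  data.frame(window = 1:73, window_start = start, window_end = end)
}

# A failed-fit row for a window.
lr_failed_row <- function(window, start, end, n_obs) {
  data.frame(window = window, window_start = start, window_end = end,
             alpha = NA_real_, pmax = NA_real_, re = NA_real_,
             n_obs = n_obs, rmse = NA_real_, converged = FALSE)
}

#' Fit the rectangular-hyperbola light response to one window
#'
#' Nonlinear least squares of -NEE on PAR for the daytime observed records
#' of one window, under the model
#' \deqn{-NEE = \frac{\alpha \, PAR \, P_{max}}{\alpha \, PAR + P_{max}} - RE}
#' where alpha is the apparent quantum efficiency (initial slope), Pmax the
#' light-saturated rate (asymptote), and RE a free respiration offset.
#' Levenberg-Marquardt with box bounds alpha in (1e-5, 0.05],
#' Pmax in (0.01, 5], RE in [0, 2] and start (0.002, 0.5, 0.1).  Windows
#' with fewer than `min_n` usable records or a degenerate PAR design are
#' flagged; fits pinned at a bound are flagged as non-converged but keep
#' their parameter values for inspection.
#'
#' @param records half-hourly records (one window's worth).
#' @param window optional `c(start, end)` dates stamped into the result.
#' @param min_n minimum daytime observed records (default 20, leaving at
#'   least ~6 residual degrees of freedom per parameter).
#' @return one-row data frame: window dates, `alpha` (mg CO2 umol-1),
#'   `pmax` (mg CO2 m-2 s-1), `re`, `n_obs`, `rmse`, `converged`.
#' @export
fit_light_window <- function(records, window = NULL, min_n = 20L) {
  d <- as.Date(records$timestamp, tz = "UTC")
  if (is.null(window)) window <- c(min(d), max(d))
  keep <- !is_night(records$par) & records$qc == "observed" &
    !is.na(records$nee) & !is.na(records$par)
  keep[is.na(keep)] <- FALSE
  keep <- keep & d >= window[1] & d <= window[2]
  par <- records$par[keep]
  y <- -records$nee[keep]
  w0 <- window[1]; w1 <- window[2]
  if (length(y) < min_n) return(lr_failed_row(NA_integer_, w0, w1, length(y)))
  if (stats::sd(par) < 1e-6) return(lr_failed_row(NA_integer_, w0, w1, length(y)))

  lower <- c(alpha = 1e-5, pmax = 0.01, re = 0)
  upper <- c(alpha = 0.05, pmax = 5, re = 2)
  dat <- data.frame(y = y, par = par)
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ light_response_gross(par, alpha, pmax) - re,
                      data = dat,
                      start = list(alpha = 0.002, pmax = 0.5, re = 0.1),
                      lower = lower, upper = upper,
                      control = minpack.lm::nls.lm.control(
                        maxiter = 500, ftol = 1e-15, ptol = 1e-15)),
    error = function(e) NULL)
  if (is.null(fit)) return(lr_failed_row(NA_integer_, w0, w1, length(y)))
  p <- stats::coef(fit)
  pinned <- any(abs(p - lower) < 1e-10) || any(abs(p - upper) < 1e-10)
  data.frame(window = NA_integer_, window_start = w0, window_end = w1,
             alpha = unname(p["alpha"]), pmax = unname(p["pmax"]),
             re = unname(p["re"]), n_obs = length(y),
             rmse = sqrt(mean(stats::resid(fit)^2)),
             converged = !pinned)
}

#' Fit light-response parameters for every 5-day window of a year
#'
#' Splits one calendar year into its 73 calendar-anchored windows and fits
#' each with [fit_light_window()].  Failed windows are present but flagged,
#' so the result always has exactly 73 rows whose date ranges partition the
#' year.  A partial year yields rows only for windows that contain data.
#'
#' @param records half-hourly records (one calendar year or part of it).
#' @param year calendar year; defaults to the year of the first record.
#' @param min_n per-window minimum passed to [fit_light_window()].
#' @return data frame of 73 window fits (fewer for a partial year).
#' @export
fit_light_year <- function(records, year = NULL, min_n = 20L) {
  d <- as.Date(records$timestamp, tz = "UTC")
  if (is.null(year)) year <- as.integer(format(d[1], "%Y"))
  wins <- year_windows(year)
  have <- wins$window_start <= max(d) & wins$window_end >= min(d)
  wins <- wins[have, ]
  out <- vector("list", nrow(wins))
  for (k in seq_len(nrow(wins))) {
    in_win <- d >= wins$window_start[k] & d <= wins$window_end[k]
    row <- fit_light_window(records[in_win, , drop = FALSE],
                            window = c(wins$window_start[k], wins$window_end[k]),
                            min_n = min_n)
    row$window <- wins$window[k]
    out[[k]] <- row
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Gaussian smoothing of a windowed parameter series
#'
#' Discrete Gaussian-kernel convolution used to reveal the seasonal trend of
#' the fitted alpha and Pmax series.  Values from non-converged windows are
#' excluded and the kernel is renormalized over the remaining weights, so a
#' constant series is returned unchanged and kernel mass is conserved.
#' Output length equals input length; positions with no usable neighbour
#' return NA.
#'
#' @param x numeric series (one value per window).
#' @param sigma kernel standard deviation in windows (> 0); the default 2
#'   corresponds to a 10-day bandwidth.
#' @param valid logical mask of usable entries (e.g. the `converged` flag);
#'   defaults to non-NA.
#' @return smoothed numeric vector of the same length.
#' @export
smooth_gaussian <- function(x, sigma = 2, valid = !is.na(x)) {
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma <= 0) {
    stop("sigma must be a positive bandwidth in windows")
  }
  n <- length(x)
  stopifnot(length(valid) == n)
  valid <- valid & !is.na(x)
  out <- rep(NA_real_, n)
  idx <- seq_len(n)
  for (i in idx) {
    w <- exp(-((idx - i)^2) / (2 * sigma^2))
    w[!valid] <- 0
    s <- sum(w)
    if (s > 0) out[i] <- sum(w * x, na.rm = TRUE) / s
  }
  out
}

#' Smooth the fitted light-response parameter series
#'
#' Adds `alpha_smooth` and `pmax_smooth` columns to a [fit_light_year()]
#' table, smoothing over converged windows only.
#'
#' @param fits window fit table.
#' @param sigma Gaussian bandwidth in windows.
#' @return `fits` with smoothed columns; requires at least 5 converged fits.
#' @export
smooth_light_fits <- function(fits, sigma = 2) {
  if (sum(fits$converged) < 5L) stop("need at least 5 converged fits to smooth")
  fits$alpha_smooth <- smooth_gaussian(fits$alpha, sigma, fits$converged)
  fits$pmax_smooth <- smooth_gaussian(fits$pmax, sigma, fits$converged)
  fits
}
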