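#' Fit the Lloyd-Taylor respiration model to nighttime NEE
#'
#' At night there is no photosynthesis, so RE = NEE; the nighttime,
#' u*-accepted, observed NEE-Ts pairs therefore identify the respiration
#' model.  Fitting is Levenberg-Marquardt nonlinear least squares with box
#' bounds (r_ref in (0, 10], e0 in (0, 1000]); on failure two further start
#' points are tried.  A window with fewer than `min_n` usable pairs, or with
#' (near-)constant soil temperature (e0 unidentifiable), returns a flagged
#' failure instead of parameters.
#'
#' @param records half-hourly records (NEE screened and still unfilled, so
#'   only `qc == "observed"` values enter the fit).
#' @param window optional `c(start, end)` Date range restricting the fit.
#' @param min_n minimum usable nighttime pairs (default 10).
#' @return object of class `lloyd_taylor_fit`: `r_ref`, `e0`, fixed `t_ref`
#'   and `t0`, `n_obs`, `rmse`, `converged`.
#' @export
fit_lloyd_taylor <- function(records, window = NULL, min_n = 10L) {
  validate_halfhourly(records, require_fluxes = TRUE)
  keep <- is_night(records$par) & records$qc == "observed" &
    !is.na(records$nee) & !is.na(records$ts)
  keep[is.na(keep)] <- FALSE
  if (!is.null(window)) {
    d <- as.Date(records$timestamp, tz = "UTC")
    keep <- keep & d >= as.Date(window[1]) & d <= as.Date(window[2])
  }
  nee <- records$nee[keep]
  ts <- records$ts[keep]
  failed <- function(n) structure(
    list(r_ref = NA_real_, e0 = NA_real_, t_ref = 283.15, t0 = 227.13,
         n_obs = n, rmse = NA_real_, converged = FALSE),
    class = "lloyd_taylor_fit")
  if (length(nee) < min_n) return(failed(length(nee)))
  if (stats::sd(ts) < 1e-6) return(failed(length(nee)))

  starts <- list(c(r_ref = 0.1, e0 = 309),
                 c(r_ref = 0.05, e0 = 150),
                 c(r_ref = 0.5, e0 = 500))
  dat <- data.frame(nee = nee, ts = ts)
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(nee ~ lloyd_taylor(ts, r_ref, e0),
                        data = dat, start = as.list(st),
                        lower = c(1e-8, 1e-8), upper = c(10, 1000),
                        control = minpack.lm::nls.lm.control(
                          maxiter = 500, ftol = 1e-15, ptol = 1e-15)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      p <- stats::coef(fit)
      return(structure(
        list(r_ref = unname(p["r_ref"]), e0 = unname(p["e0"]),
             t_ref = 283.15, t0 = 227.13, n_obs = length(nee),
             rmse = sqrt(mean(stats::resid(fit)^2)), converged = TRUE),
        class = "lloyd_taylor_fit"))
    }
  }
  failed(length(nee))
}

#' @export
print.lloyd_taylor_fit <- function(x, ...) {
  if (x$converged) {
    cat(sprintf(
      "<lloyd_taylor_fit> r_ref = %.4f mg m-2 s-1, e0 = %.1f K (n = %d, rmse = %.4f)\n",
      x$r_ref, x$e0, x$n_obs, x$rmse))
  } else {
    cat("<lloyd_taylor_fit> failed (n =", x$n_obs, ")\n")
  }
  invisible(x)
}

#' Predict respiration from a fitted Lloyd-Taylor model
#'
#' @param object a `lloyd_taylor_fit`.
#' @param ts_c soil temperature (degC).
#' @param ... unused.
#' @return predicted respiration (mg CO2 m-2 s-1).
#' @export
predict.lloyd_taylor_fit <- function(object, ts_c, ...) {
  if (!object$converged) stop("cannot predict from a failed Lloyd-Taylor fit")
  lloyd_taylor(ts_c, object$r_ref, object$e0, object$t_ref, object$t0)
}

# Covering light-response window for a date; falls back to the nearest
# converged window when the covering one failed.
covering_lr_fit <- function(lr_fits, date) {
  ok <- lr_fits$converged
  hit <- which(lr_fits$window_start <= date & lr_fits$window_end >= date & ok)
  if (length(hit) >= 1L) return(list(row = hit[1L], fallback = FALSE))
  if (!any(ok)) return(NULL)
  mid <- as.numeric(lr_fits$window_start) +
    (as.numeric(lr_fits$window_end) - as.numeric(lr_fits$window_start)) / 2
  cand <- which(ok)
  list(row = cand[which.min(abs(mid[cand] - as.numeric(date)))], fallback = TRUE)
}

#' Model-fill NEE gaps
#'
#' Nighttime NEE gaps (missing or u*-rejected) are filled with the
#' Lloyd-Taylor prediction at the record's soil temperature; daytime gaps
#' with the rectangular-hyperbola prediction
#' RE - alpha PAR Pmax / (alpha PAR + Pmax) from the light-response window
#' covering the record's date (nearest converged window if that fit failed,
#' with the fallback counted).  Filled records get `qc = "gapfilled_model"`;
#' the returned series is gap-free provided meteorology is complete.
#'
#' @param records half-hourly records with complete PAR/Ts.
#' @param lt a converged [fit_lloyd_taylor()] result.
#' @param lr_fits window fit table from [fit_light_year()] covering the
#'   record dates.
#' @return list with `records` (gap-free NEE), `n_filled_night`,
#'   `n_filled_day`, `n_fallback` (daytime fills that needed a non-covering
#'   window).
#' @export
fill_nee <- function(records, lt, lr_fits) {
  validate_halfhourly(records, require_fluxes = TRUE)
  stopifnot(inherits(lt, "lloyd_taylor_fit"), lt$converged)
  gap <- which(is.na(records$nee))
  n_night <- n_day <- n_fb <- 0L
  if (length(gap) > 0L) {
    night <- is_night(records$par[gap])
    if (anyNA(night)) stop("cannot fill NEE where PAR is missing; fill meteorology first")
    dates <- as.Date(records$timestamp[gap], tz = "UTC")
    for (k in seq_along(gap)) {
      i <- gap[k]
      if (night[k]) {
        records$nee[i] <- predict(lt, records$ts[i])
        n_night <- n_night + 1L
      } else {
        cov <- covering_lr_fit(lr_fits, dates[k])
        if (is.null(cov)) stop("no converged light-response fit available")
        f <- lr_fits[cov$row, ]
        records$nee[i] <- f$re -
          light_response_gross(records$par[i], f$alpha, f$pmax)
        n_day <- n_day + 1L
        if (cov$fallback) n_fb <- n_fb + 1L
      }
      records$qc[i] <- "gapfilled_model"
    }
  }
  list(records = records, n_filled_night = n_night, n_filled_day = n_day,
       n_fallback = n_fb)
}

#' Partition NEE into ecosystem respiration and gross productivity
#'
#' At night RE = NEE (no photosynthesis); by day RE is the Lloyd-Taylor
#' prediction at the record's soil temperature.  GEP = RE - NEE everywhere,
#' which makes nighttime GEP exactly zero by construction.
#'
#' @param records gap-free half-hourly records.
#' @param lt a converged `lloyd_taylor_fit` (or a list of them keyed by
#'   calendar year for a per-year fit scope).
#' @return `records` with columns `re` and `gep` added.
#' @export
derive_re_gep <- function(records, lt) {
  validate_halfhourly(records, require_fluxes = TRUE)
  if (anyNA(records$nee)) stop("NEE must be gap-free; run fill_nee() first")
  night <- is_night(records$par)
  if (inherits(lt, "lloyd_taylor_fit")) {
    re_day <- predict(lt, records$ts)
  } else {
    yr <- format(records$timestamp, "%Y", tz = "UTC")
    re_day <- rep(NA_real_, nrow(records))
    for (y in unique(yr)) {
      fit <- lt[[y]]
      if (is.null(fit)) stop("no Lloyd-Taylor fit for year ", y)
      re_day[yr == y] <- predict(fit, records$ts[yr == y])
    }
  }
  records$re <- ifelse(night, records$nee, re_day)
  records$gep <- records$re - records$nee
  records
}

#' Accumulate half-hourly fluxes to daily, 5-day or annual sums
#'
#' Converts each half-hourly flux (mg CO2 m-2 s-1) to a carbon mass over its
#' 30-min interval (x 1800 s x 12/44 / 1000 = gC m-2) and sums over the
#' aggregation level.  Five-day blocks are the calendar-anchored
#' light-response windows (73 per year, the last absorbing the year-end
#' remainder).  Incomplete first/last days are excluded and reported.  The
#' identity GEP = RE - NEE is preserved exactly by linearity.
#'
#' @param records partitioned records from [derive_re_gep()].
#' @param level `"daily"`, `"5day"` or `"annual"`.
#' @return data frame of sums in gC m-2 per period with a `fill_fraction`
#'   column (share of half-hours not `qc == "observed"`); excluded partial
#'   days are listed in the `"excluded_days"` attribute.
#' @export
aggregate_fluxes <- function(records, level = c("daily", "5day", "annual")) {
  level <- match.arg(level)
  stopifnot(all(c("re", "gep") %in% names(records)))
  if (anyNA(records$nee)) stop("series must be gap-free before aggregation")
  date <- as.Date(records$timestamp, tz = "UTC")
  cnt <- table(date)
  partial <- names(cnt)[cnt < 48L]
  keep <- !(as.character(date) %in% partial)
  rec <- records[keep, ]
  date <- date[keep]
  key <- switch(level,
    daily = as.character(date),
    `5day` = paste(format(date, "%Y"),
                   sprintf("%02d", window_index(date)), sep = "-W"),
    annual = format(date, "%Y"))
  agg <- function(v) tapply(v * HALFHOUR_TO_GC, key, sum)
  out <- data.frame(
    period = names(agg(rec$nee)),
    nee = as.numeric(agg(rec$nee)),
    re = as.numeric(agg(rec$re)),
    gep = as.numeric(agg(rec$gep)),
    fill_fraction = as.numeric(tapply(rec$qc != "observed", key, mean)),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  if (level == "daily") out$date <- as.Date(out$period)
  attr(out, "excluded_days") <- partial
  out
}
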