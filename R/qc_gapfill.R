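#' Friction-velocity screening of nighttime NEE
#'
#' Under weak nighttime turbulence, respired CO2 pools below the canopy and
#' the eddy system underestimates the efflux.  Nighttime records whose
#' friction velocity falls below the threshold therefore have their NEE
#' rejected.  Daytime records are never touched, and records with missing
#' PAR cannot be classified and are left alone.
#'
#' @param records half-hourly tower records.
#' @param threshold friction-velocity rejection threshold (m s-1);
#'   the conventional default is 0.2.
#' @return list with `records` (rejected NEE set to NA, `qc = "rejected"`),
#'   `n_rejected`, and `rejected_index`.
#' @export
apply_ustar_filter <- function(records, threshold = 0.2) {
  validate_halfhourly(records, require_fluxes = TRUE)
  if (!is.numeric(threshold) || length(threshold) != 1L || threshold < 0) {
    stop("threshold must be a non-negative friction velocity")
  }
  night <- is_night(records$par)
  bad <- which(!is.na(night) & night &
                 !is.na(records$ustar) & records$ustar < threshold &
                 !is.na(records$nee))
  records$nee[bad] <- NA_real_
  records$qc[bad] <- "rejected"
  list(records = records, n_rejected = length(bad), rejected_index = bad)
}

#' Locate maximal gaps in one variable
#'
#' Returns the maximal runs of missing values in the requested column as
#' `(variable, start_index, length)` segments; segments are disjoint and,
#' together with the non-missing runs, reconstruct the full index set.
#'
#' @param records half-hourly tower records.
#' @param variable column name to scan.
#' @return data frame with columns `variable`, `start_index`, `length`
#'   (zero rows if the series is complete).
#' @export
find_gaps <- function(records, variable) {
  if (!variable %in% names(records)) stop("unknown variable: ", variable)
  miss <- is.na(records[[variable]])
  r <- rle(miss)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(variable = rep(variable, sum(keep)),
             start_index = starts[keep],
             length = r$lengths[keep],
             stringsAsFactors = FALSE)
}

# Mean-diurnal-variation estimate for one missing slot: mean of non-missing
# values at the same time of day within +/- window_days, taken from the
# reference (pre-fill) series so filled values never feed later fills.
mdv_estimate <- function(ref, i, window_days) {
  offsets <- setdiff(seq(-window_days, window_days), 0L) * 48L
  idx <- i + offsets
  idx <- idx[idx >= 1L & idx <= length(ref)]
  vals <- ref[idx]
  vals <- vals[!is.na(vals)]
  if (length(vals) == 0L) return(NA_real_)
  mean(vals)
}

#' Fill gaps in a meteorological series
#'
#' Gaps up to 2 h (four half-hourly records) are filled by linear
#' interpolation between the flanking observations (`qc = "gapfilled_linear"`).
#' Longer gaps — and short gaps touching a series boundary with no flanking
#' value — use the mean-diurnal-variation (MDV) estimate: the mean of
#' observed values at the same time of day within `mdv_window_days` days on
#' either side (`qc = "gapfilled_mdv"`).  Slots whose MDV window holds no
#' observation stay missing and are counted as failures.  Observed values
#' are never altered, and a second pass is a no-op.
#'
#' @param records half-hourly tower records.
#' @param variable meteorological column to fill.
#' @param mdv_window_days half-width of the MDV window (days).
#' @param max_linear_len longest gap (records) still filled linearly;
#'   4 records corresponds to the 2-h rule.
#' @return list with `records` (filled series) and `report` (one-row data
#'   frame: counts filled linearly, by MDV, and failed).
#' @export
fill_meteo <- function(records, variable, mdv_window_days = 7,
                       max_linear_len = 4L) {
  if (!variable %in% names(records)) stop("unknown variable: ", variable)
  if (identical(variable, "nee")) {
    stop("NEE gaps are model-filled by fill_nee(), not fill_meteo()")
  }
  x <- records[[variable]]
  ref <- x  # pre-fill snapshot for MDV
  gaps <- find_gaps(records, variable)
  n_lin <- n_mdv <- n_fail <- 0L
  if (nrow(gaps) > 0L) {
    for (k in seq_len(nrow(gaps))) {
      i0 <- gaps$start_index[k]
      len <- gaps$length[k]
      idx <- seq.int(i0, length.out = len)
      left <- i0 - 1L
      right <- i0 + len
      flanked <- left >= 1L && right <= length(x) &&
        !is.na(x[left]) && !is.na(x[right])
      if (len <= max_linear_len && flanked) {
        x[idx] <- x[left] + (x[right] - x[left]) * seq_len(len) / (len + 1L)
        records$qc[idx] <- "gapfilled_linear"
        n_lin <- n_lin + len
      } else {
        for (i in idx) {
          est <- mdv_estimate(ref, i, mdv_window_days)
          if (is.na(est)) {
            n_fail <- n_fail + 1L
          } else {
            x[i] <- est
            records$qc[i] <- "gapfilled_mdv"
            n_mdv <- n_mdv + 1L
          }
        }
      }
    }
  }
  records[[variable]] <- x
  list(records = records,
       report = data.frame(variable = variable, n_linear = n_lin,
                           n_mdv = n_mdv, n_failed = n_fail,
                           stringsAsFactors = FALSE))
}

#' Fill all meteorological driver columns
#'
#' Convenience wrapper applying [fill_meteo()] to PAR, air and soil
#' temperature, VPD, precipitation and friction velocity, collecting the
#' per-variable gap report.
#'
#' @inheritParams fill_meteo
#' @param variables columns to fill.
#' @return list with `records` and the row-bound `report`.
#' @export
fill_all_meteo <- function(records,
                           variables = c("par", "ta", "ts", "vpd", "prec", "ustar"),
                           mdv_window_days = 7, max_linear_len = 4L) {
  reports <- vector("list", length(variables))
  for (j in seq_along(variables)) {
    res <- fill_meteo(records, variables[j], mdv_window_days, max_linear_len)
    records <- res$records
    reports[[j]] <- res$report
  }
  list(records = records, report = do.call(rbind, reports))
}
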