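#' Pipeline configuration
#'
#' Collects and validates every tunable of the processing chain.
#'
#' @param halfhourly path to the half-hourly CSV.
#' @param lai path to the daily LAI CSV.
#' @param calendar path to the phenology calendar CSV.
#' @param ustar_threshold friction-velocity rejection threshold (m s-1).
#' @param mdv_window_days half-width of the MDV gap-filling window (days).
#' @param window_length_days light-response window length (days; the
#'   windowing is calendar-anchored with 73 windows per year).
#' @param gaussian_sigma_windows Gaussian trend-smoothing bandwidth (windows).
#' @param lloyd_taylor_scope `"annual"` (one respiration fit per calendar
#'   year) or `"all"` (one fit over the whole record).
#' @param seed integer seed for any stochastic step.
#' @return validated config list of class `pipeline_config`.
#' @export
pipeline_config <- function(halfhourly, lai, calendar,
                            ustar_threshold = 0.2, mdv_window_days = 7,
                            window_length_days = 5,
                            gaussian_sigma_windows = 2,
                            lloyd_taylor_scope = c("annual", "all"),
                            seed = 1L) {
  lloyd_taylor_scope <- match.arg(lloyd_taylor_scope)
  cfg <- list(halfhourly = halfhourly, lai = lai, calendar = calendar,
              ustar_threshold = ustar_threshold,
              mdv_window_days = mdv_window_days,
              window_length_days = window_length_days,
              gaussian_sigma_windows = gaussian_sigma_windows,
              lloyd_taylor_scope = lloyd_taylor_scope,
              seed = as.integer(seed))
  for (v in c("ustar_threshold", "mdv_window_days", "window_length_days",
              "gaussian_sigma_windows")) {
    if (!is.numeric(cfg[[v]]) || cfg[[v]] <= 0) stop(v, " must be positive")
  }
  if (cfg$window_length_days != 5) {
    stop("only the 5-day calendar windowing (73 windows/year) is supported")
  }
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a YAML pipeline configuration
#'
#' @param path YAML file whose keys match [pipeline_config()] arguments.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

#' Assemble the 5-day driver table
#'
#' Joins, per (year, window): the 5-day NEE/RE/GEP sums (gC m-2 5day-1),
#' window means of VPD, Ta, Ts, PAR and LAI, the window precipitation sum,
#' the fitted light-response parameters, and the majority-day phenology
#' label.  This is the resolution at which correlation and path analyses
#' run (the resolution at which Pmax exists).
#'
#' @param records partitioned half-hourly records (with `re`, `gep`).
#' @param lr_fits combined window-fit table with a `year` column.
#' @param lai daily LAI data frame.
#' @param calendar a [phenology_calendar()].
#' @return data frame, one row per (year, window).
#' @export
window_driver_table <- function(records, lr_fits, lai, calendar) {
  sums <- aggregate_fluxes(records, "5day")
  key <- do.call(rbind, strsplit(sums$period, "-W"))
  sums$year <- as.integer(key[, 1])
  sums$window <- as.integer(key[, 2])

  date <- as.Date(records$timestamp, tz = "UTC")
  wkey <- paste(format(date, "%Y"), sprintf("%02d", window_index(date)), sep = "-W")
  met <- data.frame(
    period = sort(unique(wkey)),
    vpd = as.numeric(tapply(records$vpd, wkey, mean, na.rm = TRUE)),
    ta = as.numeric(tapply(records$ta, wkey, mean, na.rm = TRUE)),
    ts = as.numeric(tapply(records$ts, wkey, mean, na.rm = TRUE)),
    par = as.numeric(tapply(records$par, wkey, mean, na.rm = TRUE)),
    prec = as.numeric(tapply(records$prec, wkey, sum, na.rm = TRUE)))

  lkey <- paste(format(lai$date, "%Y"),
                sprintf("%02d", window_index(lai$date)), sep = "-W")
  laiw <- data.frame(period = sort(unique(lkey)),
                     lai = as.numeric(tapply(lai$lai, lkey, mean, na.rm = TRUE)))

  out <- merge(merge(sums, met, by = "period"), laiw, by = "period", all.x = TRUE)
  out <- merge(out, lr_fits[, c("year", "window", "alpha", "pmax", "converged")],
               by = c("year", "window"), all.x = TRUE)
  out$alpha[!is.na(out$converged) & !out$converged] <- NA_real_
  out$pmax[!is.na(out$converged) & !out$converged] <- NA_real_

  labs <- do.call(rbind, lapply(unique(out$year), function(y) {
    lw <- label_windows(calendar, y)
    lw$year <- y
    lw
  }))
  out <- merge(out, labs, by = c("year", "window"), all.x = TRUE)
  out$year_class <- ifelse(out$label %in% ON_LABELS, "on", "off")
  out[order(out$year, out$window), ]
}

#' Run the full processing chain
#'
#' Stages, in order: friction-velocity screening of nighttime NEE;
#' meteorological gap filling (linear up to 2 h, MDV beyond); Lloyd-Taylor
#' respiration fitting; 5-day light-response fitting (73 windows per year)
#' with Gaussian trend smoothing; model-filling of NEE gaps; RE/GEP
#' partitioning; daily/5-day/annual accumulation; phenology-period
#' statistics; Pearson correlation and path analyses on the 5-day driver
#' table.  Every output table carries a hash of the configuration, and
#' identical config + inputs give byte-identical outputs.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if absent); `NULL` to skip
#'   writing and just return results.
#' @return invisibly, a list with all stage products: `records`, `lt_fits`,
#'   `lr_fits`, `daily`, `fiveday`, `annual`, `driver_table`,
#'   `period_stats`, `correlations`, `path_models`, `indirect`, `log`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  hash <- fnv1a_hash(paste(deparse(unclass(config)), collapse = ""))
  log <- character()
  say <- function(...) log <<- c(log, paste0(...))

  records <- read_halfhourly(config$halfhourly)
  lai <- read_lai(config$lai)
  calendar <- read_phenology_calendar(config$calendar)
  say("read ", nrow(records), " half-hourly records")

  flt <- apply_ustar_filter(records, config$ustar_threshold)
  records <- flt$records
  say("u* filter (", config$ustar_threshold, " m s-1): rejected ",
      flt$n_rejected, " nighttime records")

  fm <- fill_all_meteo(records, mdv_window_days = config$mdv_window_days)
  records <- fm$records
  for (k in seq_len(nrow(fm$report))) {
    say("meteo fill ", fm$report$variable[k], ": ",
        fm$report$n_linear[k], " linear, ", fm$report$n_mdv[k], " MDV, ",
        fm$report$n_failed[k], " failed")
  }

  years <- sort(unique(as.integer(format(records$timestamp, "%Y", tz = "UTC"))))
  if (config$lloyd_taylor_scope == "annual") {
    lt_fits <- lapply(stats::setNames(years, years), function(y) {
      fit_lloyd_taylor(records,
                       window = c(sprintf("%d-01-01", y), sprintf("%d-12-31", y)))
    })
    bad <- !vapply(lt_fits, function(f) f$converged, logical(1))
    if (all(bad)) stop("no Lloyd-Taylor fit converged")
    if (any(bad)) {
      # under-sampled years fall back to the pooled fit
      pooled <- fit_lloyd_taylor(records)
      for (y in names(lt_fits)[bad]) lt_fits[[y]] <- pooled
      say("Lloyd-Taylor fallback to pooled fit for: ",
          paste(names(lt_fits)[bad], collapse = ", "))
    }
  } else {
    pooled <- fit_lloyd_taylor(records)
    if (!pooled$converged) stop("Lloyd-Taylor fit failed")
    lt_fits <- lapply(stats::setNames(years, years), function(y) pooled)
  }
  for (y in names(lt_fits)) {
    say("Lloyd-Taylor ", y, ": r_ref = ", signif(lt_fits[[y]]$r_ref, 4),
        ", e0 = ", signif(lt_fits[[y]]$e0, 5), " (n = ", lt_fits[[y]]$n_obs, ")")
  }

  yr <- format(records$timestamp, "%Y", tz = "UTC")
  lr_fits <- do.call(rbind, lapply(years, function(y) {
    f <- fit_light_year(records[yr == as.character(y), ], year = y)
    f <- smooth_light_fits(f, config$gaussian_sigma_windows)
    f$year <- y
    f
  }))
  say("light response: ", sum(lr_fits$converged), "/", nrow(lr_fits),
      " windows converged")

  # per-year night fills use each year's own respiration fit
  for (y in years) {
    sel <- yr == as.character(y)
    res_y <- fill_nee(records[sel, , drop = FALSE], lt_fits[[as.character(y)]],
                      lr_fits[lr_fits$year == y, , drop = FALSE])
    records[sel, ] <- res_y$records
  }
  say("NEE model fill: ", sum(records$qc == "gapfilled_model"), " records")

  records <- derive_re_gep(records, lt_fits)
  daily <- aggregate_fluxes(records, "daily")
  fiveday <- aggregate_fluxes(records, "5day")
  annual <- aggregate_fluxes(records, "annual")
  say("annual NEE (gC m-2 a-1): ",
      paste(annual$period, round(annual$nee, 1), sep = ": ", collapse = "; "))

  driver <- window_driver_table(records, lr_fits, lai, calendar)
  pstats <- period_stats(driver, c("nee", "re", "gep", "alpha", "pmax"))

  cors <- rbind(
    pearson_matrix(driver, responses = c("nee", "re", "gep", "pmax", "alpha")),
    {
      d2 <- driver
      d2$label <- d2$year_class
      pearson_matrix(d2, responses = c("nee", "re", "gep", "pmax", "alpha"))
    })

  path_models <- list()
  indirect <- list()
  for (s in unique(driver$year_class)) {
    d <- driver[driver$year_class == s, ]
    pm <- tryCatch(fit_path_model(d), error = function(e) NULL)
    if (!is.null(pm)) {
      path_models[[s]] <- pm
      indirect[[s]] <- indirect_effects(pm)
      say("path model [", s, "]: n = ", pm$n,
          if (pm$suppression) " (|PC|>1 present)" else "")
    } else {
      say("path model [", s, "]: skipped (insufficient data)")
    }
  }

  result <- list(records = records, lt_fits = lt_fits, lr_fits = lr_fits,
                 daily = daily, fiveday = fiveday, annual = annual,
                 driver_table = driver, period_stats = pstats,
                 correlations = cors, path_models = path_models,
                 indirect = indirect, log = log, config_hash = hash)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    w <- function(df, name) write_table_hashed(df, file.path(out_dir, name), hash)
    w(daily, "daily_fluxes.csv")
    w(fiveday, "fiveday_fluxes.csv")
    w(annual, "annual_fluxes.csv")
    w(lr_fits, "light_response.csv")
    w(driver, "driver_table.csv")
    w(pstats, "period_stats.csv")
    w(cors, "correlations.csv")
    if (length(path_models) > 0L) {
      pc_tab <- do.call(rbind, lapply(names(path_models), function(s) {
        d <- path_models[[s]]$direct
        d$stratum <- s
        d
      }))
      ind_tab <- do.call(rbind, lapply(names(indirect), function(s) {
        d <- indirect[[s]]
        d$stratum <- s
        d
      }))
      w(pc_tab, "path_coefficients.csv")
      w(ind_tab, "indirect_effects.csv")
    }
    writeLines(c(paste0("# config_hash: ", hash), log),
               file.path(out_dir, "run_log.txt"))
  }
  invisible(result)
}

# Non-overlapping random gaps of mixed lengths for one variable.
random_gap_spec <- function(n_records, variable, n_gaps, len_range, seed) {
  set.seed(as.integer(seed))
  taken <- integer(0)
  out <- list()
  tries <- 0L
  while (length(out) < n_gaps && tries < 50L * n_gaps) {
    tries <- tries + 1L
    len <- sample(seq(len_range[1], len_range[2]), 1L)
    start <- sample(n_records - len, 1L)
    idx <- seq.int(start, length.out = len)
    if (!any(idx %in% taken)) {
      taken <- c(taken, idx)
      out[[length(out) + 1L]] <- list(variable = variable, start = start,
                                      length = len)
    }
  }
  out
}

#' Simulate a complete tower dataset on disk
#'
#' Generates a multi-year synthetic bundle usable by [run_pipeline()]:
#' half-hourly CSV (with injected gaps and low-u* nighttime episodes),
#' a companion truth CSV with the true per-record parameters and fluxes,
#' a daily LAI series, a phenology calendar (odd years on), and a YAML
#' pipeline configuration.  Regeneration with the same seed is identical.
#'
#' @param years number of simulated years (starting 2011).
#' @param seed integer RNG seed.
#' @param out_dir output directory; `NULL` returns objects without writing.
#' @param noise_sd additive NEE noise (mg CO2 m-2 s-1).
#' @param low_ustar_fraction fraction of nighttime records forced low-u*.
#' @param n_gaps_nee NEE gaps injected per simulated year.
#' @param n_gaps_met meteorology gaps injected per variable per year.
#' @return invisibly, list with `records`, `truth`, `lai`, `calendar`,
#'   `low_ustar_index`, `gap_index`, and (if written) file `paths`.
#' @export
simulate_tower_dataset <- function(years = 2, seed = 1L, out_dir = NULL,
                                   noise_sd = 0.05, low_ustar_fraction = 0.1,
                                   n_gaps_nee = 20L, n_gaps_met = 5L) {
  start_year <- 2011L
  yrs <- start_year + seq_len(years) - 1L
  days <- sum(vapply(yrs, function(y) {
    as.integer(as.Date(sprintf("%d-12-31", y)) - as.Date(sprintf("%d-01-01", y))) + 1L
  }, integer(1)))
  met <- generate_meteorology(days, seed = seed,
                              start = sprintf("%d-01-01", start_year))
  n <- nrow(met)
  gap_spec <- c(
    random_gap_spec(n, "nee", n_gaps_nee * years, c(1L, 96L), seed + 10L),
    unlist(lapply(seq_along(c("par", "ta", "ts", "vpd")), function(j) {
      random_gap_spec(n, c("par", "ta", "ts", "vpd")[j], n_gaps_met * years,
                      c(1L, 12L), seed + 20L + j)
    }), recursive = FALSE))
  truth <- flux_truth(days, start = sprintf("%d-01-01", start_year),
                      noise_sd = noise_sd, gap_spec = gap_spec,
                      low_ustar_fraction = low_ustar_fraction, seed = seed)
  rec <- generate_fluxes(met, truth)
  inj <- inject_gaps_and_low_ustar(rec, truth)
  records <- inj$records

  calendar <- synthetic_calendar(yrs)
  dates <- seq(as.Date(sprintf("%d-01-01", start_year)), by = "day",
               length.out = days)
  lai <- generate_lai(dates, stats::setNames(ifelse(yrs %% 2L == 1L, "on", "off"),
                                             yrs), seed = seed)

  truth_tab <- data.frame(
    timestamp = records$timestamp,
    alpha = truth$daily$alpha[match(as.Date(records$timestamp, tz = "UTC"),
                                    truth$daily$date)],
    pmax = truth$daily$pmax[match(as.Date(records$timestamp, tz = "UTC"),
                                  truth$daily$date)],
    re_true = records$re_true, gep_true = records$gep_true,
    nee_true = records$nee_true)
  public <- records[, HALFHOURLY_COLUMNS]

  paths <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    paths <- list(
      halfhourly = file.path(out_dir, "halfhourly.csv"),
      truth = file.path(out_dir, "truth.csv"),
      lai = file.path(out_dir, "lai.csv"),
      calendar = file.path(out_dir, "calendar.csv"),
      config = file.path(out_dir, "config.yaml"))
    write_halfhourly(public, paths$halfhourly)
    tt <- truth_tab
    tt$timestamp <- format(tt$timestamp, "%Y-%m-%dT%H:%M:%S", tz = "UTC")
    utils::write.csv(tt, paths$truth, row.names = FALSE, na = "", quote = FALSE)
    utils::write.csv(lai, paths$lai, row.names = FALSE, quote = FALSE)
    write_phenology_calendar(calendar, paths$calendar)
    yaml::write_yaml(list(halfhourly = paths$halfhourly, lai = paths$lai,
                          calendar = paths$calendar, ustar_threshold = 0.2,
                          mdv_window_days = 7, window_length_days = 5,
                          gaussian_sigma_windows = 2,
                          lloyd_taylor_scope = "annual", seed = as.integer(seed)),
                     paths$config)
  }
  invisible(list(records = public, full_records = records, truth = truth,
                 truth_table = truth_tab, lai = lai, calendar = calendar,
                 low_ustar_index = inj$low_ustar_index,
                 gap_index = inj$gap_index, paths = paths))
}
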