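#' Phenology period labels for the Moso bamboo growth cycle
#'
#' On-years (mass bamboo shooting): FG_ON (fast growth of new culms), LS_ON
#' (leaf spreading on new culms), NF_ON (remaining days).  Off-years:
#' LR_OFF (leaf renewal on established culms), LS_OFF (leaf spreading on
#' established culms), NF_OFF (remaining days).
#' @export
PHENOLOGY_LABELS <- c("FG_ON", "LS_ON", "NF_ON", "LR_OFF", "LS_OFF", "NF_OFF")

ON_LABELS <- c("FG_ON", "LS_ON", "NF_ON")
OFF_LABELS <- c("LR_OFF", "LS_OFF", "NF_OFF")

#' Build and validate a phenology calendar
#'
#' A calendar is a set of dated period intervals plus an on/off class per
#' year.  Validation enforces: known labels; ON labels only in on-years and
#' OFF labels only in off-years; intervals within a year disjoint; every
#' interval inside its year.  Days not covered by any interval take the
#' year's NF label, so labelling is always a partition of the year.
#'
#' @param periods data frame with columns `year`, `label`, `start`, `end`
#'   (Dates or ISO strings).
#' @param year_class data frame with columns `year`, `class` ("on"/"off").
#' @return object of class `phenology_calendar`.
#' @export
phenology_calendar <- function(periods, year_class) {
  periods$start <- as.Date(periods$start)
  periods$end <- as.Date(periods$end)
  periods$year <- as.integer(periods$year)
  year_class$year <- as.integer(year_class$year)
  if (!all(periods$label %in% PHENOLOGY_LABELS)) stop("unknown phenology label")
  if (!all(year_class$class %in% c("on", "off"))) stop("year class must be 'on' or 'off'")
  if (anyDuplicated(year_class$year)) stop("duplicate year in year_class")
  cls <- stats::setNames(year_class$class, year_class$year)
  for (k in seq_len(nrow(periods))) {
    y <- periods$year[k]
    if (is.na(cls[as.character(y)])) stop("period year ", y, " missing from year_class")
    want_on <- periods$label[k] %in% ON_LABELS
    if (want_on != (cls[as.character(y)] == "on")) {
      stop("label ", periods$label[k], " inconsistent with ", y, " being an ",
           cls[as.character(y)], "-year")
    }
    if (periods$start[k] > periods$end[k]) stop("period start after end")
    if (format(periods$start[k], "%Y") != y || format(periods$end[k], "%Y") != y) {
      stop("period interval must lie within its year")
    }
  }
  for (y in unique(periods$year)) {
    p <- periods[periods$year == y, ]
    p <- p[order(p$start), ]
    if (nrow(p) > 1L && any(p$start[-1] <= p$end[-nrow(p)])) {
      stop("overlapping phenology periods in year ", y)
    }
  }
  structure(list(periods = periods, year_class = cls),
            class = "phenology_calendar")
}

#' @export
print.phenology_calendar <- function(x, ...) {
  cat("<phenology_calendar> years:",
      paste(names(x$year_class), "(", x$year_class, ")", collapse = ", "),
      "\n", sep = " ")
  print(x$periods)
  invisible(x)
}

#' Synthetic phenology calendar
#'
#' Emits a plausible Moso bamboo calendar so synthetic datasets are
#' self-contained: on-years get FG in April and LS_ON May-June; off-years
#' get LR April to mid-May and LS_OFF mid-May to July.  Remaining days fall
#' to NF by year class.
#'
#' @param years integer vector of calendar years.
#' @param classes "on"/"off" class per year; defaults to odd years on (the
#'   observed on-years 2011/2013/2015 are odd).
#' @return a [phenology_calendar()].
#' @export
synthetic_calendar <- function(years,
                               classes = ifelse(years %% 2L == 1L, "on", "off")) {
  rows <- list()
  for (i in seq_along(years)) {
    y <- years[i]
    if (classes[i] == "on") {
      rows[[length(rows) + 1L]] <- data.frame(
        year = y, label = c("FG_ON", "LS_ON"),
        start = as.Date(sprintf(c("%d-04-01", "%d-05-01"), y)),
        end = as.Date(sprintf(c("%d-04-30", "%d-06-30"), y)))
    } else {
      rows[[length(rows) + 1L]] <- data.frame(
        year = y, label = c("LR_OFF", "LS_OFF"),
        start = as.Date(sprintf(c("%d-04-01", "%d-05-16"), y)),
        end = as.Date(sprintf(c("%d-05-15", "%d-07-31"), y)))
    }
  }
  phenology_calendar(do.call(rbind, rows),
                     data.frame(year = years, class = classes))
}

#' Label days with their phenology period
#'
#' A day inside a dated interval takes that interval's label; any other day
#' takes NF_ON or NF_OFF according to its year's class.  Years absent from
#' the calendar are an error.
#'
#' @param calendar a [phenology_calendar()].
#' @param dates Date vector.
#' @return character vector of labels, one per date.
#' @export
label_days <- function(calendar, dates) {
  stopifnot(inherits(calendar, "phenology_calendar"))
  dates <- as.Date(dates)
  yr <- format(dates, "%Y")
  cls <- calendar$year_class[yr]
  if (anyNA(cls)) {
    stop("calendar lacks year(s): ",
         paste(unique(yr[is.na(cls)]), collapse = ", "))
  }
  out <- unname(ifelse(cls == "on", "NF_ON", "NF_OFF"))
  p <- calendar$periods
  for (k in seq_len(nrow(p))) {
    hit <- dates >= p$start[k] & dates <= p$end[k]
    out[hit] <- p$label[k]
  }
  out
}

#' Label 5-day blocks by majority day
#'
#' Each calendar-anchored 5-day window takes the label held by the majority
#' of its days; ties go to the period that starts earlier in the year.
#'
#' @param calendar a [phenology_calendar()].
#' @param year calendar year.
#' @return data frame `window`, `label` (73 rows).
#' @export
label_windows <- function(calendar, year) {
  days <- seq(as.Date(sprintf("%d-01-01", year)),
              as.Date(sprintf("%d-12-31", year)), by = "day")
  lab <- label_days(calendar, days)
  win <- window_index(days)
  first_seen <- tapply(seq_along(days), lab, min)   # earlier period wins ties
  labels <- vapply(split(lab, win), function(v) {
    tab <- table(v)
    cand <- names(tab)[tab == max(tab)]
    cand[which.min(first_seen[cand])]
  }, character(1))
  data.frame(window = as.integer(names(labels)), label = unname(labels))
}

#' Per-period statistics of a labelled series
#'
#' Mean, standard deviation and count per (label, variable) stratum —
#' typically over 5-day flux sums or window parameter fits.  Missing values
#' (e.g. failed window fits) are dropped within a stratum; an empty stratum
#' is reported with `n = 0` and no mean.
#'
#' @param data data frame containing `label` plus the value columns.
#' @param variables columns to summarise.
#' @return data frame `label`, `variable`, `mean`, `sd`, `n`.
#' @export
period_stats <- function(data, variables) {
  stopifnot("label" %in% names(data), all(variables %in% names(data)))
  out <- list()
  for (v in variables) {
    for (lab in unique(data$label)) {
      x <- data[[v]][data$label == lab]
      x <- x[!is.na(x)]
      out[[length(out) + 1L]] <- data.frame(
        label = lab, variable = v,
        mean = if (length(x) > 0L) mean(x) else NA_real_,
        sd = if (length(x) > 1L) stats::sd(x) else if (length(x) == 1L) 0 else NA_real_,
        n = length(x))
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Read a phenology calendar file
#'
#' The file is delimited text with columns `year,label,start,end`; rows
#' whose `label` is "on" or "off" carry the year class (start/end empty),
#' all other rows are dated period intervals.  Validated on load.
#'
#' @param path file path.
#' @return a [phenology_calendar()].
#' @export
read_phenology_calendar <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c("integer", "character", "character",
                                        "character"))
  is_class <- raw$label %in% c("on", "off")
  phenology_calendar(raw[!is_class, c("year", "label", "start", "end")],
                     data.frame(year = raw$year[is_class],
                                class = raw$label[is_class]))
}

#' Write a phenology calendar file
#'
#' @param calendar a [phenology_calendar()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_phenology_calendar <- function(calendar, path) {
  p <- calendar$periods
  rows <- rbind(
    data.frame(year = p$year, label = p$label,
               start = as.character(p$start), end = as.character(p$end)),
    data.frame(year = as.integer(names(calendar$year_class)),
               label = unname(calendar$year_class), start = "", end = ""))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
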