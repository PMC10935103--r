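#' Write half-hourly tower records as delimited text
#'
#' ISO-8601 timestamps, named variable columns, missing values encoded as
#' empty fields.  This is the dialect the QC stage consumes.
#'
#' @param records half-hourly data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_halfhourly <- function(records, path) {
  out <- records
  out$timestamp <- format(out$timestamp, "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  utils::write.csv(out, path, row.names = FALSE, na = "", quote = FALSE)
  invisible(path)
}

#' Read half-hourly tower records from delimited text
#'
#' @param path input CSV path (dialect of [write_halfhourly()]).
#' @return validated half-hourly data frame.
#' @export
read_halfhourly <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "")
  raw$timestamp <- as.POSIXct(raw$timestamp, format = "%Y-%m-%dT%H:%M:%S",
                              tz = "UTC")
  if (!"qc" %in% names(raw)) raw$qc <- "observed"
  raw$qc[is.na(raw$qc)] <- "observed"
  if (!"nee" %in% names(raw)) raw$nee <- NA_real_
  validate_halfhourly(raw)
  raw
}

#' Read a daily LAI series
#'
#' @param path CSV with columns `date`, `lai`.
#' @return data frame with Date `date` and numeric `lai`.
#' @export
read_lai <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("date", "lai") %in% names(d)))
  d$date <- as.Date(d$date)
  d
}

# 32-bit FNV-1a hash of a string, reported as 8 hex digits; used to stamp
# output tables with the configuration that produced them.
fnv1a_hash <- function(x) {
  bytes <- utf8ToInt(x)
  h <- 2166136261
  for (b in bytes) {
    # xor only touches the low byte; keep arithmetic in doubles (exact < 2^53)
    lo <- h %% 256
    h <- h - lo + bitwXor(as.integer(lo), as.integer(b))
    h <- (h * 16777619) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

# Write a table with a config-hash comment header.
write_table_hashed <- function(df, path, hash) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# config_hash: ", hash), con)
  utils::write.csv(df, con, row.names = FALSE, na = "", quote = FALSE)
  invisible(path)
}
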