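# Shared fixture builders: everything is generated in code at test time.

# A noiseless flux year with seasonally varying truth parameters.
noiseless_year <- function(seed = 1L, days = 365L) {
  met <- generate_meteorology(days, seed = seed)
  truth <- flux_truth(days, noise_sd = 0, seed = seed)
  list(records = generate_fluxes(met, truth), truth = truth, met = met)
}

# A noiseless dataset with constant truth parameters and (numerically)
# temperature-insensitive respiration, so every 5-day light-response window
# and every model fill can be recovered exactly.
constant_truth_year <- function(seed = 1L, days = 60L,
                                alpha = 0.003, pmax = 0.7, r_ref = 0.12) {
  met <- generate_meteorology(days, seed = seed)
  truth <- flux_truth(days, pmax_mean = pmax, pmax_amp = 0,
                      alpha_mean = alpha, alpha_amp = 0,
                      r_ref = r_ref, e0 = 1e-6, noise_sd = 0, seed = seed)
  list(records = generate_fluxes(met, truth), truth = truth)
}

# Minimal valid half-hourly frame from raw vectors (one day by default).
records_from <- function(n = 48L, nee = NA_real_, par = 0, ta = 15, ts = 12,
                         vpd = 5, prec = 0, ustar = 0.3,
                         start = "2011-01-01") {
  data.frame(
    timestamp = as.POSIXct(paste(start, "00:00:00"), tz = "UTC") +
      1800 * (seq_len(n) - 1L),
    nee = rep_len(nee, n), par = rep_len(par, n), ta = rep_len(ta, n),
    ts = rep_len(ts, n), vpd = rep_len(vpd, n), prec = rep_len(prec, n),
    ustar = rep_len(ustar, n), qc = "observed", stringsAsFactors = FALSE)
}
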