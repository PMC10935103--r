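#' Published period-mean flux reference table
#'
#' Five-year eddy-covariance mean carbon-flux statistics for a subtropical
#' Moso bamboo forest, as published for the six phenology periods
#' (gC m-2 5day-1, mean and standard deviation) and for on-/off-year annual
#' sums (gC m-2 a-1).  Shipped so the aggregation and sign conventions of
#' this package — in particular the identity GEP = RE - NEE — can be checked
#' against an independent published table.  Note one known internal
#' inconsistency of the published NF_ON row: its printed GEP (34.12) differs
#' from RE - NEE (33.67) by 0.45.
#'
#' @return data frame with columns `scope` ("period"/"annual"), `label`,
#'   `nee_mean`, `nee_sd`, `re_mean`, `re_sd`, `gep_mean`, `gep_sd`.
#' @export
flux_reference <- function() {
  utils::read.csv(system.file("extdata", "period_flux_reference.csv",
                              package = "bambooflux"),
                  stringsAsFactors = FALSE)
}
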