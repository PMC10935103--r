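test_that("Lloyd-Taylor fit recovers generating parameters on noiseless nights", {
  yr <- noiseless_year(seed = 4, days = 120)
  fit <- fit_lloyd_taylor(yr$records)
  expect_true(fit$converged)
  expect_equal(fit$r_ref, yr$truth$r_ref, tolerance = 1e-6)
  expect_equal(fit$e0, yr$truth$e0, tolerance = 1e-6)
  expect_gte(fit$n_obs, 10L)
  # reference-temperature identity of the prediction
  expect_equal(predict(fit, 10), fit$r_ref)
  # predictions strictly increase with soil temperature
  expect_true(all(diff(predict(fit, seq(0, 30, 1))) > 0))
})

test_that("degenerate or under-sampled respiration windows are flagged failures", {
  rec <- records_from(48 * 10, nee = 0.1, par = 0, ts = 12, ustar = 0.3)
  fit <- fit_lloyd_taylor(rec)  # Ts constant: e0 unidentifiable
  expect_false(fit$converged)
  small <- records_from(6, nee = 0.1, par = 0)
  expect_false(fit_lloyd_taylor(small)$converged)
  expect_error(predict(fit_lloyd_taylor(small), 10), "failed")
})

test_that("model filling restores punched NEE gaps to the generating truth", {
  cy <- constant_truth_year(seed = 6, days = 60)
  rec <- cy$records
  truth_nee <- rec$nee
  # gap-free input passes through identically
  lt <- fit_lloyd_taylor(rec)
  lr <- fit_light_year(rec)
  same <- fill_nee(rec, lt, lr)
  expect_identical(same$records$nee, rec$nee)
  expect_equal(same$n_filled_night + same$n_filled_day, 0L)

  # punch mixed day/night gaps, then refill
  idx <- c(200:260, 1000:1003, 1900:1999)
  rec2 <- rec
  rec2$nee[idx] <- NA
  rec2$qc[idx] <- "missing"
  lt2 <- fit_lloyd_taylor(rec2)
  lr2 <- fit_light_year(rec2)
  filled <- fill_nee(rec2, lt2, lr2)
  expect_false(anyNA(filled$records$nee))
  expect_true(all(filled$records$qc[idx] == "gapfilled_model"))
  expect_equal(filled$records$nee[idx], truth_nee[idx], tolerance = 1e-6)
  # everything else untouched
  expect_identical(filled$records$nee[-idx], rec$nee[-idx])
})

test_that("nighttime fill at the reference temperature returns r_ref", {
  rec <- records_from(48 * 40, nee = NA_real_, par = 0, ts = 10)
  # give the fit a range of temperatures, keep one gap at exactly 10 degC
  rec$ts <- 10 + 8 * sin(2 * pi * seq_len(nrow(rec)) / (48 * 40))
  rec$nee <- lloyd_taylor(rec$ts, 0.08, 309)
  gap <- 777L
  rec$ts[gap] <- 10
  rec$nee[gap] <- NA
  rec$qc[gap] <- "missing"
  lt <- fit_lloyd_taylor(rec)
  out <- fill_nee(rec, lt, lr_fits = data.frame())
  expect_equal(out$records$nee[gap], 0.08, tolerance = 1e-6)
})

test_that("partitioning enforces RE = NEE at night and GEP = RE - NEE everywhere", {
  yr <- noiseless_year(seed = 9, days = 90)
  lt <- fit_lloyd_taylor(yr$records)
  part <- derive_re_gep(yr$records, lt)
  night <- is_night(part$par)
  expect_identical(part$re[night], part$nee[night])
  expect_equal(part$gep[night], rep(0, sum(night)))
  expect_equal(part$gep, part$re - part$nee, tolerance = 1e-12)
  # a hand value: NEE = -0.4 by day with RE = 0.1 gives GEP = 0.5
  expect_equal(0.1 - (-0.4), 0.5)
  # noiseless recovery: derived GEP matches the generator truth
  expect_equal(part$gep, yr$records$gep_true, tolerance = 1e-6)
  expect_equal(part$re, yr$records$re_true, tolerance = 1e-6)
})

test_that("accumulation applies the CO2-to-carbon conversion and preserves the identity", {
  rec <- records_from(48 * 2, nee = 0.1, par = 0, ts = 12)
  rec$re <- rec$nee
  rec$gep <- 0
  daily <- aggregate_fluxes(rec, "daily")
  expect_equal(daily$nee, rep(0.1 * 86400 * (12 / 44) / 1000, 2))
  expect_equal(daily$nee[1], 2.35636, tolerance = 1e-5)

  yr <- noiseless_year(seed = 10, days = 365)
  part <- derive_re_gep(yr$records, fit_lloyd_taylor(yr$records))
  for (lvl in c("daily", "5day", "annual")) {
    tab <- aggregate_fluxes(part, lvl)
    expect_equal(tab$gep, tab$re - tab$nee, tolerance = 1e-9)
    expect_true(all(tab$re >= 0))
  }
  ann <- aggregate_fluxes(part, "annual")
  # a pure-sink synthetic year accumulates negative annual NEE
  expect_lt(ann$nee, 0)
  # zero series gives zero sums
  z <- rec; z$nee <- 0; z$re <- 0; z$gep <- 0
  expect_true(all(aggregate_fluxes(z, "daily")[, c("nee", "re", "gep")] == 0))
  # partial trailing day is excluded and reported
  p <- part[1:(48 * 3 + 7), ]
  d3 <- aggregate_fluxes(p, "daily")
  expect_equal(nrow(d3), 3L)
  expect_equal(attr(d3, "excluded_days"), "2011-01-04")
})
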