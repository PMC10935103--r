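test_that("u* filter rejects exactly the sub-threshold nighttime records", {
  yr <- noiseless_year(seed = 2, days = 30)
  # nothing below threshold: zero rejections
  clean <- apply_ustar_filter(yr$records, 0.2)
  expect_equal(clean$n_rejected, 0L)
  expect_identical(clean$records, yr$records)

  tr <- flux_truth(30, noise_sd = 0, seed = 2, low_ustar_fraction = 0.25)
  inj <- inject_gaps_and_low_ustar(yr$records, tr)
  flt <- apply_ustar_filter(inj$records, 0.2)
  expect_identical(flt$rejected_index, inj$low_ustar_index)
  expect_equal(flt$n_rejected, length(inj$low_ustar_index))
  expect_true(all(flt$records$qc[flt$rejected_index] == "rejected"))
  expect_true(all(is.na(flt$records$nee[flt$rejected_index])))
  # daytime untouched
  day <- which(!is_night(inj$records$par))
  expect_identical(flt$records$nee[day], inj$records$nee[day])
  expect_error(apply_ustar_filter(yr$records, -1), "non-negative")
})

test_that("find_gaps returns maximal segments agreeing with a brute-force scan", {
  rec <- records_from(200, nee = 0.1)
  expect_equal(nrow(find_gaps(rec, "nee")), 0L)
  rec$nee[50:54] <- NA
  g <- find_gaps(rec, "nee")
  expect_equal(g$start_index, 50L)
  expect_equal(g$length, 5L)

  set.seed(42)
  rec2 <- records_from(500, ta = 15)
  rec2$ta[stats::runif(500) < 0.2] <- NA
  g2 <- find_gaps(rec2, "ta")
  # brute-force O(n) reference scan
  miss <- is.na(rec2$ta)
  ref <- list()
  i <- 1L
  while (i <= length(miss)) {
    if (miss[i]) {
      j <- i
      while (j < length(miss) && miss[j + 1L]) j <- j + 1L
      ref[[length(ref) + 1L]] <- c(i, j - i + 1L)
      i <- j + 1L
    } else i <- i + 1L
  }
  ref <- do.call(rbind, ref)
  expect_equal(g2$start_index, ref[, 1])
  expect_equal(g2$length, ref[, 2])
  # segments plus complement reconstruct the index set
  covered <- unlist(mapply(seq, g2$start_index, g2$start_index + g2$length - 1L,
                           SIMPLIFY = FALSE))
  expect_setequal(covered, which(miss))
  expect_error(find_gaps(rec2, "nope"), "unknown variable")
})

test_that("meteo filling is linear up to 2 h, MDV beyond, and never touches observations", {
  # constant series: any fill reproduces the constant
  rec <- records_from(48 * 20, ta = 9.5)
  rec$ta[c(30:32, 200:260)] <- NA
  res <- fill_meteo(rec, "ta")
  expect_true(all(res$records$ta == 9.5))
  expect_equal(res$report$n_linear, 3L)
  expect_equal(res$report$n_mdv, 61L)

  # midpoint of a single-record gap
  rec2 <- records_from(48, ta = 1)
  rec2$ta[10] <- NA
  rec2$ta[9] <- 1.0; rec2$ta[11] <- 3.0
  out2 <- fill_meteo(rec2, "ta")$records
  expect_equal(out2$ta[10], 2.0)
  expect_equal(out2$qc[10], "gapfilled_linear")

  # noiseless diurnal sinusoid: MDV is exact on a periodic signal
  n <- 48 * 21
  rec3 <- records_from(n)
  slot <- (seq_len(n) - 1L) %% 48L
  rec3$vpd <- 5 + 3 * sin(2 * pi * slot / 48)
  truth <- rec3$vpd
  rec3$vpd[48 * 9 + seq_len(48 * 3)] <- NA  # 3-day hole mid-series
  out3 <- fill_meteo(rec3, "vpd")$records
  expect_equal(out3$vpd, truth, tolerance = 1e-12)
  expect_true(all(out3$qc[48 * 9 + seq_len(48 * 3)] == "gapfilled_mdv"))

  # boundary gap falls back to MDV even if short
  rec4 <- records_from(48 * 15, ts = 4)
  rec4$ts[1:2] <- NA
  out4 <- fill_meteo(rec4, "ts")
  expect_equal(out4$report$n_mdv, 2L)
  expect_equal(out4$records$ts[1:2], c(4, 4))

  # observed values never altered; second pass is a no-op
  res2 <- fill_meteo(res$records, "ta")
  expect_identical(res2$records, res$records)
  expect_equal(sum(res2$report[, c("n_linear", "n_mdv", "n_failed")]), 0)
  expect_error(fill_meteo(rec, "nee"), "fill_nee")
})

test_that("MDV failure leaves the value missing and is reported", {
  rec <- records_from(48 * 3, ta = 7)
  rec$ta[seq_len(48 * 3)] <- NA  # nothing observed at any slot
  out <- fill_meteo(rec, "ta")
  expect_true(all(is.na(out$records$ta)))
  expect_equal(out$report$n_failed, 48 * 3)
})
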