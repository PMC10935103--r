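make_driver_frame <- function(n, seed = 1) {
  set.seed(seed)
  d <- as.data.frame(matrix(stats::rnorm(n * 6), n, 6))
  names(d) <- c("vpd", "prec", "par", "lai", "ta", "ts")
  d$pmax <- d$ts * 0.4 + stats::rnorm(n)
  d$re <- d$ta * 0.3 + stats::rnorm(n)
  d$gep <- d$pmax * 0.6 + stats::rnorm(n)
  d$nee <- -0.7 * d$gep + 0.3 * d$re + stats::rnorm(n)
  d$label <- "ALL"
  d
}

test_that("stratified Pearson table matches the direct formula", {
  d <- data.frame(label = "S", x = c(1, 2, 3), y = c(6, 4, 2))
  tab <- pearson_matrix(d, factors = "x", responses = "y", strata = "S")
  expect_equal(tab$r, -1)
  d2 <- data.frame(label = "S", x = 1:10)
  d2$y <- d2$x
  expect_equal(pearson_matrix(d2, "x", "y")$r, 1)

  # random 20-point stratum against a from-scratch product-moment evaluation
  set.seed(77)
  x <- stats::rnorm(20); y <- stats::rnorm(20)
  tab3 <- pearson_matrix(data.frame(label = "S", x = x, y = y), "x", "y")
  r_ref <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(tab3$r, r_ref, tolerance = 1e-12)
  # symmetry and affine invariance
  tab4 <- pearson_matrix(data.frame(label = "S", x = y, y = x), "x", "y")
  expect_equal(tab4$r, tab3$r, tolerance = 1e-12)
  tab5 <- pearson_matrix(data.frame(label = "S", x = 3 * x + 7, y = -2 * y + 1),
                         "x", "y")
  expect_equal(tab5$r, -tab3$r, tolerance = 1e-12)
  # degenerate strata are reported, not computed
  z <- data.frame(label = "S", x = rep(1, 5), y = stats::rnorm(5))
  expect_true(is.na(pearson_matrix(z, "x", "y")$r))
  tiny <- data.frame(label = "S", x = c(1, 2), y = c(2, 1))
  expect_true(is.na(pearson_matrix(tiny, "x", "y")$r))
})

test_that("significance stars follow the p < 0.05 / p < 0.01 convention", {
  set.seed(5)
  n <- 40
  x <- stats::rnorm(n)
  d <- data.frame(label = "S", x = x, strong = x + stats::rnorm(n, 0, 0.2),
                  noise = stats::rnorm(n))
  tab <- pearson_matrix(d, "x", c("strong", "noise"))
  expect_equal(tab$sig[tab$response == "strong"], "**")
  expect_equal(tab$sig[tab$response == "noise"], "")
  expect_equal(tab$p[1], stats::cor.test(x, d$strong)$p.value)
})

test_that("single-predictor path coefficients equal Pearson r", {
  d <- make_driver_frame(80, seed = 3)
  pm <- fit_path_model(d)
  r_pg <- stats::cor(d$pmax, d$gep)
  pc_pg <- pm$direct$pc[pm$direct$from == "pmax" & pm$direct$to == "gep"]
  expect_equal(pc_pg, r_pg, tolerance = 1e-12)
})

test_that("orthogonal factor designs make each PC the marginal correlation", {
  set.seed(14)
  n <- 64
  # orthonormal columns, all orthogonal to the constant: exactly centred
  Q <- qr.Q(qr(cbind(1, matrix(stats::rnorm(n * 6), n, 6))))[, 2:7]
  Q <- scale(Q)
  d <- as.data.frame(Q)
  names(d) <- c("vpd", "prec", "par", "lai", "ta", "ts")
  set.seed(15)
  d$pmax <- 0.4 * d$ts + 0.3 * d$lai + stats::rnorm(n, 0, 0.5)
  d$re <- 0.5 * d$ta + stats::rnorm(n, 0, 0.5)
  d$gep <- 0.7 * d$pmax + stats::rnorm(n, 0, 0.3)
  d$nee <- -0.8 * d$gep + 0.4 * d$re + stats::rnorm(n, 0, 0.3)
  pm <- fit_path_model(d)
  for (f in c("vpd", "prec", "par", "lai", "ta", "ts")) {
    pc <- pm$direct$pc[pm$direct$from == f & pm$direct$to == "pmax"]
    expect_equal(pc, stats::cor(d[[f]], d$pmax), tolerance = 1e-8)
  }
})

test_that("indirect effects are exact chain products", {
  d <- make_driver_frame(100, seed = 4)
  pm <- fit_path_model(d)
  ind <- indirect_effects(pm)
  pc <- function(f, t) pm$direct$pc[pm$direct$from == f & pm$direct$to == t]
  for (k in seq_len(nrow(ind))) {
    f <- ind$factor[k]
    expect_equal(ind$via_pmax[k], pc(f, "pmax") * pc("pmax", "gep") * pc("gep", "nee"),
                 tolerance = 1e-12)
    expect_equal(ind$via_re[k], pc(f, "re") * pc("re", "nee"), tolerance = 1e-12)
    expect_equal(ind$total[k], ind$via_pmax[k] + ind$via_re[k], tolerance = 1e-12)
  }
  # a zero direct coefficient kills its chain
  pm0 <- pm
  pm0$direct$pc[pm0$direct$from == "vpd" & pm0$direct$to == "pmax"] <- 0
  expect_equal(indirect_effects(pm0)$via_pmax[1], 0)
})

test_that("path coefficients are recovered from linear-Gaussian structural data", {
  b_pmax <- c(vpd = -0.1, prec = 0.05, par = 0.2, lai = 0.3, ta = 0.25, ts = 0.4)
  b_re <- c(vpd = 0.1, prec = 0.1, par = 0.05, lai = 0.15, ta = 0.35, ts = 0.5)
  seeds <- 1:30
  rec <- vapply(seeds, function(s) {
    d <- simulate_path_data(500, seed = s)
    pm <- fit_path_model(d)
    pm$direct$pc[pm$direct$from == "ts" & pm$direct$to == "pmax"]
  }, numeric(1))
  mc_se <- stats::sd(rec)
  expect_lt(abs(mean(rec) - b_pmax["ts"]), 3 * mc_se / sqrt(length(seeds)))
  # single draw within 3 Monte-Carlo standard errors of the truth
  d1 <- simulate_path_data(500, seed = 99)
  pm1 <- fit_path_model(d1)
  for (f in names(b_pmax)) {
    pc <- pm1$direct$pc[pm1$direct$from == f & pm1$direct$to == "pmax"]
    expect_lt(abs(pc - b_pmax[[f]]), 3 * mc_se)
  }
})

test_that("small or singular strata are refused or fall back to ridge", {
  d <- make_driver_frame(10)
  expect_error(fit_path_model(d), "too small")
  d2 <- make_driver_frame(50, seed = 6)
  d2$prec <- d2$vpd               # perfectly collinear pair
  w <- capture_warnings(pm <- fit_path_model(d2))
  expect_true(any(grepl("ridge", w)))
  expect_s3_class(pm, "path_model")
})
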