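PATH_FACTORS <- c("vpd", "prec", "par", "lai", "ta", "ts")

#' Stratified Pearson correlation table
#'
#' Pearson's product-moment correlation between each driver and each
#' response within each stratum (phenology period or year class), computed
#' on pairwise-complete observations, with the two-sided p-value from the
#' t transform and the conventional significance stars (* p < 0.05,
#' ** p < 0.01).  A stratum pair with fewer than 3 complete observations, or
#' a zero-variance variable, is reported with `r = NA`.
#'
#' @param data data frame holding the factor and response columns plus a
#'   `label` column defining strata.
#' @param factors driver columns (default VPD, Prec, PAR, LAI, Ta, Ts).
#' @param responses response columns (e.g. NEE, RE, GEP, Pmax, alpha).
#' @param strata stratum labels to evaluate; defaults to all in `data`.
#' @return long data frame `stratum, factor, response, r, p, n, sig`.
#' @export
pearson_matrix <- function(data, factors = PATH_FACTORS,
                           responses = c("nee", "re", "gep"),
                           strata = unique(data$label)) {
  stopifnot(all(c(factors, responses, "label") %in% names(data)))
  out <- list()
  for (s in strata) {
    d <- data[data$label == s, , drop = FALSE]
    for (f in factors) for (y in responses) {
      ok <- !is.na(d[[f]]) & !is.na(d[[y]])
      n <- sum(ok)
      r <- p <- NA_real_
      if (n >= 3L && stats::sd(d[[f]][ok]) > 0 && stats::sd(d[[y]][ok]) > 0) {
        ct <- stats::cor.test(d[[f]][ok], d[[y]][ok], method = "pearson")
        r <- unname(ct$estimate)
        p <- ct$p.value
      }
      out[[length(out) + 1L]] <- data.frame(
        stratum = s, factor = f, response = y, r = r, p = p, n = n,
        sig = if (is.na(p)) "" else if (p < 0.01) "**" else if (p < 0.05) "*" else "")
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# Standardized OLS of y on columns X (all already z-scored); ridge fallback
# with penalty 1e-8 when the design is singular.
std_ols <- function(X, y) {
  X <- as.matrix(X)
  qrx <- qr(X)
  if (qrx$rank < ncol(X)) {
    warning("singular design; using ridge fallback (penalty 1e-8)")
    b <- solve(crossprod(X) + diag(1e-8, ncol(X)), crossprod(X, y))
    b <- drop(b)
  } else {
    b <- qr.coef(qrx, y)
  }
  names(b) <- colnames(X)
  fitted <- drop(X %*% b)
  r2 <- 1 - sum((y - fitted)^2) / sum(y^2)
  list(coef = b, r2 = r2)
}

#' Fit the structural path model of flux drivers
#'
#' Classic per-equation path analysis on z-standardized data for the
#' driver-attribution graph: the six abiotic/biotic factors each point to
#' Pmax and to RE; Pmax points to GEP; GEP and RE point to NEE.  Each
#' endogenous variable is regressed (ordinary least squares, no intercept)
#' on its parents after all variables are standardized within the stratum;
#' the standardized coefficients are the path coefficients (PCs).  Under
#' collinear factors PCs may exceed |1| (suppression); this is permitted and
#' flagged.  A perfectly singular design falls back to a tiny ridge penalty
#' with a warning.
#'
#' @param data data frame with the six factor columns plus `pmax`, `re`,
#'   `gep`, `nee` (one row per 5-day observation); rows with any missing
#'   value are dropped listwise.
#' @param min_n minimum complete rows (default 15).
#' @return object of class `path_model`: `direct` (data frame
#'   `from, to, pc`), `r2` per endogenous variable, `n`, and
#'   `suppression` flag (any |PC| > 1).
#' @export
fit_path_model <- function(data, min_n = 15L) {
  vars <- c(PATH_FACTORS, "pmax", "re", "gep", "nee")
  stopifnot(all(vars %in% names(data)))
  d <- data[stats::complete.cases(data[vars]), vars]
  if (nrow(d) < min_n) {
    stop("stratum too small for path analysis: n = ", nrow(d), " < ", min_n)
  }
  z <- as.data.frame(scale(d))
  if (any(!is.finite(as.matrix(z)))) stop("zero-variance variable in stratum")
  eq_pmax <- std_ols(z[PATH_FACTORS], z$pmax)
  eq_re <- std_ols(z[PATH_FACTORS], z$re)
  eq_gep <- std_ols(z["pmax"], z$gep)
  eq_nee <- std_ols(z[c("gep", "re")], z$nee)
  direct <- rbind(
    data.frame(from = PATH_FACTORS, to = "pmax", pc = unname(eq_pmax$coef)),
    data.frame(from = PATH_FACTORS, to = "re", pc = unname(eq_re$coef)),
    data.frame(from = "pmax", to = "gep", pc = unname(eq_gep$coef)),
    data.frame(from = c("gep", "re"), to = "nee", pc = unname(eq_nee$coef)))
  structure(list(direct = direct,
                 r2 = c(pmax = eq_pmax$r2, re = eq_re$r2,
                        gep = eq_gep$r2, nee = eq_nee$r2),
                 n = nrow(d),
                 suppression = any(abs(direct$pc) > 1)),
            class = "path_model")
}

#' @export
print.path_model <- function(x, ...) {
  cat("<path_model> n =", x$n, "\n")
  print(x$direct, digits = 3)
  cat("R2:", paste(names(x$r2), round(x$r2, 3), sep = "=", collapse = ", "), "\n")
  if (x$suppression) cat("note: |PC| > 1 present (collinearity/suppression)\n")
  invisible(x)
}

# Look up one direct coefficient.
pc_of <- function(pm, from, to) {
  hit <- pm$direct$from == from & pm$direct$to == to
  if (!any(hit)) stop("no arrow ", from, " -> ", to)
  pm$direct$pc[hit]
}

#' Indirect effects of each driver on NEE
#'
#' Chain products along the two causal routes of the path model: the
#' photosynthetic chain factor -> Pmax -> GEP -> NEE and the respiration
#' chain factor -> RE -> NEE.  Each indirect effect is exactly the product
#' of its chain's direct coefficients; the total is their sum.
#'
#' @param pm a fitted [fit_path_model()] result.
#' @return data frame `factor, via_pmax, via_re, total`.
#' @export
indirect_effects <- function(pm) {
  stopifnot(inherits(pm, "path_model"))
  pg <- pc_of(pm, "pmax", "gep")
  gn <- pc_of(pm, "gep", "nee")
  rn <- pc_of(pm, "re", "nee")
  via_pmax <- vapply(PATH_FACTORS, function(f) pc_of(pm, f, "pmax") * pg * gn,
                     numeric(1))
  via_re <- vapply(PATH_FACTORS, function(f) pc_of(pm, f, "re") * rn,
                   numeric(1))
  data.frame(factor = PATH_FACTORS, via_pmax = unname(via_pmax),
             via_re = unname(via_re), total = unname(via_pmax + via_re))
}

#' Simulate linear-Gaussian data from the path graph
#'
#' Draws the six factors as independent standard normals, then generates
#' each endogenous variable from its parents with the supplied standardized
#' coefficients plus Gaussian noise scaled so every variable has unit
#' variance — the generating coefficients are then exactly the population
#' path coefficients, giving a recovery oracle for [fit_path_model()].
#'
#' @param n sample size.
#' @param coef_pmax,coef_re named length-6 coefficient vectors (factors to
#'   Pmax / RE); their squared norms must be < 1.
#' @param coef_gep scalar Pmax -> GEP coefficient (|.| < 1).
#' @param coef_nee named length-2 vector `c(gep, re)`; `t(b) S b < 1` where
#'   S is the implied gep/re covariance.
#' @param seed RNG seed.
#' @return data frame with factors and `pmax`, `re`, `gep`, `nee`.
#' @export
simulate_path_data <- function(n,
                               coef_pmax = c(vpd = -0.1, prec = 0.05, par = 0.2,
                                             lai = 0.3, ta = 0.25, ts = 0.4),
                               coef_re = c(vpd = 0.1, prec = 0.1, par = 0.05,
                                           lai = 0.15, ta = 0.35, ts = 0.5),
                               coef_gep = 0.7,
                               coef_nee = c(gep = -0.8, re = 0.4),
                               seed = 1L) {
  set.seed(as.integer(seed))
  X <- matrix(stats::rnorm(n * 6), n, 6,
              dimnames = list(NULL, PATH_FACTORS))
  resid_sd <- function(explained_var) {
    if (explained_var >= 1) stop("coefficients imply explained variance >= 1")
    sqrt(1 - explained_var)
  }
  pmax <- drop(X %*% coef_pmax) +
    stats::rnorm(n, 0, resid_sd(sum(coef_pmax^2)))
  re <- drop(X %*% coef_re) +
    stats::rnorm(n, 0, resid_sd(sum(coef_re^2)))
  gep <- coef_gep * pmax + stats::rnorm(n, 0, resid_sd(coef_gep^2))
  # population covariance of (gep, re): cov = coef_gep * b_pmax' b_re
  cov_gr <- coef_gep * sum(coef_pmax * coef_re)
  expl <- coef_nee["gep"]^2 + coef_nee["re"]^2 +
    2 * coef_nee["gep"] * coef_nee["re"] * cov_gr
  nee <- drop(cbind(gep, re) %*% coef_nee) +
    stats::rnorm(n, 0, resid_sd(unname(expl)))
  data.frame(X, pmax = pmax, re = re, gep = gep, nee = nee)
}
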