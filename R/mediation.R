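#' Single-mediator path model with bootstrap inference
#'
#' Fits the triangular mediation model for an exposure `x`, mediator `m`
#' and outcome `y` (e.g. baseline WMH volume -> global network efficiency
#' -> dementia): path *a* from the linear model `m ~ x + covariates`,
#' paths *b* and *c'* (direct effect) from `y ~ m + x + covariates`.
#' The indirect effect is the product `a * b`. Continuous variables are
#' standardized on the analysed complete cases, so paths are standardized
#' estimates.
#'
#' A binary outcome (`y_binary = TRUE`) is modelled by default as a
#' linear-probability model on the 0/1 indicator, which keeps the
#' `a * b` product identity and the effect decomposition exact; a probit
#' outcome model is available via `estimator = "probit"` (its indirect
#' effect lives on the latent scale and the decomposition is then only
#' approximate).
#'
#' Inference for the indirect and direct effects uses a nonparametric
#' percentile bootstrap resampling subjects (default 2000 resamples),
#' with standardization recomputed within every resample; the classical
#' Sobel normal-theory test is also reported as a cross-check.
#'
#' @param x,m,y Numeric vectors: exposure, mediator, outcome (0/1 when
#'   `y_binary`).
#' @param covariates Optional data frame of adjustment covariates;
#'   numeric covariates are standardized, factors enter as-is.
#' @param y_binary Logical; `TRUE` leaves `y` unstandardized and (with the
#'   default estimator) fits a linear-probability outcome model.
#' @param n_boot Number of bootstrap resamples; at least 500 are required
#'   for confidence intervals (fewer fits the point estimates only, with a
#'   warning).
#' @param seed Integer seed making the bootstrap reproducible.
#' @param estimator `"lpm"` (default) or `"probit"` for the outcome model
#'   when `y_binary`.
#' @param conf_level Confidence level for all intervals.
#' @return Object of class `mediation_fit`: `paths` (data frame with rows
#'   a, b, c_prime, total: estimate, se, p_value), `indirect` (point
#'   estimate `a*b`), `boot` (percentile CIs and bootstrap p-values for
#'   the indirect and direct effects), `sobel` (z and p), `n`, `n_boot`,
#'   `seed`.
#' @examples
#' set.seed(1)
#' x <- rnorm(200); m <- 0.5 * x + rnorm(200, sd = sqrt(0.75))
#' y <- 0.4 * m + 0.1 * x + rnorm(200, sd = sqrt(0.79))
#' fit_mediation(x, m, y, n_boot = 500, seed = 1)
#' @export
fit_mediation <- function(x, m, y, covariates = NULL, y_binary = FALSE,
                          n_boot = 2000, seed = 1,
                          estimator = c("lpm", "probit"),
                          conf_level = 0.95) {
  estimator <- match.arg(estimator)
  if (!y_binary) estimator <- "lpm"
  dat <- data.frame(x = x, m = m, y = y)
  has_cov <- !is.null(covariates) && ncol(as.data.frame(covariates)) > 0
  if (has_cov) {
    covariates <- as.data.frame(covariates)
    dat <- cbind(dat, covariates)
  }
  cc <- stats::complete.cases(dat)
  dat <- dat[cc, , drop = FALSE]
  n <- nrow(dat)
  if (n < 30L) stop("need at least 30 complete cases, got ", n)
  if (y_binary && !all(dat$y %in% c(0, 1)))
    stop("`y` must be 0/1 when y_binary = TRUE")
  do_ci <- n_boot >= 500
  if (n_boot > 0 && !do_ci)
    warning("n_boot < 500: bootstrap confidence intervals are suppressed")

  cov_names <- if (has_cov) names(covariates) else character()
  point <- mediation_paths(dat, cov_names, y_binary, estimator)

  boot <- NULL
  if (n_boot > 0) {
    stats_b <- with_seed(seed, {
      if (!has_cov && estimator == "lpm") {
        idx <- matrix(sample.int(n, n * n_boot, replace = TRUE), n_boot, n)
        mediation_boot_fast(dat$x, dat$m, dat$y, idx, y_binary)
      } else {
        t(vapply(seq_len(n_boot), function(b) {
          i <- sample.int(n, n, replace = TRUE)
          p <- tryCatch(
            mediation_paths(dat[i, , drop = FALSE], cov_names, y_binary,
                            estimator, se = FALSE),
            error = function(e) NULL)
          if (is.null(p)) c(NA_real_, NA_real_)
          else c(p$est[["a"]] * p$est[["b"]], p$est[["c_prime"]])
        }, numeric(2)))
      }
    })
    indirect_b <- stats_b[, 1L]
    direct_b <- stats_b[, 2L]
    ok <- is.finite(indirect_b) & is.finite(direct_b)
    alpha <- (1 - conf_level) / 2
    pctl <- function(v) unname(stats::quantile(v[ok], c(alpha, 1 - alpha)))
    boot_p <- function(v) min(1, 2 * min(mean(v[ok] <= 0), mean(v[ok] >= 0)))
    boot <- list(
      indirect_ci = if (do_ci) pctl(indirect_b) else c(NA_real_, NA_real_),
      indirect_p = boot_p(indirect_b),
      direct_ci = if (do_ci) pctl(direct_b) else c(NA_real_, NA_real_),
      direct_p = boot_p(direct_b),
      n_effective = sum(ok))
  }

  # Sobel normal-theory cross-check for the indirect effect
  a <- point$est[["a"]]; b <- point$est[["b"]]
  se_a <- point$se[["a"]]; se_b <- point$se[["b"]]
  sobel_se <- sqrt(b^2 * se_a^2 + a^2 * se_b^2)
  sobel_z <- (a * b) / sobel_se
  paths <- data.frame(
    path = c("a", "b", "c_prime", "total"),
    estimate = unname(point$est[c("a", "b", "c_prime", "total")]),
    se = unname(point$se[c("a", "b", "c_prime", "total")]),
    p_value = unname(point$p[c("a", "b", "c_prime", "total")]),
    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(paths = paths, indirect = a * b, boot = boot,
                 sobel = list(z = sobel_z,
                              p = 2 * stats::pnorm(-abs(sobel_z))),
                 n = n, n_boot = n_boot, seed = seed,
                 y_binary = y_binary, estimator = estimator,
                 covariates = cov_names, conf_level = conf_level),
            class = "mediation_fit")
}

# Point fits of the two mediation regressions on one data set.
# Standardizes x, m (and y unless binary) and numeric covariates in-sample.
mediation_paths <- function(dat, cov_names, y_binary, estimator, se = TRUE) {
  zs <- function(v) {
    s <- stats::sd(v)
    if (is.na(s) || s == 0) stop("zero-variance column in mediation fit")
    (v - mean(v)) / s
  }
  dat$x <- zs(dat$x)
  dat$m <- zs(dat$m)
  if (!y_binary) dat$y <- zs(dat$y)
  for (v in cov_names) if (is.numeric(dat[[v]])) dat[[v]] <- zs(dat[[v]])
  f_a <- stats::reformulate(c("x", cov_names), response = "m")
  f_y <- stats::reformulate(c("m", "x", cov_names), response = "y")
  f_t <- stats::reformulate(c("x", cov_names), response = "y")
  fa <- stats::lm(f_a, data = dat)
  fy <- if (estimator == "probit")
    stats::glm(f_y, data = dat, family = stats::binomial("probit"))
  else stats::lm(f_y, data = dat)
  ft <- if (estimator == "probit")
    stats::glm(f_t, data = dat, family = stats::binomial("probit"))
  else stats::lm(f_t, data = dat)
  grab <- function(fit, term) {
    sm <- summary(fit)$coefficients
    pcol <- grep("^Pr\\(", colnames(sm))
    c(est = sm[term, 1L], se = sm[term, 2L], p = sm[term, pcol])
  }
  ga <- grab(fa, "x"); gb <- grab(fy, "m"); gc <- grab(fy, "x")
  gt <- grab(ft, "x")
  list(est = c(a = ga[["est"]], b = gb[["est"]], c_prime = gc[["est"]],
               total = gt[["est"]]),
       se = c(a = ga[["se"]], b = gb[["se"]], c_prime = gc[["se"]],
              total = gt[["se"]]),
       p = c(a = ga[["p"]], b = gb[["p"]], c_prime = gc[["p"]],
             total = gt[["p"]]))
}

# Vectorized bootstrap for the covariate-free linear case: all paths are
# closed-form functions of per-resample means/covariances.
mediation_boot_fast <- function(x, m, y, idx, y_binary) {
  n <- length(x)
  xb <- matrix(x[idx], nrow(idx), n)
  mb <- matrix(m[idx], nrow(idx), n)
  yb <- matrix(y[idx], nrow(idx), n)
  mx <- rowMeans(xb); mm <- rowMeans(mb); my <- rowMeans(yb)
  sxx <- rowMeans(xb * xb) - mx^2
  smm <- rowMeans(mb * mb) - mm^2
  syy <- rowMeans(yb * yb) - my^2
  sxm <- rowMeans(xb * mb) - mx * mm
  sxy <- rowMeans(xb * yb) - mx * my
  smy <- rowMeans(mb * yb) - mm * my
  sdx <- sqrt(sxx); sdm <- sqrt(smm)
  r_xm <- sxm / (sdx * sdm)
  a <- r_xm
  # y regressed on standardized m and x; y itself standardized unless binary
  ys <- if (y_binary) 1 else sqrt(syy)
  u <- smy / (sdm * ys)
  v <- sxy / (sdx * ys)
  den <- 1 - r_xm^2
  b <- (u - v * r_xm) / den
  c_prime <- (v - u * r_xm) / den
  cbind(indirect = a * b, direct = c_prime)
}

#' @export
print.mediation_fit <- function(x, digits = 3, ...) {
  cat(sprintf("Mediation model (n = %d, %s outcome, %d bootstrap resamples)\n",
              x$n, if (x$y_binary) "binary" else "continuous", x$n_boot))
  p <- x$paths
  for (i in seq_len(nrow(p)))
    cat(sprintf("  %-8s %8s (se %s, p = %s)\n", p$path[i],
                format(p$estimate[i], digits = digits),
                format(p$se[i], digits = digits),
                format.pval(p$p_value[i], digits = digits)))
  cat(sprintf("  indirect (a*b) = %s", format(x$indirect, digits = digits)))
  if (!is.null(x$boot)) {
    cat(sprintf("; %d%% boot CI [%s, %s], p = %s",
                round(100 * x$conf_level),
                format(x$boot$indirect_ci[1], digits = digits),
                format(x$boot$indirect_ci[2], digits = digits),
                format.pval(x$boot$indirect_p, digits = digits)))
  }
  cat("\n")
  invisible(x)
}

#' @export
coef.mediation_fit <- function(object, ...) {
  stats::setNames(c(object$paths$estimate, object$indirect),
                  c(object$paths$path, "indirect"))
}
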