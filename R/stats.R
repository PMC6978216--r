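#' Paired change test between baseline and follow-up
#'
#' Tests the mean within-subject change (follow-up minus baseline) with a
#' paired t test, reporting the mean difference with its 95% confidence
#' interval and p-value. With two time points this is exactly the
#' repeated-measures ANOVA time effect (F = t^2).
#'
#' @param baseline,followup Paired numeric vectors (same subjects, same
#'   order); pairs with a missing value are dropped.
#' @param conf_level Confidence level (default 0.95).
#' @return An object of class `change_test` with elements `estimate`
#'   (mean difference), `ci` (length-2), `p_value`, `statistic` (t), `F`
#'   (= t^2), `df` and `n`.
#' @export
paired_change_test <- function(baseline, followup, conf_level = 0.95) {
  if (length(baseline) != length(followup))
    stop("baseline and follow-up must have the same length")
  d <- followup - baseline
  d <- d[!is.na(d)]
  if (length(d) < 3L) stop("need at least 3 complete pairs")
  if (stats::sd(d) == 0) {
    # degenerate case: all change scores identical
    m <- mean(d)
    return(structure(list(estimate = m, ci = c(m, m),
                          p_value = if (m == 0) 1 else 0,
                          statistic = if (m == 0) 0 else sign(m) * Inf,
                          F = if (m == 0) 0 else Inf,
                          df = length(d) - 1L, n = length(d),
                          conf_level = conf_level),
                     class = "change_test"))
  }
  tt <- stats::t.test(d, conf.level = conf_level)
  structure(list(estimate = unname(tt$estimate),
                 ci = unname(tt$conf.int),
                 p_value = tt$p.value,
                 statistic = unname(tt$statistic),
                 F = unname(tt$statistic)^2,
                 df = unname(tt$parameter),
                 n = length(d),
                 conf_level = conf_level),
            class = "change_test")
}

#' @export
print.change_test <- function(x, digits = 3, ...) {
  cat(sprintf("Mean change %s [%s - %s]; t(%d) = %s, p = %s (n = %d)\n",
              format(x$estimate, digits = digits),
              format(x$ci[1], digits = digits),
              format(x$ci[2], digits = digits),
              x$df, format(x$statistic, digits = digits),
              format.pval(x$p_value, digits = digits), x$n))
  invisible(x)
}

#' Group-by-time interaction for a two-wave, two-group design
#'
#' Tests whether the within-subject change differs between two groups
#' (e.g. mild vs severe white matter hyperintensity burden), via the
#' group x time interaction of a repeated-measures ANOVA on the long-format
#' data with a within-subject error stratum. For two waves this is
#' equivalent to a two-sample t test on the per-subject change scores.
#'
#' @param baseline,followup Paired numeric vectors.
#' @param group Two-level factor (or coercible) of group labels, one per
#'   subject; each group needs at least 3 complete pairs.
#' @return List with `p_value`, `F`, `df` (c(1, error df)) and `n`.
#' @export
group_time_interaction <- function(baseline, followup, group) {
  if (length(baseline) != length(followup) ||
      length(group) != length(baseline))
    stop("baseline, follow-up and group must have the same length")
  group <- factor(group)
  keep <- !is.na(baseline) & !is.na(followup) & !is.na(group)
  baseline <- baseline[keep]; followup <- followup[keep]
  group <- droplevels(group[keep])
  if (nlevels(group) != 2L) stop("`group` must have exactly two levels")
  if (any(table(group) < 3L)) stop("each group needs at least 3 subjects")
  n <- length(baseline)
  long <- data.frame(
    y = c(baseline, followup),
    time = factor(rep(c("baseline", "followup"), each = n)),
    group = rep(group, 2L),
    subject = factor(rep(seq_len(n), 2L)))
  fit <- stats::aov(y ~ group * time + Error(subject), data = long)
  tab <- summary(fit)[["Error: Within"]][[1L]]
  row <- grep("group:time", rownames(tab))
  structure(list(p_value = tab[row, "Pr(>F)"],
                 F = tab[row, "F value"],
                 df = c(tab[row, "Df"], tab[nrow(tab), "Df"]),
                 n = n),
            class = "interaction_test")
}

#' @export
print.interaction_test <- function(x, digits = 3, ...) {
  cat(sprintf("Group x time interaction: F(%d, %d) = %s, p = %s (n = %d)\n",
              x$df[1], x$df[2], format(x$F, digits = digits),
              format.pval(x$p_value, digits = digits), x$n))
  invisible(x)
}

#' Covariate-adjusted group difference (ANCOVA)
#'
#' Estimates the difference in `y` between two groups adjusted for
#' covariates, as the group coefficient of the linear model
#' `y ~ group + covariates` — the "one-way ANOVA adjusted for age and sex"
#' of cohort neuroimaging studies.
#'
#' @param y Numeric outcome.
#' @param group Two-level factor; the reported difference is level 2 minus
#'   level 1.
#' @param covariates Data frame of adjustment covariates (or `NULL`).
#' @param conf_level Confidence level.
#' @return A `change_test`-like object: adjusted mean difference, CI,
#'   p-value, n.
#' @export
adjusted_group_difference <- function(y, group, covariates = NULL,
                                      conf_level = 0.95) {
  group <- factor(group)
  dat <- data.frame(y = y, group = group)
  if (!is.null(covariates)) dat <- cbind(dat, as.data.frame(covariates))
  dat <- dat[stats::complete.cases(dat), , drop = FALSE]
  dat$group <- droplevels(dat$group)
  if (nlevels(dat$group) != 2L)
    stop("`group` must have exactly two levels after removing missing data")
  fit <- stats::lm(y ~ ., data = dat)
  if (fit$rank < ncol(stats::model.matrix(fit)))
    stop("covariate matrix is rank deficient")
  co <- grep("^group", names(stats::coef(fit)), value = TRUE)
  est <- stats::coef(fit)[[co]]
  ci <- stats::confint(fit, co, level = conf_level)
  p <- summary(fit)$coefficients[co, "Pr(>|t|)"]
  structure(list(estimate = est, ci = as.numeric(ci), p_value = p,
                 statistic = summary(fit)$coefficients[co, "t value"],
                 F = summary(fit)$coefficients[co, "t value"]^2,
                 df = fit$df.residual, n = nrow(dat),
                 conf_level = conf_level),
            class = "change_test")
}

#' Standardized-beta linear regression
#'
#' z-scores the outcome and the continuous predictors (and continuous
#' covariates) on the analysed complete cases, fits ordinary least
#' squares, and reports standardized regression coefficients (beta) with
#' 95% confidence intervals and p-values — the effect-size scale of
#' epidemiological association tables. Categorical covariates enter
#' unstandardized.
#'
#' @param y Numeric outcome.
#' @param predictors Data frame (or named list) of predictors of interest.
#' @param covariates Optional data frame of adjustment covariates.
#' @param conf_level Confidence level.
#' @return Object of class `std_regression`: `coefficients` data frame
#'   (term, beta, ci_low, ci_high, p_value), `n`, `r_squared`, plus the
#'   underlying `lm` fit.
#' @export
standardized_regression <- function(y, predictors, covariates = NULL,
                                    conf_level = 0.95) {
  predictors <- as.data.frame(predictors)
  dat <- cbind(data.frame(.y = y), predictors)
  if (!is.null(covariates)) dat <- cbind(dat, as.data.frame(covariates))
  dat <- dat[stats::complete.cases(dat), , drop = FALSE]
  if (nrow(dat) < ncol(dat) + 2L) stop("too few complete cases")
  scale_cols <- c(".y", names(predictors),
                  if (!is.null(covariates))
                    names(covariates)[vapply(as.data.frame(covariates),
                                             is.numeric, TRUE)])
  for (v in intersect(scale_cols, names(dat))) {
    if (!is.numeric(dat[[v]])) next
    s <- stats::sd(dat[[v]])
    if (is.na(s) || s == 0)
      stop("zero-variance column: `", sub("^\\.y$", "y", v), "`")
    dat[[v]] <- (dat[[v]] - mean(dat[[v]])) / s
  }
  fit <- stats::lm(.y ~ ., data = dat)
  sm <- summary(fit)$coefficients
  ci <- stats::confint(fit, level = conf_level)
  terms <- setdiff(rownames(sm), "(Intercept)")
  coefs <- data.frame(term = terms,
                      beta = sm[terms, "Estimate"],
                      ci_low = ci[terms, 1L],
                      ci_high = ci[terms, 2L],
                      p_value = sm[terms, "Pr(>|t|)"],
                      row.names = NULL, stringsAsFactors = FALSE)
  structure(list(coefficients = coefs,
                 predictors = names(predictors),
                 covariates = if (is.null(covariates)) character()
                              else names(as.data.frame(covariates)),
                 n = nrow(dat), r_squared = summary(fit)$r.squared,
                 fit = fit),
            class = "std_regression")
}

#' @export
print.std_regression <- function(x, digits = 3, ...) {
  cat("Standardized linear regression (n =", x$n, ")\n")
  cf <- x$coefficients
  cf$stars <- significance_stars(cf$p_value)
  print(format(cf, digits = digits), row.names = FALSE)
  invisible(x)
}

#' @export
coef.std_regression <- function(object, ...) {
  stats::setNames(object$coefficients$beta, object$coefficients$term)
}

#' @export
summary.std_regression <- function(object, ...) object$coefficients

#' Median split into mild and severe strata
#'
#' Dichotomises a severity marker (typically baseline white matter
#' hyperintensity volume) at its median: values at or below the median are
#' `mild`, values above are `severe`. Ties with the median deliberately go
#' to the mild stratum.
#'
#' @param values Numeric vector; at least 2 non-missing, not all equal.
#' @return Factor with levels `mild`, `severe` (`NA` where `values` is
#'   missing).
#' @export
median_split <- function(values) {
  ok <- !is.na(values)
  if (sum(ok) < 2L) stop("need at least 2 non-missing values")
  med <- stats::median(values[ok])
  if (all(values[ok] == values[ok][1L]))
    stop("all values identical: median split undefined")
  factor(ifelse(values <= med, "mild", "severe"),
         levels = c("mild", "severe"))
}

#' Natural-log transform of WMH volume
#'
#' White matter hyperintensity volumes are strongly right-skewed;
#' regression analyses use their natural logarithm.
#'
#' @param volume_ml Positive volume(s) in ml.
#' @return `log(volume_ml)`.
#' @export
log_transform_wmh <- function(volume_ml) {
  if (any(!is.na(volume_ml) & volume_ml <= 0))
    stop("WMH volume must be strictly positive")
  log(volume_ml)
}
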