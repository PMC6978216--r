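test_that("paired change test: degenerate and identity cases", {
  x <- c(1, 2, 3, 4, 5)
  ct0 <- paired_change_test(x, x + 0)
  expect_equal(ct0$estimate, 0)
  expect_equal(ct0$p_value, 1)
  expect_error(paired_change_test(x[1:2], x[1:2]), "3 complete pairs")
  expect_error(paired_change_test(x, x[1:3]), "same length")

  set.seed(31)
  bl <- rnorm(20)
  fu <- bl + rnorm(20, -0.3)
  ct <- paired_change_test(bl, fu)
  expect_true(ct$ci[1] <= ct$estimate && ct$estimate <= ct$ci[2])
  expect_equal(ct$F, ct$statistic^2)
})

test_that("paired t equals the repeated-measures ANOVA time effect (F = t^2)", {
  set.seed(32)
  for (rep in 1:40) {
    n <- sample(4:30, 1)
    bl <- rnorm(n)
    fu <- bl + rnorm(n, sd = runif(1, 0.2, 2)) + runif(1, -1, 1)
    ct <- paired_change_test(bl, fu)
    long <- data.frame(y = c(bl, fu),
                       time = factor(rep(1:2, each = n)),
                       subject = factor(rep(1:n, 2)))
    fit <- stats::aov(y ~ time + Error(subject), data = long)
    tab <- summary(fit)[["Error: Within"]][[1]]
    expect_equal(ct$F, tab["time", "F value"], tolerance = 1e-8)
    expect_equal(ct$p_value, tab["time", "Pr(>F)"], tolerance = 1e-8)
  }
})

test_that("group x time interaction equals the two-sample t test on deltas", {
  set.seed(33)
  for (rep in 1:40) {
    n1 <- sample(3:20, 1); n2 <- sample(3:20, 1)
    g <- rep(c("a", "b"), c(n1, n2))
    bl <- rnorm(n1 + n2)
    fu <- bl + rnorm(n1 + n2) + ifelse(g == "a", 0, runif(1, -1, 1))
    it <- group_time_interaction(bl, fu, g)
    tt <- stats::t.test(I(fu - bl) ~ g, var.equal = TRUE)
    expect_equal(it$p_value, tt$p.value, tolerance = 1e-8)
    expect_equal(it$F, unname(tt$statistic)^2, tolerance = 1e-8)
  }
  expect_error(group_time_interaction(rnorm(5), rnorm(5),
                                      c("a", "a", "a", "a", "b")),
               "at least 3")
})

test_that("interaction power: injected differential decline is detected", {
  set.seed(34)
  hits <- 0
  for (rep in 1:60) {
    n <- 100
    g <- rep(c("a", "b"), each = n)
    bl <- rnorm(2 * n)
    fu <- bl + rnorm(2 * n, sd = 0.5) + ifelse(g == "a", -0.3, 0)
    if (group_time_interaction(bl, fu, g)$p_value < 0.05) hits <- hits + 1
  }
  expect_gte(hits / 60, 0.8)
})

test_that("adjusted group difference recovers the truth under confounding", {
  set.seed(35)
  n <- 400
  # orthogonal covariate: coefficient equals the crude difference
  g <- factor(rep(c("x", "y"), each = n / 2))
  cov_orth <- rep(c(-1, 1), n / 2)  # balanced within groups
  y <- 2 * (g == "y") + 0.5 * cov_orth + rnorm(n, sd = 0.1)
  adj <- adjusted_group_difference(y, g, data.frame(c1 = cov_orth))
  expect_equal(adj$estimate, 2, tolerance = 0.05)

  # outcome depends only on the covariate -> group coefficient near 0
  y2 <- 0.8 * cov_orth + rnorm(n, sd = 0.1)
  adj2 <- adjusted_group_difference(y2, g, data.frame(c1 = cov_orth))
  expect_lt(abs(adj2$estimate), 0.05)

  # confounded design: adjusted estimate is closer to truth than crude
  age <- rnorm(n, 68, 8)
  p_severe <- plogis((age - 68) / 4)
  grp <- factor(ifelse(runif(n) < p_severe, "severe", "mild"),
                levels = c("mild", "severe"))
  y3 <- 1.0 * (grp == "severe") + 0.3 * age + rnorm(n)
  crude <- mean(y3[grp == "severe"]) - mean(y3[grp == "mild"])
  adj3 <- adjusted_group_difference(y3, grp, data.frame(age = age))
  expect_lt(abs(adj3$estimate - 1.0), abs(crude - 1.0))
  expect_error(
    adjusted_group_difference(y3, grp,
                              data.frame(age = age, age2 = 2 * age)),
    "rank")
})

test_that("standardized regression returns unit beta for self-regression", {
  set.seed(36)
  x <- rnorm(50)
  # a perfect fit: lm warns about essentially zero residuals
  fit <- suppressWarnings(standardized_regression(x, data.frame(x = x)))
  expect_equal(unname(coef(fit)[["x"]]), 1, tolerance = 1e-12)
  fit2 <- suppressWarnings(standardized_regression(-x, data.frame(x = x)))
  expect_equal(unname(coef(fit2)[["x"]]), -1, tolerance = 1e-12)
  expect_error(standardized_regression(x, data.frame(z = rep(1, 50))),
               "zero-variance.*z")
})

test_that("standardized regression recovers a known beta with covariates", {
  set.seed(37)
  est <- replicate(60, {
    n <- 270
    x <- rnorm(n)
    age <- rnorm(n)
    y <- 0.3 * x + 0.2 * age + rnorm(n, sd = sqrt(1 - 0.09 - 0.04))
    coef(standardized_regression(y, data.frame(x = x),
                                 data.frame(age = age)))[["x"]]
  })
  expect_lt(abs(mean(est) - 0.3), 0.03)
})

test_that("median split labels and tie rule", {
  s <- median_split(c(1, 2, 3, 4))
  expect_equal(as.character(s), c("mild", "mild", "severe", "severe"))
  # ties with the median go to mild
  s2 <- median_split(c(1, 2, 2, 9))
  expect_equal(as.character(s2), c("mild", "mild", "mild", "severe"))
  expect_error(median_split(c(2, 2, 2)), "identical")
  expect_error(median_split(c(1, NA)), "non-missing")
  s3 <- median_split(c(5, NA, 1, 9, 7))
  expect_true(is.na(s3[2]))
})

test_that("WMH log transform is the natural log and rejects nonpositive volumes", {
  expect_equal(log_transform_wmh(1), 0)
  expect_equal(log_transform_wmh(exp(1)), 1)
  v <- c(0.3, 2.8, 7.8, 40)
  expect_equal(order(log_transform_wmh(v)), order(v))
  expect_error(log_transform_wmh(0), "positive")
})
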