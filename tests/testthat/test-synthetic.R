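small_config <- function(...) cohort_config(n_subjects = 30, ...)

test_that("the same config and seed reproduce the cohort exactly", {
  c1 <- generate_cohort(small_config(), seed = 5)
  c2 <- generate_cohort(small_config(), seed = 5)
  expect_identical(c1$cohort, c2$cohort)
  expect_identical(c1$networks[["S0001"]]$baseline$weights,
                   c2$networks[["S0001"]]$baseline$weights)
  c3 <- generate_cohort(small_config(), seed = 6)
  expect_false(identical(c1$cohort$wmh_ml, c3$cohort$wmh_ml))
})

test_that("an all-zero decline model leaves follow-up matrices identical", {
  cfg <- small_config(
    decline_mean = c(rich_club = 0, feeder = 0, peripheral = 0),
    decline_sd = c(rich_club = 0, feeder = 0, peripheral = 0))
  co <- generate_cohort(cfg, seed = 8)
  for (s in c("S0001", "S0015", "S0030"))
    expect_equal(co$networks[[s]]$followup$weights,
                 co$networks[[s]]$baseline$weights)
})

test_that("log-normal WMH calibration matches the configured median and IQR", {
  fit <- lognormal_from_median_iqr(2.8, c(1.3, 7.8))
  expect_equal(exp(fit$meanlog), 2.8)
  q <- qlnorm(c(0.25, 0.75), fit$meanlog, fit$sdlog)
  expect_equal(q[2] / q[1], 7.8 / 1.3, tolerance = 1e-12)

  co <- generate_cohort(cohort_config(n_subjects = 1500), seed = 9,
                        networks = FALSE)
  wmh <- co$cohort$wmh_ml[co$cohort$wave == "baseline"]
  expect_lt(abs(median(wmh) - 2.8) / 2.8, 0.1)
})

test_that("generated rich-club regions rank among the top-12 degrees", {
  frac_ok <- vapply(1:5, function(sd_) {
    co <- generate_cohort(cohort_config(n_subjects = 12), seed = sd_)
    mean(vapply(co$networks, function(nets)
      attr(degree_rank_report(nets$baseline), "all_in_top_k"), TRUE))
  }, 0)
  expect_gte(mean(frac_ok), 0.95)
})

test_that("per-subject-wave matrices respect the edge threshold", {
  co <- generate_cohort(small_config(), seed = 10)
  for (s in c("S0002", "S0020")) for (wv in c("baseline", "followup")) {
    w <- co$networks[[s]][[wv]]$weights
    expect_true(all(w[w != 0] >= co$config$threshold))
    expect_equal(w, t(w))
    expect_true(all(diag(w) == 0))
  }
})

test_that("injected class declines are recovered by the pipeline's change test", {
  co <- generate_cohort(cohort_config(n_subjects = 120), seed = 11)
  meas <- co$network_measures
  for (cl in c("rich_club", "feeder", "peripheral")) {
    v <- paste0(cl, "_strength")
    bl <- meas[[v]][meas$wave == "baseline"]
    fu <- meas[[v]][meas$wave == "followup"]
    ct <- paired_change_test(bl, fu)
    truth <- co$config$decline_mean[[cl]]
    se <- co$config$decline_sd[[cl]] / sqrt(120)
    expect_lt(abs(ct$estimate - truth), 4 * se)
  }
  # the generator's internal measures agree with the metrics module
  m1 <- network_metric_profile(co$networks[["S0001"]]$baseline)
  for (v in c("rich_club_strength", "feeder_strength",
              "peripheral_strength", "global_efficiency"))
    expect_equal(m1[[v]],
                 meas[[v]][meas$subject_id == "S0001" &
                             meas$wave == "baseline"])
})

test_that("streamline inversion is an exact right inverse of the builder", {
  p <- parcellation(c("A", "B"))
  w <- matrix(0, 2, 2)
  w[1, 2] <- w[2, 1] <- 0.75
  m <- svdnet:::new_connectivity_matrix(w, p, 0)
  s1 <- streamlines_for_matrix(m, k = 1)
  expect_equal(s1$records$length, 4 / 3)
  expect_equal(build_connectivity_matrix(s1, p, 0)$weights, m$weights)

  set.seed(13)
  wr <- random_weights(8, 0.5)
  mr <- make_cm(wr)
  for (k in c(1L, 3L)) {
    sk <- streamlines_for_matrix(mr, k = k, scale = 1.7)
    rebuilt <- build_connectivity_matrix(sk, mr$parcellation, 0)
    expect_equal(rebuilt$weights, mr$weights, tolerance = 1e-9)
  }
  sj <- streamlines_for_matrix(mr, k = 4, jitter = TRUE, seed = 3)
  expect_equal(build_connectivity_matrix(sj, mr$parcellation, 0)$weights,
               mr$weights, tolerance = 1e-9)
})

test_that("raw-test mode produces a battery whose composites track the truth", {
  co <- generate_cohort(small_config(), seed = 14, raw_tests = TRUE)
  expect_true(all(cognitive_record_columns() %in% names(co$cohort)))
  comp <- compose_domains(co$cohort)
  expect_gt(cor(comp$cognitive_index, co$cohort$cognitive_index), 0.8)
  times <- co$cohort[grep("_time$", names(co$cohort))]
  expect_true(all(times > 0))
})

test_that("unsatisfiable network configurations error", {
  expect_error(generate_cohort(small_config(density_target = 0.004),
                               seed = 1),
               "unsatisfiable")
})
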