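test_that("SAT scores divide correct responses by completion time", {
  expect_equal(sat_score(30, 60), 0.5)
  expect_equal(sat_score(0, 45), 0)
  expect_equal(sat_score(24, 80), sat_score(24, 40) / 2)
  expect_error(sat_score(10, 0), "positive")
  expect_error(sat_score(-1, 10), "non-negative")
  expect_true(is.na(sat_score(NA, 10)))
})

test_that("Stroop interference is colour-word SAT over mean read/name SAT", {
  expect_equal(stroop_interference(1, 1, 1), 1)
  expect_equal(stroop_interference(0.5, 1, 1), 0.5)
  expect_equal(stroop_interference(3, 2, 4), 1)
  expect_warning(out <- stroop_interference(1, 0, 0), "NA")
  expect_true(is.na(out))
})

test_that("z-scores anchor to the baseline population", {
  expect_equal(zscore_vs_baseline(10, 10, 2), 0)
  expect_equal(zscore_vs_baseline(14, 10, 2), 2)
  expect_error(zscore_vs_baseline(1, 0, 0), "positive")
  x <- c(3, 9, 1, 7, 5)
  z <- zscore_vs_baseline(x, mean(x), sd(x))
  expect_equal(mean(z), 0, tolerance = 1e-12)
  expect_equal(sd(z), 1, tolerance = 1e-12)
})

# A fully observed raw battery for n subjects per wave, built from known
# per-test z targets so composite expectations are exact.
fake_battery <- function(z_by_test) {
  norms <- svdnet:::raw_test_norms()
  n <- length(z_by_test[[1]])
  out <- data.frame(subject_id = sprintf("P%02d", seq_len(n)))
  val <- function(score) {
    r <- norms[norms$score == score, ]
    r$mean + r$sd * z_by_test[[score]]
  }
  out$ravlt_imm <- val("ravlt_imm"); out$ravlt_del <- val("ravlt_del")
  out$rcft_imm <- val("rcft_imm"); out$rcft_del <- val("rcft_del")
  for (s in c("ppmst1", "ppmst2", "ppmst3", "stroop_read", "stroop_name",
              "vsat")) {
    r <- norms[norms$score == paste0(s, "_sat"), ]
    sat <- pmax(r$mean + r$sd * z_by_test[[paste0(s, "_sat")]], 0.05)
    out[[paste0(s, "_correct")]] <- r$n_items
    out[[paste0(s, "_time")]] <- r$n_items / sat
  }
  read_sat <- out$stroop_read_correct / out$stroop_read_time
  name_sat <- out$stroop_name_correct / out$stroop_name_time
  interf <- 0.43 + 0.12 * z_by_test$stroop_interference
  cw_sat <- pmax(interf * (read_sat + name_sat) / 2, 0.05)
  out$stroop_cw_correct <- 100
  out$stroop_cw_time <- 100 / cw_sat
  out$sdst <- val("sdst"); out$fluency <- val("fluency")
  out
}

test_that("composites are means of constituent z-scores vs baseline stats", {
  tests <- cognitive_tests()
  # explicit baseline stats so expected z-values are hand-computable
  bs <- data.frame(score = tests, mean = rep(10, length(tests)),
                   sd = rep(2, length(tests)))
  derived <- as.data.frame(stats::setNames(
    as.list(rep(10, length(tests))), tests))
  derived$subject_id <- "P1"
  out <- compose_domains(derived, baseline_stats = bs)
  expect_equal(out$cognitive_index, 0)
  expect_equal(out$memory, 0)

  # memory constituents z = (1, 1, -1, -1, 0, 0) -> memory 0
  mem <- cognitive_domains()$memory
  d2 <- derived
  d2[mem[1:2]] <- 12; d2[mem[3:4]] <- 8
  out2 <- compose_domains(d2, baseline_stats = bs)
  expect_equal(out2$memory, 0)

  # speed constituents z = (0.2, 0.4, 0.6, 0.8) -> 0.5
  spd <- cognitive_domains()$psychomotor_speed
  d3 <- derived
  for (i in 1:4) d3[[spd[i]]] <- 10 + 2 * (0.2 * i)
  expect_equal(compose_domains(d3, baseline_stats = bs)$psychomotor_speed,
               0.5)

  # composites are invariant to constituent order (column shuffle)
  d4 <- d3[, sample(names(d3))]
  expect_equal(compose_domains(d4, baseline_stats = bs)$psychomotor_speed,
               0.5)
})

test_that("composites use available constituents and go missing only when all are", {
  tests <- cognitive_tests()
  bs <- data.frame(score = tests, mean = 0, sd = 1)
  derived <- as.data.frame(stats::setNames(
    as.list(rep(NA_real_, length(tests))), tests))
  derived$fluency <- 1.2   # executive constituent present
  out <- compose_domains(derived, baseline_stats = bs)
  expect_equal(out$executive_function, 1.2)
  expect_true(is.na(out$memory))
  expect_equal(out$cognitive_index, 1.2)
})

test_that("the full raw battery flows through to calibrated composites", {
  set.seed(21)
  z <- stats::setNames(
    lapply(cognitive_tests(), function(t) rnorm(40)), cognitive_tests())
  battery <- fake_battery(z)
  battery$wave <- "baseline"
  comp <- compose_domains(battery)
  # z-anchored baseline: every composite column is centred near 0
  expect_lt(abs(mean(comp$cognitive_index)), 0.15)
  # module-recovered per-test z correlate strongly with the injected z
  expect_gt(cor(comp$z_ravlt_imm, z$ravlt_imm), 0.99)
  expect_gt(cor(comp$z_vsat_sat, z$vsat_sat), 0.95)
  expect_gt(cor(comp$z_stroop_interference, z$stroop_interference), 0.9)
  # VSAT sign inversion flips only the executive constituents it touches
  comp_inv <- compose_domains(battery, invert_vsat = TRUE)
  expect_equal(comp_inv$z_vsat_sat, -comp$z_vsat_sat)
  expect_equal(comp_inv$memory, comp$memory)
})

test_that("delta scores subtract baseline from follow-up per subject", {
  bl <- data.frame(subject_id = c("a", "b"), cognitive_index = c(0.5, 1),
                   memory = c(0, 0.2))
  fu <- data.frame(subject_id = c("b", "a"), cognitive_index = c(0.8, 0.2),
                   memory = c(NA, 0.1))
  d <- delta_scores(fu, bl)
  expect_equal(d$cognitive_index[d$subject_id == "a"], -0.3)
  expect_equal(d$cognitive_index[d$subject_id == "b"], -0.2)
  expect_true(is.na(d$memory[d$subject_id == "b"]))
  # antisymmetry
  d2 <- delta_scores(bl, fu)
  expect_equal(d2$cognitive_index[match(d$subject_id, d2$subject_id)],
               -d$cognitive_index)
  # identical waves -> all zero
  d0 <- delta_scores(bl, bl)
  expect_true(all(d0$cognitive_index == 0))
  expect_error(delta_scores(fu[1, ], bl), "same subjects")
})
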