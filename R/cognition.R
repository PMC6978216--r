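# Composite cognition scores from a timed neuropsychological battery.
#
# Derived test scores (13), their domains, and the raw columns they come
# from. SAT = speed-accuracy trade-off score, n_correct / time_s.

cognitive_tests <- function() {
  c("ravlt_imm", "ravlt_del", "rcft_imm", "rcft_del",
    "ppmst1_sat", "ppmst2_sat", "ppmst3_sat",
    "stroop_read_sat", "stroop_name_sat", "stroop_interference",
    "sdst", "fluency", "vsat_sat")
}

cognitive_domains <- function() {
  list(
    memory = c("ravlt_imm", "ravlt_del", "rcft_imm", "rcft_del",
               "ppmst2_sat", "ppmst3_sat"),
    psychomotor_speed = c("ppmst1_sat", "stroop_read_sat",
                          "stroop_name_sat", "sdst"),
    executive_function = c("stroop_interference", "fluency", "vsat_sat"))
}

#' Speed-accuracy trade-off (SAT) score of a timed test
#'
#' Combines correctness and completion time of a timed test into one score:
#' the number of correct responses divided by the completion time in
#' seconds, so higher is better. Vectorised; `NA` inputs give `NA`.
#'
#' @param n_correct Non-negative count(s) of correct responses.
#' @param time_s Strictly positive completion time(s), seconds.
#' @return `n_correct / time_s`.
#' @examples
#' sat_score(30, 60)  # 0.5
#' @export
sat_score <- function(n_correct, time_s) {
  ok <- !is.na(time_s)
  if (any(ok & time_s <= 0))
    stop("completion time must be strictly positive")
  if (any(!is.na(n_correct) & n_correct < 0))
    stop("n_correct must be non-negative")
  n_correct / time_s
}

#' Stroop interference score
#'
#' The SAT score of the colour-word (interference) condition divided by
#' the mean SAT score of the word-reading and colour-naming conditions.
#' Under the SAT convention (higher SAT = better), *lower* interference
#' scores indicate *more* interference.
#'
#' @param sat_cw,sat_read,sat_name SAT scores of the colour-word, reading
#'   and naming conditions.
#' @return `sat_cw / mean(sat_read, sat_name)`; `NA` with a warning where
#'   the denominator is not positive.
#' @export
stroop_interference <- function(sat_cw, sat_read, sat_name) {
  denom <- (sat_read + sat_name) / 2
  out <- sat_cw / denom
  bad <- !is.na(denom) & denom <= 0
  if (any(bad)) {
    warning("zero mean reading/naming SAT: interference set to NA")
    out[bad] <- NA_real_
  }
  out
}

#' z-score against the baseline study population
#'
#' All scores, from both waves, are standardised against the mean and SD
#' of the *baseline* population, so follow-up z-scores remain comparable
#' to baseline and change scores are in baseline-SD units.
#'
#' @param raw Raw score(s).
#' @param baseline_mean,baseline_sd Baseline population mean and SD
#'   (`baseline_sd > 0`).
#' @return `(raw - baseline_mean) / baseline_sd`.
#' @export
zscore_vs_baseline <- function(raw, baseline_mean, baseline_sd) {
  if (any(is.na(baseline_sd)) || any(baseline_sd <= 0))
    stop("baseline SD must be strictly positive")
  (raw - baseline_mean) / baseline_sd
}

#' Derive the 13 test scores from raw battery results
#'
#' Applies the SAT transformation to the timed subtasks (memory scanning
#' 1/2/3-letter, Stroop reading/naming/colour-word, verbal series
#' attention) and computes the Stroop interference ratio; plain scores
#' (verbal learning and complex-figure recall, symbol-digit substitution,
#' fluency) pass through.
#'
#' @param records Data frame with one row per subject-wave holding the raw
#'   score columns (see [cognitive_record_columns()]); missing scores are
#'   `NA`.
#' @return Data frame with `subject_id`, `wave` (if present in the input)
#'   and the 13 derived score columns.
#' @export
derive_test_scores <- function(records) {
  records <- as.data.frame(records)
  col <- function(nm) if (nm %in% names(records)) records[[nm]] else
    rep(NA_real_, nrow(records))
  sat <- function(stem) sat_score(col(paste0(stem, "_correct")),
                                  col(paste0(stem, "_time")))
  out <- data.frame(
    ravlt_imm = col("ravlt_imm"), ravlt_del = col("ravlt_del"),
    rcft_imm = col("rcft_imm"), rcft_del = col("rcft_del"),
    ppmst1_sat = sat("ppmst1"), ppmst2_sat = sat("ppmst2"),
    ppmst3_sat = sat("ppmst3"),
    stroop_read_sat = sat("stroop_read"),
    stroop_name_sat = sat("stroop_name"),
    sdst = col("sdst"), fluency = col("fluency"),
    vsat_sat = sat("vsat"))
  out$stroop_interference <- stroop_interference(
    sat("stroop_cw"), out$stroop_read_sat, out$stroop_name_sat)
  id_cols <- intersect(c("subject_id", "wave"), names(records))
  cbind(records[id_cols], out[cognitive_tests()])
}

#' Raw score columns expected in a cohort table
#'
#' @return Character vector of raw cognitive score column names.
#' @export
cognitive_record_columns <- function() {
  c("ravlt_imm", "ravlt_del", "rcft_imm", "rcft_del",
    "ppmst1_correct", "ppmst1_time", "ppmst2_correct", "ppmst2_time",
    "ppmst3_correct", "ppmst3_time",
    "stroop_read_correct", "stroop_read_time",
    "stroop_name_correct", "stroop_name_time",
    "stroop_cw_correct", "stroop_cw_time",
    "sdst", "fluency", "vsat_correct", "vsat_time")
}

#' Baseline population statistics for z-anchoring
#'
#' Computes, per derived test score, the mean and SD over the baseline
#' rows, the anchor against which all waves are standardised.
#'
#' @param derived Data frame of derived scores (from
#'   [derive_test_scores()]) containing a `wave` column, or baseline rows
#'   only.
#' @return Data frame with columns `score`, `mean`, `sd`.
#' @export
baseline_statistics <- function(derived) {
  if ("wave" %in% names(derived))
    derived <- derived[derived$wave == "baseline", , drop = FALSE]
  tests <- intersect(cognitive_tests(), names(derived))
  data.frame(
    score = tests,
    mean = vapply(tests, function(t) mean(derived[[t]], na.rm = TRUE), 0),
    sd = vapply(tests, function(t) stats::sd(derived[[t]], na.rm = TRUE), 0),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Composite cognition scores (cognitive index and three domains)
#'
#' Standardises every derived test score against the baseline population
#' and averages z-scores into composites: the *cognitive index* (mean of
#' all 13 test z-scores) and the *memory*, *psychomotor speed* and
#' *executive function* domains. A composite is the mean of its available
#' (non-missing) constituent z-scores and is missing only when all
#' constituents are missing.
#'
#' @param records Data frame of raw scores per subject-wave (or already
#'   derived scores; detected by the presence of all 13 derived columns).
#' @param baseline_stats Data frame from [baseline_statistics()]. When
#'   `NULL`, it is computed from the baseline rows of `records`.
#' @param invert_vsat Logical; if `TRUE` the verbal-series-attention SAT
#'   z-score enters with inverted sign.
#' @return Data frame with identifiers, per-test z-score columns
#'   (`z_<test>`) and the four composite columns.
#' @export
compose_domains <- function(records, baseline_stats = NULL,
                            invert_vsat = FALSE) {
  derived <- if (all(cognitive_tests() %in% names(records)))
    as.data.frame(records) else derive_test_scores(records)
  if (is.null(baseline_stats)) baseline_stats <- baseline_statistics(derived)
  z <- derived[intersect(c("subject_id", "wave"), names(derived))]
  for (t in cognitive_tests()) {
    st <- baseline_stats[baseline_stats$score == t, , drop = FALSE]
    if (!nrow(st) || is.na(st$sd) || st$sd <= 0)
      stop("no usable baseline mean/SD for test score `", t, "`")
    z[[paste0("z_", t)]] <- zscore_vs_baseline(derived[[t]], st$mean, st$sd)
  }
  if (invert_vsat) z$z_vsat_sat <- -z$z_vsat_sat
  row_mean <- function(cols) {
    m <- as.matrix(z[paste0("z_", cols)])
    k <- rowSums(!is.na(m))
    out <- rowMeans(m, na.rm = TRUE)
    out[k == 0] <- NA_real_
    out
  }
  z$cognitive_index <- row_mean(cognitive_tests())
  for (d in names(cognitive_domains()))
    z[[d]] <- row_mean(cognitive_domains()[[d]])
  z
}

#' Longitudinal change (delta) scores
#'
#' Subtracts baseline composite (and per-test z) scores from follow-up
#' scores, per subject; a change score is missing if either wave is
#' missing.
#'
#' @param followup,baseline Data frames from [compose_domains()], each
#'   with a `subject_id` column covering the same subjects.
#' @return Data frame of change scores with one row per subject.
#' @export
delta_scores <- function(followup, baseline) {
  stopifnot("subject_id" %in% names(followup),
            "subject_id" %in% names(baseline))
  if (!setequal(followup$subject_id, baseline$subject_id) ||
      anyDuplicated(followup$subject_id) || anyDuplicated(baseline$subject_id))
    stop("follow-up and baseline tables must cover the same subjects once")
  baseline <- baseline[match(followup$subject_id, baseline$subject_id), ,
                       drop = FALSE]
  num <- setdiff(names(followup)[vapply(followup, is.numeric, TRUE)],
                 c("subject_id"))
  num <- intersect(num, names(baseline))
  out <- data.frame(subject_id = followup$subject_id,
                    stringsAsFactors = FALSE)
  for (v in num) out[[v]] <- followup[[v]] - baseline[[v]]
  out
}
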