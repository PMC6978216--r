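#' Per-stage analysis tables
#'
#' Each stage function turns upstream results into one output table of the
#' full pipeline run; [run_all()] chains them. They are exported so any
#' stage can be re-run in isolation from on-disk intermediates.
#'
#' @name pipeline_stages
NULL

#' @rdname pipeline_stages
#' @param cohort A `synthetic_cohort` (or a compatible list with `cohort`,
#'   `networks`, `parcellation` elements).
#' @return `stage_metrics()`: one row per subject-wave with density, total
#'   strength, global efficiency and the three class strengths/counts.
#' @export
stage_metrics <- function(cohort) {
  if (is.null(cohort$networks))
    stop("metrics stage requires retained networks")
  rows <- lapply(names(cohort$networks), function(id) {
    nets <- cohort$networks[[id]]
    do.call(rbind, lapply(names(nets), function(wv)
      cbind(data.frame(subject_id = id, wave = wv,
                       stringsAsFactors = FALSE),
            network_metric_profile(nets[[wv]]))))
  })
  do.call(rbind, rows)
}

#' @rdname pipeline_stages
#' @return `stage_composites()`: per subject-wave composite cognition
#'   scores, computed from raw test scores when present, otherwise taken
#'   from the composite columns of the cohort table.
#' @export
stage_composites <- function(cohort) {
  tab <- cohort$cohort
  if (all(cognitive_record_columns() %in% names(tab))) {
    comp <- compose_domains(tab)
    comp[c("subject_id", "wave", "cognitive_index", "memory",
           "psychomotor_speed", "executive_function")]
  } else {
    tab[c("subject_id", "wave", "cognitive_index", "memory",
          "psychomotor_speed", "executive_function")]
  }
}

pivot_by_wave <- function(df, vars) {
  bl <- df[df$wave == "baseline", c("subject_id", vars), drop = FALSE]
  fu <- df[df$wave == "followup", c("subject_id", vars), drop = FALSE]
  fu <- fu[match(bl$subject_id, fu$subject_id), , drop = FALSE]
  list(baseline = bl, followup = fu)
}

network_measure_vars <- function() {
  c("density", "total_strength", "global_efficiency",
    "rich_club_strength", "feeder_strength", "peripheral_strength")
}

composite_vars <- function() {
  c("cognitive_index", "memory", "psychomotor_speed", "executive_function")
}

#' @rdname pipeline_stages
#' @param metrics,composites Tables from [stage_metrics()] and
#'   [stage_composites()] (or read back from their TSVs).
#' @return `stage_change_tests()`: one row per measure with the paired
#'   change estimate, 95% CI, p-value and significance stars.
#' @export
stage_change_tests <- function(metrics, composites) {
  out <- list()
  for (src in list(list(df = metrics, vars = network_measure_vars()),
                   list(df = composites, vars = composite_vars()))) {
    pv <- pivot_by_wave(src$df, src$vars)
    for (v in src$vars) {
      ct <- paired_change_test(pv$baseline[[v]], pv$followup[[v]])
      out[[v]] <- data.frame(measure = v, n = ct$n,
                             mean_difference = ct$estimate,
                             ci_low = ct$ci[1], ci_high = ct$ci[2],
                             p_value = ct$p_value,
                             stars = significance_stars(ct$p_value),
                             stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, c(out, make.row.names = FALSE))
}

baseline_frame <- function(cohort_tab, metrics) {
  bl <- cohort_tab[cohort_tab$wave == "baseline", , drop = FALSE]
  mbl <- metrics[metrics$wave == "baseline", , drop = FALSE]
  mbl <- mbl[match(bl$subject_id, mbl$subject_id), , drop = FALSE]
  cbind(bl, mbl[network_measure_vars()])
}

#' @rdname pipeline_stages
#' @return `stage_svd_regressions()`: standardized beta (with 95% CI) of
#'   each conventional SVD marker (log WMH volume, lacune count,
#'   microbleed count) on each baseline connection-class strength,
#'   adjusted for age and sex.
#' @export
stage_svd_regressions <- function(cohort, metrics) {
  bl <- baseline_frame(cohort$cohort, metrics)
  markers <- list(log_wmh = log_transform_wmh(bl$wmh_ml),
                  lacune_count = bl$lacune_count,
                  microbleed_count = bl$microbleed_count)
  covs <- data.frame(age = bl$age, sex = factor(bl$sex))
  out <- list()
  for (y in c("rich_club_strength", "feeder_strength",
              "peripheral_strength")) {
    for (mk in names(markers)) {
      fit <- standardized_regression(bl[[y]],
                                     stats::setNames(data.frame(markers[[mk]]),
                                                     mk),
                                     covariates = covs)
      cf <- fit$coefficients[fit$coefficients$term == mk, , drop = FALSE]
      out[[paste(y, mk)]] <- data.frame(
        outcome = y, predictor = mk, beta = cf$beta,
        ci_low = cf$ci_low, ci_high = cf$ci_high, p_value = cf$p_value,
        stars = significance_stars(cf$p_value), n = fit$n,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, c(out, make.row.names = FALSE))
}

#' @rdname pipeline_stages
#' @return `stage_cognition_regressions()`: standardized beta of each
#'   network-measure change score on each composite cognition change
#'   score, adjusted for age, sex and education.
#' @export
stage_cognition_regressions <- function(cohort, metrics, composites) {
  mv <- setdiff(network_measure_vars(), "density")
  pm <- pivot_by_wave(metrics, mv)
  pc <- pivot_by_wave(composites, composite_vars())
  stopifnot(identical(pm$baseline$subject_id, pc$baseline$subject_id))
  bl <- cohort$cohort[cohort$cohort$wave == "baseline", , drop = FALSE]
  bl <- bl[match(pm$baseline$subject_id, bl$subject_id), , drop = FALSE]
  covs <- data.frame(age = bl$age, sex = factor(bl$sex),
                     education = bl$education_years)
  out <- list()
  for (y in composite_vars()) {
    dy <- pc$followup[[y]] - pc$baseline[[y]]
    for (x in mv) {
      dx <- pm$followup[[x]] - pm$baseline[[x]]
      fit <- standardized_regression(dy,
                                     stats::setNames(data.frame(dx),
                                                     paste0("delta_", x)),
                                     covariates = covs)
      cf <- fit$coefficients[1L, ]
      out[[paste(y, x)]] <- data.frame(
        outcome = paste0("delta_", y), predictor = paste0("delta_", x),
        beta = cf$beta, ci_low = cf$ci_low, ci_high = cf$ci_high,
        p_value = cf$p_value, stars = significance_stars(cf$p_value),
        n = fit$n, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, c(out, make.row.names = FALSE))
}

#' @rdname pipeline_stages
#' @param n_boot,seed Bootstrap resamples and master seed for the
#'   mediation models.
#' @return `stage_mediation()`: one row per mediation model (paths a, b,
#'   c', indirect effect with bootstrap CI and p).
#' @export
stage_mediation <- function(cohort, metrics, composites, n_boot = 2000,
                            seed = 1) {
  bl <- baseline_frame(cohort$cohort, metrics)
  fu <- cohort$cohort[cohort$cohort$wave == "followup", , drop = FALSE]
  fu <- fu[match(bl$subject_id, fu$subject_id), , drop = FALSE]
  covs <- data.frame(age = bl$age, sex = factor(bl$sex),
                     education = bl$education_years)
  x_wmh <- log_transform_wmh(bl$wmh_ml)
  models <- list()
  for (m in c("global_efficiency", "rich_club_strength", "feeder_strength",
              "peripheral_strength"))
    models[[paste0("wmh_dementia_via_", m)]] <- list(
      x = x_wmh, m = bl[[m]], y = fu$dementia, binary = TRUE)
  pm <- pivot_by_wave(metrics, "peripheral_strength")
  pc <- pivot_by_wave(composites, "cognitive_index")
  dper <- pm$followup$peripheral_strength - pm$baseline$peripheral_strength
  dcog <- pc$followup$cognitive_index - pc$baseline$cognitive_index
  models[["wmh_progression_cognition_via_peripheral"]] <- list(
    x = log_transform_wmh(fu$wmh_ml) - x_wmh, m = dper, y = dcog,
    binary = FALSE)
  out <- list()
  for (nm in names(models)) {
    md <- models[[nm]]
    fit <- fit_mediation(md$x, md$m, md$y, covariates = covs,
                         y_binary = md$binary, n_boot = n_boot,
                         seed = substream_seed(seed, nm))
    est <- stats::setNames(fit$paths$estimate, fit$paths$path)
    pv <- stats::setNames(fit$paths$p_value, fit$paths$path)
    out[[nm]] <- data.frame(
      model = nm, a = est[["a"]], b = est[["b"]], c_prime = est[["c_prime"]],
      a_p = pv[["a"]], b_p = pv[["b"]], c_prime_p = pv[["c_prime"]],
      indirect = fit$indirect,
      indirect_ci_low = fit$boot$indirect_ci[1],
      indirect_ci_high = fit$boot$indirect_ci[2],
      indirect_p = fit$boot$indirect_p,
      direct_ci_low = fit$boot$direct_ci[1],
      direct_ci_high = fit$boot$direct_ci[2],
      direct_p = fit$boot$direct_p,
      n = fit$n, n_boot = fit$n_boot,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, c(out, make.row.names = FALSE))
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Run the full analysis pipeline on a (simulated) cohort
#'
#' Orchestrates simulate -> network metrics -> cognition composites ->
#' change tests -> association tables -> mediation models into one
#' reproducible run, writing every output table plus a run manifest to
#' `out_dir`. Identical `config` + `seed` give byte-identical tables.
#'
#' @param config A [cohort_config()].
#' @param seed Integer master seed (drives the simulation and all
#'   bootstrap inference).
#' @param out_dir Output directory (created if needed).
#' @param cohort Optionally a pre-generated `synthetic_cohort`; when
#'   supplied the simulate stage is skipped.
#' @param n_boot Bootstrap resamples for the mediation stage.
#' @return Invisibly, a list with every stage table and the manifest. The
#'   manifest is written even if a stage fails (with the failed stage
#'   recorded).
#' @export
run_all <- function(config = cohort_config(), seed = 1, out_dir,
                    cohort = NULL, n_boot = 2000) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(
    config_hash = config_hash(unclass(config)[setdiff(names(config),
                                                      "parcellation")]),
    seed = seed,
    n_regions = length(config$parcellation$labels),
    package_version = as.character(utils::packageVersion("svdnet")),
    started = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    stages = list(), status = "running")
  write_manifest <- function() {
    manifest$finished <<- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  on.exit(write_manifest())
  results <- list()
  stage <- function(name, expr) {
    res <- tryCatch(force(expr), error = function(e) {
      manifest$status <<- paste0("failed at stage `", name, "`")
      stop("stage `", name, "`: ", conditionMessage(e), call. = FALSE)
    })
    manifest$stages[[name]] <<-
      list(rows = if (is.data.frame(res)) nrow(res) else NA)
    res
  }

  if (is.null(cohort))
    cohort <- stage("simulate", generate_cohort(config, seed = seed))
  n_in <- length(unique(cohort$cohort$subject_id))

  # complete-case accounting: subjects must have both waves and networks
  waves <- table(cohort$cohort$subject_id)
  excluded <- data.frame(subject_id = names(waves)[waves < 2L],
                         reason = rep("missing_wave",
                                      sum(waves < 2L)),
                         stringsAsFactors = FALSE)
  if (!is.null(cohort$networks)) {
    no_net <- setdiff(unique(cohort$cohort$subject_id),
                      names(cohort$networks))
    if (length(no_net))
      excluded <- rbind(excluded,
                        data.frame(subject_id = no_net,
                                   reason = "missing_network"))
  }
  keep <- setdiff(unique(cohort$cohort$subject_id), excluded$subject_id)
  cohort$cohort <- cohort$cohort[cohort$cohort$subject_id %in% keep, ,
                                 drop = FALSE]
  if (!is.null(cohort$networks))
    cohort$networks <- cohort$networks[intersect(names(cohort$networks),
                                                 keep)]
  manifest$subjects <- list(n_in = n_in, n_analysed = length(keep),
                            n_excluded = nrow(excluded),
                            exclusions = excluded)

  results$cohort <- cohort$cohort
  utils::write.csv(cohort$cohort, file.path(out_dir, "cohort.csv"),
                   row.names = FALSE, quote = FALSE)
  results$metrics <- stage("metrics", stage_metrics(cohort))
  write_tsv(results$metrics, file.path(out_dir, "metrics.tsv"))
  results$composites <- stage("cognition", stage_composites(cohort))
  write_tsv(results$composites, file.path(out_dir, "composites.tsv"))
  results$change_tests <- stage("change_tests",
                                stage_change_tests(results$metrics,
                                                   results$composites))
  write_tsv(results$change_tests, file.path(out_dir, "change_tests.tsv"))
  results$svd_regressions <- stage("svd_regressions",
                                   stage_svd_regressions(cohort,
                                                         results$metrics))
  write_tsv(results$svd_regressions,
            file.path(out_dir, "svd_regressions.tsv"))
  results$cognition_regressions <- stage(
    "cognition_regressions",
    stage_cognition_regressions(cohort, results$metrics,
                                results$composites))
  write_tsv(results$cognition_regressions,
            file.path(out_dir, "cognition_regressions.tsv"))
  results$mediation <- stage("mediation",
                             stage_mediation(cohort, results$metrics,
                                             results$composites,
                                             n_boot = n_boot, seed = seed))
  write_tsv(results$mediation, file.path(out_dir, "mediation.tsv"))
  manifest$status <- "ok"
  results$manifest <- manifest
  invisible(results)
}
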