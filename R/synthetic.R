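#' Configuration for the synthetic two-wave SVD cohort generator
#'
#' Bundles every tunable parameter of the synthetic cohort: sample size,
#' demographic calibration, the log-normal WMH volume model (matched by
#' median and IQR), the baseline network model (density target, per-class
#' weight scales, hub premium), the per-class decline model, the injected
#' effect sizes tying WMH burden to network decline, network decline to
#' cognitive decline, and baseline network integrity to dementia, and the
#' noise scales. The shipped defaults reproduce the population parameters
#' of a memory-clinic-free SVD cohort: age 67.9 +/- 7.8 y, ~60% male,
#' follow-up 3.4 +/- 0.2 y, WMH median 2.8 ml (IQR 1.3-7.8), dementia
#' rate 23/329, and a mean rich-club connection-strength change of -0.44
#' over follow-up against -0.03 (feeder) and -0.02 (peripheral).
#'
#' @param n_subjects Number of subjects (two waves each).
#' @param parcellation A [parcellation]; defaults to [aal90_parcellation()].
#' @param age_mean,age_sd,prop_male,education_mean,education_sd Demographics.
#' @param followup_years_mean,followup_years_sd Follow-up interval (years).
#' @param wmh_median_ml,wmh_iqr_ml Baseline WMH volume calibration (ml);
#'   the log-normal is fitted to this median and IQR.
#' @param wmh_growth_log_mean,wmh_growth_log_sd Log-scale WMH progression
#'   over follow-up.
#' @param lacune_prevalence,microbleed_prevalence,hypertension_prevalence
#'   Baseline marker prevalences (fraction of subjects with >= 1 / with
#'   the condition).
#' @param density_target Baseline network density in (0, 1].
#' @param class_weight_means Named vector: mean baseline edge weight per
#'   connection class (1/mm units).
#' @param weight_floor Minimum baseline edge weight, kept well above the
#'   edge threshold so follow-up decline does not prune edges.
#' @param hub_premium Multiplier on the connection probability of edges
#'   touching a rich-club region (produces the hub degree ranking).
#' @param distance_scale Length scale of the distance penalty of the
#'   random geometric template graph (unit-cube coordinates).
#' @param burden_network_effect Log baseline network strength per SD of
#'   latent SVD burden (negative: more burden, weaker networks).
#' @param subject_network_sd,edge_jitter_sd Log-scale subject-level and
#'   edge-level weight noise.
#' @param decline_mean,decline_sd Named vectors (rich_club, feeder,
#'   peripheral): mean and SD of the per-subject change in class mean
#'   strength over the follow-up interval.
#' @param wmh_network_effect Correlation between the WMH progression
#'   latent and each class's decline (negative: progression accelerates
#'   decline).
#' @param network_cognition_effect Standardized effect of peripheral
#'   strength decline on cognitive change.
#' @param wmh_cognition_direct Standardized direct effect of WMH
#'   progression on cognitive change (0 makes the mediation complete by
#'   construction).
#' @param cognition_change_mean Named vector of mean composite change per
#'   domain; `cognition_change_sd` its common SD.
#' @param cognition_change_sd SD of composite change scores.
#' @param dementia_base_rate Marginal dementia probability at follow-up.
#' @param dementia_efficiency_logodds,dementia_peripheral_logodds Log-odds
#'   of dementia per SD of baseline global efficiency / peripheral
#'   strength.
#' @param wmh_dementia_direct_logodds Direct WMH-to-dementia log-odds per
#'   SD of burden (0: dementia risk acts purely through the network).
#' @param threshold Edge threshold applied to generated matrices.
#' @return A validated list of class `cohort_config`.
#' @export
cohort_config <- function(
    n_subjects = 270,
    parcellation = aal90_parcellation(),
    age_mean = 67.9, age_sd = 7.8,
    prop_male = 0.596,
    education_mean = 10.1, education_sd = 1.5,
    followup_years_mean = 3.4, followup_years_sd = 0.2,
    wmh_median_ml = 2.8, wmh_iqr_ml = c(1.3, 7.8),
    wmh_growth_log_mean = 0.25, wmh_growth_log_sd = 0.20,
    lacune_prevalence = 0.254,
    microbleed_prevalence = 0.173,
    hypertension_prevalence = 0.596,
    density_target = 0.20,
    class_weight_means = c(rich_club = 12, feeder = 6, peripheral = 4),
    weight_floor = 2.5,
    hub_premium = 3.0,
    distance_scale = 0.35,
    burden_network_effect = -0.12,
    subject_network_sd = 0.25,
    edge_jitter_sd = 0.10,
    decline_mean = c(rich_club = -0.44, feeder = -0.03, peripheral = -0.02),
    decline_sd = c(rich_club = 1.5, feeder = 0.40, peripheral = 0.18),
    wmh_network_effect = -0.3,
    network_cognition_effect = 0.35,
    wmh_cognition_direct = 0,
    cognition_change_mean = c(cognitive_index = -0.10, memory = -0.05,
                              psychomotor_speed = -0.12,
                              executive_function = -0.10),
    cognition_change_sd = 0.35,
    dementia_base_rate = 23 / 329,
    dementia_efficiency_logodds = -0.6,
    dementia_peripheral_logodds = -0.5,
    wmh_dementia_direct_logodds = 0,
    threshold = 1) {
  cfg <- as.list(environment())
  stopifnot(inherits(parcellation, "parcellation"),
            n_subjects >= 2,
            density_target > 0, density_target <= 1,
            all(c("rich_club", "feeder", "peripheral") %in%
                  names(class_weight_means)),
            all(c("rich_club", "feeder", "peripheral") %in%
                  names(decline_mean)),
            all(decline_sd >= 0), cognition_change_sd >= 0,
            age_sd >= 0, followup_years_sd >= 0,
            prop_male >= 0, prop_male <= 1,
            dementia_base_rate >= 0, dementia_base_rate <= 1,
            length(wmh_iqr_ml) == 2L, wmh_iqr_ml[1] > 0,
            wmh_iqr_ml[2] > wmh_iqr_ml[1],
            weight_floor > threshold,
            abs(wmh_network_effect) <= 1,
            threshold >= 0)
  class(cfg) <- "cohort_config"
  cfg
}

#' Fit a log-normal distribution from a median and IQR
#'
#' Two-parameter fit: the log-mean matches the median exactly and the
#' log-SD matches the ratio of the quartiles,
#' `sdlog = log(q3/q1) / (2 * qnorm(0.75))`.
#'
#' @param median Distribution median (> 0).
#' @param iqr Length-2 vector `c(q1, q3)` with `0 < q1 < q3`.
#' @return List with `meanlog` and `sdlog`.
#' @export
lognormal_from_median_iqr <- function(median, iqr) {
  stopifnot(median > 0, length(iqr) == 2L, iqr[1] > 0, iqr[2] > iqr[1])
  list(meanlog = log(median),
       sdlog = log(iqr[2] / iqr[1]) / (2 * stats::qnorm(0.75)))
}

# Distance-penalized random geometric template graph with a hub premium on
# the rich-club regions. The 28 rich-rich edges are always present (the
# rich club is densely interconnected); other pairs connect with
# probability proportional to exp(-d / distance_scale), multiplied by
# `hub_premium` for feeder pairs and scaled to hit the density target.
# Redrawn (fresh coordinates) until all rich regions rank in the top-12
# degrees; errors if the configuration cannot achieve that.
build_network_template <- function(config, seed, max_tries = 20L) {
  parc <- config$parcellation
  labels <- parc$labels
  n <- length(labels)
  is_rich <- labels %in% parc$rich_club
  if (sum(is_rich) < 2L)
    stop("template generation needs at least 2 rich-club regions")
  ut <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  n_ends <- is_rich[ut[, 1L]] + is_rich[ut[, 2L]]
  cls <- c("peripheral", "feeder", "rich_club")[n_ends + 1L]
  target_edges <- round(config$density_target * n * (n - 1) / 2)
  if (target_edges < sum(cls == "rich_club"))
    stop("unsatisfiable density/rich-club configuration: ",
         "density target below the fully connected rich club")
  with_seed(seed, {
    for (try in seq_len(max_tries)) {
      coords <- matrix(stats::runif(n * 3), n, 3)
      d <- sqrt(rowSums((coords[ut[, 1L], ] - coords[ut[, 2L], ])^2))
      raw <- exp(-d / config$distance_scale)
      raw[cls == "feeder"] <- raw[cls == "feeder"] * config$hub_premium
      other <- cls != "rich_club"
      s <- (target_edges - sum(!other)) / sum(raw[other])
      p <- pmin(raw * s, 0.98)
      present <- !other | (stats::runif(length(p)) < p)
      shape <- 4
      mu <- config$class_weight_means[cls[present]]
      base_w <- config$weight_floor +
        stats::rgamma(sum(present), shape = shape,
                      scale = pmax(mu - config$weight_floor, 0.1) / shape)
      tmpl <- list(i = ut[present, 1L], j = ut[present, 2L],
                   class = factor(cls[present],
                                  levels = c("rich_club", "feeder",
                                             "peripheral")),
                   base_weight = base_w, n = n, labels = labels,
                   parcellation = parc)
      deg <- tabulate(c(tmpl$i, tmpl$j), nbins = n)
      rank <- match(deg, sort(unique(deg), decreasing = TRUE))
      if (all(rank[is_rich] <= 12L)) {
        tmpl$degree <- deg
        return(tmpl)
      }
    }
    stop("unsatisfiable density/rich-club configuration: could not place ",
         "all rich-club regions in the top-12 degrees")
  })
}

template_matrix <- function(template, weights, parcellation, threshold) {
  n <- template$n
  w <- matrix(0, n, n)
  w[cbind(template$i, template$j)] <- weights
  w[cbind(template$j, template$i)] <- weights
  new_connectivity_matrix(w, parcellation, threshold)
}

# Class mean strengths straight from a template weight vector (zero
# weights = pruned edges are excluded, mirroring class_mean_strength()).
template_class_means <- function(template, weights) {
  out <- c(rich_club = NA_real_, feeder = NA_real_, peripheral = NA_real_)
  for (cl in names(out)) {
    v <- weights[template$class == cl & weights > 0]
    if (length(v)) out[[cl]] <- mean(v)
  }
  out
}

template_efficiency <- function(template, weights) {
  keep <- weights > 0
  g <- igraph::make_empty_graph(n = template$n, directed = FALSE)
  g <- igraph::add_edges(g, rbind(template$i[keep], template$j[keep]))
  d <- igraph::distances(g, weights = 1 / weights[keep],
                         algorithm = "dijkstra")
  inv <- 1 / d
  inv[!is.finite(inv)] <- 0
  diag(inv) <- 0
  sum(inv) / (template$n * (template$n - 1))
}

# Solve an intercept so that the in-sample mean event probability matches
# a target rate, given a linear predictor without intercept.
calibrate_intercept <- function(lin, target, inverse_link = stats::plogis) {
  stats::uniroot(function(i) mean(inverse_link(i + lin)) - target,
                 interval = c(-30, 30), tol = 1e-10)$root
}

#' Generate a synthetic two-wave SVD cohort with known injected effects
#'
#' Draws a complete synthetic cohort: demographics, SVD markers (log-normal
#' WMH volumes, Poisson lacune and microbleed counts driven by a latent
#' burden), per-subject baseline and follow-up connectivity matrices
#' (perturbations of a hub-premium geometric template graph, weakened with
#' burden), per-class connection-strength decline correlated with WMH
#' progression, cognitive composites driven by peripheral-strength decline
#' (with a configurable direct WMH effect, default 0), and a follow-up
#' dementia indicator driven by baseline global efficiency and peripheral
#' strength. All randomness flows from `seed` through named substreams, so
#' the cohort is fully reproducible.
#'
#' @param config A [cohort_config()].
#' @param seed Integer master seed.
#' @param networks Logical; keep the per-subject-wave connectivity
#'   matrices (set `FALSE` for large calibration-only cohorts).
#' @param raw_tests Logical; additionally synthesize raw neuropsychological
#'   test scores consistent with the generated composites.
#' @return Object of class `synthetic_cohort`: `cohort` (long data frame,
#'   one row per subject-wave), `networks` (per subject: `baseline` and
#'   `followup` connectivity matrices, or `NULL`), `network_measures`
#'   (the generator's own per-subject-wave class strengths and baseline
#'   efficiency, for internal wiring; analyses should recompute from the
#'   matrices), and `ground_truth` (every injected parameter).
#' @export
generate_cohort <- function(config = cohort_config(), seed = 1,
                            networks = TRUE, raw_tests = FALSE) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n_subjects
  parc <- config$parcellation
  ids <- sprintf("S%04d", seq_len(n))

  template <- build_network_template(config, substream_seed(seed, "template"))

  ## --- demographics / SVD markers -----------------------------------
  lnorm <- lognormal_from_median_iqr(config$wmh_median_ml, config$wmh_iqr_ml)
  demo <- with_seed(substream_seed(seed, "demographics"), {
    age <- stats::rnorm(n, config$age_mean, config$age_sd)
    sex <- ifelse(stats::runif(n) < config$prop_male, "M", "F")
    edu <- pmax(stats::rnorm(n, config$education_mean, config$education_sd), 0)
    fup <- pmax(stats::rnorm(n, config$followup_years_mean,
                             config$followup_years_sd), 0.5)
    burden <- stats::rnorm(n)
    progression <- stats::rnorm(n)
    wmh_bl <- exp(lnorm$meanlog + lnorm$sdlog * burden)
    wmh_fu <- wmh_bl * exp(config$wmh_growth_log_mean +
                           config$wmh_growth_log_sd * progression)
    l0 <- calibrate_intercept(0.7 * burden, config$lacune_prevalence,
                              function(x) 1 - exp(-exp(x)))
    lac_bl <- stats::rpois(n, exp(l0 + 0.7 * burden))
    m0 <- calibrate_intercept(0.6 * burden, config$microbleed_prevalence,
                              function(x) 1 - exp(-exp(x)))
    mb_bl <- stats::rpois(n, exp(m0 + 0.6 * burden))
    lac_fu <- lac_bl + stats::rpois(n, 0.10 * exp(0.3 * progression))
    mb_fu <- mb_bl + stats::rpois(n, 0.08 * exp(0.3 * progression))
    h0 <- calibrate_intercept(0.5 * burden, config$hypertension_prevalence)
    htn <- stats::rbinom(n, 1, stats::plogis(h0 + 0.5 * burden))
    tbv_bl <- 1066.2 - 20 * burden + stats::rnorm(n, 0, 75)
    gm_bl <- 0.5727 * tbv_bl + stats::rnorm(n, 0, 20)
    atrophy <- pmax(8 + 3 * burden + stats::rnorm(n, 0, 4), 0)
    list(age = age, sex = sex, edu = edu, fup = fup, burden = burden,
         progression = progression, wmh_bl = wmh_bl, wmh_fu = wmh_fu,
         lac_bl = lac_bl, lac_fu = lac_fu, mb_bl = mb_bl, mb_fu = mb_fu,
         htn = htn, tbv_bl = tbv_bl, gm_bl = gm_bl,
         tbv_fu = tbv_bl - atrophy, gm_fu = gm_bl - 0.6 * atrophy,
         lacune_intercept = l0, microbleed_intercept = m0,
         hypertension_intercept = h0)
  })

  ## --- connectomes ---------------------------------------------------
  ne <- length(template$base_weight)
  cls_idx <- template$class
  nets <- with_seed(substream_seed(seed, "networks"), {
    w_bl <- matrix(0, n, ne)
    w_fu <- matrix(0, n, ne)
    delta <- matrix(0, n, 3,
                    dimnames = list(NULL,
                                    c("rich_club", "feeder", "peripheral")))
    rho <- config$wmh_network_effect
    subj_factor <- exp(config$burden_network_effect * demo$burden +
                       config$subject_network_sd * stats::rnorm(n))
    for (s in seq_len(n)) {
      jit <- exp(config$edge_jitter_sd * stats::rnorm(ne) -
                 config$edge_jitter_sd^2 / 2)
      wb <- template$base_weight * subj_factor[s] * jit
      wb[wb < config$threshold] <- 0
      mu <- template_class_means(template, wb)
      dcl <- config$decline_mean[colnames(delta)] +
        config$decline_sd[colnames(delta)] *
          (rho * demo$progression[s] +
           sqrt(1 - rho^2) * stats::rnorm(3))
      delta[s, ] <- dcl
      fac <- pmax(1 + dcl / mu, 0.05)
      wf <- wb * fac[as.integer(cls_idx)]
      wf[wf < config$threshold] <- 0
      w_bl[s, ] <- wb
      w_fu[s, ] <- wf
    }
    list(w_bl = w_bl, w_fu = w_fu, delta = delta,
         subj_factor = subj_factor)
  })

  meas <- data.frame(subject_id = rep(ids, each = 2L),
                     wave = rep(c("baseline", "followup"), n),
                     stringsAsFactors = FALSE)
  cm_bl <- t(vapply(seq_len(n), function(s)
    template_class_means(template, nets$w_bl[s, ]), numeric(3)))
  cm_fu <- t(vapply(seq_len(n), function(s)
    template_class_means(template, nets$w_fu[s, ]), numeric(3)))
  eff_bl <- vapply(seq_len(n), function(s)
    template_efficiency(template, nets$w_bl[s, ]), 0)
  meas$rich_club_strength <- as.vector(rbind(cm_bl[, 1], cm_fu[, 1]))
  meas$feeder_strength <- as.vector(rbind(cm_bl[, 2], cm_fu[, 2]))
  meas$peripheral_strength <- as.vector(rbind(cm_bl[, 3], cm_fu[, 3]))
  meas$global_efficiency <- as.vector(rbind(eff_bl, rep(NA_real_, n)))

  ## --- cognition -----------------------------------------------------
  b <- config$network_cognition_effect
  dir <- config$wmh_cognition_direct
  cog <- with_seed(substream_seed(seed, "cognition"), {
    g <- stats::rnorm(n, 0, 0.6)
    bl <- data.frame(
      memory = g + stats::rnorm(n, 0, 0.45),
      psychomotor_speed = g + stats::rnorm(n, 0, 0.45),
      executive_function = g + stats::rnorm(n, 0, 0.45))
    bl$cognitive_index <- rowMeans(bl) + stats::rnorm(n, 0, 0.15)
    zdp <- (nets$delta[, "peripheral"] -
              config$decline_mean[["peripheral"]]) /
      config$decline_sd[["peripheral"]]
    resid_sd <- sqrt(max(0, 1 - b^2 - dir^2))
    dl <- list()
    for (d in names(config$cognition_change_mean)) {
      driven <- d != "memory"
      dl[[d]] <- config$cognition_change_mean[[d]] +
        config$cognition_change_sd *
          (if (driven) b * zdp + dir * demo$progression +
             resid_sd * stats::rnorm(n)
           else stats::rnorm(n))
    }
    list(baseline = bl, delta = as.data.frame(dl))
  })

  ## --- dementia ------------------------------------------------------
  dem <- with_seed(substream_seed(seed, "dementia"), {
    zE <- as.vector(scale(eff_bl))
    zP <- as.vector(scale(cm_bl[, 3]))
    lin <- config$dementia_efficiency_logodds * zE +
      config$dementia_peripheral_logodds * zP +
      config$wmh_dementia_direct_logodds * demo$burden
    i0 <- calibrate_intercept(lin, config$dementia_base_rate)
    list(flag = stats::rbinom(n, 1, stats::plogis(i0 + lin)),
         intercept = i0)
  })

  ## --- assemble cohort table ----------------------------------------
  two <- function(bl, fu) as.vector(rbind(bl, fu))
  cohort <- data.frame(
    subject_id = rep(ids, each = 2L),
    wave = rep(c("baseline", "followup"), n),
    age = two(demo$age, demo$age + demo$fup),
    sex = rep(demo$sex, each = 2L),
    education_years = rep(demo$edu, each = 2L),
    followup_years = rep(demo$fup, each = 2L),
    hypertension = rep(demo$htn, each = 2L),
    wmh_ml = two(demo$wmh_bl, demo$wmh_fu),
    lacune_count = two(demo$lac_bl, demo$lac_fu),
    microbleed_count = two(demo$mb_bl, demo$mb_fu),
    total_brain_ml = two(demo$tbv_bl, demo$tbv_fu),
    grey_matter_ml = two(demo$gm_bl, demo$gm_fu),
    dementia = two(rep(0L, n), dem$flag),
    stringsAsFactors = FALSE)
  cohort$white_matter_ml <- cohort$total_brain_ml - cohort$grey_matter_ml
  for (d in c("cognitive_index", "memory", "psychomotor_speed",
              "executive_function"))
    cohort[[d]] <- two(cog$baseline[[d]], cog$baseline[[d]] + cog$delta[[d]])

  if (raw_tests)
    cohort <- cbind(cohort, synthesize_raw_tests(cohort, seed))

  net_list <- NULL
  if (networks) {
    net_list <- lapply(seq_len(n), function(s) list(
      baseline = template_matrix(template, nets$w_bl[s, ], parc,
                                 config$threshold),
      followup = template_matrix(template, nets$w_fu[s, ], parc,
                                 config$threshold)))
    names(net_list) <- ids
  }

  ground_truth <- list(
    config = config,
    wmh_lognormal = lnorm,
    decline_mean = config$decline_mean,
    decline_sd = config$decline_sd,
    wmh_network_effect = config$wmh_network_effect,
    network_cognition_effect = config$network_cognition_effect,
    wmh_cognition_direct = config$wmh_cognition_direct,
    dementia_intercept = dem$intercept,
    lacune_intercept = demo$lacune_intercept,
    microbleed_intercept = demo$microbleed_intercept,
    hypertension_intercept = demo$hypertension_intercept,
    template_density = length(template$base_weight) /
      (template$n * (template$n - 1) / 2),
    template_rich_degrees = template$degree[
      parc$labels %in% parc$rich_club],
    latent_burden = demo$burden,
    latent_progression = demo$progression,
    injected_delta = nets$delta,
    seed = seed)

  structure(list(cohort = cohort, networks = net_list,
                 network_measures = meas, ground_truth = ground_truth,
                 parcellation = parc, config = config, seed = seed,
                 template = template),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("Synthetic SVD cohort:", x$config$n_subjects,
      "subjects x 2 waves, seed", x$seed, "\n")
  cat(sprintf("  WMH median %.2f ml; dementia rate %.1f%%; %s\n",
              stats::median(x$cohort$wmh_ml[x$cohort$wave == "baseline"]),
              100 * mean(x$cohort$dementia[x$cohort$wave == "followup"]),
              if (is.null(x$networks)) "networks not retained"
              else "networks retained"))
  invisible(x)
}

# Plausible raw-score scales per derived test score; SAT-based tests carry
# a fixed item count from which completion times are back-computed.
raw_test_norms <- function() {
  data.frame(
    score = c("ravlt_imm", "ravlt_del", "rcft_imm", "rcft_del",
              "ppmst1_sat", "ppmst2_sat", "ppmst3_sat",
              "stroop_read_sat", "stroop_name_sat", "stroop_cw_sat",
              "sdst", "fluency", "vsat_sat"),
    mean = c(40, 8, 18, 17, 1.4, 0.9, 0.7, 2.4, 1.8, 0.9, 45, 22, 1.1),
    sd = c(10, 3, 6, 6, 0.4, 0.3, 0.25, 0.5, 0.4, 0.35, 10, 6, 0.3),
    n_items = c(NA, NA, NA, NA, 24, 24, 24, 100, 100, 100, NA, NA, 55),
    stringsAsFactors = FALSE)
}

# Synthesize per-test raw scores whose module-computed composites track the
# generated composite columns (constituent test z = domain composite +
# test-specific scatter; timed tests are expressed as item counts and
# completion times, Stroop colour-word via the target interference ratio).
synthesize_raw_tests <- function(cohort, seed) {
  norms <- raw_test_norms()
  rw <- function(score) norms[norms$score == score, , drop = FALSE]
  domains <- cognitive_domains()
  with_seed(substream_seed(seed, "raw_tests"), {
    nr <- nrow(cohort)
    test_z <- function(domain) cohort[[domain]] + stats::rnorm(nr, 0, 0.6)
    sat_val <- function(score, domain) {
      r <- rw(score)
      pmax(r$mean + r$sd * test_z(domain), 0.05)
    }
    plain <- function(score, domain) {
      r <- rw(score)
      r$mean + r$sd * test_z(domain)
    }
    out <- data.frame(row.names = seq_len(nr))
    out$ravlt_imm <- plain("ravlt_imm", "memory")
    out$ravlt_del <- plain("ravlt_del", "memory")
    out$rcft_imm <- plain("rcft_imm", "memory")
    out$rcft_del <- plain("rcft_del", "memory")
    for (spec in list(c("ppmst1", "ppmst1_sat", "psychomotor_speed"),
                      c("ppmst2", "ppmst2_sat", "memory"),
                      c("ppmst3", "ppmst3_sat", "memory"),
                      c("stroop_read", "stroop_read_sat",
                        "psychomotor_speed"),
                      c("stroop_name", "stroop_name_sat",
                        "psychomotor_speed"),
                      c("vsat", "vsat_sat", "executive_function"))) {
      r <- rw(spec[2])
      sat <- sat_val(spec[2], spec[3])
      out[[paste0(spec[1], "_correct")]] <- rep(r$n_items, nr)
      out[[paste0(spec[1], "_time")]] <- r$n_items / sat
    }
    # colour-word SAT chosen so the interference ratio carries the
    # executive-function signal
    interference <- pmax(0.43 + 0.12 * test_z("executive_function"), 0.05)
    mean_rn <- (rw("stroop_read_sat")$n_items /
                  out$stroop_read_time +
                rw("stroop_name_sat")$n_items /
                  out$stroop_name_time) / 2
    cw_sat <- pmax(interference * mean_rn, 0.05)
    out$stroop_cw_correct <- rep(rw("stroop_cw_sat")$n_items, nr)
    out$stroop_cw_time <- rw("stroop_cw_sat")$n_items / cw_sat
    out$sdst <- plain("sdst", "psychomotor_speed")
    out$fluency <- plain("fluency", "executive_function")
    out
  })
}

#' Invert a connectivity matrix into streamline records
#'
#' Emits, for every present edge, `k` streamline records whose scaled
#' inverse lengths sum exactly to the edge weight, so that
#' [build_connectivity_matrix()] on the result reproduces the matrix (an
#' exact right inverse, used to exercise the connectome builder
#' end-to-end). By default the `k` records of an edge share one length
#' `l = k * scale / weight`; with `jitter = TRUE` lengths vary randomly
#' while preserving the exact inverse-length sum.
#'
#' @param target A `connectivity_matrix` with non-negative weights.
#' @param k Streamline records per edge (>= 1).
#' @param scale Seed-density scale factor recorded on the output.
#' @param jitter Logical; randomize lengths within each edge.
#' @param seed Seed for the jitter (ignored when `jitter = FALSE`).
#' @param subject_id,wave Identifiers for the returned [streamline_set].
#' @return A [streamline_set] with `k` records per present edge.
#' @export
streamlines_for_matrix <- function(target, k = 3L, scale = 1,
                                   jitter = FALSE, seed = 1,
                                   subject_id = "S1", wave = "baseline") {
  validate_connectivity_matrix(target)
  if (k < 1L) stop("`k` must be at least 1")
  w <- target$weights
  labels <- target$parcellation$labels
  ut <- which(upper.tri(w) & w != 0, arr.ind = TRUE)
  wt <- w[ut]
  if (any(wt <= 0)) stop("edge weights must be strictly positive")
  if (!nrow(ut)) {
    rec <- data.frame(region_a = character(), region_b = character(),
                      length = numeric())
    return(streamline_set(rec, scale = scale, subject_id = subject_id,
                          wave = wave, parcellation = target$parcellation))
  }
  inv_per_record <- if (jitter) {
    with_seed(seed, {
      u <- matrix(stats::runif(nrow(ut) * k, 0.5, 1.5), nrow(ut), k)
      (wt / scale) * u / rowSums(u)
    })
  } else matrix(wt / (scale * k), nrow(ut), k)
  rec <- data.frame(
    region_a = rep(labels[ut[, 1L]], each = k),
    region_b = rep(labels[ut[, 2L]], each = k),
    length = as.vector(t(1 / inv_per_record)))
  streamline_set(rec, scale = scale, subject_id = subject_id, wave = wave,
                 parcellation = target$parcellation)
}
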