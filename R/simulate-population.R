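#' Configuration for simulating a study population
#'
#' Describes a cohort of riding horses measured in the four study conditions
#' (straight line on hard and soft surface, lunge left and right) with
#' rider-linked questionnaire responses. Defaults emulate the study
#' conditions: 123 horses in three disciplines, 51 riders (a rider may ride
#' several horses), roughly 70% of horses carrying a genuinely
#' above-threshold asymmetry, stride counts and missing-trial rates per
#' condition as observed, and questionnaire marginals matching the reported
#' response distribution. Under the null
#' (`sidedness_association_effect = 0`) questionnaire answers are
#' independent of the horses' asymmetries; a positive effect shifts each
#' lunge parameter magnitude by `effect * grade` mm for riders perceiving
#' sidedness grade 1 (mild) and above.
#'
#' @param n_horses,n_riders Cohort sizes; riders are assigned to horses at
#'   random, so `n_riders <= n_horses` is not required.
#' @param discipline_mix Named fractions over
#'   `show_jumping`/`dressage`/`eventing`; must be non-negative and sum to 1.
#' @param asymmetry_prevalence Probability that a horse has a true
#'   above-threshold asymmetry.
#' @param trigger_probs Per-parameter probability that an asymmetric horse's
#'   given parameter is one of its above-threshold ones (at least one is
#'   forced).
#' @param effect_range Magnitude of a triggered parameter's true trial mean,
#'   as uniform multiples of its threshold (default 1.2-2.5 x).
#' @param sub_effect_max Magnitude cap of non-triggered parameters, as a
#'   multiple of the threshold (default 0.6 x, i.e. clearly sub-threshold).
#' @param stride_sd_head,stride_sd_pelvis Stride-to-stride SD of head and
#'   pelvic differences, mm.
#' @param n_strides_mean,n_strides_sd,n_strides_min,n_strides_max Per-trial
#'   stride-count distribution (normal, rounded, clipped), named by
#'   `straight_hard`/`straight_soft`/`lunge`.
#' @param missing_prob Probability a horse lacks each condition entirely,
#'   same names (lunge missing drops both directions).
#' @param stride_duration_mean Population mean stride duration, s.
#' @param stride_duration_sd_between Between-trial SD of mean duration, s.
#' @param stride_duration_cv Within-trial duration coefficient of variation.
#' @param condition_jitter_sd Between-condition jitter of a horse's true
#'   parameter means, mm.
#' @param lunge_offset_hd,lunge_offset_pd Systematic direction-dependent
#'   lunge shift of `hd_min`/`pd_min`, mm (subtracted on the left circle,
#'   added on the right).
#' @param rider_effect_sd SD of a rider-level shift added to the horse's
#'   parameter magnitudes, mm.
#' @param outlier_stride_prob,outlier_magnitude Rate and size (mm, on
#'   `hd_min`) of sporadic outlier strides.
#' @param questionnaire_coverage Fraction of horses with questionnaire
#'   responses.
#' @param sidedness_association_effect mm per perceived-sidedness grade
#'   added to lunge parameter magnitudes; 0 = null association.
#' @param seed Optional integer seed.
#' @return A validated list of class `population_config`.
#' @export
population_config <- function(n_horses = 123,
                              n_riders = 51,
                              discipline_mix = c(show_jumping = 61 / 123,
                                                 dressage = 47 / 123,
                                                 eventing = 15 / 123),
                              asymmetry_prevalence = 0.7,
                              trigger_probs = c(hd_min = 0.49, hd_max = 0.35,
                                                pd_min = 0.54, pd_max = 0.47),
                              effect_range = c(1.2, 2.5),
                              sub_effect_max = 0.6,
                              stride_sd_head = 2,
                              stride_sd_pelvis = 1.5,
                              n_strides_mean = c(straight_hard = 33,
                                                 straight_soft = 31, lunge = 56),
                              n_strides_sd = c(straight_hard = 9.7,
                                               straight_soft = 9.8, lunge = 20),
                              n_strides_min = c(straight_hard = 17,
                                                straight_soft = 16, lunge = 25),
                              n_strides_max = c(straight_hard = 63,
                                                straight_soft = 60, lunge = 178),
                              missing_prob = c(straight_hard = 9 / 123,
                                               straight_soft = 12 / 123,
                                               lunge = 2 / 123),
                              stride_duration_mean = 0.7,
                              stride_duration_sd_between = 0.03,
                              stride_duration_cv = 0.05,
                              condition_jitter_sd = 0.5,
                              lunge_offset_hd = 3,
                              lunge_offset_pd = 4,
                              rider_effect_sd = 1,
                              outlier_stride_prob = 0.01,
                              outlier_magnitude = 40,
                              questionnaire_coverage = 71 / 123,
                              sidedness_association_effect = 0,
                              seed = NULL) {
  cfg <- as.list(environment())
  if (n_horses < 1 || n_riders < 1) {
    abort("`n_horses` and `n_riders` must be >= 1", class = "equisym_config_error")
  }
  if (any(discipline_mix < 0) || abs(sum(discipline_mix) - 1) > 1e-8) {
    abort("`discipline_mix` must be non-negative fractions summing to 1",
          class = "equisym_config_error")
  }
  probs <- c(asymmetry_prevalence, trigger_probs, missing_prob,
             outlier_stride_prob, questionnaire_coverage)
  if (any(probs < 0 | probs > 1)) {
    abort("probabilities must lie in [0, 1]", class = "equisym_config_error")
  }
  if (length(effect_range) != 2 || effect_range[1] <= 1 ||
      diff(effect_range) < 0) {
    abort("`effect_range` must be an increasing pair of multipliers > 1",
          class = "equisym_config_error")
  }
  structure(cfg, class = "population_config")
}

# questionnaire answer marginals (study-like response distribution)
q_marginals <- function() {
  list(
    q1_sidedness = c(no = 0.085, mild = 0.662, moderate = 0.225, severe = 0.028),
    q2_weak_hind = c(no = 0.380, left = 0.296, right = 0.296, na = 0.028),
    q3_rein = c(no = 0.310, left = 0.352, right = 0.338, na = 0),
    q4_drift = c(no = 0.451, left = 0.254, right = 0.281, na = 0.014),
    q5_rider_side = c(no = 0.451, left = 0.240, right = 0.309, na = 0)
  )
}

draw_levels <- function(n, probs) {
  sample(names(probs), n, replace = TRUE, prob = probs / sum(probs))
}

#' Simulate a study population with known ground truth
#'
#' Draws horses, riders, per-horse true asymmetry effects, stride-level
#' parameter tables for the four conditions, and rider questionnaire
#' responses from a [population_config()]. Asymmetric horses carry at least
#' one parameter whose true trial mean clearly exceeds its threshold;
#' symmetric horses stay clearly below all thresholds, so downstream
#' classification recovers the configured prevalence up to sampling noise.
#' Everything is reproducible given `seed`.
#'
#' @param config A [population_config()].
#' @param thresholds The [asym_thresholds()] the effect magnitudes are
#'   anchored to.
#' @return A list of tibbles:
#'   \describe{
#'     \item{horses}{one row per horse: ids, discipline, `true_asymmetric`,
#'       true per-parameter straight-line effects (mm).}
#'     \item{trials}{one row per simulated trial: condition, stride count,
#'       trial mean duration, the condition-specific true parameter means.}
#'     \item{strides}{stride-level table: `horse_id`, `condition`,
#'       `stride_index`, `duration_s`, the four `*_mm` parameters,
#'       `outlier` (truth flag).}
#'     \item{questionnaire}{one row per covered horse: `horse_id`,
#'       `rider_id`, answers `q1_sidedness` ... `q5_rider_side`.}
#'   }
#' @export
#' @examples
#' pop <- simulate_population(population_config(n_horses = 10, seed = 1))
#' pop$horses
simulate_population <- function(config = population_config(),
                                thresholds = asym_thresholds()) {
  if (!inherits(config, "population_config")) {
    config <- do.call(population_config, config)
  }
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- config$n_horses
  thr <- threshold_vector(thresholds)
  params <- asym_params()$parameter

  horses <- tibble::tibble(
    horse_id = sprintf("H%03d", seq_len(n)),
    rider_id = sprintf("R%03d", sample.int(config$n_riders, n, replace = TRUE)),
    discipline = draw_levels(n, config$discipline_mix),
    true_asymmetric = runif(n) < config$asymmetry_prevalence
  )

  # per-horse true straight-line effects: triggered parameters clearly above
  # threshold, the rest clearly below; at least one trigger per asymmetric horse
  trig <- matrix(runif(n * 4) < rep(config$trigger_probs, each = n), n, 4)
  none <- !rowSums(trig)
  trig[cbind(which(none), sample.int(4, sum(none), replace = TRUE))] <- TRUE
  trig <- trig & horses$true_asymmetric
  magnitude <- matrix(runif(n * 4, config$effect_range[1], config$effect_range[2]),
                      n, 4) * rep(thr, each = n)
  sub_mag <- matrix(runif(n * 4, 0, config$sub_effect_max), n, 4) * rep(thr, each = n)
  rider_shift <- rnorm(config$n_riders, 0, config$rider_effect_sd)
  shift <- rider_shift[as.integer(sub("R", "", horses$rider_id))]
  eff_mag <- ifelse(trig, magnitude, sub_mag)
  eff_mag <- pmax(eff_mag + shift, 0)
  # the rider shift must not blur the design margins: triggered parameters
  # stay above threshold, non-triggered ones clearly below
  thr_mat <- rep(thr, each = n)
  eff_mag <- ifelse(trig, pmax(eff_mag, 1.2 * thr_mat),
                    pmin(eff_mag, 0.7 * thr_mat))
  sign_mat <- matrix(sample(c(-1, 1), n * 4, replace = TRUE), n, 4)
  effects <- eff_mag * sign_mat
  colnames(effects) <- paste0("effect_", params, "_mm")
  horses <- dplyr::bind_cols(horses, tibble::as_tibble(effects))

  # questionnaire (drawn before trials so an association effect can feed back)
  n_q <- round(config$questionnaire_coverage * n)
  q_ids <- sort(sample.int(n, n_q))
  qm <- q_marginals()
  questionnaire <- tibble::tibble(
    horse_id = horses$horse_id[q_ids],
    rider_id = horses$rider_id[q_ids],
    q1_sidedness = draw_levels(n_q, qm$q1_sidedness),
    q2_weak_hind = draw_levels(n_q, qm$q2_weak_hind),
    q3_rein = draw_levels(n_q, qm$q3_rein),
    q4_drift = draw_levels(n_q, qm$q4_drift),
    q5_rider_side = draw_levels(n_q, qm$q5_rider_side)
  )
  grade <- rep(0, n)
  grade[q_ids] <- dplyr::case_when(
    questionnaire$q1_sidedness == "mild" ~ 1,
    questionnaire$q1_sidedness == "moderate" ~ 2,
    questionnaire$q1_sidedness == "severe" ~ 3,
    TRUE ~ 0
  )

  conditions <- c("straight_hard", "straight_soft", "lunge_left", "lunge_right")
  cond_group <- c(straight_hard = "straight_hard", straight_soft = "straight_soft",
                  lunge_left = "lunge", lunge_right = "lunge")
  missing_draw <- sapply(c("straight_hard", "straight_soft", "lunge"), function(g) {
    runif(n) < config$missing_prob[[g]]
  })

  trials <- tidyr::expand_grid(horse_id = horses$horse_id, condition = conditions) |>
    dplyr::mutate(group = cond_group[.data$condition])
  present <- !missing_draw[cbind(
    match(trials$horse_id, horses$horse_id), match(trials$group, colnames(missing_draw))
  )]
  trials <- trials[present, ]

  nt <- nrow(trials)
  mu_n <- config$n_strides_mean[trials$group]
  sd_n <- config$n_strides_sd[trials$group]
  trials$n_strides <- pmin(pmax(round(rnorm(nt, mu_n, sd_n)),
                                config$n_strides_min[trials$group]),
                           config$n_strides_max[trials$group])
  trials$trial_duration_s <- rnorm(nt, config$stride_duration_mean,
                                   config$stride_duration_sd_between)

  # condition-specific true means: straight effects + jitter; lunge adds the
  # systematic direction shift and any questionnaire-linked magnitude shift
  hrow <- match(trials$horse_id, horses$horse_id)
  base <- effects[hrow, , drop = FALSE]
  jitter <- matrix(rnorm(nt * 4, 0, config$condition_jitter_sd), nt, 4)
  mu <- base + jitter
  dir_sign <- ifelse(trials$condition == "lunge_left", -1,
                     ifelse(trials$condition == "lunge_right", 1, 0))
  mu[, 1] <- mu[, 1] + dir_sign * config$lunge_offset_hd
  mu[, 3] <- mu[, 3] + dir_sign * config$lunge_offset_pd
  is_lunge <- trials$group == "lunge"
  assoc <- config$sidedness_association_effect * grade[hrow] * is_lunge
  mu <- sign(mu) * (abs(mu) + assoc)
  colnames(mu) <- paste0("true_", params, "_mm")
  trials <- dplyr::bind_cols(dplyr::select(trials, -"group"), tibble::as_tibble(mu))

  strides <- trials |>
    dplyr::select("horse_id", "condition", "n_strides", "trial_duration_s",
                  dplyr::starts_with("true_")) |>
    tidyr::uncount(.data$n_strides, .id = "stride_index")
  ns <- nrow(strides)
  sds <- c(config$stride_sd_head, config$stride_sd_head,
           config$stride_sd_pelvis, config$stride_sd_pelvis)
  vals <- sapply(1:4, function(j) {
    strides[[paste0("true_", params[j], "_mm")]] + rnorm(ns, 0, sds[j])
  })
  outlier <- runif(ns) < config$outlier_stride_prob
  vals[, 1] <- vals[, 1] + outlier * config$outlier_magnitude *
    sample(c(-1, 1), ns, replace = TRUE)
  colnames(vals) <- paste0(params, "_mm")

  strides <- dplyr::bind_cols(
    dplyr::select(strides, "horse_id", "condition", "stride_index"),
    tibble::tibble(
      duration_s = strides$trial_duration_s *
        (1 + config$stride_duration_cv * rnorm(ns))
    ),
    tibble::as_tibble(vals),
    tibble::tibble(outlier = outlier)
  )

  list(horses = horses, trials = trials, strides = strides,
       questionnaire = questionnaire)
}
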