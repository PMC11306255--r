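#' Configuration for the synthetic longitudinal cohort generator
#'
#' `sim_config()` assembles and validates the generative model for an
#' ALSPAC-like cohort: nine clinic visits (ages ~7.5-17.8 y) measuring
#' height, weight and bone mineral content, and nine puberty questionnaires
#' (ages ~8-17 y) collecting Tanner stages (pubic hair; breast in females;
#' genitalia in males), axillary hair, voice breaking (males) and menarche
#' (females). Each individual carries a latent common timing factor; the
#' per-measure timing effects load on it, which induces the positive
#' inter-measure correlations seen in cohort data.
#'
#' @param n_per_sex individuals per sex.
#' @param clinic_ages nominal clinic visit ages (years), strictly increasing.
#' @param questionnaire_ages nominal questionnaire ages (years).
#' @param measures named list of per-measure definitions from
#'   [measure_def()]; defaults cover the full nine-indicator battery.
#' @param cross_measure_timing_correlation scalar in `[0, 1]`: common
#'   correlation between per-measure timing effects, implemented as a
#'   one-factor loading `sqrt(rho)` on the shared latent timing factor.
#' @param timing_cor_matrix optional explicit correlation matrix for the
#'   per-measure timing effects (rows/cols in `names(measures)` order,
#'   menarche included); overrides the one-factor structure.
#' @param latent_timing_sd SD (years) of the latent common timing factor.
#' @param age_jitter_sd SD (years) of the per-visit jitter around nominal
#'   ages (default 2 months).
#' @param missingness_rate probability that an individual misses a whole
#'   assessment occasion (clinic visit or questionnaire).
#' @param inconsistency_rate probability that a reported ordinal stage
#'   regresses by one category.
#' @param menarche_recall_sd SD (years) of recall noise on the reported age
#'   at menarche.
#' @param grs_timing_correlation target correlation between the simulated
#'   standardized genetic risk score and the latent timing factor.
#' @param fmi_effect,lmi_effect direct effect (years per SD) of childhood
#'   fat/lean mass index on the latent timing factor.
#' @param confounder_effect effect (years per SD) of the maternal/childhood
#'   confounder composite on the latent timing factor.
#' @param fmi_confounder_loading correlation between fat mass index and the
#'   confounder composite (the confounding path).
#' @param seed integer RNG seed stored in the config; `simulate_cohort()`
#'   uses it unless overridden.
#' @return object of class `sim_config`.
#' @seealso [simulate_cohort()], [measure_def()]
#' @export
sim_config <- function(n_per_sex = 250,
                       clinic_ages = c(7.5, 8.5, 9.9, 10.7, 11.8, 12.8,
                                       13.8, 15.4, 17.8),
                       questionnaire_ages = c(8.1, 9.6, 10.6, 11.7, 13.1,
                                              14.6, 15.4, 16.1, 17.0),
                       measures = default_measures(),
                       cross_measure_timing_correlation = 0.55,
                       timing_cor_matrix = NULL,
                       latent_timing_sd = 1.0,
                       age_jitter_sd = 2 / 12,
                       missingness_rate = 0.1,
                       inconsistency_rate = 0.03,
                       menarche_recall_sd = 0.25,
                       grs_timing_correlation = 0.25,
                       fmi_effect = -0.35,
                       lmi_effect = -0.25,
                       confounder_effect = -0.15,
                       fmi_confounder_loading = 0.3,
                       seed = 20240807L) {
  cfg <- list(n_per_sex = n_per_sex, clinic_ages = clinic_ages,
              questionnaire_ages = questionnaire_ages, measures = measures,
              cross_measure_timing_correlation = cross_measure_timing_correlation,
              timing_cor_matrix = timing_cor_matrix,
              latent_timing_sd = latent_timing_sd,
              age_jitter_sd = age_jitter_sd,
              missingness_rate = missingness_rate,
              inconsistency_rate = inconsistency_rate,
              menarche_recall_sd = menarche_recall_sd,
              grs_timing_correlation = grs_timing_correlation,
              fmi_effect = fmi_effect, lmi_effect = lmi_effect,
              confounder_effect = confounder_effect,
              fmi_confounder_loading = fmi_confounder_loading,
              seed = seed)
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  fail <- function(field, msg) stop("invalid `", field, "`: ", msg, call. = FALSE)
  if (!is.numeric(cfg$n_per_sex) || length(cfg$n_per_sex) != 1L ||
      cfg$n_per_sex < 1 || cfg$n_per_sex != round(cfg$n_per_sex))
    fail("n_per_sex", "must be a positive integer")
  if (is.unsorted(cfg$clinic_ages, strictly = TRUE))
    fail("clinic_ages", "must be strictly increasing")
  if (is.unsorted(cfg$questionnaire_ages, strictly = TRUE))
    fail("questionnaire_ages", "must be strictly increasing")
  for (nm in c("latent_timing_sd", "age_jitter_sd", "menarche_recall_sd"))
    if (cfg[[nm]] < 0) fail(nm, "must be non-negative")
  for (nm in c("missingness_rate", "inconsistency_rate"))
    if (cfg[[nm]] < 0 || cfg[[nm]] > 1) fail(nm, "must be in [0, 1]")
  if (cfg$cross_measure_timing_correlation < 0 ||
      cfg$cross_measure_timing_correlation > 1)
    fail("cross_measure_timing_correlation", "must be in [0, 1]")
  if (abs(cfg$grs_timing_correlation) > 1)
    fail("grs_timing_correlation", "must be in [-1, 1]")
  if (abs(cfg$fmi_confounder_loading) > 1)
    fail("fmi_confounder_loading", "must be in [-1, 1]")
  if (!length(cfg$measures) || is.null(names(cfg$measures)))
    fail("measures", "must be a named list of measure_def objects")
  for (m in names(cfg$measures)) {
    md <- cfg$measures[[m]]
    if (!inherits(md, "measure_def")) fail("measures", paste0(m, " is not a measure_def"))
    for (nm in c("timing_sd", "size_sd", "intensity_sd", "postgrowth_sd", "residual_sd"))
      if (!is.null(md[[nm]]) && any(md[[nm]] < 0))
        fail(paste0("measures$", m, "$", nm), "must be non-negative")
    if (!is.na(md$timing_loading) && (md$timing_loading < 0 || md$timing_loading > 1))
      fail(paste0("measures$", m, "$timing_loading"), "must be in [0, 1]")
  }
  if (!is.null(cfg$timing_cor_matrix)) {
    tm <- cfg$timing_cor_matrix
    k <- length(cfg$measures)
    if (!is.matrix(tm) || nrow(tm) != k || ncol(tm) != k ||
        any(abs(tm) > 1) || any(abs(tm - t(tm)) > 1e-10) ||
        min(eigen(tm, symmetric = TRUE, only.values = TRUE)$values) < -1e-8)
      fail("timing_cor_matrix",
           "must be a symmetric positive semi-definite correlation matrix, one row per measure")
  }
  cfg
}

#' Per-measure definition for the cohort generator
#'
#' Describes one outcome: its assessment type, the sex-specific population
#' mean curves (distance curves for continuous outcomes, latent development
#' curves for ordinal scales), the SDs of the individual-level effects
#' (size/timing/intensity/post-growth), the residual SD, and for ordinal
#' scales the number of categories.
#'
#' @param type "clinic" (continuous) or "questionnaire" (ordinal/event).
#' @param scale "continuous", "ordinal" or "event" (menarche).
#' @param curve_f,curve_m sex-specific population mean curves
#'   ([growth_curves] objects); `NULL` for event measures.
#' @param k_categories number of ordinal categories (5 Tanner, 3 voice,
#'   2 axillary hair); `NA` otherwise.
#' @param sexes which sexes the measure is observed in.
#' @param timing_sd,size_sd,intensity_sd,postgrowth_sd,residual_sd SDs of
#'   the individual effects and the measurement residual, in outcome units
#'   (timing in years).
#' @param timing_loading loading of this measure's timing effect on the
#'   latent common factor; `NA` means use the config-level value.
#' @param adult_onset age (years) at which the individual post-growth slope
#'   switches on.
#' @param occasions indices of the assessment occasions at which the measure
#'   is collected (`NULL` = all); e.g. BMC at five clinic visits, axillary
#'   hair at the last seven questionnaires.
#' @param landmark_level for ordinal scales, the mean-curve level defining
#'   the pubertal landmark (3 for Tanner stage 3; midpoints for voice and
#'   axillary hair).
#' @param mean_age_f,mean_age_m for event measures (menarche), the
#'   sex-specific population mean event age in years.
#' @return object of class `measure_def`.
#' @export
measure_def <- function(type, scale, curve_f = NULL, curve_m = NULL,
                        k_categories = NA_integer_,
                        sexes = c("F", "M"),
                        timing_sd = 1.0, size_sd = 0, intensity_sd = 0.15,
                        postgrowth_sd = 0, residual_sd = 0.5,
                        timing_loading = NA_real_, adult_onset = 16,
                        occasions = NULL, landmark_level = NA_real_,
                        mean_age_f = NA_real_, mean_age_m = NA_real_) {
  structure(list(type = type, scale = scale, curve_f = curve_f,
                 curve_m = curve_m, k_categories = k_categories,
                 sexes = sexes, timing_sd = timing_sd, size_sd = size_sd,
                 intensity_sd = intensity_sd, postgrowth_sd = postgrowth_sd,
                 residual_sd = residual_sd, timing_loading = timing_loading,
                 adult_onset = adult_onset, occasions = occasions,
                 landmark_level = landmark_level,
                 mean_age_f = mean_age_f, mean_age_m = mean_age_m),
            class = "measure_def")
}

#' Default nine-indicator measure battery
#'
#' Mean-curve parameters are chosen to reproduce the typical features of
#' cohort growth data: childhood height velocity ~5.5 cm/y decaying over
#' age, a pubertal spurt peaking near 11.7 y (females) / 13.4 y (males) at
#' ~9-10 cm/y, weight and BMC spurts slightly later than height, Tanner
#' development curves passing stage 3 near the ages reported for
#' population cohorts, menarche mean 12.7 y, voice breaking mean 14.2 y.
#' Effect-size SDs follow the anthropometric defaults (timing SD 1.0 y,
#' size SD 3 cm for height, intensity SD 0.15) scaled to each outcome.
#'
#' @return named list of [measure_def()] objects.
#' @export
default_measures <- function() {
  list(
    height = measure_def(
      "clinic", "continuous",
      curve_f = growth_spurt_curve(121, 5.5, 0.18, 24, 11.8, 1.3),
      curve_m = growth_spurt_curve(123, 5.3, 0.15, 28, 13.5, 1.25),
      timing_sd = 1.0, size_sd = 3, intensity_sd = 0.15,
      residual_sd = 0.8),
    weight = measure_def(
      "clinic", "continuous",
      curve_f = growth_spurt_curve(24, 2.8, 0.10, 16, 12.1, 1.0),
      curve_m = growth_spurt_curve(24, 2.6, 0.08, 20, 13.8, 1.0),
      timing_sd = 1.1, size_sd = 4, intensity_sd = 0.18,
      postgrowth_sd = 0.6, residual_sd = 1.0),
    bmc = measure_def(
      "clinic", "continuous",
      curve_f = growth_spurt_curve(800, 110, 0.10, 900, 12.4, 1.1),
      curve_m = growth_spurt_curve(820, 105, 0.08, 1100, 13.9, 1.05),
      timing_sd = 0.9, size_sd = 120, intensity_sd = 0.15,
      postgrowth_sd = 25, residual_sd = 40,
      occasions = c(3L, 5L, 7L, 8L, 9L)),
    pubic_hair = measure_def(
      "questionnaire", "ordinal",
      curve_f = sigmoid_stage_curve(5, 11.9, 0.9),
      curve_m = sigmoid_stage_curve(5, 12.6, 0.9),
      k_categories = 5L, timing_sd = 1.1, size_sd = 0,
      intensity_sd = 0.15, residual_sd = 0.3, landmark_level = 3),
    breast = measure_def(
      "questionnaire", "ordinal",
      curve_f = sigmoid_stage_curve(5, 11.5, 0.85),
      sexes = "F", k_categories = 5L, timing_sd = 1.1, size_sd = 0,
      intensity_sd = 0.15, residual_sd = 0.3, landmark_level = 3),
    genitalia = measure_def(
      "questionnaire", "ordinal",
      curve_m = sigmoid_stage_curve(5, 12.8, 0.8),
      sexes = "M", k_categories = 5L, timing_sd = 1.2, size_sd = 0,
      intensity_sd = 0.15, residual_sd = 0.3, landmark_level = 3),
    axillary_hair = measure_def(
      "questionnaire", "ordinal",
      curve_f = sigmoid_stage_curve(2, 12.2, 1.1),
      curve_m = sigmoid_stage_curve(2, 13.3, 1.1),
      k_categories = 2L, timing_sd = 1.0, size_sd = 0,
      intensity_sd = 0.12, residual_sd = 0.15,
      occasions = 3:9, landmark_level = 1.5),
    voice = measure_def(
      "questionnaire", "ordinal",
      curve_m = sigmoid_stage_curve(3, 14.2, 1.0),
      sexes = "M", k_categories = 3L, timing_sd = 1.0, size_sd = 0,
      intensity_sd = 0.12, residual_sd = 0.2,
      occasions = 2:9, landmark_level = 2),
    menarche = measure_def(
      "questionnaire", "event", sexes = "F",
      timing_sd = 1.2, mean_age_f = 12.7)
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat("  n_per_sex:", x$n_per_sex, " seed:", x$seed, "\n")
  cat("  clinic ages:", paste(x$clinic_ages, collapse = ", "), "\n")
  cat("  questionnaire ages:", paste(x$questionnaire_ages, collapse = ", "), "\n")
  cat("  measures:", paste(names(x$measures), collapse = ", "), "\n")
  cat("  timing correlation:",
      if (is.null(x$timing_cor_matrix)) x$cross_measure_timing_correlation
      else "explicit matrix", "\n")
  invisible(x)
}
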