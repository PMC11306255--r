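#' Simulate an ALSPAC-like longitudinal puberty cohort
#'
#' Draws a cohort from the shape-invariant generative model: each individual
#' i receives, for every measure m, a size effect \eqn{\alpha_{im}}, a
#' timing effect \eqn{\beta_{im}} (years), an intensity effect
#' \eqn{\gamma_{im}} (log age-scale factor) and, where configured, a
#' post-growth slope \eqn{\delta_{im}}. Timing effects share a latent
#' common factor so that measures are positively correlated; the factor is
#' also the hook through which the simulated genetic risk score and the
#' body-composition/confounder paths act. Continuous outcomes are observed
#' with Gaussian residual noise at jittered clinic ages; ordinal outcomes
#' are produced by thresholding a monotone latent development curve at
#' jittered questionnaire ages, with optional reporting inconsistencies
#' (a stage regressing by one); menarche is reported at the first
#' questionnaire after its occurrence with optional recall noise.
#'
#' @param config a [sim_config()] object.
#' @param seed RNG seed; defaults to `config$seed`.
#' @return list with:
#'   \item{measurements}{long data.frame: `id`, `sex`, `occasion`, `age`
#'     (years), `measure`, `value`. For menarche, `value` is 0/1 status and
#'     `reported_age` holds the reported onset age (years).}
#'   \item{true_effects}{per individual x measure: `alpha`, `beta`, `gamma`,
#'     `delta`, plus per-individual `latent_timing`; for menarche the true
#'     event age is `menarche_age`.}
#'   \item{covariates}{per individual: standardized GRS, fat/lean mass index
#'     (raw kg/m^2 and z), age at DXA, confounder composite and its
#'     components.}
#'   \item{config}{the config used.}
#' @export
simulate_cohort <- function(config, seed = NULL) {
  config <- validate_sim_config(config)
  set.seed(if (is.null(seed)) config$seed else seed)
  n <- config$n_per_sex
  ids <- seq_len(2L * n)
  sex <- rep(c("F", "M"), each = n)
  meas_names <- names(config$measures)
  k <- length(meas_names)

  ## latent common timing factor (years)
  s_lat <- config$latent_timing_sd

  ## confounder composite and body composition acting on latent timing
  conf <- stats::rnorm(2L * n)
  p1 <- config$fmi_confounder_loading
  fmi_z <- p1 * conf + sqrt(1 - p1^2) * stats::rnorm(2L * n)
  lmi_z <- 0.3 * fmi_z + sqrt(1 - 0.3^2) * stats::rnorm(2L * n)
  thF <- config$fmi_effect; thL <- config$lmi_effect
  thC <- config$confounder_effect
  # Var(thF*F + thL*L + thC*C) with Corr(F,C)=p1, Corr(L,C)=0.3*p1, Corr(F,L)=0.3
  struct_var <- thF^2 + thL^2 + thC^2 +
    2 * thF * thL * 0.3 + 2 * thF * thC * p1 + 2 * thL * thC * 0.3 * p1
  if (struct_var > s_lat^2)
    stop("configured covariate effects imply more latent timing variance ",
         "than latent_timing_sd allows")
  u_sd <- sqrt(s_lat^2 - struct_var)
  latent <- thF * fmi_z + thL * lmi_z + thC * conf +
    stats::rnorm(2L * n, 0, u_sd)

  ## standardized GRS correlated with the latent timing factor
  r_g <- config$grs_timing_correlation
  grs <- r_g * (latent / s_lat) + sqrt(1 - r_g^2) * stats::rnorm(2L * n)
  grs <- as.numeric(scale(grs))

  ## per-measure timing effects
  t_sds <- vapply(config$measures, function(m) m$timing_sd, numeric(1))
  if (!is.null(config$timing_cor_matrix)) {
    # explicit-matrix mode: timing effects drawn directly from the target
    # correlation matrix (decoupled from the covariate/GRS paths); used for
    # correlation-structure studies
    R <- config$timing_cor_matrix
    Z <- matrix(stats::rnorm(2L * n * k), ncol = k) %*% chol(R)
    beta <- sweep(Z, 2L, t_sds, `*`)
  } else {
    lam <- vapply(config$measures, function(m) {
      if (is.na(m$timing_loading))
        sqrt(config$cross_measure_timing_correlation)
      else m$timing_loading
    }, numeric(1))
    eps <- matrix(stats::rnorm(2L * n * k), ncol = k)
    beta <- sapply(seq_len(k), function(j) {
      t_sds[j] * (lam[j] * latent / s_lat + sqrt(1 - lam[j]^2) * eps[, j])
    })
    if (is.null(dim(beta))) beta <- matrix(beta, nrow = 2L * n)
  }
  colnames(beta) <- meas_names

  alpha <- sapply(config$measures, function(m) stats::rnorm(2L * n, 0, m$size_sd))
  gamma <- sapply(config$measures, function(m) stats::rnorm(2L * n, 0, m$intensity_sd))
  delta <- sapply(config$measures, function(m) stats::rnorm(2L * n, 0, m$postgrowth_sd))

  true_effects <- do.call(rbind, lapply(seq_len(k), function(j) {
    data.frame(id = ids, sex = sex, measure = meas_names[j],
               alpha = alpha[, j], beta = beta[, j], gamma = gamma[, j],
               delta = delta[, j], stringsAsFactors = FALSE)
  }))
  true_effects$latent_timing <- rep(latent, k)

  ## occasion-level missingness, shared across measures on the same occasion
  n_clin <- length(config$clinic_ages)
  n_q <- length(config$questionnaire_ages)
  miss_clin <- matrix(stats::runif(2L * n * n_clin) < config$missingness_rate,
                      nrow = 2L * n)
  miss_q <- matrix(stats::runif(2L * n * n_q) < config$missingness_rate,
                   nrow = 2L * n)
  age_clin <- outer(rep(1, 2L * n), config$clinic_ages) +
    matrix(stats::rnorm(2L * n * n_clin, 0, config$age_jitter_sd), nrow = 2L * n)
  age_q <- outer(rep(1, 2L * n), config$questionnaire_ages) +
    matrix(stats::rnorm(2L * n * n_q, 0, config$age_jitter_sd), nrow = 2L * n)

  rows <- vector("list", k)
  menarche_truth <- NULL
  for (j in seq_len(k)) {
    m <- config$measures[[j]]
    nm <- meas_names[j]
    in_sex <- sex %in% m$sexes
    if (m$scale == "event") {
      ev_mean <- ifelse(sex == "F", m$mean_age_f, m$mean_age_m)
      ev_age <- ev_mean + beta[, j]
      menarche_truth <- data.frame(id = ids, sex = sex,
                                   menarche_age = ifelse(in_sex, ev_age, NA))
      recall <- stats::rnorm(2L * n, 0, config$menarche_recall_sd)
      sub <- which(in_sex)
      rws <- do.call(rbind, lapply(sub, function(i) {
        occ <- which(!miss_q[i, ])
        if (!length(occ)) return(NULL)
        aa <- age_q[i, occ]
        status <- as.numeric(aa >= ev_age[i])
        rep_age <- ifelse(status == 1, ev_age[i] + recall[i], NA)
        data.frame(id = ids[i], sex = sex[i], occasion = occ, age = aa,
                   measure = nm, value = status, reported_age = rep_age,
                   stringsAsFactors = FALSE)
      }))
      rows[[j]] <- rws
      next
    }
    occ_all <- if (m$type == "clinic") seq_len(n_clin) else seq_len(n_q)
    occ_use <- if (is.null(m$occasions)) occ_all else intersect(m$occasions, occ_all)
    ages <- if (m$type == "clinic") age_clin else age_q
    miss <- if (m$type == "clinic") miss_clin else miss_q
    sub <- which(in_sex)
    rws <- do.call(rbind, lapply(sub, function(i) {
      occ <- occ_use[!miss[i, occ_use]]
      if (!length(occ)) return(NULL)
      aa <- ages[i, occ]
      crv <- if (sex[i] == "F") m$curve_f else m$curve_m
      lat <- sitar_generative_curve(crv, alpha[i, j], beta[i, j],
                                    gamma[i, j], delta[i, j], aa,
                                    adult_onset = m$adult_onset,
                                    age_center = crv$params$midpoint)
      val <- if (m$scale == "continuous") {
        lat + stats::rnorm(length(aa), 0, m$residual_sd)
      } else {
        # ordinal stages come from the noiseless latent curve: rounding to
        # stages is itself the measurement error, and injected
        # inconsistencies are the only source of stage regression
        thr <- seq(1.5, m$k_categories - 0.5)
        discretize_to_stages(lat, thr, config$inconsistency_rate)
      }
      data.frame(id = ids[i], sex = sex[i], occasion = occ, age = aa,
                 measure = nm, value = val, reported_age = NA_real_,
                 stringsAsFactors = FALSE)
    }))
    rows[[j]] <- rws
  }
  measurements <- do.call(rbind, rows)
  rownames(measurements) <- NULL

  if (!is.null(menarche_truth))
    true_effects <- merge(true_effects,
                          menarche_truth[, c("id", "menarche_age")],
                          by = "id", sort = FALSE)

  covariates <- data.frame(
    id = ids, sex = sex, grs = grs,
    fmi_z = fmi_z, lmi_z = lmi_z,
    fmi = 10.2 + 2.3 * fmi_z, lmi = 12.6 + 1.4 * lmi_z,
    dxa_age = 9.9 + stats::rnorm(2L * n, 0, config$age_jitter_sd),
    confounder = conf,
    maternal_age = 28 + 5 * conf * 0.4 + stats::rnorm(2L * n, 0, 4.6),
    maternal_bmi = 23 + 3.5 * conf * 0.4 + stats::rnorm(2L * n, 0, 3.2),
    maternal_education = as.numeric(stats::plogis(conf) > stats::runif(2L * n)),
    maternal_smoking = as.numeric(stats::plogis(-1 + 0.5 * conf) > stats::runif(2L * n)),
    parity = stats::rpois(2L * n, 0.9),
    energy_intake_kj = 6500 + 400 * conf * 0.3 + stats::rnorm(2L * n, 0, 900),
    stringsAsFactors = FALSE)

  list(measurements = measurements, true_effects = true_effects,
       covariates = covariates, config = config)
}

#' Threshold a latent development value into an ordinal stage
#'
#' Stage = 1 + number of thresholds below the latent value. With
#' `inconsistency_rate > 0`, each reported stage above 1 regresses by one
#' category with that probability, emulating inconsistent questionnaire
#' responses.
#'
#' @param latent numeric latent development values.
#' @param thresholds strictly increasing vector of K-1 thresholds for K
#'   categories.
#' @param inconsistency_rate probability of a one-stage regression.
#' @return integer stages in 1..K.
#' @export
discretize_to_stages <- function(latent, thresholds, inconsistency_rate = 0) {
  if (length(thresholds) > 1L && is.unsorted(thresholds, strictly = TRUE))
    stop("thresholds must be strictly increasing")
  stopifnot(inconsistency_rate >= 0, inconsistency_rate <= 1)
  stage <- 1L + rowSums(outer(latent, thresholds, `>`))
  if (inconsistency_rate > 0) {
    knock <- stage > 1L & stats::runif(length(stage)) < inconsistency_rate
    stage[knock] <- stage[knock] - 1L
  }
  as.integer(stage)
}
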