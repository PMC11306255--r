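#' Age at menarche from questionnaire reports
#'
#' Age at menarche is the first reported age at onset of menstruation: the
#' earliest questionnaire at which onset is reported wins, later
#' (possibly contradictory) reports are ignored. Individuals who never
#' report onset are missing.
#'
#' @param qdata data.frame with `id`, `age` (age at questionnaire, years),
#'   `value` (0/1 onset status) and `reported_age` (reported onset age,
#'   years, where status is 1).
#' @return data.frame with `id` and `menarche_age` (years; `NA` when onset
#'   was never reported).
#' @export
derive_menarche_age <- function(qdata) {
  stopifnot(all(c("id", "age", "value", "reported_age") %in% names(qdata)))
  qdata <- qdata[order(qdata$id, qdata$age), ]
  rep1 <- qdata[qdata$value == 1 & !is.na(qdata$reported_age), ]
  first <- rep1[!duplicated(rep1$id), c("id", "reported_age")]
  names(first)[2] <- "menarche_age"
  out <- data.frame(id = unique(qdata$id))
  out <- merge(out, first, by = "id", all.x = TRUE, sort = FALSE)
  out[order(out$id), , drop = FALSE]
}

#' Remove inconsistent voice-breaking reports
#'
#' Voice-breaking stage reports that regress below an individual's running
#' maximum are removed before modelling (they are kept for every other
#' measure, where the regression model absorbs them as measurement error,
#' but they prevent the voice model from converging).
#'
#' @param vdata data.frame with `id`, `age`, `value` (stages 1-3).
#' @return the data with regressing observations dropped; attribute
#'   `n_removed` records the count.
#' @export
clean_voice_series <- function(vdata) {
  stopifnot(all(c("id", "age", "value") %in% names(vdata)))
  vdata <- vdata[order(vdata$id, vdata$age), ]
  keep <- unlist(tapply(vdata$value, vdata$id, function(v) {
    runmax <- cummax(c(-Inf, v[-length(v)]))
    v >= runmax
  }), use.names = FALSE)
  out <- vdata[keep, , drop = FALSE]
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Derive the nine indicator-based pubertal age measures
#'
#' Fits the per-measure SITAR variant separately in each sex, derives the
#' population landmark (age at peak velocity for height/weight/BMC; mean
#' curve crossing stage 3 for Tanner measures; crossing the category
#' midpoint for voice breaking and axillary hair), and adds each
#' individual's predicted timing effect. Menarche comes directly from
#' first-reported onset age. Failed fits are skipped with a warning.
#'
#' @param measurements long data.frame (`id`, `sex`, `age`, `measure`,
#'   `value`, and `reported_age` for menarche), e.g.
#'   `simulate_cohort()$measurements`.
#' @param specs named list of [sitar_spec()] per measure; defaults from
#'   [default_specs()].
#' @param landmark_levels named numeric: mean-curve crossing level per
#'   ordinal measure.
#' @param clean_voice remove regressing voice reports first (default TRUE).
#' @param outlier_threshold if non-`NULL`, run [remove_outliers()] at this
#'   SD threshold on continuous measures before fitting (the +/-5 SD
#'   sensitivity analysis).
#' @return object of class `pubertal_ages`: list with `ages` (wide
#'   data.frame: `id`, `sex`, one column per derived measure, years),
#'   `landmarks` (per measure x sex), `fits` (list of `sitar_fit`),
#'   `outlier_report` (when filtering was requested).
#' @export
derive_all_measures <- function(measurements, specs = default_specs(),
                                landmark_levels = c(pubic_hair = 3,
                                                    breast = 3,
                                                    genitalia = 3,
                                                    axillary_hair = 1.5,
                                                    voice = 2),
                                clean_voice = TRUE,
                                outlier_threshold = NULL) {
  stopifnot(all(c("id", "sex", "age", "measure", "value") %in%
                  names(measurements)))
  present <- intersect(names(specs), unique(measurements$measure))
  ids <- unique(measurements[, c("id", "sex")])
  ids <- ids[order(ids$id), ]
  ages <- ids
  landmarks <- list()
  fits <- list()
  outlier_report <- list()

  for (nm in present) {
    mdat <- measurements[measurements$measure == nm, ]
    if (nm == "menarche") {
      men <- derive_menarche_age(mdat)
      ages <- merge(ages, stats::setNames(men, c("id", "menarche")),
                    by = "id", all.x = TRUE, sort = FALSE)
      next
    }
    if (nm == "voice" && clean_voice) {
      mdat <- clean_voice_series(mdat)
    }
    if (!is.null(outlier_threshold) &&
        nm %in% c("height", "weight", "bmc")) {
      flt <- remove_outliers(mdat, outlier_threshold)
      mdat <- flt$data
      outlier_report[[nm]] <- data.frame(measure = nm,
                                         n_removed = flt$n_removed,
                                         pct_removed = flt$pct_removed)
    }
    col <- stats::setNames(data.frame(ids$id, NA_real_), c("id", nm))
    for (sx in intersect(c("F", "M"), unique(mdat$sex))) {
      sdat <- mdat[mdat$sex == sx, ]
      fit <- tryCatch(fit_sitar(sdat, specs[[nm]]), error = function(e) {
        warning("fit failed for ", nm, " (", sx, "): ",
                conditionMessage(e), call. = FALSE)
        NULL
      })
      if (is.null(fit)) next
      fits[[paste(nm, sx, sep = "_")]] <- fit
      lmk <- if (nm %in% names(landmark_levels)) {
        age_at_level(fit, landmark_levels[[nm]])
      } else {
        age_at_peak_velocity(fit)
      }
      landmarks[[paste(nm, sx, sep = "_")]] <-
        data.frame(measure = nm, sex = sx, landmark_age = lmk)
      if (is.na(lmk)) next
      ind <- individual_pubertal_age(fit, lmk)
      col[[nm]][match(ind$id, col$id)] <- ind$pubertal_age
    }
    ages <- merge(ages, col, by = "id", all.x = TRUE, sort = FALSE)
  }
  missing_meas <- setdiff(names(specs), present)
  if (length(missing_meas))
    warning("measures absent from data: ",
            paste(missing_meas, collapse = ", "), call. = FALSE)
  ages <- ages[order(ages$id), ]
  rownames(ages) <- NULL
  structure(list(ages = ages,
                 landmarks = do.call(rbind, c(landmarks,
                                              list(make.row.names = FALSE))),
                 fits = fits,
                 outlier_report = if (length(outlier_report))
                   do.call(rbind, outlier_report) else NULL),
            class = "pubertal_ages")
}

#' Default per-measure SITAR variants
#'
#' Height uses the standard three random effects (size, timing, intensity);
#' weight and BMC add the post-growth effect; ordinal development scales
#' use the reduced two-effect variant (timing, intensity).
#'
#' @param n_knots internal knots for every measure (default 4; weight and
#'   BMC use one more so that a spline knot falls near the post-growth
#'   onset, decoupling the adult-slope effect from the last spline
#'   segment).
#' @param postgrowth_onset onset age (years) of the adult-slope effect for
#'   weight/BMC; the default 15 places at least two late assessment
#'   occasions beyond onset, which the adult slope needs to be identified.
#' @return named list of [sitar_spec()] objects (menarche has no model and
#'   maps to `NA`).
#' @export
default_specs <- function(n_knots = 4L, postgrowth_onset = 15) {
  list(
    height = sitar_spec("height", c("size", "timing", "intensity"),
                        n_knots = n_knots),
    weight = sitar_spec("weight",
                        c("size", "timing", "intensity", "postgrowth"),
                        n_knots = min(n_knots + 1L, 5L),
                        postgrowth_onset = postgrowth_onset),
    bmc = sitar_spec("bmc", c("size", "timing", "intensity", "postgrowth"),
                     n_knots = min(n_knots + 1L, 5L),
                     postgrowth_onset = postgrowth_onset),
    pubic_hair = sitar_spec("pubic_hair", c("timing", "intensity"),
                            n_knots = n_knots),
    breast = sitar_spec("breast", c("timing", "intensity"),
                        n_knots = n_knots),
    genitalia = sitar_spec("genitalia", c("timing", "intensity"),
                           n_knots = n_knots),
    axillary_hair = sitar_spec("axillary_hair", c("timing", "intensity"),
                               n_knots = n_knots),
    voice = sitar_spec("voice", c("timing", "intensity"),
                       n_knots = n_knots),
    menarche = NA)
}

#' @export
print.pubertal_ages <- function(x, ...) {
  meas <- setdiff(names(x$ages), c("id", "sex"))
  cat("Pubertal age table:", nrow(x$ages), "individuals,",
      length(meas), "measures\n")
  print(summarize_timing(x$ages)$timing, digits = 3)
  invisible(x)
}

#' Summarise pubertal timing and its chronological sequence
#'
#' Per measure and sex: n, mean age and between-individual SD. On the
#' complete-case subset (individuals with every measure observed for their
#' sex), the fraction of individuals for whom each measure comes
#' chronologically first and last; ties are split equally.
#'
#' @param ages wide pubertal-age data.frame (`id`, `sex`, measures), as in
#'   `derive_all_measures()$ages`.
#' @return list with `timing` (measure, sex, n, mean_y, sd_y) and
#'   `sequence` (measure, sex, n_complete, pct_first, pct_last).
#' @export
summarize_timing <- function(ages) {
  if (inherits(ages, "pubertal_ages")) ages <- ages$ages
  meas <- setdiff(names(ages), c("id", "sex"))
  timing <- do.call(rbind, lapply(split(ages, ages$sex), function(d) {
    do.call(rbind, lapply(meas, function(m) {
      v <- d[[m]][!is.na(d[[m]])]
      if (length(v) < 2) return(NULL)
      data.frame(measure = m, sex = d$sex[1], n = length(v),
                 mean_y = mean(v), sd_y = stats::sd(v))
    }))
  }))
  sequence <- do.call(rbind, lapply(split(ages, ages$sex), function(d) {
    obs <- meas[colSums(!is.na(d[meas])) > 0]
    cc <- d[stats::complete.cases(d[obs]), obs, drop = FALSE]
    if (!nrow(cc) || length(obs) < 2) return(NULL)
    firsts <- lasts <- stats::setNames(numeric(length(obs)), obs)
    for (i in seq_len(nrow(cc))) {
      v <- unlist(cc[i, ])
      f <- which(v == min(v)); l <- which(v == max(v))
      firsts[f] <- firsts[f] + 1 / length(f)
      lasts[l] <- lasts[l] + 1 / length(l)
    }
    data.frame(measure = obs, sex = d$sex[1], n_complete = nrow(cc),
               pct_first = 100 * firsts / nrow(cc),
               pct_last = 100 * lasts / nrow(cc))
  }))
  rownames(timing) <- rownames(sequence) <- NULL
  list(timing = timing, sequence = sequence)
}
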