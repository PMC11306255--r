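#' Read a long-format measurement table
#'
#' CSV contract: columns `id`, `sex`, `age_months`, `measure`, `value`
#' (optional `occasion`, `reported_age_months`). Ages are supplied in
#' months (the precision at which cohort visit ages are recorded) and
#' converted to years for analysis; a file whose ages all fall below 25 is
#' rejected as being in years.
#'
#' @param path CSV file path.
#' @return data.frame with `id`, `sex`, `age` (years), `measure`, `value`
#'   (plus `occasion`/`reported_age` when present).
#' @export
read_measurements <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "sex", "age_months", "measure", "value")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("measurement file missing column(s): ", paste(miss, collapse = ", "))
  if (!is.numeric(d$age_months)) stop("age_months must be numeric")
  if (max(d$age_months, na.rm = TRUE) < 25)
    stop("age_months values look like years (all < 25); supply ages in months")
  key <- paste(d$id, d$measure,
               if ("occasion" %in% names(d)) d$occasion else d$age_months)
  if (anyDuplicated(key))
    stop("duplicate (id, measure, occasion) rows in measurement file")
  out <- data.frame(id = d$id, sex = d$sex, age = d$age_months / 12,
                    measure = d$measure, value = d$value,
                    stringsAsFactors = FALSE)
  if ("occasion" %in% names(d)) out$occasion <- d$occasion
  if ("reported_age_months" %in% names(d))
    out$reported_age <- d$reported_age_months / 12
  out
}

#' Write a measurement table in the months-based CSV contract
#' @param data data.frame with `id`, `sex`, `age` (years), `measure`,
#'   `value` (optional `occasion`, `reported_age`).
#' @param path output CSV path.
#' @export
write_measurements <- function(data, path) {
  out <- data.frame(id = data$id, sex = data$sex,
                    age_months = data$age * 12,
                    measure = data$measure, value = data$value)
  if ("occasion" %in% names(data)) out$occasion <- data$occasion
  if ("reported_age" %in% names(data))
    out$reported_age_months <- data$reported_age * 12
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Read a pipeline configuration file (YAML)
#'
#' Flat keys are passed to [sim_config()]; the optional `pipeline` block
#' holds flags (`outlier_sensitivity`, `clean_voice`, `associate`,
#' `n_knots`, `seed`, `out_dir`).
#'
#' @param path YAML file path.
#' @return list with `sim` (a `sim_config`) and `pipeline` (flag list).
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  pl <- y$pipeline
  y$pipeline <- NULL
  sim_args <- y[names(y) %in% names(formals(sim_config))]
  cfg <- do.call(sim_config, sim_args)
  defaults <- list(outlier_sensitivity = FALSE, clean_voice = TRUE,
                   associate = TRUE, n_knots = 4L,
                   seed = cfg$seed, out_dir = "results")
  pl <- utils::modifyList(defaults, if (is.null(pl)) list() else pl)
  list(sim = cfg, pipeline = pl)
}

#' Run the full analysis pipeline on a (simulated) cohort
#'
#' Stages: simulate (or take supplied measurements) -> clean voice ->
#' fit the per-measure SITAR variants by sex -> derive the nine pubertal
#' age measures -> summarise timing and sequence -> pairwise correlations
#' -> GRS and body-composition regressions. All tables are written as CSV
#' under `out_dir` together with a provenance manifest (seed, package
#' version, config hash).
#'
#' @param config list as from [read_pipeline_config()], or a `sim_config`
#'   (default pipeline flags then apply).
#' @param out_dir output directory (overrides the config's).
#' @param cohort optional pre-simulated cohort (as from
#'   [simulate_cohort()]); when `NULL` one is simulated from the config.
#' @return (invisibly) list with the derived tables and fitted models.
#' @export
run_pipeline <- function(config, out_dir = NULL, cohort = NULL) {
  if (inherits(config, "sim_config"))
    config <- list(sim = config,
                   pipeline = list(outlier_sensitivity = FALSE,
                                   clean_voice = TRUE, associate = TRUE,
                                   n_knots = 4L, seed = config$seed,
                                   out_dir = "results"))
  pl <- config$pipeline
  if (!is.null(out_dir)) pl$out_dir <- out_dir
  dir.create(pl$out_dir, recursive = TRUE, showWarnings = FALSE)

  stage <- "simulate"
  res <- tryCatch({
    if (is.null(cohort)) cohort <- simulate_cohort(config$sim, seed = pl$seed)
    write_measurements(cohort$measurements,
                       file.path(pl$out_dir, "measurements.csv"))
    utils::write.csv(cohort$true_effects,
                     file.path(pl$out_dir, "true_effects.csv"),
                     row.names = FALSE)
    utils::write.csv(cohort$covariates,
                     file.path(pl$out_dir, "covariates.csv"),
                     row.names = FALSE)

    stage <- "derive"
    specs <- default_specs(n_knots = pl$n_knots)
    pa <- derive_all_measures(cohort$measurements, specs,
                              clean_voice = pl$clean_voice)
    utils::write.csv(pa$ages, file.path(pl$out_dir, "pubertal_ages.csv"),
                     row.names = FALSE)

    stage <- "summarize"
    sm <- summarize_timing(pa$ages)
    utils::write.csv(sm$timing, file.path(pl$out_dir, "timing_summary.csv"),
                     row.names = FALSE)
    utils::write.csv(sm$sequence,
                     file.path(pl$out_dir, "sequence_summary.csv"),
                     row.names = FALSE)

    stage <- "correlate"
    cors <- lapply(split(pa$ages, pa$ages$sex), function(d) {
      d <- d[, colSums(!is.na(d)) > 0, drop = FALSE]
      tryCatch(pairwise_correlations(d), error = function(e) NULL)
    })
    for (sx in names(cors)) {
      if (is.null(cors[[sx]])) next
      utils::write.csv(as.data.frame(cors[[sx]]$r),
                       file.path(pl$out_dir,
                                 paste0("correlations_", sx, ".csv")))
    }

    assoc <- NULL
    if (isTRUE(pl$associate)) {
      stage <- "associate"
      dat <- merge(pa$ages, cohort$covariates, by = c("id", "sex"))
      meas <- setdiff(names(pa$ages), c("id", "sex"))
      conf_set <- c("maternal_age", "maternal_bmi", "maternal_education",
                    "maternal_smoking", "parity", "energy_intake_kj",
                    "dxa_age")
      assoc <- do.call(rbind, unlist(lapply(split(dat, dat$sex), function(d) {
        lapply(meas[colSums(!is.na(d[meas])) > 2], function(m) {
          rbind(
            cbind(sex = d$sex[1], model = "grs",
                  regress_univariable(d, m, "grs")),
            cbind(sex = d$sex[1], model = "fmi_adjusted",
                  regress_adjusted(d, m, "fmi_z", conf_set)),
            cbind(sex = d$sex[1], model = "lmi_adjusted",
                  regress_adjusted(d, m, "lmi_z", conf_set)))
        })
      }), recursive = FALSE))
      rownames(assoc) <- NULL
      utils::write.csv(assoc, file.path(pl$out_dir, "associations.csv"),
                       row.names = FALSE)
    }

    outlier <- NULL
    if (isTRUE(pl$outlier_sensitivity)) {
      stage <- "outlier_sensitivity"
      pa5 <- derive_all_measures(
        cohort$measurements,
        specs[c("height", "weight", "bmc")],
        clean_voice = FALSE, outlier_threshold = 5)
      utils::write.csv(pa5$outlier_report,
                       file.path(pl$out_dir, "outlier_report.csv"),
                       row.names = FALSE)
      utils::write.csv(summarize_timing(pa5$ages)$timing,
                       file.path(pl$out_dir,
                                 "timing_summary_outlier_filtered.csv"),
                       row.names = FALSE)
      outlier <- pa5
    }

    stage <- "manifest"
    cfg_file <- file.path(pl$out_dir, "config_used.yaml")
    yaml::write_yaml(list(seed = pl$seed, pipeline = pl,
                          n_per_sex = config$sim$n_per_sex,
                          measures = names(config$sim$measures)), cfg_file)
    manifest <- list(
      seed = pl$seed,
      config_hash = unname(tools::md5sum(cfg_file)),
      r_version = as.character(getRversion()),
      timestamp = format(Sys.time(), tz = "UTC"))
    yaml::write_yaml(manifest, file.path(pl$out_dir, "manifest.yaml"))

    list(cohort = cohort, pubertal_ages = pa, summary = sm,
         correlations = cors, associations = assoc,
         outlier_sensitivity = outlier)
  }, error = function(e) {
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  invisible(res)
}

#' Diagnostic plot of a SITAR fit: data cloud, fitted mean distance curve,
#' and the velocity curve on a secondary axis.
#' @param x a `sitar_fit`.
#' @param data optional data.frame (`age`, `value`) to overplot.
#' @param ... passed to [plot()].
#' @export
plot.sitar_fit <- function(x, data = NULL, ...) {
  grid <- seq(x$boundary[1], x$boundary[2], length.out = 200)
  pc <- predict_curves(x, grid)
  if (!is.null(data)) {
    plot(data$age, data$value, pch = 16, cex = 0.3,
         col = grDevices::grey(0.7), xlab = "age (y)",
         ylab = x$spec$outcome, ...)
    graphics::lines(pc$age, pc$distance, lwd = 2)
  } else {
    plot(pc$age, pc$distance, type = "l", lwd = 2, xlab = "age (y)",
         ylab = x$spec$outcome, ...)
  }
  graphics::par(new = TRUE)
  plot(pc$age, pc$velocity, type = "l", lty = 2, axes = FALSE,
       xlab = "", ylab = "")
  graphics::axis(4)
  invisible(x)
}
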