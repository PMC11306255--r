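#' Specify a SITAR model
#'
#' SITAR (SuperImposition by Translation And Rotation) fits one natural
#' cubic spline mean curve h to all individuals and tailors it with
#' individual random effects: size (`a`, vertical shift), timing (`b`,
#' horizontal shift in years), intensity (`c`, log age-scale factor) and,
#' optionally, a post-growth slope (`d`, extra adult slope beyond the upper
#' boundary knot):
#' \deqn{y_{ij} = (a_0 + a_i) + h(e^{c_0 + c_i}(t_{ij} - b_0 - b_i)) +
#'   (d_0 + d_i)(t_{ij} - t_U)_+ + \epsilon_{ij}}
#' The standard anthropometric variant uses \{size, timing, intensity\};
#' weight/BMC-style outcomes add the post-growth effect; ordinal stage
#' scores use the reduced \{timing, intensity\} variant (no size effect,
#' since everyone sits on the same bounded scale).
#'
#' @param outcome measure name (informational).
#' @param random_effects non-empty subset of
#'   `c("size", "timing", "intensity", "postgrowth")`.
#' @param n_knots number of internal knots (2-5) placed at equally spaced
#'   quantiles of the observed ages.
#' @param max_iter maximum outer iterations for the alternating
#'   penalized-least-squares / variance-component algorithm.
#' @param tol relative convergence tolerance.
#' @param postgrowth_onset age (years) at which the post-growth slope
#'   starts; `NULL` uses the highest internal knot (the late end of the
#'   pubertal phase). Only used when `postgrowth` is a random effect.
#' @return object of class `sitar_spec`.
#' @export
sitar_spec <- function(outcome = "outcome",
                       random_effects = c("size", "timing", "intensity"),
                       n_knots = 4L, max_iter = 40L, tol = 1e-4,
                       postgrowth_onset = NULL) {
  random_effects <- match.arg(random_effects,
                              c("size", "timing", "intensity", "postgrowth"),
                              several.ok = TRUE)
  n_knots <- as.integer(n_knots)
  if (n_knots < 2L || n_knots > 5L) stop("n_knots must be in 2..5")
  if (!length(random_effects)) stop("random_effects must be non-empty")
  structure(list(outcome = outcome, random_effects = random_effects,
                 n_knots = n_knots, max_iter = as.integer(max_iter),
                 tol = tol, postgrowth_onset = postgrowth_onset),
            class = "sitar_spec")
}

re_letters <- c(size = "a", timing = "b", intensity = "cc", postgrowth = "d")

# Construct the SITAR model function used by nlme, with analytic gradients
# for the spline coefficients and all four effects. Closure carries the
# (fixed) knots; nlme evaluates parameters as observation-length vectors.
make_sitar_fn <- function(knots, boundary, p, use_d, onset = boundary[2],
                          x0 = 0) {
  sargs <- paste0("s", seq_len(p))
  args <- c("x", sargs, "a", "b", "cc", if (use_d) "d")
  txt <- paste0(
    "function(", paste(args, collapse = ","), ") {\n",
    " u <- .x0 + exp(cc) * (x - b - .x0)\n",
    " B <- ns_basis(u, .kn, .bd)\n",
    " B1 <- ns_basis(u, .kn, .bd, 1L)\n",
    " S <- cbind(", paste(sargs, collapse = ","), ")\n",
    " if (nrow(S) == 1L && length(x) > 1L) S <- S[rep(1L, length(x)), , drop = FALSE]\n",
    " h1 <- rowSums(B1 * S)\n",
    " v <- a + rowSums(B * S)\n",
    if (use_d) " hg <- pmax(x - .onset, 0)\n v <- v + d * hg\n" else "",
    " grad <- cbind(B, 1, -exp(cc) * h1, (u - .x0) * h1",
    if (use_d) ", hg" else "", ")\n",
    " colnames(grad) <- c(", paste0("'", sargs, "'", collapse = ","),
    ", 'a', 'b', 'cc'", if (use_d) ", 'd'" else "", ")\n",
    " attr(v, 'gradient') <- grad\n v\n}")
  env <- new.env(parent = getNamespace("stats"))
  env$.kn <- knots
  env$.bd <- boundary
  env$.onset <- onset
  env$.x0 <- x0
  env$ns_basis <- ns_basis
  f <- eval(parse(text = txt), env)
  environment(f) <- env
  f
}

#' Fit a SITAR shape-invariant growth model
#'
#' Maximum-likelihood estimation via iterated first-order conditional
#' linearization about the current random-effect modes (Lindstrom-Bates),
#' alternating a penalized nonlinear least-squares step with a
#' linear-mixed-effects update of the variance components
#' (through [nlme::nlme()]). When neither timing nor intensity is a random
#' effect the model is linear in all parameters and is fitted exactly with
#' [nlme::lme()]. The random-effect covariance is unstructured; the
#' marginal (approximate) log-likelihood is reported, and
#' BIC = -2 logLik + p log(N) with N = number of individuals.
#'
#' @param data data.frame with columns `id`, `age` (years), `value`; one
#'   outcome, one sex.
#' @param spec a [sitar_spec()].
#' @return object of class `sitar_fit` with elements `spec`, `knots`,
#'   `boundary`, `coef` (spline coefficients), `fixed` (named fixed effects
#'   a, b, cc, d), `Omega` (random-effect covariance), `ranef`
#'   (per-individual empirical-Bayes effects), `sigma`, `logLik`, `bic`,
#'   `n_par`, `converged`, `n_individuals`, `n_observations`.
#' @export
fit_sitar <- function(data, spec) {
  stopifnot(inherits(spec, "sitar_spec"),
            all(c("id", "age", "value") %in% names(data)))
  data <- data[stats::complete.cases(data[, c("id", "age", "value")]), ]
  if (!nrow(data)) stop("no non-missing observations to fit")
  data <- data[order(data$id, data$age), ]
  data$id <- factor(data$id)

  kb <- spline_knots(data$age, spec$n_knots)
  p <- spec$n_knots + 1L
  eff <- spec$random_effects
  use_d <- "postgrowth" %in% eff
  nonlinear <- any(c("timing", "intensity") %in% eff)

  B0 <- ns_basis(data$age, kb$knots, kb$boundary)
  ols <- stats::lm.fit(cbind(1, B0), data$value)

  onset <- if (is.null(spec$postgrowth_onset)) max(kb$knots) else spec$postgrowth_onset
  if (!nonlinear) {
    fit <- fit_sitar_linear(data, spec, kb, B0, use_d, onset)
  } else {
    fit <- fit_sitar_nonlinear(data, spec, kb, p, use_d, ols, onset)
  }
  fit$onset <- onset
  fit$spec <- spec
  fit$knots <- kb$knots
  fit$boundary <- kb$boundary
  fit$n_individuals <- nlevels(data$id)
  fit$n_observations <- nrow(data)
  q <- nrow(fit$Omega)
  n_vc <- if (identical(fit$re_structure, "diagonal")) q else q * (q + 1) / 2
  fit$n_par <- fit$n_fixed + n_vc + 1L
  fit$bic <- -2 * fit$logLik + fit$n_par * log(fit$n_individuals)
  class(fit) <- "sitar_fit"
  fit
}

# Linear reduction: no timing/intensity random effect, so
# y = a_i + h(t) (+ d_i hinge) is a linear mixed model (exact ML via lme).
fit_sitar_linear <- function(data, spec, kb, B0, use_d, onset = max(kb$knots)) {
  eff <- spec$random_effects
  df <- data.frame(value = data$value, id = data$id, B0)
  scols <- colnames(B0)
  re_terms <- c(if ("size" %in% eff) "1",
                if (use_d) "hinge")
  if (use_d) df$hinge <- pmax(data$age - onset, 0)
  fixed_terms <- c(scols, if (use_d) "hinge")
  fixed_form <- stats::reformulate(fixed_terms, response = "value")
  ran_form <- stats::as.formula(paste("~", paste(re_terms, collapse = "+")))
  fit <- nlme::lme(fixed_form, data = df,
                   random = list(id = nlme::pdSymm(ran_form)),
                   method = "ML",
                   control = nlme::lmeControl(maxIter = spec$max_iter,
                                              returnObject = TRUE))
  fx <- nlme::fixef(fit)
  Om <- fit$sigma^2 * as.matrix(fit$modelStruct$reStruct[[1]])
  enames <- c(if ("size" %in% eff) "a", if (use_d) "d")
  dimnames(Om) <- list(enames, enames)
  re <- as.data.frame(nlme::ranef(fit))
  names(re) <- enames
  re <- re[match(levels(data$id), rownames(re)), , drop = FALSE]
  fixed <- c(a = unname(fx["(Intercept)"]), b = 0, cc = 0,
             d = if (use_d) unname(fx["hinge"]) else 0)
  list(coef = unname(fx[scols]), fixed = fixed, Omega = Om, ranef = re,
       sigma = fit$sigma, logLik = as.numeric(stats::logLik(fit)),
       n_fixed = length(fx), converged = TRUE)
}

# Nonlinear variants: timing and intensity carry fixed effects as well as
# random ones -- the spline's knots are fixed in the data's age scale, so a
# common shift/stretch of the whole cohort relative to the quantile-placed
# knots is a real fixed effect, and omitting it inflates the timing variance
# component. After fitting, the empirical-Bayes means are absorbed into the
# fixed part so the reported mean curve is the population-typical curve and
# the reported random effects are centred.
fit_sitar_nonlinear <- function(data, spec, kb, p, use_d, ols,
                                onset = max(kb$knots)) {
  eff <- spec$random_effects
  # anchoring the intensity stretch at the mean age keeps it a rotation of
  # the curve about the centre of the data rather than a timing shift
  x0 <- mean(data$age)
  .fn <- make_sitar_fn(kb$knots, kb$boundary, p, use_d, onset, x0)
  sargs <- paste0("s", seq_len(p))
  call_args <- c("age", sargs, "a", "b", "cc", if (use_d) "d")
  form <- stats::as.formula(paste0("value ~ .fn(",
                                   paste(call_args, collapse = ","), ")"))
  # nlme ignores the formula environment when evaluating the model, so the
  # closure is spliced into the formula as a literal
  form[[3]][[1]] <- .fn
  fenv <- new.env(parent = environment(.fn))
  fenv$.fn <- .fn
  environment(form) <- fenv
  fixed_pars <- c(sargs, "a", "b", "cc", if (use_d) "d")
  fixed_form <- stats::as.formula(paste(paste(fixed_pars, collapse = "+"), "~ 1"))
  ran_pars <- re_letters[eff]
  ran_form <- stats::as.formula(paste(paste(ran_pars, collapse = "+"), "~ 1"))
  start <- c(ols$coefficients[-1], ols$coefficients[1], 0, 0, if (use_d) 0)

  # initial random-effect covariance, scaled per effect: the effects live on
  # wildly different scales (outcome units vs years vs log-age), and nlme's
  # default initialization is unstable for the reduced variants
  res0 <- data$value - cbind(1, ns_basis(data$age, kb$knots, kb$boundary)) %*%
    ols$coefficients
  ind_mean <- tapply(res0, data$id, mean)
  s20 <- max(stats::var(drop(res0)), 1e-8)
  init_var <- c(a = max(stats::var(ind_mean), 0.1 * s20),
                b = 0.49, cc = 0.01,
                d = 0.01 * s20)[ran_pars]
  omega_init <- diag(init_var / s20, nrow = length(ran_pars))
  dimnames(omega_init) <- list(ran_pars, ran_pars)

  # nlme resolves the model function through the calling frame, so the
  # call is evaluated inside the environment that carries .fn
  fenv$..data <- data.frame(value = data$value, age = data$age, id = data$id)
  fenv$..fixed <- fixed_form
  fenv$..random <- nlme::pdSymm(omega_init, form = ran_form)
  fenv$..start <- unname(start)
  fenv$..ctrl <- nlme::nlmeControl(maxIter = spec$max_iter,
                                   tolerance = spec$tol,
                                   returnObject = TRUE)
  fenv$..form <- form
  fit_call <- quote(nlme::nlme(..form, data = ..data, fixed = ..fixed,
                               random = ..random, groups = ~id,
                               start = ..start, method = "ML",
                               control = ..ctrl))
  run_nlme <- function() {
    converged <- TRUE
    fit <- withCallingHandlers(
      tryCatch(eval(fit_call, fenv), error = function(e) e),
      warning = function(w) {
        # transient LME-step messages are benign; only the final
        # "reached without convergence" indicates a failed fit
        if (grepl("without convergence", conditionMessage(w)))
          converged <<- FALSE
        invokeRestart("muffleWarning")
      })
    list(fit = fit, converged = converged)
  }
  res <- run_nlme()
  structure_used <- "unstructured"
  if (inherits(res$fit, "error")) {
    # retry ladder: an unstructured covariance can collapse when one effect
    # carries almost no variance (e.g. intensity on a 2-category scale);
    # fall back to a diagonal covariance, then to timing-only
    fenv$..random <- nlme::pdDiag(diag(diag(omega_init),
                                       nrow = length(ran_pars)),
                                  form = ran_form)
    res <- run_nlme()
    structure_used <- "diagonal"
  }
  if (inherits(res$fit, "error") && length(ran_pars) > 1L &&
      "b" %in% ran_pars) {
    ran_pars <- "b"
    ran_form <- b ~ 1
    fenv$..random <- nlme::pdSymm(omega_init["b", "b", drop = FALSE],
                                  form = ran_form)
    res <- run_nlme()
    structure_used <- "timing_only"
  }
  fit <- res$fit
  converged <- res$converged
  if (inherits(fit, "error"))
    stop("SITAR fit failed for '", spec$outcome, "': ",
         conditionMessage(fit), call. = FALSE)
  if (structure_used != "unstructured")
    warning("SITAR fit for '", spec$outcome,
            "' required a reduced random-effect structure (",
            structure_used, ")", call. = FALSE)
  if (!converged)
    warning("SITAR fit for '", spec$outcome,
            "' did not fully converge; results flagged", call. = FALSE)

  fx <- nlme::fixef(fit)
  Om <- fit$sigma^2 * as.matrix(fit$modelStruct$reStruct[[1]])
  dimnames(Om) <- list(ran_pars, ran_pars)
  re <- as.data.frame(nlme::ranef(fit))
  names(re) <- ran_pars
  re <- re[match(levels(data$id), rownames(re)), , drop = FALSE]
  fixed <- c(a = unname(fx["a"]), b = unname(fx["b"]),
             cc = unname(fx["cc"]), d = if (use_d) unname(fx["d"]) else 0)
  # canonical recentring: absorb empirical-Bayes means into the fixed part
  for (rp in ran_pars) {
    m <- mean(re[[rp]])
    fixed[rp] <- fixed[rp] + m
    re[[rp]] <- re[[rp]] - m
  }
  list(coef = unname(fx[sargs]), fixed = fixed, Omega = Om, ranef = re,
       sigma = fit$sigma, logLik = as.numeric(stats::logLik(fit)),
       n_fixed = length(fx), converged = converged, age_center = x0,
       re_structure = structure_used)
}

#' @export
print.sitar_fit <- function(x, ...) {
  cat("SITAR fit:", x$spec$outcome, "\n")
  cat("  random effects:", paste(x$spec$random_effects, collapse = ", "),
      "| knots:", x$spec$n_knots, "\n")
  cat("  individuals:", x$n_individuals, "| observations:",
      x$n_observations, "\n")
  cat(sprintf("  logLik %.2f | BIC %.2f | sigma %.4f | converged: %s\n",
              x$logLik, x$bic, x$sigma, x$converged))
  cat("  random-effect SDs:",
      paste(sprintf("%s=%.3g", rownames(x$Omega), sqrt(diag(x$Omega))),
            collapse = ", "), "\n")
  invisible(x)
}

# Population mean curve of a fit, evaluated with the fixed effects.
fit_mean_fun <- function(fit) {
  fx <- fit$fixed
  x0 <- if (is.null(fit$age_center)) 0 else fit$age_center
  function(t) {
    u <- x0 + exp(fx["cc"]) * (t - fx["b"] - x0)
    v <- fx["a"] + drop(ns_basis(u, fit$knots, fit$boundary) %*% fit$coef)
    if (fx["d"] != 0) v <- v + fx["d"] * pmax(t - fit$onset, 0)
    unname(v)
  }
}

fit_velocity_fun <- function(fit) {
  fx <- fit$fixed
  x0 <- if (is.null(fit$age_center)) 0 else fit$age_center
  function(t) {
    u <- x0 + exp(fx["cc"]) * (t - fx["b"] - x0)
    v <- exp(fx["cc"]) *
      drop(ns_basis(u, fit$knots, fit$boundary, 1L) %*% fit$coef)
    if (fx["d"] != 0) v <- v + fx["d"] * (t > fit$onset)
    unname(v)
  }
}

#' Distance and velocity curves from a fitted model
#'
#' Velocity is the analytic first derivative of the fitted mean spline
#' (chain rule through the intensity/timing transformation), not a finite
#' difference. Beyond the boundary knots the natural spline is linear, so
#' velocity is constant there (plus the post-growth slope above the upper
#' boundary when fitted).
#'
#' @param fit a [fit_sitar()] result.
#' @param ages ages (years) at which to evaluate.
#' @return data.frame with `age`, `distance`, `velocity`.
#' @export
predict_curves <- function(fit, ages) {
  stopifnot(inherits(fit, "sitar_fit"))
  data.frame(age = ages,
             distance = fit_mean_fun(fit)(ages),
             velocity = fit_velocity_fun(fit)(ages))
}

# Locate the interior maximum of a velocity function on [lo, up]:
# dense grid (step <= 0.01 y) then local refinement by golden-section.
peak_age <- function(vfun, lo, up, step = 0.01) {
  grid <- seq(lo, up, by = min(step, (up - lo) / 200))
  v <- vfun(grid)
  i <- which.max(v)
  if (i <= 1L || i >= length(grid)) return(NA_real_)
  stats::optimize(vfun, c(grid[i - 1L], grid[i + 1L]),
                  maximum = TRUE, tol = 1e-6)$maximum
}

#' Age at peak velocity
#'
#' Argmax of the velocity curve within the boundary-knot range (for a fit)
#' or a supplied range (for a generator curve). Returns `NA` with a warning
#' when the maximum sits on the boundary, i.e. no interior peak exists.
#'
#' @param object a `sitar_fit` or `growth_curve`.
#' @param ... passed to methods; for `growth_curve`, `range` (length-2 ages).
#' @return age in years, or `NA` if no interior peak.
#' @export
age_at_peak_velocity <- function(object, ...) UseMethod("age_at_peak_velocity")

#' @rdname age_at_peak_velocity
#' @export
age_at_peak_velocity.sitar_fit <- function(object, ...) {
  # with a post-growth effect, the adult-slope segment is excluded from the
  # search: peak growth velocity is a pubertal-phase landmark, and the slope
  # change at the onset age is not a growth spurt
  upper <- if ("postgrowth" %in% object$spec$random_effects)
    min(object$onset, object$boundary[2]) else object$boundary[2]
  apv <- peak_age(fit_velocity_fun(object), object$boundary[1], upper)
  if (is.na(apv))
    warning("no interior velocity peak for '", object$spec$outcome, "'",
            call. = FALSE)
  apv
}

#' @rdname age_at_peak_velocity
#' @param range age interval to search.
#' @export
age_at_peak_velocity.growth_curve <- function(object, range = c(7, 18), ...) {
  apv <- peak_age(object$deriv, range[1], range[2])
  if (is.na(apv)) warning("no interior velocity peak", call. = FALSE)
  apv
}

#' Age at which the mean curve crosses a level
#'
#' Smallest age in the boundary-knot range (or supplied range) at which the
#' fitted or generator mean curve equals `level`; used for the Tanner
#' stage-3, voice-breaking and axillary-hair landmarks. Root found by
#' bracketing on a fine grid then [stats::uniroot()] to 0.001 y.
#'
#' @param object a `sitar_fit` or `growth_curve`.
#' @param level outcome value to cross.
#' @param ... passed to methods.
#' @return age in years, or `NA` with a warning when the curve never
#'   crosses `level`.
#' @export
age_at_level <- function(object, level, ...) UseMethod("age_at_level")

level_crossing <- function(fun, level, lo, up) {
  grid <- seq(lo, up, length.out = 512)
  g <- fun(grid) - level
  if (any(g == 0)) return(grid[which(g == 0)[1]])
  sgn <- which(g[-1] * g[-length(g)] < 0)
  if (!length(sgn)) return(NA_real_)
  i <- sgn[1]
  stats::uniroot(function(t) fun(t) - level, c(grid[i], grid[i + 1L]),
                 tol = 1e-4)$root
}

#' @rdname age_at_level
#' @export
age_at_level.sitar_fit <- function(object, level, ...) {
  x <- level_crossing(fit_mean_fun(object), level, object$boundary[1],
                      object$boundary[2])
  if (is.na(x))
    warning("mean curve for '", object$spec$outcome,
            "' does not cross level ", level, call. = FALSE)
  x
}

#' @rdname age_at_level
#' @param range age interval to search.
#' @export
age_at_level.growth_curve <- function(object, level, range = c(7, 18), ...) {
  x <- level_crossing(object$fun, level, range[1], range[2])
  if (is.na(x)) warning("curve does not cross level ", level, call. = FALSE)
  x
}

#' Individual pubertal ages from the timing random effect
#'
#' Individual pubertal age = population landmark age (e.g. age at peak
#' velocity, or a stage-crossing age) plus the individual's predicted
#' timing effect. Because empirical-Bayes predictions are shrunken with
#' mean ~0, the population mean of the result is approximately the
#' landmark age.
#'
#' @param fit a [fit_sitar()] result whose spec includes the timing effect.
#' @param landmark_age landmark age in years.
#' @return data.frame with `id` and `pubertal_age` (years).
#' @export
individual_pubertal_age <- function(fit, landmark_age) {
  stopifnot(inherits(fit, "sitar_fit"))
  if (!"timing" %in% fit$spec$random_effects)
    stop("timing is not a random effect in this fit")
  data.frame(id = rownames(fit$ranef),
             pubertal_age = landmark_age + fit$ranef$b,
             stringsAsFactors = FALSE)
}

#' Select the number of spline knots by BIC
#'
#' Fits the model for each candidate knot count (default 2-5) and returns
#' the converged fit with smallest BIC, plus the full comparison table.
#' Ties are broken in favour of fewer knots.
#'
#' @param data as in [fit_sitar()].
#' @param spec template [sitar_spec()]; its `n_knots` is overridden.
#' @param knot_range candidate internal knot counts.
#' @return list with `fit` (best) and `table` (data.frame: n_knots, logLik,
#'   n_par, bic, converged).
#' @export
select_model <- function(data, spec, knot_range = 2:5) {
  fits <- lapply(knot_range, function(k) {
    sp <- spec
    sp$n_knots <- as.integer(k)
    tryCatch(suppressWarnings(fit_sitar(data, sp)), error = function(e) NULL)
  })
  tab <- data.frame(
    n_knots = knot_range,
    logLik = vapply(fits, function(f) if (is.null(f)) NA_real_ else f$logLik, 1),
    n_par = vapply(fits, function(f) if (is.null(f)) NA_real_ else f$n_par, 1),
    bic = vapply(fits, function(f) if (is.null(f)) NA_real_ else f$bic, 1),
    converged = vapply(fits, function(f) !is.null(f) && f$converged, TRUE))
  ok <- which(tab$converged)
  if (!length(ok)) stop("no candidate model converged")
  best <- ok[which.min(tab$bic[ok])] # which.min takes the first = fewest knots
  list(fit = fits[[best]], table = tab)
}

#' Remove putative outliers relative to visit-level distributions
#'
#' Flags observations further than `threshold` SDs from the mean of their
#' sex-by-occasion cell and removes them, reporting the count and
#' percentage removed -- the conventional +/-5 SD screen used as a
#' sensitivity analysis for the anthropometric fits.
#'
#' @param data data.frame with `value` and, if available, `sex` and
#'   `occasion` columns defining the comparison cells.
#' @param threshold SD-unit cutoff (> 0), default 5.
#' @return list with `data` (filtered), `n_removed`, `pct_removed`.
#' @export
remove_outliers <- function(data, threshold = 5) {
  stopifnot(threshold > 0, "value" %in% names(data))
  cells <- interaction(
    if ("sex" %in% names(data)) data$sex else rep(1, nrow(data)),
    if ("occasion" %in% names(data)) data$occasion else rep(1, nrow(data)),
    drop = TRUE)
  mu <- stats::ave(data$value, cells)
  sdv <- stats::ave(data$value, cells, FUN = stats::sd)
  keep <- is.na(sdv) | sdv == 0 | abs(data$value - mu) <= threshold * sdv
  list(data = data[keep, , drop = FALSE],
       n_removed = sum(!keep),
       pct_removed = 100 * sum(!keep) / nrow(data))
}
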