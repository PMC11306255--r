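#' Population mean growth curves
#'
#' Curve objects represent the population mean distance curve h(t) of one
#' outcome. Two families are provided: a linear-plus-logistic curve (baseline
#' growth plus a pubertal spurt, with a closed-form peak-velocity age at the
#' logistic midpoint) and a natural-spline curve with given coefficients.
#' Both expose values and first derivatives, which the generator and the
#' test oracles use.
#'
#' @name growth_curves
NULL

new_growth_curve <- function(fun, deriv, family, params) {
  structure(list(fun = fun, deriv = deriv, family = family, params = params),
            class = "growth_curve")
}

#' @param base outcome value at age 0 of the linear component.
#' @param slope pre/post-spurt background growth rate (units/year).
#' @param amplitude total gain attributable to the pubertal spurt (units).
#' @param midpoint age of the spurt midpoint (years); for `slope`-constant
#'   curves this is exactly the age at peak velocity.
#' @param rate logistic steepness (1/years).
#' @rdname growth_curves
#' @export
logistic_curve <- function(base, slope, amplitude, midpoint, rate) {
  stopifnot(is.finite(base), is.finite(slope), amplitude > 0, rate > 0)
  fun <- function(t) base + slope * t +
    amplitude * stats::plogis(rate * (t - midpoint))
  deriv <- function(t) {
    p <- stats::plogis(rate * (t - midpoint))
    slope + amplitude * rate * p * (1 - p)
  }
  new_growth_curve(fun, deriv, "logistic",
                   list(base = base, slope = slope, amplitude = amplitude,
                        midpoint = midpoint, rate = rate))
}

#' @param v_child childhood background velocity at `age_ref` (units/year),
#'   decaying exponentially at rate `decay` (1/years); `decay = 0` gives a
#'   constant background slope.
#' @param age_ref reference age anchoring `base` and the decay.
#' @rdname growth_curves
#' @export
growth_spurt_curve <- function(base, v_child, decay, amplitude, midpoint,
                               rate, age_ref = 7) {
  stopifnot(v_child >= 0, decay >= 0, amplitude > 0, rate > 0)
  fun <- function(t) {
    bg <- if (decay > 0)
      (v_child / decay) * (1 - exp(-decay * (t - age_ref)))
    else v_child * (t - age_ref)
    base + bg + amplitude * stats::plogis(rate * (t - midpoint))
  }
  deriv <- function(t) {
    p <- stats::plogis(rate * (t - midpoint))
    v_child * exp(-decay * (t - age_ref)) + amplitude * rate * p * (1 - p)
  }
  new_growth_curve(fun, deriv, "growth_spurt",
                   list(base = base, v_child = v_child, decay = decay,
                        amplitude = amplitude, midpoint = midpoint,
                        rate = rate, age_ref = age_ref))
}

#' @param k_categories number of ordinal categories (5 Tanner, 3 voice,
#'   2 axillary hair); the latent curve rises from 1 to `k_categories`.
#' @rdname growth_curves
#' @export
sigmoid_stage_curve <- function(k_categories, midpoint, rate) {
  stopifnot(k_categories >= 2, rate > 0)
  fun <- function(t) 1 + (k_categories - 1) * stats::plogis(rate * (t - midpoint))
  deriv <- function(t) {
    p <- stats::plogis(rate * (t - midpoint))
    (k_categories - 1) * rate * p * (1 - p)
  }
  new_growth_curve(fun, deriv, "sigmoid_stage",
                   list(k_categories = k_categories, midpoint = midpoint,
                        rate = rate))
}

#' @param knots,boundary natural-spline knots (see [ns_basis()]).
#' @param coef spline coefficients, length `length(knots) + 1`.
#' @param intercept curve intercept.
#' @rdname growth_curves
#' @export
nspline_curve <- function(knots, boundary, coef, intercept = 0) {
  stopifnot(length(coef) == length(knots) + 1L)
  fun <- function(t) intercept + drop(ns_basis(t, knots, boundary) %*% coef)
  deriv <- function(t) drop(ns_basis(t, knots, boundary, deriv = 1L) %*% coef)
  new_growth_curve(fun, deriv, "nspline",
                   list(knots = knots, boundary = boundary, coef = coef,
                        intercept = intercept))
}

#' @export
print.growth_curve <- function(x, ...) {
  cat("<growth_curve:", x$family, ">\n")
  utils::str(x$params, give.attr = FALSE)
  invisible(x)
}

#' Evaluate an individual growth curve under the shape-invariant model
#'
#' The shape-invariant model tailors the population mean curve h to an
#' individual through four effects: size `alpha` shifts the curve up or down,
#' timing `beta` shifts it left or right, intensity `gamma` stretches or
#' shrinks the age scale, and the post-growth slope `delta` adds an
#' individual adult slope beyond `adult_onset`:
#' \deqn{y(t) = \alpha + h(e^{\gamma}(t - \beta)) + \delta (t - t_0)_+}
#' With all effects zero the mean curve is returned exactly.
#'
#' @param curve a [growth_curves] object (the population mean curve h).
#' @param alpha,beta,gamma,delta individual effects (scalars or vectors
#'   recycled against `age`).
#' @param age ages in years.
#' @param adult_onset age at which the post-growth slope starts (years);
#'   defaults to the spline's upper boundary knot when available.
#' @param age_center age (years) about which the intensity effect stretches
#'   the age scale: \eqn{u = t_c + e^{\gamma}(t - \beta - t_c)}. The default
#'   0 gives the plain form \eqn{e^{\gamma}(t - \beta)}; anchoring at a
#'   central age (e.g. the spurt midpoint) keeps the intensity effect a pure
#'   stretch of the spurt rather than an additional timing shift, matching
#'   how shape-invariant growth software offsets age.
#' @return numeric vector of outcome values.
#' @export
sitar_generative_curve <- function(curve, alpha, beta, gamma, delta, age,
                                   adult_onset = NULL, age_center = 0) {
  stopifnot(inherits(curve, "growth_curve"))
  if (is.null(adult_onset)) {
    adult_onset <- if (curve$family == "nspline") curve$params$boundary[2] else Inf
  }
  u <- age_center + exp(gamma) * (age - beta - age_center)
  val <- alpha + curve$fun(u)
  if (any(delta != 0)) val <- val + delta * pmax(age - adult_onset, 0)
  val
}
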