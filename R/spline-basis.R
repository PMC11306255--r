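#' Natural cubic spline basis with analytic derivatives
#'
#' Builds the natural (restricted) cubic spline basis used for the population
#' mean growth curve: cubic between the boundary knots, linear beyond them
#' (zero second derivative at and outside the boundaries). The construction
#' matches \code{splines::ns} without an intercept column, so a basis with
#' \code{k} internal knots has \code{k + 1} columns. Unlike \code{ns()},
#' derivatives of the basis are available analytically, which the model fit
#' and the velocity curves rely on.
#'
#' @param x numeric vector of evaluation points (ages in years).
#' @param knots internal knot locations, strictly increasing.
#' @param boundary length-2 boundary knots; points outside are extrapolated
#'   linearly (first-order Taylor expansion about the nearer boundary).
#' @param deriv derivative order: 0 (values), 1 or 2.
#' @return matrix with \code{length(x)} rows and \code{length(knots) + 1}
#'   columns.
#' @examples
#' b <- ns_basis(seq(7, 17, 0.5), knots = c(10, 13), boundary = c(7, 17))
#' @export
ns_basis <- function(x, knots, boundary, deriv = 0L) {
  stopifnot(is.numeric(x), length(boundary) == 2L, boundary[1] < boundary[2])
  if (length(knots)) {
    if (is.unsorted(knots, strictly = TRUE))
      stop("internal knots must be strictly increasing")
    if (any(knots <= boundary[1]) || any(knots >= boundary[2]))
      stop("internal knots must lie strictly inside the boundary knots")
  }
  deriv <- as.integer(deriv)
  stopifnot(deriv %in% 0:2)

  akn <- sort(c(rep(boundary, 4L), knots))
  ncol_full <- length(akn) - 4L
  # constraint: zero second derivative at both boundaries (naturality)
  const <- splines::splineDesign(akn, boundary, ord = 4L, derivs = c(2L, 2L))
  # drop the leading B-spline column (intercept handled by the model)
  const <- const[, -1L, drop = FALSE]
  qr_const <- qr(t(const))

  project <- function(des) {
    des <- des[, -1L, drop = FALSE]
    as.matrix(t(qr.qty(qr_const, t(des)))[, -(1:2), drop = FALSE])
  }

  eval_inside <- function(xx, d) {
    project(splines::splineDesign(akn, xx, ord = 4L,
                                  derivs = rep(d, length(xx))))
  }

  out <- matrix(0, length(x), ncol_full - 3L)
  lo <- x < boundary[1]
  hi <- x > boundary[2]
  inside <- !(lo | hi)
  if (any(inside)) out[inside, ] <- eval_inside(x[inside], deriv)
  # linear extrapolation beyond the boundary knots
  for (side in c(1L, 2L)) {
    sel <- if (side == 1L) lo else hi
    if (!any(sel)) next
    b0 <- eval_inside(boundary[side], 0L)
    b1 <- eval_inside(boundary[side], 1L)
    out[sel, ] <- switch(deriv + 1L,
      rep(1, sum(sel)) %o% drop(b0) + (x[sel] - boundary[side]) %o% drop(b1),
      rep(1, sum(sel)) %o% drop(b1),
      matrix(0, sum(sel), ncol(out)))
  }
  dimnames(out) <- list(NULL, paste0("s", seq_len(ncol(out))))
  out
}

#' Internal knots at equally spaced quantiles of the age distribution
#'
#' With \code{n_knots = k}, knots sit at the \code{1/(k+1), ..., k/(k+1)}
#' quantiles of the observed ages, the placement used for all mean-curve
#' spline fits.
#'
#' @param ages numeric vector of observed ages.
#' @param n_knots number of internal knots, between 2 and 5.
#' @return list with \code{knots} and \code{boundary}.
#' @export
spline_knots <- function(ages, n_knots) {
  n_knots <- as.integer(n_knots)
  if (n_knots < 2L || n_knots > 5L)
    stop("n_knots must be between 2 and 5")
  ages <- ages[is.finite(ages)]
  if (length(unique(ages)) < n_knots + 2L)
    stop("too few distinct ages for ", n_knots, " internal knots")
  probs <- seq_len(n_knots) / (n_knots + 1)
  list(knots = unname(stats::quantile(ages, probs)),
       boundary = range(ages))
}
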