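# Shared fixtures and independent oracles, all built in code.

# Standard clinic visit design
visit_ages <- c(7.5, 8.5, 9.9, 10.7, 11.8, 12.8, 13.8, 15.4, 17.8)

# Female/male height mean curves used across tests
height_curve_f <- function() growth_spurt_curve(121, 5.5, 0.18, 24, 11.8, 1.3)
height_curve_m <- function() growth_spurt_curve(123, 5.3, 0.15, 28, 13.5, 1.25)

# Directly simulate single-measure height-like data with known effects,
# bypassing the cohort machinery (keeps unit tests independent of it).
make_height_data <- function(n, seed = 1, curve = height_curve_f(),
                             timing_sd = 1, size_sd = 3, intensity_sd = 0.15,
                             residual_sd = 0.8, jitter_sd = 2 / 12,
                             age_shift = 0) {
  set.seed(seed)
  tb <- rnorm(n, 0, timing_sd)
  ta <- rnorm(n, 0, size_sd)
  tg <- rnorm(n, 0, intensity_sd)
  rows <- lapply(seq_len(n), function(i) {
    t <- visit_ages + rnorm(length(visit_ages), 0, jitter_sd)
    v <- sitar_generative_curve(curve, ta[i], tb[i], tg[i], 0, t,
                                age_center = curve$params$midpoint) +
      rnorm(length(t), 0, residual_sd)
    data.frame(id = i, age = t + age_shift, value = v)
  })
  list(data = do.call(rbind, rows),
       truth = data.frame(id = seq_len(n), alpha = ta, beta = tb, gamma = tg))
}

# Closed-form marginal ML log-likelihood for the random-intercept linear
# mixed model y = X beta + u_i + e, maximised by profiling beta and sigma^2
# and a 1-d search over the variance ratio lambda = tau^2 / sigma^2.
# Written from the GLS normal equations, independent of nlme.
gls_random_intercept_loglik <- function(y, X, id) {
  ids <- unique(id)
  profile_ll <- function(lambda) {
    W <- matrix(0, ncol(X), ncol(X))
    z <- rep(0, ncol(X))
    logdet <- 0
    Vinv <- list()
    for (i in ids) {
      sel <- id == i
      ni <- sum(sel)
      V <- diag(ni) + matrix(lambda, ni, ni)
      Vinv[[as.character(i)]] <- solve(V)
      logdet <- logdet + as.numeric(determinant(V)$modulus)
      Xi <- X[sel, , drop = FALSE]
      W <- W + t(Xi) %*% Vinv[[as.character(i)]] %*% Xi
      z <- z + t(Xi) %*% Vinv[[as.character(i)]] %*% y[sel]
    }
    beta <- solve(W, z)
    rss <- 0
    for (i in ids) {
      sel <- id == i
      r <- y[sel] - X[sel, , drop = FALSE] %*% beta
      rss <- rss + t(r) %*% Vinv[[as.character(i)]] %*% r
    }
    n <- length(y)
    s2 <- as.numeric(rss) / n
    -0.5 * (n * log(2 * pi * s2) + logdet + n)
  }
  stats::optimize(profile_ll, c(1e-8, 1e4), maximum = TRUE,
                  tol = 1e-10)$objective
}

# Small cohort reused by several files (helpers are loaded once per file;
# the closure caches within a file's session)
shared_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- simulate_cohort(sim_config(n_per_sex = 60, seed = 42))
    cache
  }
})
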