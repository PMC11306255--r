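#' Build a genetic risk score from SNP dosages and weights
#'
#' Raw score for individual i is the weighted mean over SNPs,
#' \eqn{\sum_j d_{ij} w_j / m} with dosages \eqn{d_{ij} \in [0, 2]} and m
#' the number of SNPs used, i.e. the average per-SNP effect on the source
#' trait; the standardized score rescales to mean 0, SD 1. SNPs in the
#' weight table but absent from the dosage matrix are dropped with a
#' warning (m is reduced accordingly). Missing dosages are mean-imputed
#' per SNP by default, or excluded per individual (per-individual m).
#'
#' @param dosages numeric matrix (individuals x SNPs, entries in `[0, 2]`,
#'   fractional allowed for imputed genotypes) with SNP ids as column names
#'   and, optionally, individual ids as row names.
#' @param weights data.frame with columns `snp`, `effect_allele`, `weight`.
#' @param missing how to handle missing dosages: "impute_mean" or
#'   "exclude".
#' @return data.frame with `id`, `grs_raw`, `grs_std`.
#' @export
build_grs <- function(dosages, weights,
                      missing = c("impute_mean", "exclude")) {
  missing <- match.arg(missing)
  stopifnot(is.matrix(dosages),
            all(c("snp", "weight") %in% names(weights)))
  if (anyDuplicated(weights$snp)) stop("duplicate SNP ids in weights")
  if (!all(is.finite(weights$weight))) stop("weights must be finite")
  rng <- range(dosages, na.rm = TRUE)
  if (rng[1] < 0 || rng[2] > 2)
    stop("dosages must lie in [0, 2]")
  use <- weights$snp %in% colnames(dosages)
  if (!any(use)) stop("no usable SNPs: none of the weight-table SNPs are in the dosage matrix")
  if (any(!use))
    warning(sum(!use), " SNP(s) in weights absent from dosages; excluded",
            call. = FALSE)
  w <- weights$weight[use]
  D <- dosages[, weights$snp[use], drop = FALSE]
  if (missing == "impute_mean" && anyNA(D)) {
    for (j in seq_len(ncol(D))) {
      nas <- is.na(D[, j])
      if (any(nas)) D[nas, j] <- mean(D[, j], na.rm = TRUE)
    }
  }
  if (missing == "exclude") {
    m_i <- rowSums(!is.na(D))
    if (any(m_i == 0)) stop("some individuals have no non-missing dosages")
    raw <- rowSums(sweep(D, 2L, w, `*`), na.rm = TRUE) / m_i
  } else {
    raw <- drop(D %*% w) / length(w)
  }
  std <- if (stats::sd(raw) > 0) as.numeric(scale(raw)) else raw * NA
  data.frame(id = if (is.null(rownames(dosages)))
               seq_len(nrow(dosages)) else rownames(dosages),
             grs_raw = unname(raw), grs_std = std,
             stringsAsFactors = FALSE)
}

#' Read a 3-column GRS weight table (TSV: snp, effect_allele, weight)
#' @param path file path.
#' @return data.frame with `snp`, `effect_allele`, `weight`.
#' @export
read_grs_weights <- function(path) {
  w <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("snp", "effect_allele", "weight")
  if (!all(need %in% names(w)))
    stop("weights file must have columns: ", paste(need, collapse = ", "))
  w
}

#' Read a dosage matrix from CSV (rows = individuals, columns = SNPs,
#' first column `id`) or from a VCF with per-genotype DS (dosage) fields.
#' @param path file path (`.vcf` handled via the DS field).
#' @return numeric matrix, individuals x SNPs, rownames = ids.
#' @export
read_dosages <- function(path) {
  if (grepl("\\.vcf(\\.gz)?$", path)) return(read_vcf_dosages(path))
  d <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!"id" %in% names(d)) stop("dosage CSV must have an `id` column")
  m <- as.matrix(d[setdiff(names(d), "id")])
  rownames(m) <- d$id
  storage.mode(m) <- "double"
  m
}

# Minimal VCF DS-field reader via vcfR; returns individuals x SNPs.
read_vcf_dosages <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  ds <- vcfR::extract.gt(v, element = "DS", as.numeric = TRUE)
  t(ds)
}

#' Pairwise Pearson correlations between pubertal age measures
#'
#' Computed on the complete-case subset: individuals (within the table
#' passed in, typically one sex) with every measure non-missing. A
#' zero-variance column yields `NA` correlations for its pairs, with a
#' warning.
#'
#' @param ages wide pubertal-age data.frame (`id`, optional `sex`, one
#'   column per measure).
#' @return list with `r` (correlation matrix), `n` (complete cases).
#' @export
pairwise_correlations <- function(ages) {
  meas <- setdiff(names(ages), c("id", "sex"))
  cc <- ages[stats::complete.cases(ages[meas]), meas, drop = FALSE]
  if (nrow(cc) < 3) stop("fewer than 3 complete-case individuals")
  sds <- vapply(cc, stats::sd, numeric(1))
  if (any(sds == 0))
    warning("zero-variance measure(s): ",
            paste(meas[sds == 0], collapse = ", "),
            "; correlations undefined", call. = FALSE)
  r <- suppressWarnings(stats::cor(cc))
  r[, sds == 0] <- NA
  r[sds == 0, ] <- NA
  diag(r) <- ifelse(sds == 0, NA, 1)
  list(r = r, n = nrow(cc))
}

association_result <- function(fit, exposure, outcome, covariates = character()) {
  sm <- summary(fit)$coefficients
  est <- sm[exposure, "Estimate"]
  se <- sm[exposure, "Std. Error"]
  data.frame(exposure = exposure, outcome = outcome,
             beta = est, se = se,
             lcl = est - 1.96 * se, ucl = est + 1.96 * se,
             n = length(fit$residuals),
             covariates = paste(covariates, collapse = "+"),
             stringsAsFactors = FALSE)
}

#' Univariable linear regression of a pubertal age on an exposure
#'
#' Ordinary least squares of the outcome (years) on the exposure
#' (typically a standardized GRS), giving the mean difference in pubertal
#' age per SD of exposure with normal-approximation 95\% CI.
#'
#' @param data data.frame holding both variables.
#' @param outcome,exposure column names.
#' @return one-row data.frame: exposure, outcome, beta, se, lcl, ucl, n,
#'   covariates.
#' @export
regress_univariable <- function(data, outcome, exposure) {
  regress_adjusted(data, outcome, exposure, covariates = character())
}

#' Confounder-adjusted linear regression
#'
#' OLS of the pubertal age on the exposure plus covariates on complete
#' cases; the reported coefficient is the partial (adjusted) slope for the
#' exposure. With an empty covariate set this is exactly the univariable
#' model. A rank-deficient design is an error naming the aliased columns.
#'
#' @param data data.frame holding all variables.
#' @param outcome,exposure column names.
#' @param covariates character vector of covariate column names.
#' @return one-row data.frame as in [regress_univariable()].
#' @export
regress_adjusted <- function(data, outcome, exposure,
                             covariates = character()) {
  vars <- c(outcome, exposure, covariates)
  stopifnot(all(vars %in% names(data)))
  cc <- data[stats::complete.cases(data[vars]), vars, drop = FALSE]
  if (nrow(cc) < length(vars) + 1)
    stop("too few complete cases (n = ", nrow(cc), ")")
  if (stats::sd(cc[[exposure]]) == 0) stop("exposure is constant")
  form <- stats::reformulate(c(exposure, covariates), response = outcome)
  fit <- stats::lm(form, data = cc)
  if (any(is.na(stats::coef(fit))))
    stop("collinear design; aliased: ",
         paste(names(stats::coef(fit))[is.na(stats::coef(fit))],
               collapse = ", "))
  association_result(fit, exposure, outcome, covariates)
}

#' Standardize values within sex/age-band groups
#'
#' Z-scores with mean 0 and SD 1 within each group (e.g. sex x age band),
#' the coding used for fat and lean mass indices. Singleton groups give
#' `NA` with a warning.
#'
#' @param values numeric vector.
#' @param groups grouping vector/factor of the same length.
#' @return numeric vector of within-group z-scores.
#' @export
standardize_by_group <- function(values, groups) {
  stopifnot(length(values) == length(groups))
  groups <- as.factor(groups)
  sizes <- table(groups)[groups]
  if (any(sizes < 2))
    warning("singleton group(s); z-scores set to NA", call. = FALSE)
  mu <- stats::ave(values, groups)
  sdv <- stats::ave(values, groups, FUN = stats::sd)
  z <- (values - mu) / sdv
  z[sizes < 2] <- NA
  z
}

#' Fat or lean mass index: mass divided by height squared
#' @param mass_kg total body fat or lean mass, kg.
#' @param height_m height, m.
#' @return index in kg/m^2.
#' @export
mass_index <- function(mass_kg, height_m) {
  stopifnot(all(height_m > 0, na.rm = TRUE))
  mass_kg / height_m^2
}
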