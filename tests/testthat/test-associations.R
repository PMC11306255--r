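test_that("GRS arithmetic matches a brute-force oracle", {
  # printed toy: dosages (2,1,0), weights (.1,.2,.3) -> (2*.1 + 1*.2)/3
  D <- matrix(c(2, 1, 0), nrow = 1,
              dimnames = list("i1", c("rs1", "rs2", "rs3")))
  W <- data.frame(snp = c("rs1", "rs2", "rs3"),
                  effect_allele = c("A", "C", "G"),
                  weight = c(0.1, 0.2, 0.3))
  g <- build_grs(rbind(D, D * 0 + 1), W) # add a 2nd individual for SD
  expect_equal(g$grs_raw[1], 0.4 / 3, tolerance = 1e-12)

  # brute-force loop oracle on random data
  set.seed(5)
  D2 <- matrix(runif(50 * 7, 0, 2), 50, 7,
               dimnames = list(NULL, paste0("rs", 1:7)))
  W2 <- data.frame(snp = paste0("rs", 1:7), effect_allele = "A",
                   weight = rnorm(7))
  oracle <- sapply(1:50, function(i) {
    acc <- 0
    for (j in 1:7) acc <- acc + D2[i, j] * W2$weight[j]
    acc / 7
  })
  g2 <- build_grs(D2, W2)
  expect_equal(g2$grs_raw, oracle, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(mean(g2$grs_std), 0, tolerance = 1e-12)
  expect_equal(sd(g2$grs_std), 1, tolerance = 1e-12)
})

test_that("GRS construction is invariant to column order and weight scale", {
  set.seed(6)
  D <- matrix(runif(30 * 5, 0, 2), 30, 5,
              dimnames = list(NULL, paste0("rs", 1:5)))
  W <- data.frame(snp = paste0("rs", 1:5), effect_allele = "A",
                  weight = rnorm(5))
  g1 <- build_grs(D, W)
  g2 <- build_grs(D[, c(3, 1, 5, 2, 4)], W)
  expect_equal(g1$grs_raw, g2$grs_raw, tolerance = 1e-12)
  W3 <- W; W3$weight <- W3$weight * 4
  g3 <- build_grs(D, W3)
  expect_equal(g3$grs_raw, 4 * g1$grs_raw, tolerance = 1e-12)
  expect_equal(g3$grs_std, g1$grs_std, tolerance = 1e-12)

  # weights all zero: raw score identically zero
  W0 <- W; W0$weight <- 0
  expect_equal(build_grs(D, W0)$grs_raw, rep(0, 30))
})

test_that("missing SNPs and missing dosages are handled as documented", {
  set.seed(7)
  D <- matrix(runif(20 * 3, 0, 2), 20, 3,
              dimnames = list(NULL, c("rs1", "rs2", "rs3")))
  W <- data.frame(snp = c("rs1", "rs2", "rs3", "rs9"),
                  effect_allele = "A", weight = c(.1, .2, .3, .4))
  expect_warning(g <- build_grs(D, W), "absent")
  expect_equal(g$grs_raw, drop(D %*% c(.1, .2, .3)) / 3, tolerance = 1e-12)

  Dm <- D; Dm[1, 2] <- NA
  gi <- build_grs(Dm, W[1:3, ])
  exp1 <- (Dm[1, 1] * .1 + mean(Dm[-1, 2]) * .2 + Dm[1, 3] * .3) / 3
  expect_equal(gi$grs_raw[1], unname(exp1), tolerance = 1e-12)
  ge <- build_grs(Dm, W[1:3, ], missing = "exclude")
  expect_equal(ge$grs_raw[1], unname((Dm[1, 1] * .1 + Dm[1, 3] * .3) / 2),
               tolerance = 1e-12)

  expect_error(build_grs(D, data.frame(snp = "zz", effect_allele = "A",
                                       weight = 1)), "no usable SNPs")
  expect_error(build_grs(D * 2, W[1:3, ]), "\\[0, 2\\]")
})

test_that("dosage readers round-trip CSV and parse VCF DS fields", {
  set.seed(8)
  D <- matrix(round(runif(6 * 3, 0, 2), 3), 6, 3,
              dimnames = list(paste0("ind", 1:6), paste0("rs", 1:3)))
  csv <- tempfile(fileext = ".csv")
  write.csv(data.frame(id = rownames(D), D, check.names = FALSE), csv,
            row.names = FALSE)
  D2 <- read_dosages(csv)
  expect_equal(unname(D2), unname(D), tolerance = 1e-12)
  expect_identical(rownames(D2), rownames(D))

  skip_if_not_installed("vcfR")
  vcf <- tempfile(fileext = ".vcf")
  hdr <- c("##fileformat=VCFv4.2",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Dosage\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", rownames(D)), collapse = "\t"))
  body <- sapply(1:3, function(j) {
    paste(c("1", j * 100, paste0("rs", j), "A", "G", ".", "PASS", ".",
            "GT:DS", paste0("0/1:", D[, j])), collapse = "\t")
  })
  writeLines(c(hdr, body), vcf)
  Dv <- read_dosages(vcf)
  expect_equal(unname(Dv[rownames(D), ]), unname(D), tolerance = 1e-6)
})

test_that("pairwise correlations use complete cases and stay PSD", {
  ages <- data.frame(id = 1:6,
                     m1 = c(1, 2, 3, 4, 5, NA),
                     m2 = c(3, 2, 1, 0, -1, 7),
                     m3 = c(1, 1, 2, 2, 3, 3))
  pc <- pairwise_correlations(ages)
  expect_identical(pc$n, 5L)
  expect_equal(pc$r["m1", "m2"], -1, tolerance = 1e-12)
  expect_equal(diag(pc$r), c(m1 = 1, m2 = 1, m3 = 1))
  expect_equal(pc$r, t(pc$r))
  expect_gte(min(eigen(pc$r, symmetric = TRUE, only.values = TRUE)$values),
             -1e-10)

  ages$m3 <- 2
  expect_warning(pz <- pairwise_correlations(ages), "zero-variance")
  expect_true(all(is.na(pz$r["m3", ])))
  expect_error(pairwise_correlations(ages[1:2, ]), "fewer than 3")
})

test_that("univariable regression identities hold", {
  # exact linear relation: slope recovered with zero residual error
  d <- data.frame(x = c(-1, 0, 1, 2), y = c(-2, 0, 2, 4))
  r <- regress_univariable(d, "y", "x")
  expect_equal(r$beta, 2, tolerance = 1e-12)
  expect_lt(r$se, 1e-12)
  expect_equal(r$n, 4L, ignore_attr = TRUE)
  expect_equal(r$lcl, r$beta - 1.96 * r$se)
  expect_error(regress_univariable(data.frame(x = rep(1, 9), y = 1:9),
                                   "y", "x"), "constant")

  # permutation null: CI covers zero at ~95%
  set.seed(9)
  cover <- replicate(20, {
    x <- rnorm(500); y <- sample(x) + rnorm(500)
    r <- regress_univariable(data.frame(x = x, y = y), "y", "x")
    r$lcl < 0 && r$ucl > 0
  })
  expect_gte(sum(cover), 17)
})

test_that("slope on a standardized exposure equals r times SD of outcome", {
  set.seed(10)
  n <- 2000
  x <- as.numeric(scale(rnorm(n)))
  r_target <- 0.4; s_out <- 1.2
  y <- s_out * (r_target * x + sqrt(1 - r_target^2) * rnorm(n))
  fit <- regress_univariable(data.frame(x = x, y = y), "y", "x")
  expect_lt(abs(fit$beta - r_target * s_out), 3 * fit$se)
})

test_that("within-group standardization is exact and flags singletons", {
  z <- standardize_by_group(c(1, 2, 3), rep("a", 3))
  expect_equal(z, c(-1, 0, 1))
  v <- c(1, 2, 3, 10, 20, 30)
  g <- rep(c("a", "b"), each = 3)
  z2 <- standardize_by_group(v, g)
  expect_equal(as.vector(tapply(z2, g, mean)), c(0, 0), tolerance = 1e-12)
  expect_equal(as.vector(tapply(z2, g, sd)), c(1, 1), tolerance = 1e-12)
  expect_warning(z3 <- standardize_by_group(c(1, 2, 3), c("a", "a", "b")),
                 "singleton")
  expect_true(is.na(z3[3]))
})

test_that("adjusted regression reduces to univariable and removes confounding", {
  set.seed(11)
  n <- 4000
  C <- rnorm(n)
  x <- 0.5 * C + sqrt(1 - 0.25) * rnorm(n)
  y <- -0.35 * x - 0.3 * C + rnorm(n, 0, 0.6)
  d <- data.frame(x = x, y = y, C = C)
  unadj <- regress_univariable(d, "y", "x")
  adj <- regress_adjusted(d, "y", "x", "C")
  # linear-SEM closed form: unadjusted = direct + conf_effect * cor(x, C)
  expect_lt(abs(adj$beta - (-0.35)), 0.05)
  expect_lt(abs(unadj$beta - (-0.35 - 0.3 * 0.5)), 0.05)

  # empty covariate set reproduces the univariable fit exactly
  expect_equal(regress_adjusted(d, "y", "x", character())$beta, unadj$beta)
  # irrelevant covariates leave the slope essentially unchanged
  d$z <- rnorm(n)
  expect_lt(abs(regress_adjusted(d, "y", "x", "z")$beta - unadj$beta), 0.02)
  # collinear design errors with the offending column
  d$x2 <- d$x
  expect_error(regress_adjusted(d, "y", "x", "x2"), "collinear")
})

test_that("fat mass index is mass over height squared", {
  expect_equal(mass_index(20, 1.40), 20 / 1.96, tolerance = 1e-12)
  expect_equal(mass_index(c(10, 30), c(1.2, 1.5)),
               c(10 / 1.44, 30 / 2.25))
})
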