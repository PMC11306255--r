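#!/usr/bin/env Rscript

# Stage 4: associations of the derived pubertal ages with the simulated
# genetic risk score and with childhood body composition.
#
# GRS models are unadjusted univariable regressions (years of pubertal
# age per SD of standardized score). Fat/lean mass index models adjust
# for age at DXA and the maternal/childhood confounder set, reporting the
# partial slope in years per SD.

suppressMessages(library(pubtiming))

ages <- read.csv("results/pubertal_ages/pubertal_ages.csv")
covs <- read.csv("results/cohort/covariates.csv")
out_dir <- "results/associations"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

dat <- merge(ages, covs, by = c("id", "sex"))
meas <- setdiff(names(ages), c("id", "sex"))
conf <- c("maternal_age", "maternal_bmi", "maternal_education",
          "maternal_smoking", "parity", "energy_intake_kj", "dxa_age")

rows <- list()
for (sx in c("F", "M")) {
  d <- dat[dat$sex == sx, ]
  for (m in meas[colSums(!is.na(d[meas])) > 10]) {
    rows[[paste(sx, m, "grs")]] <-
      cbind(sex = sx, model = "grs_univariable",
            regress_univariable(d, m, "grs"))
    rows[[paste(sx, m, "fmi")]] <-
      cbind(sex = sx, model = "fmi_adjusted",
            regress_adjusted(d, m, "fmi_z", conf))
    rows[[paste(sx, m, "lmi")]] <-
      cbind(sex = sx, model = "lmi_adjusted",
            regress_adjusted(d, m, "lmi_z", conf))
  }
}
assoc <- do.call(rbind, rows)
rownames(assoc) <- NULL
write.csv(assoc, file.path(out_dir, "associations.csv"), row.names = FALSE)

cat("GRS associations (years per SD of score; positive = later puberty):\n")
print(assoc[assoc$model == "grs_univariable",
            c("sex", "outcome", "beta", "lcl", "ucl", "n")],
      digits = 2, row.names = FALSE)
cat("\nFat mass index, confounder-adjusted (years per SD; negative =",
    "earlier puberty with higher fat mass):\n")
print(assoc[assoc$model == "fmi_adjusted",
            c("sex", "outcome", "beta", "lcl", "ucl", "n")],
      digits = 2, row.names = FALSE)
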