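---
title: "Modelling pubertal timing from longitudinal growth and development data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling pubertal timing from longitudinal growth and development data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pubtiming)
```

## The problem

Puberty has no single observable onset. Cohort studies instead track many
downstream indicators — the adolescent growth spurt in height, weight and
bone mineral content (BMC), Tanner stages of pubic hair, breast and
genitalia development, axillary hair, voice breaking, and menarche — each
measured repeatedly between roughly ages 7 and 17. `pubtiming` turns such
longitudinal data into per-individual *pubertal ages* (one per indicator),
and then asks how the indicators relate to each other and to genetic and
body-composition exposures.

The package is organised as an analysis workflow: the numbered scripts
under `analysis/` run the stages (simulate, fit, derive, associate) over
the functions in `R/`, which carry all the computation and are what the
tests exercise.

## The shape-invariant growth model

All indicators except menarche are modelled with SITAR (SuperImposition by
Translation And Rotation), a shape-invariant nonlinear mixed-effects
model. One natural cubic spline mean curve $h$ is fitted to the whole
sample (per sex), and individual curves are deviations from it:

$$
y_{ij} = (a_0 + a_i) + h\!\left(t_0 + e^{c_0 + c_i}\,(t_{ij} - b_0 - b_i - t_0)\right)
       + (d_0 + d_i)\,(t_{ij} - t_U)_+ + \varepsilon_{ij}
$$

* **size** $a_i$ (outcome units) shifts the curve up/down;
* **timing** $b_i$ (years) shifts it left/right — this is the quantity of
  interest, interpreted as relative pubertal timing;
* **intensity** $c_i$ (log age-scale) stretches or shrinks the age axis,
  i.e. lengthens or shortens the growth spurt;
* **post-growth** $d_i$ (units/year) lets the adult slope beyond an onset
  age $t_U$ vary between individuals.

Random effects $(a_i, b_i, c_i, d_i) \sim N(0, \Omega)$ with unstructured
$\Omega$, residuals $\varepsilon_{ij} \sim N(0, \sigma^2)$.

Three variants are used, matching what each outcome supports:
height uses \{size, timing, intensity\}; weight and BMC add the
post-growth effect (they keep growing after the spurt); ordinal
development scales (Tanner stages treated as continuous scores, voice
breaking 1–3, axillary hair 1–2) use the reduced \{timing, intensity\}
variant — everyone occupies the same bounded scale, so a size effect has
no meaning there.

### Parameterisation choices

**Age-centred intensity.** We write the age transformation as
$u = t_0 + e^{c}(t - b - t_0)$ with the anchor $t_0$ at the mean
observation age (and, in the generator, at the spurt midpoint). An
intensity effect anchored at age 0 would move the spurt by
$\approx 12\,c$ years — at a realistic intensity SD of 0.15 that is a
±1.8 y pseudo-timing shift that swamps the true timing signal. Anchored
centrally, intensity is a pure stretch ("rotation") of the curve about
the middle of the data, and timing and intensity decouple cleanly. With
$c = 0$ the two forms coincide.

**Fixed effects for timing and intensity.** The spline's knots are fixed
at quantiles of the observed ages, so a common shift or stretch of the
whole cohort relative to those knots is a genuine fixed effect
$(b_0, c_0)$. Omitting it forces the spline to absorb the alignment,
which we found biases the timing variance component upward by tens of
percent for late-spurt (male-like) curves; estimating $b_0, c_0$
restores the variance to within a few percent. After fitting, the means
of the empirical-Bayes effects are absorbed into the fixed part, so the
reported mean curve is the population-typical curve and the reported
random effects are centred (their mean is 0 by construction).

**Post-growth onset.** The adult-slope effect needs observations beyond
its onset to be identified. With boundary knots at the data range, "the
upper boundary knot" is the oldest observed age and the effect is
degenerate, so the onset is a parameter (`postgrowth_onset`); the default
used for weight and BMC is 15 y, placing the last two clinic visits
(≈15.4 and ≈17.8 y) beyond onset. The velocity-peak search excludes the
post-onset segment: the slope change at onset is not a growth spurt.

### Estimation

`fit_sitar()` maximises the marginal likelihood by iterated first-order
conditional linearization about the current random-effect modes
(Lindstrom–Bates), alternating penalized nonlinear least squares with a
variance-component update; the machinery is `nlme::nlme` with analytic
gradients for all parameters (the natural-spline basis and its
derivative are computed in closed form by `ns_basis()`, which matches
`splines::ns` exactly and extrapolates linearly beyond the boundary
knots). When neither timing nor intensity is random the model is linear
in everything and `nlme::lme` gives the exact ML solution; the test
suite checks this reduction against a hand-written closed-form GLS
oracle to 1e-4.

The random-effect covariance starts from a scaled diagonal (the effects
live on wildly different scales); if the unstructured matrix collapses —
which happens on two-category scales where intensity carries almost no
variance — the fit falls back to a diagonal covariance and then to
timing-only, with a warning. This mirrors the "up to two random effects"
character of the reduced model.

**Model selection.** Candidates with 2–5 internal knots (at equally
spaced age quantiles) are compared by BIC,
$-2\ell + p\log N$ with $N$ = number of individuals and $p$ = fixed
effects + variance parameters; ties prefer fewer knots. The likelihood
entering BIC is the marginal (approximate) one.

## From fits to pubertal ages

Each measure defines a population landmark:

| measure | landmark | default |
|---|---|---|
| height, weight, BMC | age at peak velocity of the fitted mean curve | argmax of the analytic derivative, grid step 0.01 y + local refinement |
| pubic hair, breast, genitalia | mean curve crosses stage 3 | root-find to 0.001 y |
| voice breaking | mean curve crosses 2 (midpoint of 1–3) | configurable |
| axillary hair | mean curve crosses 1.5 (midpoint of 1–2) | configurable |
| menarche | first reported onset age | no model |

The crossing values for voice and axillary hair are design choices (the
scales' category midpoints, the natural "event" boundary); "stage 3" is
implemented as entry into stage 3 (curve = 3), the other defensible
reading being the stage-3 midpoint. All are exposed as the
`landmark_levels` argument.

An individual's pubertal age for a measure is
*landmark + predicted timing effect* $b_i$ — not rescaled by intensity,
keeping the derived age a pure translation of the population landmark.
Because empirical-Bayes predictions are shrunken with mean ≈ 0, the
population mean of each derived age is the landmark itself.

Inconsistent ordinal reports (a stage lower than previously reported)
are left in — the regression model treats them as measurement error —
except for voice breaking, where regressions below the individual's
running maximum are removed before fitting (`clean_voice_series()`);
they otherwise destabilise that model's convergence. A ±5 SD screen
within sex × assessment occasion (`remove_outliers()`) re-runs the
anthropometric fits as a sensitivity analysis.

## The synthetic cohort

Because the motivating cohort data are managed-access, the package ships
a generator (`simulate_cohort()`) that emulates the observed-data design
and doubles as the test oracle: every downstream stage is validated by
recovering known individual effects.

What it emulates: nine clinic visits (~7.5–17.8 y; BMC at five of them)
and nine questionnaires (~8–17 y; voice from the second, axillary hair
from the third); exact ages jittered by SD 2 months; occasion-level
missingness (default 10%); sex-specific mean curves; a per-individual
latent timing factor shared across measures; ordinal stages produced by
thresholding a monotone latent development curve; menarche reported at
the first questionnaire after occurrence with configurable recall noise;
a standardized GRS correlated with latent timing; fat/lean mass indices
and maternal confounders with configured paths into timing.

Key default magnitudes, chosen once for realism: timing SD 1.0–1.2 y per
measure (between-individual SDs of pubertal ages in cohorts are
0.7–1.2 y), size SD 3 cm for height, intensity SD 0.15, residual SD
0.8 cm for height; height mean curves with childhood velocity ~5.5 cm/y
decaying over age and a logistic spurt peaking near 11.7 y (F) / 13.4 y
(M) at 9–10 cm/y; stage-3 crossings near 11.5 y (breast) / 12.6 y (male
pubic hair); menarche mean 12.7 y; voice breaking 14.2 y. A constant
background slope would make timing unidentifiable from size (the two
trade off exactly wherever the curve is straight), so the decaying
childhood velocity is not cosmetic — it is what makes the recovery
criteria meaningful.

Cross-measure coupling is one-factor by default: measure $m$'s timing is
$\beta_{im} = \sigma_m(\lambda_m T_i + \sqrt{1-\lambda_m^2}\,
\epsilon_{im})$ with a shared factor $T_i$, giving pairwise correlations
$\lambda_a \lambda_b$. A one-factor structure cannot reach every
correlation pattern (e.g. the triple 0.3/0.5/0.7 implies a loading above
1), so an explicit correlation matrix can be supplied instead
(`timing_cor_matrix`), drawn by Cholesky factorisation; in that mode the
covariate/GRS paths are decoupled from timing.

What the generator does **not** emulate — and hence what passing tests do
not establish about real data: informative (attrition-like) missingness,
secular trends, reporting heaping on whole years, parent-vs-child
questionnaire differences, scale-dependent measurement error in DXA, and
genuine genotypes (the GRS is simulated directly as a standardized
score).

## Numerical behaviour and known limitations

* **Translation equivariance.** Shifting all input ages by +1 y shifts
  every derived pubertal age by 1 y and leaves $\Omega$, $\sigma$
  unchanged — knots are quantile-based, so the whole analysis is
  equivariant; this is a tested invariant.
* **Peak-location resolution.** With 2–5 quantile knots, the spline can
  misplace a velocity peak by ~0.05–0.1 y where visits are sparse
  (the late male spurt): even the best $L_2$ spline approximation of a
  male-type curve misses its peak by 0.13–0.27 y, and curve registration
  via the random effects recovers most but not all of that. The
  acceptance check therefore evaluates the *mean* fitted-vs-analytic
  peak error over replicate cohorts.
* **Variance components from few visits.** BMC (five visits) yields
  shrunken timing predictions and a downward-biased timing SD — an
  imprecision intrinsic to the design, not the estimator; derived BMC
  ages correlate well with truth but compress its spread.
* **Four-effect convergence.** The weight/BMC variant's unstructured
  4x4 covariance has a nearly flat direction: the individual adult slope
  is informed by only the last two clinic visits, and its fixed part is
  close to collinear with the spline's tail. At several hundred
  individuals `nlme` can cycle without meeting its convergence criterion
  even though the estimates stabilise within a few iterations (such fits
  are returned flagged), and for BMC (five occasions) the design can go
  outright singular. The analysis drivers therefore run the full
  nine-measure battery at 80 individuals per sex, a regime where all
  thirteen measure-by-sex fits converge; the recovery studies, which use
  the three- and two-effect variants, run at 500-2000.
* **Approximate likelihood.** The first-order linearization's
  $\ell$ is what BIC and the reduction oracle use; it is exact for the
  linear variants. Adding a random effect never decreased the
  approximate $\ell$ in our tests, but this is not guaranteed by theory.
* **Problem sizes.** The shipped tests run the recovery studies at 500
  individuals per sex (9 visits), correlation-structure studies at 2000,
  and knot-selection replicates at 1000 individuals × 20 replicates;
  these sizes give Monte-Carlo errors comfortably below the tolerances
  they are tested at.

## Downstream statistics

Pairwise Pearson correlations between derived ages use complete cases
(all measures present for the individual's sex). The GRS is the weighted
mean of effect-allele dosages over the SNP set (sum of dosage × weight,
divided by the number of SNPs), standardized to mean 0, SD 1 before
analysis; missing dosages are mean-imputed per SNP by default (or
excluded, reducing the per-individual denominator). GRS models are
unadjusted univariable OLS; body-composition models are OLS adjusted for
age at DXA and the maternal/childhood confounder set, with fat/lean mass
index = mass / height² standardized in sex (and, where relevant,
age-band) groups. CIs are normal-approximation $\beta \pm 1.96\,$SE; no
multiple-testing adjustment is applied, matching per-model reporting.
Each analysis defines its own complete-case set (correlations: all
measures; GRS: score + all measures; body composition: exposure,
covariates and all measures).

## Reproducing the validation

`scripts/acceptance.R --seed <int> --out <path>` re-runs the recovery
study and the derivation/association pipeline from scratch and writes
the headline quantities as JSON; `tests/testthat/test-acceptance.R`
holds the corresponding pass/fail checks at their stated tolerances.
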