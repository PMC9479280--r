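---
title: "Distance-based analysis of network volumetrics: models, defaults and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Distance-based analysis of network volumetrics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mdmrvol)
```

# The scientific problem

`mdmrvol` tests whether participant subgroups differ in the joint volumetric
configuration of a brain network — all regions at once — rather than region
by region. The motivating design has three IQ-trajectory subgroups of
autistic children (persistently high, persistently low, changers) compared
at about age three on two intrinsic networks: the fronto-parietal network
(11 bilateral regions) and the default-mode network (12 bilateral regions).
The group labels are inputs, produced upstream by a latent-class analysis of
longitudinal IQ; deriving them is out of scope here, as is image
segmentation — the pipeline starts from a participant table and an
ROI-volume table.

# Normalization

ROI volumes (mm³) are divided by the participant's total brain volume
(supplied in cm³, converted once to mm³), removing overall head-size
differences, and each region's proportions are then T-scored across the
analyzed participants so that small and large regions contribute
comparably: `t = 50 + 10 * (x - mean) / sd`, sample (n−1) SD.

Two conventions had to be fixed where the procedure is usually left
unstated. We use the psychometric T convention (mean 50, SD 10) and the
sample SD. Neither choice affects inference: any affine standardization
changes the Manhattan/Euclidean distance geometry only by a global scale,
to which every MDMR statistic (pseudo-R², pseudo-F, permutation p) is
invariant — the test suite asserts this directly. Standardization uses the
analyzed sample after listwise rejection of incomplete rows (no
imputation); rows with missing ROI values are rejected with a named report,
never silently dropped.

# MDMR: statistic and inference

From the standardized matrix `Y` (n × q) we compute pairwise Manhattan
distances by default — more robust to extreme values than Euclidean or
correlation distances and well-behaved as q grows — and Gower-center them:
`A = -D^2 / 2`, `G = C A C`, `C = I - J/n`. This is the McArdle–Anderson
construction: for Euclidean distances `G = Yc Yc'` exactly, so the
Euclidean special case collapses to classical multivariate regression and
serves as an exact oracle (with a single outcome the pseudo-F equals the
OLS F to 1e-8; the suite checks both identities, and cross-checks the
Manhattan case against an independent PERMANOVA implementation).

For a design `X` with hat matrix `H`:

* full-model pseudo-R² = `tr(HGH) / tr(G)`;
* a term's pseudo-R² (the per-contrast "β" reported by this class of
  analysis) is the increment over the reduced model without that term;
* pseudo-F = `(Δtr / df1) / (tr(RGR) / df2)`, `R = I - H`,
  `df1 = rank(X) - rank(X_reduced)`, `df2 = n - rank(X)`.

Covariate models are: group + age + sex (model 1), adding family-income
bracket (model 2) or parental education (model 3). Ordinal covariates are
dummy-coded against a reference level with `"missing"` as an explicit
category; aliased columns are dropped with a message.

**Permutation scheme.** p-values use Freedman–Lane permutation: residuals
under the term's reduced model are permuted while the covariate fit is
retained, preserving exchangeability for covariate-adjusted contrasts. The
algebra is implemented so each permutation costs O(n²) (the permuted
`G* = M G M'` decomposes into fixed blocks plus gathers), with the hot loop
in C++. A raw label-permutation scheme is available behind a flag for
comparison. The p-value is the add-one estimator `(1 + #{F* ≥ F})/(1 + B)`;
ties count as exceedances (conservative), and p = 0 is never reported. The
default B in the pipeline driver is 999, chosen so a desk-scale replication
(two networks, all contrasts) completes in seconds; for publication-grade
p-values users should raise B (9,999 is a common choice) — the estimator
and seeding are unchanged.

**Pairwise contrasts and interactions.** Pairwise group differences are
two-group refits: the distance submatrix is re-centered on the subset
(Gower centering is sample-dependent, so subsetting the full-sample `G`
would be wrong — a test asserts the recomputation) and the two-level group
term is tested adjusted for covariates. The sex × group interaction is
tested as a single product-term block against the main-effects model. No
multiplicity correction is applied across the three contrasts or the two
networks, matching the descriptive framing of the source design;
`stats::p.adjust`-style correction can be applied downstream by the user.

**Indefinite G.** Under Manhattan distances `G` can have negative
eigenvalues, so a term's pseudo-R² is not mathematically confined to
[0, 1]; values outside it are reported as computed with a warning.
Permutation inference is rank-based and unaffected.

# Jack-knife effect sizes

To attribute a multivariate term effect to individual regions, each column
of `Y` is in turn dissociated from the predictors: the column's values are
shuffled across participants K times, the distance matrix is rebuilt (only
the shuffled column's additive contribution changes, which keeps each
shuffle at O(n²)), and the term's pseudo-R² recomputed. The effect size is
`delta = pseudoR2(observed) - mean_k pseudoR2(shuffled)`, with a
Monte-Carlo SE (`sd_k / sqrt(K)`) so users can judge stability; K defaults
to 1,000 (tests and the pipeline use 100–500). Shuffles are unstratified
uniform permutations — dissociating one outcome at a time is the stated
intent of the procedure; stratified variants are not implemented.

delta is a *relative* quantity: it scales with the dimensionality and
covariance of the outcome set and must not be compared across studies.
Its resolving power is also bounded by sampling noise: with group sizes
near 50–110, the sampling SE of a standardized group difference is ≈ 0.17,
commensurate with realistic effects (0.3–0.65 SD), so the identity of the
top-ranked regions is reproducible across cohort replications only for
effects well clear of that noise floor. The acceptance suite measures this
honestly under the default generator rather than assuming it away.

# Ordination and centroid geometry

dbRDA partials the covariates out of `G` (projection onto their orthogonal
complement), applies the constraint block's hat matrix on both sides and
eigen-decomposes; participant scores are eigenvectors scaled by the square
roots of the positive eigenvalues, giving at most two constrained axes for
three groups. Group centroids and per-axis standard errors (within-group
score SD / √n_g, the plot-ellipse contract; covariance ellipses are a
user-side option on the returned scores) are reported as data — plotting
style is left to the user, and no assertion in the package depends on
rendered figures.

Exact centroid separations are computed directly from `G` via indicator
contrasts, `d²(u,v) = e_u'Ge_u + e_v'Ge_v - 2e_u'Ge_v`, which uses the full
geometry including negative-eigenvalue directions — hence no
Cailliez/Lingoes correction is needed; a negative squared distance (only
possible with non-Euclidean metrics) is flagged, never silently clipped.
Whether covariates should be partialled out before ordination is genuinely
open; the default partials out the model-1 covariates, consistent with the
MDMR adjustment, and `partial = FALSE` disables it.

# The synthetic cohort: what it emulates and what it does not

`simulate_cohort()` generates the study conditions the pipeline assumes:

* cell sizes 30/18, 76/32, 70/39 (males/females in P-high, P-low,
  changers; 265 total, 89 female);
* age ~ Normal(3.2, 0.5) years, identical across groups (no baseline age
  differences were reported);
* TBV ~ Normal per group × sex with the published means/SDs (cm³); no
  between-group TBV shift is planted by default (the groups did not differ),
  though the configuration permits one;
* family income (7 brackets) and parental education (4 levels) drawn
  independently of group — so the model-2/model-3 χ² tests (df 12 and 6)
  are calibrated null tests under the defaults;
* baseline DQ and ADOS severity scores per group × sex for the descriptive
  summary.

ROI volumes are built on a standardized latent scale:
`s = rho * f + shift + noise_sd * e`, with `f` a single shared Gaussian
factor per participant inducing inter-regional structural covariance,
`shift` the planted effect, and `noise_sd = sqrt(1 - rho^2)` by default so
each latent column has unit variance. The latent score maps to mm³ as
`TBV * base_prop * (1 + roi_cv * s)`, so the normalization stage recovers
an affine image of `s` exactly and planted shifts equal the standardized
effects the post-hoc regressions estimate. Defaults: `rho = 0.6`
(inter-ROI correlation ρ² = 0.36, a moderate structural covariance chosen
once as realistic for TBV-proportioned regional volumes), `roi_cv = 0.08`
(8% coefficient of variation of a region's TBV share), per-region baseline
proportions stored in the network fixture (amygdala ≈ 0.16% of TBV up to
superior frontal ≈ 2%).

The default planted scenario places the published post-hoc magnitudes on
the published regions: left middle occipital −0.65 (changers vs P-high)
and −0.56 (P-low vs P-high); left inferior temporal +0.44 and +0.58;
both middle temporal gyri −0.35 (changers vs the others); right angular
+0.29 (female vs male). Reference levels P-high and male carry no shift.

What the generator does **not** emulate: realistic inter-regional
covariance *structure* (one shared factor, not an anatomically patterned
covariance matrix), hemispheric asymmetries, non-Gaussian volume
distributions, segmentation error, scanner or site effects, or any
dependence of income/education on group. Passing tests therefore
demonstrate that the statistics are correct and calibrated under a
faithful abstraction of the design — not that the pipeline would return
the same regions on the original MRI data.

# Post-hoc regressions and descriptives

Univariate follow-ups are OLS fits on the two-group subset (group indicator
+ age + sex), with the T-scored outcome rescaled to unit SD, so
coefficients are standardized adjusted mean differences — the scale on
which effects like −0.65 (SE 0.17) are interpretable. The descriptive
summary reports group × sex counts, mean (SD) tables, pairwise OLS
contrasts for continuous measures, a TBV group ANOVA, and Pearson χ² tests
(no continuity correction) for the ordinal covariates, with df determined
by the observed levels.

# Numerical and testing choices

* All randomness flows from explicit integer seeds; identical
  configuration and seed reproduce every stochastic output bit-identically
  (asserted at pipeline scale).
* Full-precision (17 significant digits) CSV serialization makes
  write/read round trips bit-identical.
* Hat matrices come from QR decompositions; rank deficiency is repaired by
  dropping aliased columns with a message.
* Test problem sizes were chosen to exercise the defaults at the study's
  own scale while keeping the default suite in minutes: the null
  calibration uses 500 replicates of an n = 60 cohort at B = 499 (the
  empirical type-I rate is required to sit inside the binomial 95% CI
  around 0.05, for both the group term and the sex × group interaction);
  the planted-scenario study uses 100 replicates at the full published
  sample sizes with K = 200.
* Zero-variance columns, degenerate configurations, empty design cells and
  groups too small for SEs raise explicit errors (or a warning plus a
  defined value, e.g. delta = 0 for a constant column).

# Known limitations

* Effect-size attribution is relative and noise-limited (see above); top-k
  region lists from single cohorts of this size should be treated as
  descriptive, which is also how the post-hoc step frames them.
* The Manhattan-metric pseudo-R² lacks the [0, 1] guarantee of the
  Euclidean case.
* Mixed-effects/longitudinal MDMR, kernel distances, analytic effect-size
  approximations and per-region permutation p-values are out of scope.
* The income/education covariates enter as dummy-coded categories; ordinal
  trend modelling is not implemented.
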