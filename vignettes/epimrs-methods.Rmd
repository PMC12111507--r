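---
title: "Methods: EWAS, methylation risk scores and epigenetic clocks in epimrs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: EWAS, methylation risk scores and epigenetic clocks in epimrs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epimrs)
```

`epimrs` implements the analysis chain used in small case-control
DNA-methylation studies of psychiatric phenotypes: per-CpG association of
methylation with case status, a p-value-threshold methylation risk score
built from the association weights, and linear epigenetic clocks with
their downstream correlation and regression analyses. Because cohorts of
this kind are rarely deposited, the package ships a synthetic cohort
generator with planted ground truth; every stage is validated against
what was planted rather than against irreproducible study-specific
numbers.

## Data model

The central object is a CpG-by-sample matrix of methylation fractions
("beta values", $\beta \in [0,1]$). The log-odds transform
$M = \log_2\{(\beta + a)/(1 - \beta + a)\}$ gives the variance-stabilised
M-value scale; the offset $a$ (default $10^{-6}$, configurable in
$[0, 0.01]$) keeps boundary values finite while leaving mid-range values
essentially untouched. At offset zero the transform is exactly invertible
and the package tests the round trip to $10^{-10}$.

A sample sheet carries per-sample phenotypes: `group` (case/control),
`age` in years, `sex` coded 0 = male / 1 = female, plus clinical
covariates (schooling years, global-functioning score, admission counts,
comorbidity counts, binary symptom flags).

## Preprocessing

Two filters precede association testing. The low-variability filter
removes CpGs whose across-sample SD falls below a threshold; published
pipelines report only the count removed, never the rule, so the threshold
is a parameter with default 0.01 on the beta scale — roughly the
technical noise floor of methylation arrays. The blacklist filter drops
an explicit id list (typically SNP-overlapping probes); ids absent from
the matrix are ignored with a message. Both filters are idempotent and
conserve ids (retained plus removed equals input), which the pipeline
manifest records per stage.

### Surrogate variables

Batch and other technical structure is captured by $k$ latent covariates
(default $k = 5$) estimated from the data and entered into the
association model. The estimator identifies latent *directions* as the
first $k$ principal components of the sample-space residuals after
removing the group means from every CpG, then *scores* the samples by
least-squares projection of the full row-centred data onto the implied
CpG loadings.

The second step matters. Pure residual-space PCA yields components that
are exactly orthogonal to the group indicator, so any part of the batch
structure that is incidentally correlated with group — unavoidable in
finite samples — would be left in the error term and inflate the
association scan. In simulation this inflation is substantial (genomic
inflation $\lambda$ up to 1.7 at unlucky seeds with two latent
components). Re-scoring on the full data recovers the confounded
component (the same idea that motivates two-step surrogate-variable
analysis) and restores calibration: across seeds, null cohorts give
$\lambda \in [0.96, 1.05]$ and type-I error within half a point of
nominal. The estimated surrogate variables are orthogonal, zero-mean,
unit-variance, and defined up to sign. Whether they are estimated on the
beta or M scale is a choice published methods leave unstated; the
pipeline default is the M scale, where the generator's latent structure
is exactly linear.

Covariate multicollinearity is screened with variance inflation factors,
$\mathrm{VIF}_j = 1/(1 - R_j^2)$; exact collinearity is reported as
infinite and rejected rather than silently dropped.

## The association scan

For each CpG the default model regresses methylation on group plus
covariates by ordinary least squares and reports the group coefficient:
on the beta scale this is the covariate-adjusted case-minus-control
methylation difference, the quantity that published top-hit tables print
alongside its SE and Wald $t = \hat\beta/\mathrm{SE}$. Published text
sometimes describes the model in the logistic orientation (case status as
response, CpG as predictor); both orientations are implemented, but the
reported effect sizes in the tables this package emulates (differences of
$-0.58$ to $0.31$ with SEs of $0.03$–$0.09$) are only consistent with the
methylation-as-outcome parameterisation, which is therefore the default.
The two orientations agree in sign for planted effects, which is tested.

Two-sided p-values use the Student $t$ reference with
$n - p$ degrees of freedom, where $p$ counts all fitted coefficients —
with 23 samples and 7 covariates the normal approximation would be
badly anticonservative. Constant CpG rows are flagged and skipped, never
fatal. No multiple-testing correction gates reporting (the emulated
studies report nominal significance at $10^{-5}$); Bonferroni and
Benjamini-Hochberg columns are emitted for convenience.

Calibration is summarised by the genomic inflation factor
$\lambda = \mathrm{median}\{\chi^2_1(1 - p_i)\} / 0.4549364$, by QQ
coordinates (expected quantile $(i - 0.5)/n$), and by Manhattan
coordinates with cumulative positions over chromosomes ordered 1–22 and
labels only below the significance threshold.

## Methylation risk score

CpG sets are stratified by strict p-value cutoffs (default ladder
$10^{-6}, \dots, 10^{-1}$; the sets are nested by construction). The raw
score for sample $s$ is

$$\mathrm{MRS}_s = \sum_{i \in \text{set}} M_{is} \, Z_i, \qquad
Z_i = \hat\beta_i / \mathrm{SE}_i,$$

i.e. the published formula sums *M-values* weighted by the EWAS Wald
statistic even though the association model is fitted on beta values;
the implementation follows the formula as printed, and accepts a beta
matrix for users preferring scale consistency. Scores are z-scored per
threshold with the $n-1$ SD (mean 0, SD 1 to $10^{-9}$, tested).

Score-phenotype association regresses the phenotype on the z-scored
score (logistic for two-valued phenotypes, linear otherwise, with Wald
95% intervals). At 23 samples logistic separation is likely; separated
fits are refit by Firth-penalised likelihood (Jeffreys-prior score
correction) and flagged — never reported silently. By default no
covariates enter these models, matching the forest-plot analyses this
package emulates; covariates can be added by the user.

Weights and scores are computed on the same cohort by default, exactly
as the emulated studies do; this is in-sample reuse and overfits by
construction. It is the documented default, not a recommendation — with
a replication cohort, apply the fitted weights to the new samples.

## Epigenetic clocks

A clock is an intercept plus named CpG weights applied to beta values,
optionally followed by the inverse Horvath age transform
($x < 0 \mapsto (A+1)e^x - 1$, $x \ge 0 \mapsto x(A+1) + A$, anchor age
$A$), continuous and strictly increasing. Telomere-length clocks are
handled as `units = "kilobases"` and pace-of-aging clocks as
`units = "rate"`, both with the identity transform. Published clock
coefficients are not bundled; any clock can be loaded from a small
coefficient file (`#name=`, `#intercept=`, `#transform=`, `#units=`
directives followed by `cpg,weight` records), and tests run on fixtures
generated jointly with the synthetic cohort.

Age acceleration is the residual of epigenetic on chronological age.
Clock-trait correlation uses Pearson when both variables pass a
Shapiro-Wilk screen at $\alpha = 0.05$ and Spearman otherwise (published
tables state only that "either" was used; the screen makes the choice
reproducible), recording the method per cell. Stepwise regression of
clock output on candidate predictors is bidirectional from the
intercept-only model under AIC (BIC available); the selection criterion
is unstated in the emulated studies and AIC-both is the most common
default. Retained terms are reported with
$\mathrm{CI}_{95} = \hat\beta \pm t_{0.975,\mathrm{df}}\,\mathrm{SE}$.

## Group-comparison statistics

The clinical "Table 1" machinery is implemented exactly:

* **t test from summaries** — Welch (Satterthwaite df) or pooled, computed
  directly from per-group $(n, \bar x, s)$ so printed tables can be
  re-tested without raw data. Welch is the default because it reproduces
  the published age comparison where the pooled form does not.
* **Mann-Whitney** — exact when $n_1 n_2 \le 400$ without ties, else the
  tie-corrected normal approximation without continuity correction.
* **Fisher exact (2×2)** — two-sided p by the *minimum-likelihood* rule:
  the sum of hypergeometric probabilities of all tables with the observed
  margins whose probability does not exceed the observed table's. This
  rule (and not the doubling rule) reproduces the published contingency
  p-values 0.027, 0.036, 0.155, 0.093 and 0.680 to three decimals.
* **Chi-square with Fisher fallback** — Pearson without continuity
  correction when all *expected* counts are at least 5, Fisher otherwise
  (published notes say "values < 5" without specifying observed or
  expected; expected is standard practice), with the branch reported.

One published comparison is knowingly not reproducible from its printed
summaries: the age row's p = 0.030 recomputes to 0.0295 from the rounded
means/SDs (agreement within one unit of the last printed digit); a few
other rows resist any standard test applied to their printed counts and
are not targets.

## The synthetic cohort generator

`simulate_cohort()` emulates a 12-case / 11-control cohort (configurable)
with $10^4$ CpGs by default. Beta values are built on the logit scale —
a Gaussian linear model pushed through the logistic function — which
guarantees values strictly inside $(0,1)$ without clipping and keeps the
M-value transform exact:

* per-CpG baselines from a bimodal mixture (low / mid / high
  methylation), mimicking array-wide beta distributions;
* a planted case-control difference of `effect_delta` (default 0.15 on
  the beta scale, random sign) at `n_causal` causal CpGs, encoded as
  group-specific target means so the realised group difference equals
  the planted value in expectation;
* a linear age signal on `clock_cpg_count` reserved CpGs (default 50)
  with per-CpG slopes drawn from a seed-derived stream shared with
  `simulate_clock()`, so a jointly simulated clock inverts the signal
  (age recovery $r > 0.99$ in practice against a $r > 0.9$ contract);
* `n_latent` latent batch components (default 2) with Gaussian loadings
  (SD 0.2 on the logit scale) and standard-normal sample scores;
* a small sex effect on 2% of sites;
* residual noise calibrated through the delta method so the beta-scale
  SD is `noise_sd` (default 0.05, typical inter-individual variation).

Auxiliary phenotypes are monotone in group plus noise, so score-phenotype
associations exist by construction: GAF $= 75 - 30\,[\text{case}] +
\mathcal N(0,8)$ clamped to $[1,100]$; admissions
$\sim \mathrm{Pois}(0.2 + 1.3\,[\text{case}])$; comorbidities
$1 + \mathrm{Pois}(0.8 + 0.7\,[\text{case}])$; symptom flags
$\mathrm{Bern}\{\mathrm{logit}^{-1}(-2 + 2.2\,[\text{case}])\}$; ages
uniform on 10–18 years (the recruitment window of the emulated studies),
independent of group so that planted methylation effects are not
age-confounded; schooling tracks age. All randomness flows from the
single config seed and output is bit-identical under a fixed seed.

What the generator does *not* emulate: probe chemistry and probe-type
effects, detection failures, cell-type composition, realistic genome
coordinates or CpG-island correlation structure, and age-group
confounding. Passing tests therefore demonstrate that the statistical
machinery is correct and calibrated under the stated generative model,
not that any biological conclusion transfers to real arrays.

## Numerical choices and problem sizes

Degenerate inputs are errors with informative messages (single-sample SD,
zero-variance scores with the threshold named, all-zero tables, constant
chronological age), except where a scan must survive (constant CpGs,
constant traits: flagged). Fisher's rule uses a $1 + 10^{-7}$ relative
tolerance when comparing hypergeometric masses, matching standard
practice for ties in floating point. Firth fits iterate Newton steps with
hat-value score corrections to $10^{-8}$.

The test and acceptance suites run at desk scale, chosen so the full
suite completes in well under a minute while leaving comfortable
statistical margins: null calibration on 5000 CpGs × 100 samples;
planted-effect recovery on 1000 CpGs × 200 samples with 50 causal sites;
the 12/11 default cohort at 800–10,000 CpGs for end-to-end pipeline
runs; 100–200 replicates for selection-frequency and null-association
rates. Seeds are fixed in the tests; the acceptance script takes its
seed on the command line.

## Limitations

The association scan fits one CpG at a time and models no spatial
correlation; the risk score does no pruning of correlated CpGs; the
clock machinery is linear only (no elastic-net refitting); and the
generator's independence assumptions (age independent of group, latent
scores independent of everything) are idealisations that real cohorts
violate. The in-sample MRS default overfits by construction, as noted
above.
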