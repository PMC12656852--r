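---
title: "Evaluating enteric methane prediction models: methods and conventions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating enteric methane prediction models: methods and conventions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methaneval)
```

## The problem

Empirical equations that predict enteric methane (CH₄) from intake and diet
composition are the workhorse of dairy greenhouse-gas inventories. They are
fitted on particular databases and extrapolate with unknown reliability, so
they must be re-evaluated whenever diets, breeds or intake levels drift away
from the data they were trained on. The unit of observation for such
evaluations is the *treatment mean*: the average of one dietary treatment
group reported by a source study. This package evaluates a frozen registry
of 40 published equations against any treatment-mean database and, because
such databases are rarely deposited, generates synthetic ones with a known
true mechanism.

## The metric engine

For observed emissions $y_i$ and predictions $\hat y_i$ ($i = 1..n$, in the
model's native unit):

$$\mathrm{MSPE} = \tfrac1n \sum (y_i - \hat y_i)^2, \qquad
\mathrm{RMSPE} = \sqrt{\mathrm{MSPE}}, \qquad
\mathrm{RMSPE\%} = \mathrm{RMSPE}/\bar y \times 100$$

and the decomposition into mean bias, slope bias and random error

$$\mathrm{ECT} = (\bar{\hat y} - \bar y)^2,\quad
\mathrm{ER} = (\sigma_{\hat y} - r\,\sigma_y)^2,\quad
\mathrm{ED} = (1 - r^2)\,\sigma_y^2 .$$

**Moment convention.** With population ($/n$) variances these three terms
sum to the MSPE *exactly*; with sample ($/(n-1)$) variances — the convention
in which summary SDs are usually printed — the percentages can total
slightly above 100. The package defaults to the population convention
(`convention = "population"`) so the identity holds to $10^{-9}$, and
offers `"paper_compat"` because published tables are commonly in the sample
convention (their ECT% + ER% + ED% sums of 101–103 are the signature of
mixing $/(n-1)$ moments into a $/n$ MSPE). Printed ± SDs, CCC, ν and μ are
reported in the sample convention throughout, matching how such tables are
read.

Lin's concordance correlation coefficient is computed through its accuracy
decomposition, $\nu = \sigma_y/\sigma_{\hat y}$,
$\mu = (\bar y - \bar{\hat y})/\sqrt{\sigma_y \sigma_{\hat y}}$,
$C_b = 2/(\nu + 1/\nu + \mu^2)$, $\mathrm{CCC} = r\,C_b$. The identical
value is obtained from Lin's covariance form
$2 s_{y\hat y}/(s_y^2 + s_{\hat y}^2 + (\bar y - \bar{\hat y})^2)$, which
the test suite uses as an independent oracle. Because the chain needs only
means, SDs and $r$, printed evaluation rows can be re-derived without raw
data (`ccc_from_summary()`); that is the basis of the package's
reproduction of the published 15-row summary (`published_evaluation()`).

**R² conventions.** Published evaluation tables print R² equal to $r^2$
(every row of the shipped summary satisfies this, e.g. $0.81^2 \approx
0.66$), whereas the textbook definition $1 - \mathrm{SSE}/\mathrm{SST}$ can
go negative for biased models. Both are reported (`r2`, `r2_sse`); they
coincide exactly when the predictions are the least-squares projection of
the observations, a property the suite checks by construction.

**RSR and ranking.** $\mathrm{RSR} = \mathrm{RMSPE}/\sigma_y$ (sample
$\sigma_y$) normalises the error by the spread of the observations, making
models comparable across databases; RSR < 1 beats the observed mean as a
predictor. `rank_models()` sorts ascending with ties broken by ascending
model id — the order in which the published table resolves its three-way
0.98 tie — and reports the mean RSR of the retained models.

**Degenerate inputs.** Constant predictions leave $r$, and hence CCC, ν, μ
and $r^2$, undefined; they are reported missing rather than coerced to 0.
A zero-variance pair makes the decomposition pure mean bias (ER = ED = 0,
with a message). Pearson $r$ is clamped to $[-1, 1]$ against floating-point
overshoot on perfectly concordant vectors. Display rounding is half-even to
2 decimals (R's `round()`), with full precision kept in the machine output.

## The model registry

The 40 equations live in `inst/extdata/model_registry.csv` as parsed
arithmetic expressions over the canonical variables, so the registry is
human-editable and extensible (`new_ch4_model()` builds compatible objects
for user equations). Each entry stores the published equation string for
audit. Ambiguities in the printed forms were resolved as follows:

- **Model 1** is implemented as $(75.42 + 94.28\,\mathrm{DMI}) \times
  0.05524$ MJ/d — a g/d equation converted whole. Converting only the slope
  term would leave a 75.42 MJ/d intercept, three times a cow's total
  emission.
- **Model 6** (Mitscherlich) divides the whole MJ/d form by the energy
  content of methane: $56.27(1 - e^{-0.028\,\mathrm{DMI}})/0.05565$ g/d.
- **Models 37–38**: OMD enters in g/kg (percent × 10). At the database mean
  inputs the percent reading predicts ≈148 g/d against a published
  predicted mean of 430.31 g/d; the g/kg reading predicts ≈433 g/d. The
  registry encodes this as an explicit per-model input-scale adapter
  (`omd_scale = 10`) rather than a silent coefficient change. Model 37 is
  treated analogously by construction of the same source; no printed
  predicted mean pins it, which is flagged here.
- **Models 33–34** divide EE and NDF (supplied in g/kg DM) by 10 exactly as
  printed, i.e. those terms enter as % of DM.
- **Model 36's** divisor 0.05566 is kept verbatim, not normalised to 0.05565.
- **Model 18** carries both attribution candidates (`label`, `alt_label`)
  because the source table and text disagree.

Each model is evaluated in its **native output unit** against observed CH₄
in that unit; the other unit's observation is converted
(×/÷ 0.05565 MJ g⁻¹) only when the native one is absent. RSR and RMSPE%
are unit-invariant, so mixed-unit rankings are comparable.

A soft sanity envelope (`prediction_envelope()`) flags models predicting
outside 100–700 g/d at the database-mean inputs; violations (e.g. the 1930s
Model 1 at modern intakes) are diagnostics, not errors.

## Outlier screening

Observed CH₄ (g/d, falling back to MJ/d ÷ 0.05565) is screened with the
IQR rule: flag outside $[Q_1 - 1.5\,\mathrm{IQR},\; Q_3 +
1.5\,\mathrm{IQR}]$. The quartile convention is fixed to linear
interpolation between order statistics (R's type 7) so the mask is
deterministic; the screening variable and multiplier are configurable, and
other variables can be screened per-variable. The source method does not
state which variable(s) were screened; observed CH₄ is the natural reading
of "removing an outlier" from an emission database and is the default.

## The synthetic generator

`generator_config()` transcribes the published per-variable summary table
(mean, SD, min, max, n out of 135) as marginal targets and missingness
rates ($1 - n/135$, independent Bernoulli per variable). Base variables
(BW, NDF, EE, DMI, OMI, MEI, OMD, NDFD, forage) are drawn from a latent
Gaussian copula with correlation 0.5 among the intake variables
{DMI, OMI, MEI} — a generator convention, the source reports no
cross-correlations — and mapped through range-truncated normal quantile
functions. The latent location/scale of each marginal is **moment-matched**
(Nelder-Mead on the truncated-normal moment equations) so the *truncated*
distribution hits the target mean and SD; naive truncation at the published
min/max would under-disperse the heavily range-limited variables (MEI's
target SD is within 3% of the uniform limit of its range, NDFD's plain
truncation loses 17%).

Derived variables keep the intake identities realistic without exact
collinearity:

- `ndfi = dmi × ndf/1000 × (1 + ε)`, ε ~ N(0, 0.05), then clamped to the
  dietary plausibility band NDFI/DMI ∈ [0.2, 0.5];
- `adfi = ndfi × 0.576 × (1 + ε)` with relative SD 0.21 — 0.576 is the
  target ADFI/NDFI ratio, and the ratio noise is set so ADFI's CV matches
  its target (32.4%), reflecting the real spread of ADF:NDF across diets;
- `gei = dmi × 17.07 MJ/kg × (1 + ε)` with relative SD 0.176: 17.07 is the
  ratio of the target GEI and DMI means, and the density noise is likewise
  CV-matched. (A textbook feed gross-energy density of ~18.4 MJ/kg DM would
  systematically overshoot the target GEI mean by 8%, so the
  database-consistent ratio is used and documented here.)

CH₄ is generated from a **mechanism**: a registry model as the true mean
function (default 21, the quadratic DMI equation), optional additive
NDF/EE modifiers (default 0), plus N(0, 85) g/d residual noise, and
`ch4_mj = ch4_g × 0.05565` exactly. The residual SD is calibrated so the
realized CH₄ CV is ≈22%, the spread of the emulated database. By default
CH₄ is clipped to the published [129, 510] g/d range; `clip_ch4 = FALSE`
disables this, which matters for inference checks: winsorising at ~1.5
residual SDs above the mechanism mean injects a small genuine negative
mean/slope bias, so the *exact* no-bias null — used for the slope-test
size study and the parameter-recovery checks — is the unclipped variant.

**What the generator does and does not emulate.** It reproduces marginal
locations/spreads/ranges, missingness intensity, intake-variable coupling
and a DMI-driven emission mechanism. It does *not* reproduce study-level
clustering (treatments within a study share management and cows; records
here are exchangeable), measurement-method effects, breed structure, or the
actual literature values. Passing tests therefore demonstrate correctness
of the pipeline's computations and calibration under a known mechanism, not
predictive validity of any equation on real farms. One structural
consequence: the emulated summary's two CH₄ rows (g/d, n = 117;
MJ/d, n = 134) describe different record subsets and are mutually
inconsistent (381.34 × 0.05565 ≠ 22.52), so a generator whose two CH₄
columns are exactly unit-consistent can match only the g/d targets; the
MJ/d marginal lands ≈5% low and is excluded from the marginal self-check.

**CCC under the true mechanism.** With the quadratic DMI mechanism over the
database's DMI spread, the mechanism explains ~(39 g/d)² of variance, so
calibrating the total CV to 22% forces $r \approx 0.42$ and CCC ≈ 0.3 for
the *true* model at n = 500 — an instructive reminder that CCC measures
achievable concordance, which is bounded by the noise share, not model
correctness. Recovery of the error structure is the sharper check: across
20 fixed seeds the true model shows ECT% < 2, ER% < 2, ED% > 96.

## Residual analysis

`st_pierre_fit()` regresses residuals on centered predictions; centering
makes the intercept exactly the mean residual (checked to $10^{-10}$) and
the slope exactly the observed-on-predicted slope minus one. "No
significant slope bias" is operationalised as the OLS slope t-test at
α = 0.05 (the source names no test); HC3 robust SEs are available by flag,
off by default since the classical analysis assumes homoscedasticity.
Residual fits are run per native unit, as mixed-unit pooling would be
meaningless. Under the no-bias null the slope test holds its nominal 5%
size within ±2 Monte-Carlo SEs over 1000 replicates.

## Problem sizes and determinism

Everything stochastic flows from a single integer seed
(`generator_config(seed = )`); reports are byte-identical across reruns.
The test suite uses n = 135 databases for structural checks, n = 500 × 20
seeds for parameter recovery, 1000 randomized trials for the algebraic
identities, and 1000 replicates (n ≈ 110 eligible each) for the
slope-test size study — sizes chosen to make Monte-Carlo error small
relative to the asserted margins. The full suite runs in well under two
minutes on one core.

## Known limitations

- Treatment means are treated as independent observations; no
  study-as-random-effect variant of the residual analysis is provided, and
  no meta-analytic weighting by study precision.
- No confidence intervals on CCC or RMSPE; the evaluation literature this
  mirrors reports point statistics.
- The registry is frozen: coefficients are never re-fitted to the data at
  hand.
- Re-deriving statistics from printed summary rows inherits their 2-decimal
  input rounding; re-derived CCC/μ/RSR can differ from printed values by
  one unit in the last digit, and ED% (quadratic in $r$) by up to ~1.6
  points.
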