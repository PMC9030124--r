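---
title: "Exposure score models, their calibration, and a mechanistic counterpart"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Exposure score models, their calibration, and a mechanistic counterpart}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(exposcore)
```

## The modelling problem

Occupational exposure assessment tools in the STOFFENMANAGER / Advanced
REACH Tool (ART) family estimate a worker's airborne exposure from a
structured questionnaire rather than from measurements. Each answer selects
a dimensionless *multiplier* from an exposure taxonomy — "very fine powder",
"careful handling", a ventilation category — and the multipliers combine
into a dimensionless *exposure score*. The score is then translated into a
concentration (mg m⁻³) either through an occupational exposure limit (OEL)
or through a *calibration*: a lognormal mixed-effects regression of measured
concentrations on scores, fitted on pooled field data.

`exposcore` implements this whole chain openly so that its statistical
behaviour can be studied: the score equations, the taxonomy machinery, the
calibration model, a mechanistic two-compartment mass-balance counterpart,
a synthetic-study generator that emulates how calibration data are collected
(including subjective assessor error), and an evaluation harness encoding
the validation statistics and the Dutch Social Economic Council (SEC)
acceptance criteria.

## The score equations

All scores are sums of products of non-negative multipliers; they are
dimensionless, and every function is exactly linear in each multiplier with
the others held fixed.

The simplest multiplicative model scales a measured base estimate:
$WE = BE \cdot K_1 K_2 \cdots K_n$ (`multiplicative_estimate()`).

The two-zone structured score (1996 form, `cherrie96_score()`) splits the
room into a near field (NF, the breathing zone) and far field (FF):

$$C = \varepsilon_T\, t_{a,NF}\, \eta_{ppe} +
      \varepsilon_T\, t_{a,FF}\, \eta_{ppe}\, d_{gv}, \qquad
  \varepsilon_T = \varepsilon_i h \eta_{lev} + \varepsilon_p$$

with intrinsic emission $\varepsilon_i$, handling $h$, engineering control
$\eta_{lev}$, passive emission $\varepsilon_p$, source active times
$t_a$, personal protection $\eta_{ppe}$ and a general-ventilation
multiplier $d_{gv}$. The 1999 revision (`cherrie99_score()`) moves the
passive term outside the active-time product and allows zone-specific
intrinsic emissions. The grouping of $d_{gv}$ is read as outermost on the
FF term, the way the equations are conventionally printed.

STOFFENMANAGER's score (`stoffenmanager_score()`) is

$$B = \left[(E H \eta_{lcnf} \eta_{gvnf}) + (E H \eta_{lcff} \eta_{gvff})
      + (E a)\right] \eta_{imm}\, t_h f_h$$

where one intrinsic emission $E$ and one handling multiplier $H$ are shared
by both zones (the tool assumes the worker is always in the NF and that the
same handling occurs in the FF); our scenario type makes zone-specific $E$
or $H$ unrepresentable rather than merely discouraged. ART's score
(`art_score()`) extends this with personal behavior $P$, surface
contamination $Su$ (which may be zero), dilution $D$, segregation $Seg$,
separation $Sep$, and respiratory protection $RPE$:

$$C_t = \left[(E_{nf} H_{nf} LC_{nf} P_{nf} + Su_{nf}) D_{nf} +
        (E_{ff} H_{ff} LC_{ff} Seg_{ff} + Su_{ff}) D_{ff} Sep_{ff}\right]
        RPE$$

Scenario objects accept any positive real value; conformity with the
half-decade multiplier grid is a *taxonomy* property, checked by
`validate_grid()`, not an equation property — the equations are defined for
arbitrary positive reals.

## The taxonomy

`load_taxonomy()` reads a CSV of `(model, factor, descriptor) → value`
entries, each tagged with a provenance class: `quantitative_exact`
(measured values), `quantitative_category` (physical ranges, e.g. an
application rate of 0.3–3 l min⁻¹), or `qualitative` (expert-assigned).
Qualitative multipliers conventionally live on the decimal half-decade grid
$\{10^k, 3\cdot10^k\}$ (…, 0.1, 0.3, 1, 3, 10, …). Although these steps are
often described as "natural logarithm steps", the printed values form the
decimal {1,3} grid, and that is the grid we test against, exactly, with a
1e-9 tolerance on the log10 scale. Descriptor matching is exact after
case-folding and whitespace collapse — deliberately no fuzzy matching, since
subjective interpretation of descriptors is precisely the failure mode this
package exists to study. The packaged table contains only a handful of
documented example entries and is user-extensible; reconstructing the
official taxonomies is out of scope.

```{r}
tab <- load_taxonomy(system.file("extdata", "taxonomy_quoted.csv",
                                 package = "exposcore"))
lookup_multiplier(tab, "cherrie96", "substance_emission_powder",
                  "very fine powder")
```

## Score-to-concentration translation

Two routes are provided, mirroring practice:

* **OEL translation** (`score_to_concentration_oel()`): a score of 1
  corresponds to the OEL, so concentration = score × OEL.
* **Calibration** (`fit_calibration()`): by REML,
  $\ln C = \alpha + \beta_s \ln S + b_{company}\,(+\,b_{worker}) +
  \varepsilon$, natural logs throughout. The `"sm"` mode has
  between-company and within-company variance components; the `"art"` mode
  adds a worker-within-company intercept. `predict_gm()` returns
  $\exp(\alpha + \beta_s \ln S)$; `predict_percentile()` adds
  $z_p \sigma_{total}$ on the log scale with
  $\sigma^2_{total} = \sum \text{variance components}$.

Because descriptions of the "calibration factor" are ambiguous between a
regression and a single multiplicative ratio, both modes exist: the default
estimates the slope freely; `fix_slope = TRUE` pins $\beta_s = 1$ so the
intercept is the log calibration factor.

The upper confidence bound on a percentile is computed by a seeded
parametric bootstrap (default 2000 draws): fixed effects are drawn from a
bivariate normal with the fit's covariance, and each variance component
from a scaled inverse-chi-square with effective degrees of freedom
(companies − 1 for the between-company component, records − companies for
the residual). This is a pragmatic, documented choice; the official tools'
interval procedure is not public, and a full refit bootstrap would cost two
thousand mixed-model fits per prediction for little gain at these sample
sizes. On convergence failure the fit falls back to method-of-moments
variance components (OLS fixed effects, one-way ANOVA components) and
records the fallback in `diagnostics$method`. Fits need at least 20
records; with a single company the between-company component is reported
as 0 with a warning rather than an error.

## The mechanistic counterpart

`simulate_transient()` integrates the standard two-compartment NF/FF mass
balance,

$$V_{nf}\dot C_{nf} = G' + \beta (C_{ff} - C_{nf}), \qquad
  V_{ff}\dot C_{ff} = \beta (C_{nf} - C_{ff}) - Q C_{ff},$$

with $G' = G(1-\eta_{lev})$, source in the NF and exhaust from the FF only
(the single supported topology; a rising-plume three-box variant is out of
scope). Integration uses an adaptive stiff-capable solver at relative
tolerance 1e-8; the test suite checks it against an independent
eigen-decomposition solution and against quadrature mass balance. The
closed-form steady state is $C_{ff} = G'/Q$, $C_{nf} = G'/Q + G'/\beta$
(`steady_state()`), which makes the NF increment over the room average
explicit — the physically meaningful analogue of a "dilution multiplier".

`tiered_params()` encodes the tiered-assessment convention: tier 1 takes
the exposure-maximizing end of every plausible range (min $Q$, min
$\beta$, max $G$, no local-exhaust credit), tier 2 takes central
(geometric-mean) values; monotonicity of $G'/Q + G'/\beta$ in each argument
guarantees tier 1 ≥ tier 2, which `tier_conservatism_check()` verifies on
any set of estimates.

## The synthetic study generator

`make_study()` generates calibration datasets with the statistical
structure such studies actually have, so the calibration and evaluation
machinery can be exercised with known truth:

* **Groups**: by default four exposure groups with 408, 112, 256 and 176
  records (powders and granules; comminuting; low-volatile substances;
  volatile substances).
* **Heterogeneous strata**: each group contains 3 industry strata (think
  pharmacies / bakeries / construction) assigned cyclically to 12
  companies of 3 workers. Strata differ in their intrinsic-emission grids
  and in their intercepts, which are anchored mechanistically: stratum
  $s$'s reference scenario maps onto the NF steady state of a
  stratum-specific two-compartment parameter set. This is what makes the
  "different exposure groups" pooling critique reproducible: a pooled fit
  across strata has inflated variance relative to stratum-specific fits.
* **Random effects**: between-company SD 0.5 and between-worker SD 0.3 on
  the log scale, within-worker noise as a measurement GSD of 1.5 — typical
  magnitudes for occupational datasets.
* **Assessor noise**: with probability `p_mis` (default 0.3) each
  *qualitative* multiplier is independently shifted one step up or down
  (equal probability) on the {1,3}×10ᵏ grid; quantitative multipliers are
  never perturbed. The step distribution is a modelling choice — real
  assignment-error rates are not documented anywhere, so the default is
  illustrative, chosen once and not tuned.

Scores are computed twice: from the true multipliers (truth channel) and
from the assessor-assigned ones (observed channel). Calibrations see the
observed score against the measured concentration — an errors-in-variables
situation. The classic consequences emerge rather than being programmed in:
the fitted slope attenuates below 1 (increasingly with `p_mis`), and
residuals trend negatively with the measured level — the familiar
"overestimate low exposures, underestimate high exposures" pattern.

```{r}
cfg <- study_config(group_counts = c(powders_granules = 120),
                    companies_per_group = 8, seed = 42)
st <- make_study(cfg)
fit <- suppressWarnings(fit_calibration(as.data.frame(st), mode = "sm"))
fit
```

What the generator does *not* emulate: real industry exposure magnitudes,
censored measurements below detection limits, unbalanced company sizes,
correlated multiplier errors, or taxonomy descriptors that are genuinely
ambiguous between groups. Passing tests therefore demonstrate the
statistical mechanics of score calibration, not field performance of any
real tool.

## The evaluation harness

`comparison_set()` pairs predictions with measurements;
`ratio_stats()` reports the geometric-mean ratio and the ratio range (the
"spread over N orders of magnitude" figure); `correlation_summary()`
reports Pearson and Spearman coefficients on ln-transformed pairs (the
scale validation studies report; midranks for ties; a raw-scale mode is
available and labelled); `residual_trend()` regresses the log residual on
the log measurement and flags a significantly negative slope;
`exceedance_fraction()` counts measurements above the (percentile-type)
estimate. `sec_criteria_check()` applies the Dutch SEC acceptance
criteria — at least 20 comparisons, Spearman ≥ 0.6, exceedance ≤ 10% — and
its overall verdict is exactly the conjunction of those three flags. The
"reasonable worst-case" criterion has no operational definition, so it is
surfaced only as an advisory flag tied to the exceedance criterion, never
as an independent numeric test. Whether the Spearman criterion is meant on
the log or raw scale is not specified anywhere we know of; log is the
default because that is how the validation literature reports correlations.

## Numerical and design choices

* Natural logarithms everywhere in calibration; every fit records
  `log_base = "natural"`.
* Grid membership: $|\log_{10} v - \text{nearest half-decade}| < 10^{-9}$;
  the value 3 is exactly 3.0, not $e^{1.0986}$.
* Grid steps are computed and then rounded to 12 significant digits so
  that 1 → 0.3 gives exactly 0.3, not a binary artefact.
* ODE integration: `lsoda`, rtol 1e-8, atol 1e-12; concentrations clipped
  at 0 to absorb solver noise near zero.
* Ties in Spearman: midranks (grid-valued scores tie often).
* Degenerate inputs: zero-variance channels flag correlations as
  undefined rather than erroring; constant residuals report slope exactly
  0 (pure bias is not a trend); an empty comparison set errors.
* All randomness flows from explicit seeds (`study_config(seed=)`,
  `predict_percentile(seed=)`); no function draws from an unseeded global
  stream.

Problem sizes used in the shipped test-suite experiments — e.g. 100
replicate fits of 50 companies × 10 records for coverage, 1000 random
draws for the ODE and tier-monotonicity properties — were chosen as the
smallest sizes at which the distributional claims are stable.

## Limitations

The package reproduces the *form* of the official tools' algorithms, not
their content: the full taxonomies and the calibration databases are not
public, so the packaged taxonomy holds only documented example values and
all calibration fits are to synthetic or user-supplied data. The
mechanistic module is limited to the two-compartment constant- or
piecewise-constant-source topology. None of this package's outputs should
be used for actual chemical safety assessment.
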