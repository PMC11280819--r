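---
title: "Methods: water-source quality, eutrophication, health risk and source apportionment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: water-source quality, eutrophication, health risk and source apportionment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aquarisk)
```

aquarisk chains four assessment stages that are standard in surface
drinking-water studies — a weighted water-quality index (WQI), the
logarithmic power-function universal eutrophication index (EI), USEPA-style
oral-ingestion health-risk assessment with Monte Carlo uncertainty
propagation, and geodetector source apportionment — plus a synthetic
monitoring-campaign generator used to validate all of them against known
ground truth. This vignette documents the models, their assumptions, the
tunable constants, and the design choices made where the methodological
literature leaves the details open.

## Water-quality index

For one record of the eight parameters (pH, DO, COD~Mn~, BOD~5~, NH~3~-N,
TP, TN, NO~3~-N; mg/L except pH),

$$\mathrm{WQI} = k\,\frac{\sum_i C_i P_i}{\sum_i P_i},$$

where $C_i \in [0,100]$ is a normalized score, $P_i \in [1,4]$ an integer
weight and $k$ a subjective constant (1.00 no visible pollution, 0.75
slight, 0.50 obvious, 0.25 high; default 1.00). TP and TN default to the
maximum weight 4, reflecting their elevated pollution status in the kind
of nutrient-stressed basins the package targets.

The $C_i$ scoring tables in the WQI literature are scattered across
sources and rarely printed in full, so aquarisk ships them as an
*editable, non-authoritative* YAML default (`wqi_config.yaml`): for each
parameter an ordered set of concentration breakpoints with scores, scored
by piecewise-linear interpolation (`stats::approx`) and clamped to the
extreme scores outside the table. The default anchors follow the Class
I–V limits of the Chinese surface-water standard (GB3838-2002), scoring
100 at the Class I limit down to 0 well beyond Class V. Harm-oriented
tables are non-increasing in concentration, DO non-decreasing, and pH
peaks at neutral. Class labels (`excellent`/`good`/`medium`/`poor`/
`very_poor`) are ordered lower bounds; a WQI exactly on a boundary takes
the *better* class — a documented tie-break, applied consistently.
Because both the score tables and the class bands are non-authoritative
defaults, the distribution of class labels on any dataset should be read
relative to this scheme, not compared across schemes.

Exceedance summaries compare each parameter against a configurable
standard limit (default: Class III, the regulatory floor for centralized
drinking-water sources), respecting orientation (DO is a floor, the rest
are ceilings), and report the mean, sample SD and coefficient of
variation (SD/mean, `NA` for a zero mean).

## Eutrophication index

Seven indicators (DO, TP, TN, COD~Mn~, BOD~5~, NH~3~-N, NO~3~-N) enter

$$EI_j = 10.77\,(\ln x_j)^{1.1826}, \qquad EI = \sum_j W_j\,EI_j,$$

with equal weights $W_j = 1/n$ by default (overridable; weights are
renormalized to sum to 1). The exact normalization $x_j$ behind this
index family is published only by reference, so aquarisk uses a
transparent ratio-to-reference transform: for harm-oriented indicators
$x_j = \mathrm{clamp}\big((C_j/C_{j0})\,x_{\max},\,1,\,x_{\max}\big)$,
with the ratio inverted for DO. $C_{j0}$ is the "extremely poor"
(severely eutrophic) anchor at which $x_j$ saturates; $x_{\max} =
721.9288$ is chosen so that $EI_j$ spans exactly 0–100
($10.77(\ln x_{\max})^{1.1826} = 100$). The shipped $C_{j0}$ anchors are
non-authoritative defaults at severely eutrophic magnitudes (e.g. DO
0.2 mg/L, TP 2.0 mg/L, TN 20 mg/L).

Properties guaranteed by construction and verified by tests: $EI_j(1)=0$,
$EI_j(e)=10.77$, strict monotonicity in $x_j$; the composite with equal
weights is the arithmetic mean of the $EI_j$; EI is non-decreasing in
every harm-oriented concentration and non-increasing in DO.

Grades are ordered EI bands (1 oligotrophic … 6 severely eutrophic). Only
the grade-2/3 (mesotrophic/eutrophic) boundary, 39.42, is anchored to the
assessment convention in common use; other boundaries are defaults. An EI
exactly on a boundary takes the *higher* (more eutrophic) grade — the
conservative direction for a protection-oriented assessment. Each site is
classified once, on the arithmetic mean of its seasonal indicator
concentrations; the season-aggregation step is an open choice in the
literature and the mean is the least informative-assumption option given
that seasonal differences in these indices are typically slight.

## Health-risk assessment

Oral ingestion is the dominant exposure route for drinking water, and the
only one modelled. For each metal (As, Hg, Cd, Cr⁶⁺, Pb) and population
(adult, child):

$$\mathrm{ADD} = \frac{C \cdot IR \cdot EF \cdot ED}{BW \cdot AT},
\qquad \mathrm{CR} = \mathrm{ADD}\times SF,
\qquad \mathrm{HQ} = \mathrm{ADD}/RfD,$$

with C the concentration (mg/L), IR the intake rate (L/d), EF the
exposure frequency (d/a), ED the exposure duration (a), BW body weight
(kg) and AT the averaging time (d). CR below 10⁻⁶ is a low cancer risk,
10⁻⁶–10⁻⁴ a potential risk (both bounds inclusive), above 10⁻⁴ high;
HQ ≤ 1 is acceptable. By the standard USEPA convention (the default
`at_rule: derived`), AT is ED×365 for noncarcinogenic risk and a 70-year
lifetime for carcinogenic risk; an explicit AT distribution can be
configured instead. Hg has no oral slope factor, so no CR is computed for
it — rankings therefore cover four metals for CR and five for HQ.

The Monte Carlo layer draws `n_iter` (default 10,000) independent
realizations of (C, IR, EF, ED, BW) per metal and population from
configurable distributions (`point`, `normal`, `lognormal`, `triangular`,
`uniform`, each with optional truncation applied by inverse-CDF
conditioning, so truncation never changes the draw count or breaks
reproducibility). Exposure factors are sampled independently — no
correlation structure is assumed. Concentration distributions are
typically fitted from the measurement table by `fit_concentration()`,
a closed-form maximum-likelihood lognormal (the HRA convention, and it
guarantees positive draws); a constant series degrades gracefully to a
point mass. Summaries report the mean, standard error of the mean,
percentiles, the exceedance fractions P(CR > 10⁻⁶), P(CR > 10⁻⁴),
P(HQ > 1), and empirical cumulative-frequency curves.

Two reproducibility choices matter. First, every metal–population cell
has its own child random stream, derived from the global seed, the metal
name and a canonical string of the population's exposure specs — *not*
the population label — so that exchanging the adult and child spec sets
exchanges their results exactly, and divergence between populations is
purely a function of the specs. Second, with all specs degenerate
(point masses) the Monte Carlo layer reproduces the deterministic
equations to machine precision, which the tests assert.

The shipped exposure distributions and SF/RfD values follow standard
USEPA oral-ingestion practice but the exact values used in any given
study are often behind inaccessible appendices; both YAML files are
marked non-authoritative and meant to be replaced when auditing a
specific assessment.

## Geodetector

The factor detector quantifies spatial stratified heterogeneity:

$$q = 1 - \frac{\sum_{h=1}^{L} N_h \sigma_h^2}{N \sigma^2},$$

with *population* (divide-by-count) variances — under that convention
$q$ is exactly the between-strata share of the total sum of squares
(SSB/SST) and lies in $[0,1]$ whenever the total variance is positive.
Zero total variance is an explicit error ("undefined q"), not a silent
zero. Singleton strata are legal (their within-variance is zero) but are
counted and surfaced in results as a data-quality signal, since they
mechanically inflate q.

Continuous covariates must be discretized; the method and class count are
almost never stated in applied work, so both are configuration
(`geodetector.yaml`), defaulting to **natural breaks with 5 classes** —
the dominant convention in geodetector applications. The natural-breaks
implementation is the exact dynamic-programming optimum (minimal
within-class sum of squared deviations), verified in tests against
brute-force enumeration of all partitions; quantile, equal-interval and
geometric-interval methods are also provided. Discretization refuses
fewer distinct values than classes.

The interaction detector forms the intersection stratification (distinct
label pairs), computes $q_{12}$, and classifies against $q_1$, $q_2$ with
a small tolerance (default 10⁻⁹): independence means
$|q_{12}-(q_1+q_2)| \le$ tol; above $q_1+q_2$ is nonlinear enhancement;
above $\max(q_1,q_2)+$tol bivariable enhancement; the remaining cases are
univariable or nonlinear weakening. Under population variances a
refinement can never explain less, so $q_{12} \ge \max(q_1,q_2)$ up to
rounding and the weakening categories are reachable only through the
tolerance — they are implemented and tested nonetheless, because the
five-category scheme is the fixed vocabulary of the method. The response
variable for screening is the per-site season mean, consistent with the
trophic aggregation.

## Source grouping

`correlation_matrix()` is a Spearman rank matrix (average-rank ties;
constant columns give `NA`). Spearman is used throughout the package for
consistency — monitoring concentrations are skewed and the rank version
is the safer default when the correlation type is otherwise unspecified.
`pca_rotated()` takes principal components of the (by default Spearman)
correlation matrix of standardized variables, applies varimax — the
standard choice wherever an unnamed "orthogonal rotation" is called for —
re-computes explained variance after rotation as each component's sum of
squared loadings over the variable count, orders components by it, and
fixes signs so each component's dominant loading is positive. Varimax
preserves the retained subspace's total variance (asserted to 10⁻⁸), and
with full rank the unrotated shares sum to exactly 100 %.

## The synthetic campaign

`generate_dataset()` emulates a monitoring campaign of 59 sites sampled
in three seasons (wet, dry, normal) — 177 records — over a rectangular
extent, with nine per-site covariates: DEM, NDVI, Precipitation,
Temperature, Soil Type, Land Use, Road Network Density, GDP and
Population Density. Continuous covariates are a latitude gradient plus
Gaussian noise (the defaults emulate terrain that is higher, wetter and
greener in the south while road density, GDP and population rise
northwards); categorical covariates are jittered latitude bands, so
strata are spatially coherent.

Measurements are lognormal around a site-level mean (additive normal for
pH), strictly positive by construction. A *planted effect* replaces a
parameter's baseline mean with per-stratum means of a covariate
(categorical levels, or quantile classes Q1..Qk of a continuous
covariate). The explanatory power such an effect induces is known in
closed form — `expected_q()` evaluates
$q^\* = B/(B+W)$ from the size-weighted population variance of the
stratum means ($B$) and the size-weighted within-stratum noise variance
($W$), using the exact lognormal moments
($\mu_h = m_h e^{s^2/2}$, $v_h = m_h^2 e^{s^2}(e^{s^2}-1)$) or the
normal ones ($m_h$, $s^2$). This is what makes the geodetector stage
testable: the suite plants $q^\* \in \{0.2, 0.5, 0.8\}$ on 200-site
campaigns and requires recovery within ±0.05 in at least 95 of 100 seeds.

Defaults were chosen once to be realistic for lightly polluted source
water in a nutrient-stressed agricultural basin: an overall EI near the
mesotrophic/eutrophic boundary with a mesotrophic majority, TN exceeding
the Class III limit in roughly 2–3 % of records and TP well under 1 %,
high-CV (>90 %) Cr⁶⁺ and Pb, and factor→response links that mirror
commonly reported drivers (As and Pb tied to Precipitation, Cr⁶⁺ to DEM,
Cd, Hg and TP to GDP, TN to Precipitation).

Seasons are independent draws around the same site mean with a
configurable multiplicative offset, defaulting to none — seasonal
differences in the indices this package computes are typically slight,
and a seasonal model would add parameters the validation does not need.

Each generator salts the user's seed with its own stage label before
seeding the RNG. This matters: feeding the *same* seed to the covariate
and measurement generators would otherwise overlap their random streams
and induce spurious covariate–noise correlation (discovered as an
inflated planted q during development). With salting, one global seed
yields three mutually independent streams, and the pipeline derives all
per-stage seeds from a single `seed` by the same rule, so disabling one
stage never changes another stage's output.

**What the generator does not emulate:** spatial autocorrelation beyond
the latitude gradient (no kriging fields or hydrological routing),
correlated multi-metal sources beyond one driving factor per parameter
(so, e.g., metal groupings in the PCA reflect shared *drivers*, not a
full mixing model), seasonal dynamics, censoring at detection limits, and
measurement error structure. Passing tests on synthetic data therefore
demonstrates correctness of the statistical machinery under the stated
model, not robustness to every feature of real campaigns.

## Pipeline and numerical conventions

`run_pipeline()` executes simulate → wqi → ei → hra → geodetect →
associate from a single `run_config()`, writes each stage's CSVs and a
`report.json` of headline quantities (class counts, grade shares,
exceedance fractions, top-3 factors and interactions per response), logs
stage timings to stderr, and on a stage failure removes that stage's
partial outputs and aborts naming the stage. Output file names in the
report are outdir-relative, so two runs with the same seed produce
byte-identical bundles wherever they are written — the determinism the
tests assert.

Conventions collected in one place: WQI class boundary ties go to the
better class, trophic boundary ties to the worse grade; CR band edges are
inclusive (10⁻⁶ and 10⁻⁴ are both "potential"); risk rankings break mean
ties alphabetically; undefined quantities (CV at zero mean, Spearman on a
constant series, CR without a slope factor, q at zero variance) are `NA`
or explicit errors, never silent zeros; interaction classification uses
an absolute tolerance of 10⁻⁹.

Problem sizes used by the test suite (chosen as comfortably informative
at interactive speeds): 1,000 random instances for the q-oracle and
refinement checks, 100 seeds × 200 sites × 3 planted-q levels, 10,000
Monte Carlo iterations × 5 metals × 2 populations for the closed-form and
lognormal-tail checks, and two full 59-site pipeline runs for the
determinism check.

## Known limitations

The non-authoritative YAML defaults are the main caveat: WQI scoring
tables, EI anchors and grade bands (other than 39.42), and SF/RfD and
exposure distributions all shape absolute output values, so comparisons
against any published assessment require substituting that assessment's
tables. The geodetector stage inherits the usual sensitivities of the
method — q depends on the discretization method and class count, and
singleton strata inflate it. Exposure factors are sampled independently;
correlated exposure (e.g. IR with BW) is not modelled. No q significance
testing is provided, and no spatial interpolation or mapping.
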