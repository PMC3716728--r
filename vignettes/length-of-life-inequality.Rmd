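---
title: "Modeling length-of-life inequality with relational life tables"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling length-of-life inequality with relational life tables}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lifeineq)
```

## The problem

In countries without usable vital registration, mortality is known only
through summary rates: under-five mortality (5q0) stratified by wealth
quintile, gender or residence from household surveys, and adult mortality
(45q15) available nationally from modeled sources. `lifeineq` turns those
two numbers per group into a full abridged life table via a relational
model life table system, and from the implied distribution of age at death
computes *within-group* inequality — the Gini health index and absolute
length-of-life inequality (ALI) — alongside the usual *between-group*
measures: the concentration index (CI) and the absolute difference in life
expectancy between the extreme groups. Comparing the two answers a
substantive question: how much of a population's lifespan inequality do
socioeconomic group differences actually account for?

## The relational model

The Brass logit system expresses any survivorship curve $l(x)$ as a linear
function, on the logit scale, of a single standard curve $l_s(x)$:

$$Y(x) = \alpha + \beta\, Y_s(x), \qquad
  Y(x) = \tfrac{1}{2}\log\frac{1 - l(x)}{l(x)}.$$

$\alpha$ shifts the overall mortality level (positive $\alpha$ = higher
mortality) and $\beta$ tilts the balance between child and adult mortality;
$(\alpha,\beta)=(0,1)$ reproduces the standard exactly. The modified-logit
extension adds age-specific correction terms

$$Y(x) = \alpha + \beta\, Y_s(x) + \gamma_x\, c_5 + \theta_x\, c_{60},$$

where $c_5$ and $c_{60}$ are the fitted curve's logit deviations from the
standard at ages 5 and 60 under the uncorrected relation, and the
coefficient vectors $\gamma, \theta$ vanish at those two anchor ages so
they are always reproduced exactly. The published coefficient values of
the WHO system are not distributed with this package: the default is
$\gamma = \theta = 0$ (plain Brass), and any coefficient set can be
supplied through `standard_schedule()` or a standard CSV. This keeps the
framework exact while leaving the uncheckable constants external; results
are always labelled with the standard and correction status used.

### Fitting

`fit_brass_params()` matches a target pair $(5q_0,\ {}_{45}q_{15})$. For
any $\beta$, the age-5 anchor gives $\alpha$ in closed form,
$\alpha = Y_{\text{target}}(5) - \beta Y_s(5)$ (valid with corrections
active too, because they vanish at the anchors). $\beta$ is then the root
of the 45q15 residual, found with `stats::uniroot` on a bracket that starts
at $[0.3, 3]$ and expands geometrically to at most $[0.05, 10]$; endpoints
where a corrected curve leaves its domain are treated as unusable rather
than fatal, so aggressive correction vectors cannot crash the bracketing.
Default tolerance is $10^{-8}$ on both target probabilities. A target pair
that no $\beta$ in the bracket can reconcile (e.g. very high child
mortality with near-zero adult mortality) raises an error reporting the
bracket and residual signs — it is not silently clipped.

### The default standard

No empirical standard is bundled. `builtin_standard()` generates a fully
synthetic one (`siler-synthetic-v1`) from a Siler hazard — exponentially
decaying infant mortality, constant background, Gompertz senescence:

$$\mu(x) = a_1 e^{-b_1 x} + c + a_3 e^{b_3 x},$$

with $a_1 = 0.12$, $b_1 = 1.2$, $c = 0.0018$, $a_3 = 5\times10^{-5}$,
$b_3 = 0.105$. Survivorship is the exact closed-form integral of this
hazard on the abridged grid. The parameters were chosen once to give a
high-mortality shape plausible for a poor, largely rural Sub-Saharan
population around 2010 — $e_0 \approx 57$ years, $5q_0 \approx 0.10$,
${}_{45}q_{15} \approx 0.29$ — so that fitted $(\alpha,\beta)$ values for
realistic targets stay near $(0,1)$, where the relational model is most
trustworthy.

## Life-table conventions

The default grid is 0, 1–4, then five-year bands to the open interval 85+
(19 intervals); any grid with the anchor ages 5, 15 and 60 works. The
radix is 1 internally; deaths per 1000 appear only in exports.

Separation factors (`ax`) are a stated convention, because published
third-decimal Gini values are sensitive to them while typical inputs
cannot adjudicate between reasonable choices:

* infant interval: $a_0 = 0.07 + 1.7\, m_0$, iterated to consistency with
  $m_0$ and capped to $[0.01, 1]$;
* ages 1–4: $1.361$ years;
* other closed intervals: half the width;
* open interval: $1/m_{85+}$, with $m_{85+}$ continued log-linearly from
  the central death rates of the last two closed intervals. Defining the
  open interval this way makes the identity
  $\sum_t f_t h_t = e_0$ — the death distribution's mean equals life
  expectancy at birth — hold to machine precision for *any* input, which
  the test suite asserts at $10^{-9}$.

The rule object is swappable (`ax_rule("midpoint")`, or an explicit numeric
vector), and every report records which rule produced it. After
survivorship reaches zero, remaining `qx` are set to 1; no division by
zero occurs.

## Estimating group adult mortality

Surveys stratify under-five mortality but not adult mortality. The
estimator scales the national rate by each group's under-five mortality
ratio $U5_i$ (relative to the best-off reference group) and a correction
factor

$$x = \frac{1}{\sum_i U5_i\, p_i}, \qquad
  {}_{45}q_{15}^{(i)} = {}_{45}q_{15}^{\text{nat}} \times U5_i \times x,$$

where $p_i$ are population shares. Because $x$ normalizes the
share-weighted ratios to mean 1, the group estimates preserve the national
rate on average: $\sum_i p_i\, {}_{45}q_{15}^{(i)} =
{}_{45}q_{15}^{\text{nat}}$ exactly, which the tests assert for random
group sets. The estimator deliberately imports only the *tendency* of the
under-five gradient into adult ages; where the true adult gradient is
flatter or steeper than the child gradient, group life expectancies are
correspondingly compressed or stretched (the synthetic recovery experiment
with the estimator active shows exactly this). A unique $x$ is computed
per grouping and period. Male and female schedules are combined on the
central-death-rate scale with a constant male population share
(`combine_sexes()`); an age-varying share can be passed by combining
per-age slices directly.

## Inequality measures

With $f_t$ the proportion of deaths in age interval $t$, $h_t$ the mean
age at death in it ($h_t = x_t + a_{x_t}$), $\mu = \sum_t f_t h_t$ (equal
to $e_0$), and $R_t$ the midpoint fractional rank after ordering intervals
from early to late death, the Gini health index in Wagstaff's general form
is

$$\mathrm{Gini}_H = 1 - \frac{v}{\mu} \sum_t f_t\, h_t\, (1 - R_t)^{v-1},$$

with inequality aversion $v = 2$ by default (the standard Gini). At
$v = 2$ it equals the half relative mean absolute pairwise difference,
which the tests verify against a brute-force double sum at $10^{-10}$ over
hundreds of random distributions. Consequences used throughout:
$\mathrm{Gini}_H$ is scale-invariant, population-replication-invariant,
tie-invariant at $v=2$, and zero iff everyone dies at the same age.

$$\mathrm{ALI} = 2 \times LE \times \mathrm{Gini}_H$$

is the expected absolute lifespan difference between two randomly drawn
individuals (in years), exactly the mean pairwise absolute difference at
$v = 2$. It is directly comparable with between-group gaps in $LE$.

The concentration index uses the same midpoint-rank convention, but ranked
by *socioeconomic position* (an explicit input, never inferred from
outcomes; 1 = worst-off):

$$CI = \frac{2}{\mu} \sum_t f_t\, h_t\, R_t - 1,$$

algebraically twice the area between the concentration curve and the line
of equality, which the tests confirm against a trapezoidal area
computation at $10^{-10}$. Reversing the ranking flips the sign. The
absolute difference is the signed $LE$ gap between the highest- and
lowest-ranked groups.

Reported tables round to the conventional precision (years at 1 decimal,
Gini at 2, CI at 3); machine outputs keep full precision.

## The synthetic generator

`generate_scenario()` creates $K$ ordered groups by applying a monotone
$\alpha$ gradient (shared $\beta$) to the standard, so the ground truth —
tables, $e_0$, $5q_0$, ${}_{45}q_{15}$, $\mathrm{Gini}_H$ — is known
exactly. The observables mimic the survey situation: per-group $5q_0$
(exact, or binomial death counts from a cohort of configurable size) and a
single national ${}_{45}q_{15}$ formed as the share-weighted mean of group
truths. The default scenario is five equal-share quintiles calibrated once
so true $e_0$ runs 53.4–62.5 years (a spread of ~9 years), the scale
observed across wealth quintiles in the motivating setting; the gradient
$\alpha = (0.150, 0.059, -0.033, -0.125, -0.216)$, $\beta = 1$ is frozen
in `scenario_config()`.

What the generator does *not* emulate — and hence what passing recovery
tests do not establish about real data: survey design (clusters, weights,
household structure), HIV-specific age patterns of adult mortality,
recall and heaping errors in birth histories, and any discrepancy between
the true population's age pattern and the chosen standard. Noise enters
only through binomial sampling of under-five deaths, mirroring the fact
that group adult mortality is never observed at all.

`recovery_experiment()` closes the loop: with the estimator bypassed (true
group ${}_{45}q_{15}$ supplied) the pipeline recovers $e_0$ to better than
0.05 years and $\mathrm{Gini}_H$ to better than 0.005 per group on the
noise-free default scenario; with the estimator active the residual error
is dominated by the estimator's proportionality assumption, not by the
fit.

## National totals

The national row is computed by pooling the share-weighted group death
distributions (default). Each pooled interval's mean age at death is the
deaths-weighted mean of the group values, so the pooled mean equals the
share-weighted mean of group life expectancies exactly (asserted at
$10^{-9}$); no inequality ordering between the pooled Gini and the mean of
group Ginis is asserted, since none holds in general. A `refit` mode —
fitting the relational model directly to national $(5q_0, {}_{45}q_{15})$
— is provided as well, since either reading of a "total" row is
defensible; the report's metadata records which was used.

## Validation scale and numerical choices

The test-suite problem sizes are chosen for thorough desk-scale checking:
200 random discrete distributions for the Gini oracle and 200 ranked-group
sets for the CI area oracle (both at $10^{-10}$), 100 random
$(\alpha,\beta)$ draws for parameter recovery (max error below $10^{-5}$),
and full-pipeline recovery on the 5-group default scenario. Fit tolerance
is $10^{-8}$ on probabilities with at most 200 root iterations; life-table
identities are asserted at $10^{-9}$–$10^{-12}$. Degenerate inputs are
defined, not special-cased: $q_0 = 1$ gives $e_0 = a_0$, zero-survivor
tails absorb with $q_x = 1$, and a single group yields a within-group
report with no between-group block.

## Known limitations

* Published third-decimal $\mathrm{Gini}_H$ values from other
  implementations are not exactly reproducible here: they depend on the
  (unpublished) standard, its correction coefficients, and unrounded
  intermediate life expectancies. Within/between *patterns* and the
  between-group indices computed from published life expectancies are
  reproducible, and are what the acceptance checks target.
* The adult-mortality estimator transfers the under-five gradient to adult
  ages up to a single normalization; it is a tendency estimate, not a
  measurement.
* Abridged (grouped-age) tables only; no smoothing of raw rates, no
  cohort tables, no HIV-specific corrections, no decomposition of the CI.
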