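---
title: "Watershed nutrient balances and river-load trend attribution: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Watershed nutrient balances and river-load trend attribution: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nutrientlag)
```

## Scope and data model

The pipeline answers one question: when annual river nutrient loads stop
tracking the watershed's annual nutrient balance, how much of the load
trend is attributable to lagged (legacy) balances and how much to latent
watershed processes that no input dataset measures? Everything operates on
`annual_series` objects — one value per calendar year, in
kg km<sup>-2</sup> yr<sup>-1</sup> unless noted — because at the scale of
a large basin the analysis-ready inputs genuinely are two annual tables
per nutrient: a balance-component ledger and a flow-normalized (FN) river
load series. Upstream machinery (daily load estimation, flow
normalization, GIS aggregation of point sources) is deliberately out of
scope; its outputs are this package's inputs.

## The mass balance

`compute_balance()` implements inputs-minus-outputs per year. Nitrogen
inputs are fertilizer, manure, wastewater effluent, biological fixation,
and *oxidized* atmospheric deposition; reduced (ammonia/organic)
deposition is excluded on the assumption that it is recycled
fertilizer/manure volatilization redeposited locally within the year — a
table may carry the reduced column, but it is never summed. Nitrogen
outputs are crop harvest, agricultural N<sub>2</sub>O (1% of fertilizer +
manure N), complete denitrification N<sub>2</sub> (1.7 x the
N<sub>2</sub>O flux), and a constant riverine surface emission of
114 kg km<sup>-2</sup>. Phosphorus has no gaseous pathway: inputs are
fertilizer, manure, wastewater, and a constant weathering supply of
7.16 kg km<sup>-2</sup> yr<sup>-1</sup>; the only output is harvest.

Choices worth making explicit:

* **Riverine N emission.** The literature supports both a constant and a
  "19% of N delivered to rivers" rate. The rate definition is circular in
  an annual accounting (delivery itself depends on the emission), so the
  constant is the default and `river_emission_rate = 0.19` applies the
  rate to net-of-land-outputs delivery for sensitivity runs.
* **Negative balances** (outputs exceeding inputs) are scientifically
  meaningful deficiencies, so they are allowed and only reported via a
  message.
* **Crop terms.** Uptake is yield x nutrient content summed over crops,
  with content factors constant across years; N fixation is defined as
  the harvest-N of the N-fixing crops, which makes fixation and its
  removal self-canceling for those crops — an intended property of that
  estimation rule, not a bug.
* The components are validated as nonnegative, gap-free, and
  nutrient-consistent at construction (`balance_components()`), so the
  balance arithmetic itself never needs defensive code.

## Trend description

`theil_sen()` is the exact median of all pairwise slopes (even pair counts
take the mean of the central pair), with the intercept as
`median(value - slope * year)`; it is checked against a brute-force
enumeration in the tests. `loess_smooth()` wraps `stats::loess` with span
0.75 and local quadratics — the conventional defaults, since nothing in
the problem dictates others — evaluated at the observed years.
`percent_change()` is the signed two-endpoint change used in decadal
summary tables.

`bootstrap_trend_likelihood()` supplies a likelihood statistic for a trend
direction by resampling (year, value) pairs with replacement and reporting
the fraction of resampled Theil-Sen slopes that share the observed
slope's sign. Because the bootstrap distribution recenters on the
*observed* slope, this statistic's null expectation is
E[&Phi;(|Z|)] = 0.75, not 0.5; it is a strength-of-evidence score that
saturates toward 1 for real trends, and the test suite verifies both
behaviors by simulation. The category thresholds ("likely" above 0.85,
"somewhat likely" in [0.70, 0.85], "as likely as not" below 0.70) are
applied with intervals closed on the lower side, so 0.85 and 0.70 both
classify as "somewhat likely"; the published interval endpoints overlap
and a convention had to be fixed.

## Retention and stoichiometry

Retention is `(1 - load/balance) * 100` on shared years. Years with zero
or negative balance yield `NA` with a warning — the ratio is undefined or
uninterpretable there, and propagating a fake number would poison the
Theil-Sen retention trends downstream. The operation does not care which
load estimate (flow-normalized or Kalman-filter) is supplied; published
practice differs between the two for retention versus regression, so the
caller chooses. `molar_ratio()` defaults to the true P atomic weight
30.974 g mol<sup>-1</sup>; some published conversions round P to 32, and
`m_p = 32` reproduces them literally.

## The lag-attribution regression

The load model is

$$\text{load}(t) = \beta_0 + \sum_k \beta_k\,\text{balance}(t-k)
  + \sum_{d=1}^{3} \gamma_d\,\tau(t)^d + \varepsilon(t),
  \qquad \tau = \text{year} - 1975 .$$

**Pre-whitening.** Only the load series is pre-whitened before
lag-correlation screening: an AR(1) coefficient is estimated as the lag-1
autocorrelation (Yule-Walker) and the working series becomes
`y(t) - phi * y(t-1)`. Balances enter the screen raw. Both choices follow
the published procedure as stated; whether the original analysis also
whitened the balances is unknowable from the text, and whitening one
series already removes the shared serial persistence that inflates
spurious lag correlations.

**Screening.** For each lag 0-25 (25 is the hard cap: a 1950 balance
start and 1975 load start leave exactly 25 usable lags), the Pearson
correlation between the whitened loads and the lagged balance is tested.
Nitrogen uses *positive and significant* (two-sided p < 0.05); phosphorus
uses *positive only*. The type-I behavior of the significant-positive rule
(each lag admitted at about &alpha;/2 under independence) is verified by
simulation in the test suite.

**Selection.** `best_subset_bic()` enumerates every subset of the
screened lags plus year polynomial terms up to `max_terms = 8` (above the
largest published model, but bounding the search), fits each by OLS, and
minimizes `BIC = n ln(RSS/n) + (k+1) ln(n)`. The enumeration runs in
compiled code: the intercept is absorbed by centering, and each subset
costs one small Cholesky solve of the centered Gram submatrix, which keeps
tens of millions of candidate subsets tractable — this matters because the
loose positive-only phosphorus screen routinely admits most of the 26
lags. Correctness is pinned by a test that compares the compiled search
against an independent QR-based enumerator on random designs. Year
polynomials are hierarchical by default (&tau;&sup2; only with &tau;,
&tau;&sup3; only with &tau;&sup2;), matching how such models are reported;
`enforce_year_hierarchy = FALSE` gives the unrestricted search. Numerical
choices: BIC ties within 1e-9 resolve to fewer terms, then lexicographic
column order; subsets whose centered Gram matrix is not positive definite
relative to its diagonal (rank-deficient, e.g. a constant column) are
skipped and counted. Diagnostics come from a final `stats::lm` refit:
standard errors, two-sided t p-values (n-k-1 df), standardized
coefficients `b_j sd(x_j)/sd(y)`, and VIFs from regressing each selected
term on the others.

**Year indexing.** `tau = year - 1975` (first load year) by default and
configurable. The intercept and year-term coefficients are only
identified up to this centering convention; predictions and
counterfactual deltas are invariant to it, which is why they, not the
year coefficients, are the quantities to compare across analyses.

## Counterfactuals

Scenario A freezes the balance story: every selected `lag k` column is
held at its 1975 value — which is the balance of calendar year `1975 - k`
— for all prediction years. Scenario B freezes the latent story: each
year term is held at `tau(1975)^d`. "Held constant at 1975 levels" is
interpreted per regressor; the alternative reading (all lag columns set to
the *1975 balance itself*) is available via `freeze_mode = "common"`. The
per-regressor reading preserves each regressor's own baseline value and
makes the degenerate identities exact: a model with no year terms is
unchanged by B, a model fitted on constant balances is unchanged by A, and
both identities are tested to machine precision. Impacts are window means
(default 2013-2017) compared as absolute and percent differences against
the original-design predictions.

## The synthetic watershed

`generate_components()` builds component tables from smooth trends plus
stationary AR(1) noise truncated at zero (components are physically
nonnegative), and `generate_loads()` evaluates the structural model above
with i.i.d. Gaussian noise, persisting the full ground truth
(`synthetic_truth`, also serialized as a flat key-value file) so recovery
tests read rather than re-derive it.

The defaults emulate a mid-century agricultural intensification: logistic
ramps that mostly complete by 1980 (strong balance growth to the
mid-1980s, near-plateau after — the regime in which lag attribution is
actually interesting), levels chosen so the nitrogen balance averages
about 1.3e3 and phosphorus about 3.3e2 kg km<sup>-2</sup> yr<sup>-1</sup>
over 1950-2017, magnitudes typical of a large grain-belt basin. Noise is
component-specific: harvest-driven terms (crop uptake, fixation) get
weakly persistent weather-scale variability (CV 10-15%, &phi; &asymp;
0.2, the size of real interannual yield swings), economic inputs
(fertilizer, manure) get smaller but more persistent variability (CV
3-4%, &phi; 0.7-0.8). This structure is what makes the inverse problem
well-posed: the trend component of the balance is nearly identical across
lags, and it is the weather-scale noise that lets neighboring lags be
distinguished. The default truth plants lags {2: 0.25, 9: 0.35} — a total
lag transfer of 0.6, with the longer lag weighted higher — plus a
quadratic latent term for nitrogen and a small cubic latent term for
phosphorus, and `calibrate_noise_sd()` sets the load noise so the
structural signal explains a target share (default 80%) of the load
variance.

What the generator does *not* emulate: the balance components are
mutually independent given their trends (real fertilizer and yield
co-vary with prices and weather), load noise is homoscedastic and
serially independent (FN load errors are autocorrelated by construction),
there are no censuses-driven step artifacts, and the latent process truly
is a low-order polynomial. Passing recovery tests therefore demonstrate
that the estimation machinery is correct and well-calibrated under the
model's own assumptions — not that a 43-year record can always separate
collinear lags in real data, where screens and selections should be read
with the same caution as any observational regression.

## Problem sizes and runtime choices

The shipped tests run the recovery study at the analysis scale itself
(n = 43 load years, 100 replicates), the screen type-I simulation at 1000
replicates, and the selector cross-validation on designs up to 12
candidate columns, which keeps the default suite under a minute of
compute for the heavy blocks while still exercising every contract at
full problem size. The compiled enumerator makes the full
26-lag phosphorus search a sub-second operation, so no approximation
(stepwise, branch-and-bound pruning) is used anywhere.

## Known limitations

* Best-subset + BIC is consistent but greedy-free, not inference-safe:
  post-selection standard errors and p-values are reported as OLS
  computes them, without selection adjustment — as is conventional for
  this analysis style.
* OLS standard errors assume uncorrelated homoscedastic residuals;
  autocorrelation-robust alternatives are deliberately out of scope.
* The counterfactual deltas are point comparisons with no uncertainty
  intervals.
* The pairs bootstrap for trend likelihood ignores serial correlation; it
  stands in for the load-model bootstrap used with full
  discharge-resolved trend machinery, which operates on data this
  pipeline never sees.
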