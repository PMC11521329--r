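---
title: "Validating internet-based allergy surveillance: models, tests, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating internet-based allergy surveillance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(allergywatch)
```

## The problem

Seasonal allergic disease leaves three observable daily traces at regional
scale: emergency-department (ED) visits coded for allergic rhinitis and
related conditions, social-media posts in which people describe their
symptoms, and search activity for allergy topics. All three are plausibly
driven by one unobserved process — the airborne concentration of
aeroallergens such as pollens and molds. If that is true, internet streams
can substitute for clinical surveillance where hospital data are delayed or
unavailable. But each stream is a nonstationary, strongly seasonal time
series, and naive correlation between nonstationary series is spurious with
high probability. The sound framing is **cointegration**: if each stream is
integrated of order one (I(1)) and they share a single stochastic trend,
then linear combinations of them are stationary, the series have a long-run
equilibrium, and correlations computed on deseasonalized residuals are
meaningful.

`allergywatch` implements (a) that statistical validation battery, (b) the
text, geographic and aggregation plumbing that turns raw posts into
region-day series, (c) a cross-region intensity mapping stage, and (d) a
synthetic-data generator with the exact dependence structure the analysis
assumes, so the whole pipeline is testable without access to proprietary
archives.

## The latent-process model behind the generator

For region $r$ on day $t$ the latent aeroallergen level is

$$A_r(t) = \sum_k a_k \exp\!\left(-\frac{d(t, p_k)^2}{2 w_k^2}\right) + T_r(t) + Z_r(t),$$

where the first term is deterministic annual seasonality (Gaussian bumps at
day-of-year $p_k$ with amplitude $a_k$ and width $w_k$; $d(\cdot)$ is
circular day-of-year distance on a 365.25-day wrap so mid-winter seasons
behave correctly), $T_r$ is a random walk with innovation standard
deviation `trend_sd`, and $Z_r$ is a stationary AR(1) anomaly
(`anomaly_sd`, `anomaly_ar`).

Observation links:

- `ed_count` $\sim$ Poisson$\big(\frac{\text{pop}}{10^5}(\beta_{ED} + c_{ED} A_r(t))^+ \, w_{dow(t)}\big)$ — rate truncated at zero, with a day-of-week multiplier $w$;
- `total_posts` $\sim$ Poisson$\big(\frac{\text{pop}}{10^5}\beta_{P}\, w_{dow(t)}\big)$;
- `allergy_posts` $\sim$ Binomial(`total_posts`, $f(A_r(t))$) — Binomial thinning with a monotone relevance fraction $f$;
- `search_probability` $=$ logistic$(\text{logit}(\beta_S) + c_S A_r(t))$ plus small noise, clipped to $[0,1]$.

The single random walk $T_r$ is shared by **all streams of a region**, which
is precisely what makes the observed streams pairwise cointegrated and
gives the three-stream system Johansen rank 2 (three series, one common
trend). Optionally one walk is shared across regions with per-region
scaling (`share_trend_across_regions`), and `stream_trend_sd` instead gives
every stream its **own** independent walk — the null design in which all
streams are I(1) but nothing is cointegrated, used to check test size.

### Why the default relevance link is truncated-linear

The default $f(A) = \min\{1, \max\{0, f_0 (1 + c_P A)\}\}$ rather than a
logistic link. Cointegration is a *linear* concept: with a logistic link
the post-probability stream is a curved transform of the latent level, the
Engle–Granger step-1 regression against the (linear) ED stream leaves a
nonlinear function of the random walk in its residuals, and the residual
unit-root test weakens substantially. A locally linear link keeps the
cointegrating relation itself linear, which is the regime the validation
battery is designed to detect. The logistic form remains available by
passing `relevant_fraction_link` explicitly; the search stream keeps its
logistic link (it is a bounded probability) and is correspondingly the
weakest member of the triple.

### Default parameter values

Defaults describe a large, allergy-prone county: ED baseline 1.0
allergy-coded visit per 100,000 per day with coupling 0.5; 150 total posts
per 100,000 per day, of which about 5% are allergy-relevant at baseline;
spring peak near day 100 with a weaker fall peak near day 265;
`trend_sd = 0.06` and AR(1) anomalies (`sd = 0.25`, `ar = 0.8`) in latent
units where the seasonal amplitude is about 1. These scales make the shared
stochastic trend the dominant low-frequency signal relative to Poisson and
Binomial observation noise after 7-day smoothing — a "strong coupling"
regime in which the cointegration machinery should, and does, detect the
shared trend essentially always. Contamination: 20% of keyword-matching
posts are irrelevant confounders that *share* keywords with relevant posts
(an "allergy free expo" problem), plus a 10% stream of plain posts with no
keywords.

What the generator does **not** emulate: real linguistic variety (posts are
templated sentences, so text classification is substantially easier than on
real social-media language — classifier metrics near 1.0 on synthetic
corpora say nothing about transformer-level performance on real posts);
real geography (regions are rectangles); demographic and platform biases;
reporting artifacts in clinical data. Passing tests demonstrate that the
*statistical machinery* behaves correctly under the assumed data-generating
process, not that real internet streams are cointegrated with real ED data.

## The validation battery

Per region, on 7-day-smoothed, quality-filtered series:

1. **Canova–Hansen seasonal stability** on weekly aggregates (period 52):
   tests stable deterministic seasonality against a seasonal unit root;
   the recommended seasonal differencing order is 1 when the null is
   rejected at 5%.
2. **Bidirectional Engle–Granger** between each internet stream and the ED
   stream: step 1 is OLS with intercept; step 2 is an ADF regression on the
   residuals with no deterministic term, judged against two-variable
   cointegration critical values (MacKinnon 2010 response surfaces). Both
   regression directions are reported because the choice of dependent
   variable is arbitrary; cointegration in both is the stronger statement.
3. **Johansen trace** on the (ED, posts, search) triple: reduced-rank
   regression of the VECM, trace statistics against Osterwald-Lenum (1992)
   critical values, selected rank = smallest non-rejected rank at 5%.
4. **Zero-lag Pearson correlations** of the raw series and of two residual
   variants: parametric (OLS on intercept + 11 calendar-month dummies +
   linear time index) and nonparametric (remainder of a robust STL
   decomposition at period 365). Agreement between the two residualizations
   guards against either one's artifacts.

No multiple-testing adjustment is applied across regions; per-region
p-values are reported as-is and should be read descriptively.

## Tunable parameters that matter

| Parameter | Default | Units / meaning |
|---|---|---|
| `min_population` | 500,000 | region inclusion floor |
| `min_ed_per_100k` | 450 | ED encounters per 100k over the window |
| `min_posts_per_100k` | 80 | allergy posts per 100k over the window |
| ADF `max_lags` | auto | AIC over 0..⌊12(n/100)^¼⌋ (Schwert) |
| EG critical values | MacKinnon 2-variable, constant | 1/5/10% |
| Johansen `lag_order` | 7 | VAR lags; weekly dynamics in daily data |
| Johansen `deterministic` | `rconst` | constant restricted to the cointegrating relation |
| CH `period` | 52 (weekly aggregates) | annual seasonality |
| smoothing window | 7 days, centered | ±3 days, ≥4 of 7 present |
| season windows | Mar–May, Jun–Aug, Sep–Oct, Nov–Feb | spring/summer/fall/winter |

Boundary semantics: quality thresholds are inclusive (a region at exactly
450/80/500,000 passes; "fewer than" excludes). Winter of year $Y$ runs
November $Y$ through February $Y{+}1$.

## Numerical and design choices

- **Critical values.** ADF and Engle–Granger use MacKinnon (2010)
  response-surface constants with $1/T$ and $1/T^2$ finite-sample
  corrections. Johansen uses the Osterwald-Lenum (1992) trace tables for
  the restricted-constant and unrestricted-constant specifications.
- **ADF lag selection** compares AIC on a common estimation sample, then
  refits the chosen order on the longest sample it allows. Missing values
  are allowed only at series edges; interior gaps are an error at the test
  level, and the battery linearly interpolates sporadic interior gaps
  (with a warning) before testing.
- **Canova–Hansen truncation.** The Bartlett long-run-covariance truncation
  uses the short Newey–West rule $\ell = \text{round}(4 (n/100)^{1/4})$. A
  truncation that grows with the period absorbs the very nonstationarity
  under test and destroys power. The 5% critical value uses the
  $0.269\,m^{0.928}$ approximation to the generalized von Mises
  distribution with $m-1$ degrees of freedom, which permits arbitrary
  periods (at $m=12$ it gives 2.70 against the exact 2.75, i.e. the test
  runs slightly conservative). At least 3 full periods are required and
  fewer than 5 triggers a warning: 4 years of daily data aggregated to
  weeks is usable but close to the calibration limit.
- **Smoothing rule.** A centered 7-day window removes day-of-week effects
  *exactly* on interior days (each weekday appears once). The ≥4-of-7 rule
  extends coverage to edges and mildly gappy data without interpolating
  counts.
- **Edge/tie rules.** Points exactly on a shared polygon edge go to the
  lexicographically smallest region id (determinism over geometric fuzz);
  peak-date ties break to the earliest day; geometry is planar lon/lat, fine
  at county scale.
- **Z-scores** are computed across regions (the maps compare regions, not
  years); seasonal means pool all days of a season across years. Both
  standardizations are exact by construction (mean 0, sd 1 to 1e-9).
- **Randomness.** One master seed; every generator component draws from a
  deterministic sub-stream keyed by (purpose, region, stream), so adding
  regions never perturbs existing ones, and pipeline reruns are
  byte-identical.
- **Timezone.** Timestamps bin by UTC calendar date.

## Validation experiments and problem sizes

The `experiment_*()` functions (run by `scripts/acceptance.R` and the
acceptance tests) re-derive the battery's operating characteristics at
n = 1460 days: Engle–Granger empirical size on independent seasonal I(1)
series (500 replicates; the null uses seasonal amplitude 1 against
random-walk innovation sd 0.1, comparable magnitudes in latent units),
power and slope recovery under cointegration with stationary AR(1) noise at
10% of the trend innovation sd (100 replicates), Johansen rank recovery
(50), Canova–Hansen decisions at period 12 with 20 periods (100),
residualization diagnostics, end-to-end coupled and null battery runs (50
seeds each with one region per run), exact small-case oracles (1,000 cases),
amplitude-rank recovery (20 regions, 50 replicates, `trend_sd = 0` and
anomaly sd 0.15 — the mapping stage does not assume a stochastic trend, so
"moderate noise" here means observation plus anomaly noise), peak-timing
recovery (sharp season: amplitude 2, width 12 days, anomaly sd 0.05,
population 1.5M; the estimate is the per-region median peak day over the
four years, robust to single-year outliers), the quality-rule boundary
cases, and classifier accuracy on separable and contaminated corpora
(2,000/2,000 splits).

## Known limitations

- The Canova–Hansen critical value is an approximation; at period 52 with
  only 4 annual cycles its calibration is rough (the battery reports the
  recommended order, it does not gate on it).
- The Johansen implementation covers 2–5 series with the two constant
  specifications; no seasonal dummies inside the VECM.
- STL requires interpolating interior gaps; counts themselves are never
  interpolated.
- The reference classifier is a ridge-penalized bag-of-words model — a
  deliberately simple, deterministic stand-in behind the pluggable
  `classify()` interface; a fine-tuned transformer can be slotted in
  without touching the rest of the pipeline.
- Synthetic-data results bound what the tests can say about real data; see
  the generator caveats above.
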