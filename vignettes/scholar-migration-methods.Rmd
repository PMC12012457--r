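---
title: "Methods: estimating scholarly migration from affiliation histories"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: estimating scholarly migration from affiliation histories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scholmig)
```

`scholmig` estimates internal (within-country) and international migration
of actively publishing scholars from author–year–affiliation records. This
vignette documents the model and its assumptions, the tunable parameters,
what the synthetic-data generator does and does not emulate, the numerical
choices, and the known limitations.

## Residence model

The atomic observation is an affiliation record: an author, a calendar
year, and the region (with its country) of one affiliation appearing on
that year's publications. An author may have several records in one year
(multiple affiliations, mid-year changes).

**Modal residence.** The residence country of an author-year is the mode of
that year's affiliation countries; the residence region is then the mode of
the regions *within that modal country*. Nesting the region mode inside the
country mode is a design choice: computing the two modes independently can
place an author's regional residence in a country other than their national
residence, which would break the internal/international classification.
Ties at either level are broken in favour of the candidate that appears in
the closest previous residence year, scanning backwards one year at a time
(only prior years are used — future information never influences the
current year's residence). If none of the tied candidates has been seen
before, one is drawn uniformly at random from a named, seeded stream
(`derive_seed(seed, "ties")`), so whole-pipeline runs are bit-reproducible.

**Backward fill.** Publications lag the work (and the residence) that
produced them, on the order of two years across disciplines. We therefore
assume a two-year preparation time, realized entirely as a backward fill:
if an observed year `y` is preceded by a publication gap of length `g >= 1`,
years `y-1` and `y-2` (i.e. `min(g, 2)` years) inherit `y`'s residence,
never overwriting an observed year. Years deeper than two into a gap stay
unassigned — we do not interpolate, because a long silence carries no
evidence of residence either way. There is no additional global two-year
shift of all records; the fill is the whole mechanism. One consequence
surfaces in tests: a move that becomes visible after a gap is dated two
years before the next publication.

**Events.** A migration event is recorded whenever the region differs
between two consecutive residence years (observed or backfilled); the
migration year is the first year carrying the new residence. Same-country
events are internal, cross-country events international; an event can never
have identical origin and destination. Authors observed in a single year
contribute to populations but can never generate events.

**Censoring.** Events and residences are restricted to an inclusive
analysis window, 1998–2017 by default inside a 1996–2020 data span: the
first years of a panel cannot distinguish immobile authors from authors
whose earlier residence is unobserved (left truncation), and the two-year
fill makes the last years incomplete (right truncation). Both bounds are
inclusive, matching the "from 1998 to 2017" reading.

## Accounting

Per region `i`, year `t` and scope `k` (internal, international, total):
`N[i,t]` is the number of distinct authors resident in `i` at `t`
(backfilled residence-years included — they are residences by construction;
`tabulate_flows()` operates on whatever residence table it is given, so a
caller can drop backfilled rows to measure the sensitivity), and `I`, `E`
count events into and out of `i`. The net migration rate is
`NMR = 1000 (I - E) / N` per year; pooled over a period it is
`1000 (ΣI - ΣE) / ΣN`, a per-year rate because the denominator accumulates
person-years. Region-years with `N = 0` are emitted flagged rather than
dropped or zeroed: 0/0 is not evidence of zero migration, and downstream
analyses exclude flagged rows explicitly. Directional rates are `count/N`.

## Inequality series

Within each continent (or any alternative grouping label the registry
carries), the annual inequality of a directional rate across regions is the
population-weighted relative Gini

G = Σᵢ Σⱼ wᵢ wⱼ |xᵢ − xⱼ| / (2 (Σw)² x̄_w),

with `x` the regional rates, `w = N[i,t]` the same year's populations, and
x̄_w the weighted mean. "Relative" is read as mean-normalized — the standard
relative Gini — since only weighting is stated as the small-region
mitigation; we do not additionally winsorize or filter small regions.
Weights are year-specific, not fixed at a base year, consistent with an
annually recomputed index. The implementation uses the sorted Lorenz form
(O(n log n)) and is tested to 1e-12 against a brute-force pairwise oracle;
group-year cells with fewer than two usable regions are skipped with a
warning. G satisfies scale invariance, weight-merging consistency, and
0 ≤ G ≤ 1 − min(w)/Σw.

## Per-region trends

For each region and each of the four series (in/out × internal/
international), annual counts are modelled as overdispersed Poisson with a
log link and exposure offset: `E[count_t] = N_t exp(a + b t)`. The fit is
the standard IRLS GLM (`stats::glm`, `quasipoisson`); the dispersion
`phi = Pearson X² / (n − 2)` inflates the Poisson standard errors by
`sqrt(phi)` — the conventional quasi-Poisson estimator. Slopes are reported
on the percent scale via `T(b) = 100 (exp(b) − 1)`.

Eligibility: a region enters with (1) more than 25 scholars in at least one
observation year (strict: a peak of exactly 25 is excluded), (2) at least
10 observation years, and (3) at least 5 years with a nonzero count. We
parse the three clauses as conjunctive conditions — the natural reading —
but the alternative ("at least 10 years each with at least 5 events") is
available as `eligibility_rule(parse = "joint")`, and all thresholds are
configurable.

Numerical choices: the year covariate is centered at the window midpoint
(slope invariant, intercept better conditioned); years with `N = 0` are
dropped rather than given an infinite offset; convergence is a relative
deviance change below 1e-8 within 100 IRLS iterations; an all-zero count
series is a no-information error, not a slope of 0. Calibration is tested
by simulation: across 1,000 Poisson replicates the mean slope bias is
within Monte-Carlo error of zero and the empirical SD of the slope agrees
with the mean reported SE within 15%.

## Interrelation of internal and international migration

**Errors-in-variables regression.** Trend slopes carry heterogeneous
uncertainty, so regressing internal slopes (y) on international slopes (x)
naively would both attenuate the slope (noise in x) and misweight regions.
We fit the structural measurement-error model

- x_i ~ N(ξ_i, sx_i²), y_i ~ N(α + β ξ_i, sy_i² + σ²)
- ξ_i ~ N(μ_ξ, τ²)

with weakly informative priors α, β ~ N(0, 10²), σ ~ half-N(0, 5) — scale-
free for slope magnitudes near 0–1 — a wide Normal prior on μ_ξ and a
weakly informative inverse-gamma prior on τ² scaled to var(x). The
hierarchical (learned) τ is essential: with an effectively flat latent
prior the posterior slope stays attenuated like least squares, whereas
learning τ recovers the de-attenuated slope; both behaviours are asserted
in the test suite. Sampling is Gibbs for ξ, (α, β), μ_ξ and τ², with an
adaptive random-walk Metropolis step on log σ (target acceptance ≈ 0.44,
adaptation only during warm-up); defaults are 4 chains × 2,000 draws after
1,000 warm-up iterations, seeded per chain from the run seed. Convergence
is monitored with split-R̂ (flagged above 1.1) and an autocorrelation-based
ESS (slope flagged below 100). A slope is "significant" when the central
95% credible interval excludes zero. Coverage is verified by simulation
(the 95% interval covers a true slope of 0.8 in ≈95% of 100 replicates at
n = 200), and the no-measurement-error limit is checked against ordinary
least squares.

**Quadrants and rank correlations.** Quadrant fractions of the
(international, internal) slope scatter are percentages of points with
strictly positive/negative coordinates; points on an axis go to a separate
bucket, so the four quadrants plus the bucket sum to exactly 100%. The
association between internal and international annual rates within a
region is Kendall's τ-b — the tie-corrected variant, because small regions
produce many tied zero rates (τ-a would be biased toward zero there).
Regions where either series is constant get an undefined, flagged τ.

## The synthetic cohort generator

Real author-affiliation panels are proprietary, so the package generates
cohorts with known ground truth. The generator emulates: careers with a
start year and a Poisson-distributed length (default mean 12 active years)
inside a 1996–2020 span; intermittent publishing (i.i.d. Bernoulli per
active year, default `publish_prob = 0.7`, with at least one record per
author); occasional second same-year affiliations (default
`multi_affil_prob = 0.1`, split evenly between same-country and foreign
regions) to exercise tie-breaking; and year-boundary moves driven by
per-author-year hazards (defaults `internal_move_rate = 0.03`,
`international_move_rate = 0.015` — internal moves roughly twice as common
as international, small per-year as migration hazards are) optionally
scaled per region by a multiplicative annual trend factor. Moves happen at
most once per author-year, at year boundaries, so the true residence is
single-valued per year and matches the annual resolution of the inference;
a mover's publications carry the new region from the move year onward.

What it deliberately does not emulate: author-name disambiguation noise,
affiliation geocoding errors, coauthorship or field structure, sub-annual
move timing, or genuinely simultaneous dual residences. Passing tests on
synthetic cohorts therefore validate the *pipeline logic* — identity
recovery under full observation, ≤2-year event dating error under
intermittent publishing, conservation of flows — not the measurement
quality of any real bibliometric database.

## Problem sizes and reproducibility

The shipped test suite and demo run at desk scale by choice: worlds of
12–36 regions, cohorts of 300–2,000 authors, 1,000-replicate calibration
loops for the GLM, and 100-replicate coverage loops (2 chains × 800 draws)
for the errors-in-variables sampler. These sizes keep the full suite around
a minute while leaving the Monte-Carlo error well inside the asserted
tolerances. One global seed fans out through `derive_seed()` to named
per-stage streams, so `run_pipeline()` with a fixed configuration
byte-reproduces every output file (asserted via digests in the manifest).

## Known limitations

- An author who leaves and returns within the same year is invisible at
  annual resolution; this is accepted as consistent with the modal-year
  design.
- Residence is forced to be single-valued per year; genuinely dual-based
  scholars are assigned their modal base.
- Gap years beyond the two-year fill are unassigned, so populations dip
  during long silences even if the author never moved.
- The eligibility sentence admits two parsings (see above); both are
  implemented, and the conjunctive one is the default.
- The Gini series carries no uncertainty intervals, and the Gini is not
  decomposed into within/between components.
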