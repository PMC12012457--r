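# scholmig

Estimating internal and international migration of scholars from
longitudinal author–affiliation records.

Bibliometric databases record, for millions of researchers, the country and
first-level subnational region (state/province) of their institutional
affiliations year by year. Changes in those affiliations are a usable — if
noisy — signal of residential migration. `scholmig` implements the full
analysis chain for turning such author–year–region records into subnational
migration estimates, for demographers and science-of-science researchers who
work with this kind of panel:

1. **Residence inference.** An author's annual residence is the *modal*
   affiliation country of that year, then the modal region within that
   country. Ties go to the country/region seen in the closest previous
   year; all-new ties are broken at random from a seeded stream. A
   publication gap before an observed year is backward-filled for up to two
   years (publication preparation delay), so a move surfacing after a gap
   is dated two years before the next publication.
2. **Migration events.** An event is recorded when the modal region changes
   between consecutive residence years; the migration year is the first
   year with the new residence. Moves within one country are *internal*,
   across countries *international*. Events and residences are censored to
   an analysis window (default 1998–2017) to limit edge truncation.
3. **Accounting.** Per region *i*, year *t* and scope *k*, inflows
   `I[i,t,k]`, outflows `E[i,t,k]` and populations `N[i,t]` give the net
   migration rate

       NMR[i,t,k] = 1000 × (I[i,t,k] − E[i,t,k]) / N[i,t]

   annually or pooled over multi-year periods (person-years in the
   denominator make the pooled figure a per-year rate), and directional
   migration rates `count / N` feed the analyses below.
4. **Inequality.** Annual population-weighted relative Gini coefficients,
   G = Σᵢⱼ wᵢwⱼ|xᵢ−xⱼ| / (2(Σw)² x̄_w), of regional rates within each
   continent (or any other grouping label), for the six migration types
   (internal/international/total × in/out).
5. **Trends.** Per region and series, a quasi-Poisson log-link regression
   of annual counts on year with offset `log N` — eligibility: more than 25
   scholars in at least one year, ≥ 10 observation years, ≥ 5 nonzero-count
   years — whose slope β is reported as percent change per year via
   `T(β) = 100 × (exp(β) − 1)`.
6. **Interrelation.** A Bayesian errors-in-variables regression (Gibbs/
   Metropolis sampler, structural latent-x model) of internal-trend slopes
   on international-trend slopes using the standard errors of both;
   quadrant fractions of the slope scatter; and per-region Kendall τ-b
   between internal and international annual rates.

Raw commercial bibliometric extracts cannot be redistributed, so the
package ships a **synthetic cohort simulator** (`build_world()`,
`simulate_cohort()`) that generates careers, intermittent publishing,
multiple affiliations and region-level time-varying move hazards with known
ground truth; every stage of the pipeline is validated against that truth.

## Worked example

```r
library(scholmig)
cfg <- pipeline_config(out_dir = "demo", seed = 42)
run <- run_pipeline(cfg)   # simulates a cohort, runs every stage, writes CSVs
print(run)
#> Scholar migration pipeline run
#>   window: 1998-2017   seed: 42   grouping: continent
#>   records: 14344   residences: 16675   events: 795
#>   flows: 720 rows   gini: 360   trends: 97   kendall: 36
#>   outputs: demo
```

The run simulates 2,000 authors on a 36-region synthetic world (14,344
affiliation records), infers 16,675 residence-years and 795 migration
events inside the 1998–2017 window, and writes every product
(`flows.csv`, `nmr.csv`, `gini.csv`, `trends.csv`, `eiv_fits.csv`,
`kendall.csv`, ...) plus a manifest under `demo/`. For example, the
period-averaged net migration rates for 2012–2017:

```r
head(subset(run$nmr, period_start == 2012 & defined), 3)
#>     region_id period_start period_end scope nmr_per_1000 defined
#> 217  C1.c1.r1         2012       2017 total     25.31646    TRUE
#> 218  C1.c1.r2         2012       2017 total      0.00000    TRUE
#> 219  C1.c1.r3         2012       2017 total    -66.66667    TRUE
```

`C1.c1.r1` gained about 25 scholars per 1,000 resident scholars per year
over the period; `C1.c1.r3` lost about 67 per 1,000 per year. Single
estimators are available directly: `fit_qp_trend()` returns a classed fit
(`print`, `coef`, `summary`, `confint`), e.g. a noise-free series built
with a 20 %/yr growth rate is recovered exactly:

```r
t <- 0:19
fit <- fit_qp_trend(round(10000 * 0.01 * exp(0.1823 * t)), rep(10000, 20), 1998 + t)
fit$slope_pct_per_year
#> [1] 19.99496
```

and `fit_eiv()` fits the measurement-error regression with `print`/`plot`
methods and MCMC diagnostics (split-R̂, ESS).

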