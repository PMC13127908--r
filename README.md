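# rajastat

Dual assessment of data-poor skate (Rajidae) populations: **conservation
status** from mitochondrial COI barcode diversity compared against a
Mediterranean–Atlantic reference framework, and **exploitation status** from
data-poor stock assessment — a Bayesian state-space Schaefer
surplus-production model on catch/CPUE and length-based Bayesian biomass
estimation (LBB) on trawl-survey length frequencies, supported by
horsepower-standardized fishing effort and VMS-based allocation of fishing
days to depth strata.

The package is written for fisheries and population-genetics analysts
working on bycatch species where neither full stock assessments nor dense
genetic sampling exist: every input is a plain tibble, every result a
tibble (or a fitted object with `tidy()`/`glance()`/`autoplot()` methods),
and every estimator ships with a seeded synthetic-data generator carrying
ground-truth labels so the whole pipeline is testable end to end.

## The methods in brief

* **Diversity:** haplotype diversity `h = n/(n−1)·(1 − Σ p_i²)` and
  nucleotide diversity `π = n/(n−1)·Σ x_i x_j π_ij`, both with Nei's
  variance estimators; exact-identity haplotypes after complete deletion of
  gap/`N` columns.
* **Framework:** percentile bootstrap (10,000 replicates) of the median π
  over a packaged 42-population Rajidae compilation, overall and per basin;
  focal populations are classified `below`/`at`/`within`/`above` the 95% CI
  with a rounding-aware boundary rule.
* **Effort/CPUE/VMS:** monthly effort = Σ actual HP × permitted time at
  sea; CPUE = catch/annual effort; trawling pings filtered to the 2–3.6 kn
  band; vessel-days split 1/k over the k depth strata fished that day
  (shelf 50–100 m, shelf break 100–200 m, upper slope 200–500 m, middle
  slope 500–800 m); OLS trends per stratum.
* **BSM:** Schaefer dynamics `B' = B + rB(1−B/k) − C` with lognormal
  process error, CPUE observation model `log I ~ N(log qB, σ_obs)`,
  log-uniform r and k priors, hard B/k windows at anchor years; fitted by
  adaptive kernel-mixture importance sampling over an extended-Kalman
  marginal likelihood, with Kobe-quadrant posterior probabilities.
* **LBB:** equilibrium length composition
  `N_Li = N_Li−1·((L∞−Li)/(L∞−Li−1))^(M/K + F/K·S_Li)` with logistic
  selectivity, fitted per 6-year period by mode search plus dense grid
  integration; reports L∞, Lc, M/K, F/K, F/M, B/B0, Lmean, Lopt, Lc_opt.

## Worked example

Classify the seven Balearic skate species against the comparative
framework:

```r
library(rajastat)

bs <- build_framework(B = 10000, seed = 1)
bs[, c("median", "lci", "uci")]
#> # A tibble: 1 × 3
#>   median    lci    uci
#>    <dbl>  <dbl>  <dbl>
#> 1  0.001 0.0005 0.0019

classify_balearic(summary = bs)[, c("species", "pi", "status")]
#> # A tibble: 7 × 3
#>   species                  pi status
#>   <chr>                 <dbl> <fct>
#> 1 Dipturus oxyrinchus  0      below_lci
#> 2 Leucoraja naevus     0.0008 within_ci
#> 3 Raja brachyura       0.0014 within_ci
#> 4 Raja miraletus       0.0004 below_lci
#> 5 Raja polystigma      0      below_lci
#> 6 Raja radula          0.0005 at_lci
#> 7 Raja clavata         0.0002 below_lci
```

The framework median nucleotide diversity is 0.001 (95% CI 0.0005–0.0019):
four species fall below the lower CI bound (a worse conservation state than
the reference average), one sits exactly on it, and two lie within the
interval.

A stock-assessment round trip on synthetic data with known truth:

```r
gs <- gen_schaefer_series(r = 0.25, k = 1000, q = 0.001,
                          sigma_obs = 0.1, years = 1985:2024, seed = 105)
fit <- fit_bsm(gs$data,
               bk_priors = tibble::tibble(year = 1985, lo = 0.75, hi = 1),
               seed = 205)
tidy(fit)
#> # A tibble: 6 × 4
#>   term     estimate        lci        uci
#>   <chr>       <dbl>      <dbl>      <dbl>
#> 1 r        0.200      0.0829      0.314
#> 2 k     1194.       834.       2596.
#> 3 q        0.000836   0.000384    0.00123
#> 4 msy     60.2       46.6        70.5
#> 5 fmsy     0.0998     0.0414      0.157
#> 6 bmsy   597.       417.       1298.
kobe_probabilities(fit)   # quadrant posterior probabilities, summing to 1
#> # A tibble: 1 × 5
#>    year   green yellow orange    red
#>   <int>   <dbl>  <dbl>  <dbl>  <dbl>
#> 1  2024 0.00133  0.988      0 0.0107
autoplot(fit)             # Kobe plot
```

The 95% posterior intervals cover the generating `r = 0.25` and `k = 1000`;
`msy = r·k/4` holds for every draw by construction.

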