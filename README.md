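# popersist

Range-wide assessment of population persistence for rare species known
mainly from presence-only occurrence records.

Opportunistic records (museums, GBIF, iNaturalist-style platforms,
monitoring programs) say where a species was seen, not whether it is
still there: a site without recent records may be extirpated, or simply
unsearched.  `popersist` resolves this by reconstructing *search effort*
from detections of co-occurring non-target species — an observer who
reported an indexing species inside a known population would plausibly
have reported the target too — and fitting a modified Cormack–Jolly–Seber
(CJS) state-space model in which the "individual" is a population and
"survival" is persistence.

For population *i* in year *t* (default 1950–2024):

- latent state: `z[i,1] = 1`;  `z[i,t+1] | z[i,t]=1 ~ Bern(phi_i)`, absorbing at 0, with
  `logit(phi_i) = alpha_ecoregion(i) + beta_HS * h_i + beta_rain * w_i + beta_imp * v_i`
  (mean habitat suitability, scaled winter precipitation and
  imperviousness over the population polygon, all on [0, 1]);
- detection: `y[i,t] | z[i,t]=1 ~ Bern(p_it)`, with
  `logit(p_it) = gamma0 + beta_trend * (t - 1987) + beta_effort * e_it`
  where `e_it` is the scaled observer-day count.

The latent extirpation time is summed out analytically, giving an exact
marginal likelihood (verified against brute-force enumeration to 1e-12)
sampled by adaptive Metropolis-within-Gibbs MCMC under Normal(0, 10)
priors, with split-chain convergence diagnostics, posterior predictive
checks, and per-population posterior probabilities of persistence in the
final year.

The package covers the whole workflow: record cleaning (range, location
uncertainty, duplicate and season rules), buffer-dissolve population
delineation, ecoregion/protected-area assignment, zonal covariate
extraction, detection/effort history construction, model fitting,
grouped summaries, Welch protected-area comparisons and buffer-size
sensitivity reruns — plus a synthetic-data generator with known truth
for end-to-end testing and simulation-based calibration.

## Worked example

Simulate a small study, run the pipeline, and read the results:

```r
library(popersist)

dir <- file.path(tempdir(), "demo")
fixture_bundle("tiny", dir)          # 12 populations, full record tables
res <- run_pipeline(file.path(dir, "config.yaml"))

nrow(res$populations)
#> [1] 12

head(res$persistence[, c("pop_id", "persist_mean", "persist_q025",
                         "persist_q975", "last_detection_year")], 3)
#> # A tibble: 3 x 5
#>   pop_id   persist_mean persist_q025 persist_q975 last_detection_year
#>   <chr>           <dbl>        <dbl>        <dbl>               <int>
#> 1 pop_0001        0.461    5.68e- 72        1.000                  NA
#> 2 pop_0002        0.495    5.37e-121        1.000                  NA
#> 3 pop_0003        0.522    6.78e- 24        1.000                  NA

res$summaries$categories
#>   [0,0.25) [0.25,0.5) [0.5,0.75) [0.75,0.9)    [0.9,1]
#>          0          3          4          0          5

res$summaries$last_obs$r
#> [1] 0.835401
```

`persist_mean` is each population's posterior probability of being
extant in the final modeled year.  The first three populations here were
never detected inside the modeled window (`last_detection_year` is NA;
they are anchored by pre-1950 records), so their posteriors hover near
the covariate-driven expectation and their credible intervals span
almost the whole unit interval — exactly the honest answer for a
population known only from a historical record.  Populations with recent
detections concentrate near 1.  The category histogram is the standard
presentation (populations below 0.5 are "possibly extirpated", above 0.9
"almost certainly extant"), and the final number is the Pearson
correlation between persistence and the year of last observation.
Parameter posteriors are in
`summarize_posterior(res$fit)`, convergence in `gelman_rubin(res$fit)`,
fit checks in `posterior_predictive_check(res$fit)`.

A thin command-line wrapper is available for shell use:

```sh
exec/popersist simulate --outdir /tmp/demo --fixture tiny
exec/popersist all --config /tmp/demo/config.yaml
```

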