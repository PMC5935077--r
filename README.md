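# marshtransplant

Analysis of reciprocal sediment-transplant experiments read out by 16S
rRNA gene OTU tables — built around a fully factorial transplant of
*Spartina alterniflora* salt-marsh cores between five US East Coast sites
(WB, PI, JR, RC, AB, north to south; 88 samples after two losses).

A reciprocal transplant simulates a mass dispersal event: does a
transplanted sediment community keep its original composition (**no
change**), converge on its host marsh (**total adoption**), land in
between (**host shift**), or drift somewhere else entirely (**random
shift**)? And which individual taxa track the environmental change each
core experienced? The package answers both questions with a tested,
reproducible pipeline:

* **OTU-table processing** — rarefaction to even depth (hypergeometric,
  seeded), singleton removal, prevalence curation with the strict
  `k/n > f` threshold (84 of 88 samples at f = 0.95), top-n subsetting,
  relative abundance, display-taxon aggregation.
* **Matrix statistics** — Bray–Curtis dissimilarity
  `1 − 2·Σmin(x,y)/(Σx+Σy)`, haversine geographic distance (6371 km
  sphere), environmental difference matrices, Mantel tests (999
  permutations, exact enumeration for ≤7 labels), matrix regressions
  (R² = M² by construction), and non-metric multidimensional scaling
  minimising Kruskal stress-1 with pool-adjacent-violators monotone
  regression.
* **The indicator-OTU scan** — for every prevalent OTU and each of
  temperature, nitrogen, salinity and geographic distance, regress the
  OTU's per-sample share of its grand total on the directional ln-delta
  `ln v_destination − ln v_origin` (controls at x = 0), with Bonferroni
  family-wise control `α / (n_OTUs × 4)`; with 63,337 OTUs this is the
  canonical `0.001 / 253,348 = 3.9e-9`.
* **The outcome classifier** — a deterministic rule over mean Bray–Curtis
  distances to the origin and destination pristine-control clouds, with a
  tolerance band `τ × baseline` (τ = 1.5) around each cloud.
* **A ground-truth simulator** — Dirichlet-multinomial communities over
  the real factorial design, with a north/south regional signature,
  site-level idiosyncrasy, an origin/destination invasion mixture, and
  planted indicator OTUs whose expected abundance responds log-linearly
  (`exp(β·Δv)`) to the environmental delta.

Everything is data-frame-first and pipe-friendly; fitted objects have
`tidy()`, `glance()` and `autoplot()` methods.

## Worked example

Simulate the 88-sample study design with five planted indicators, scan for
them, and classify every transplant:

```r
library(marshtransplant)
library(dplyr)

sim <- simulate_dataset(simulation_config(seed = 2025))
sim
#> Simulated transplant dataset: 300 OTUs x 88 samples at depth 14376
#>   (pi = 0.05, 5 planted indicators)

scan <- run_scan(sim$otu_table, sim$metadata, sim$sites)
scan
#> Indicator-OTU scan: 264 OTUs x 4 variables = 1056 regressions
#> Bonferroni-corrected alpha = 9.47e-07 (family alpha 0.001);
#>   8 passing result(s) among 5 OTU(s)
#> # A tibble: 8 x 9
#>   otu_id  variable     slope intercept r_squared  p_value     n passes
#> 1 otu_005 geographic…  8.27e-4  0.00790     0.664 4.29e-22    88 TRUE
#> 2 otu_004 salinity     5.63e-3  0.0113      0.650 2.59e-21    88 TRUE
#> 3 otu_001 air_temp    -1.27e-2  0.0113      0.535 5.96e-16    88 TRUE
#> ...
```

264 of the 300 OTUs survive the >95% prevalence curation, so the corrected
threshold is `0.001 / 1056 = 9.5e-7`. All five planted OTUs are recovered
and no unplanted OTU passes. The extra passes are planted OTUs detected
under a second, collinear variable (temperature and nitrogen deltas are
strongly correlated across these five sites) — the same behaviour the
original field analysis showed, where one taxon passed both temperature
and nitrogen. The negative temperature slope of `otu_001` is the planted
warm-adapted pattern: the further a core moved toward warmer conditions
relative to its origin, the smaller that OTU's share.

```r
bc  <- bray_curtis(sim$otu_table)
ordinate_nmds(bc, k = 2, seed = 1)
#> nMDS ordination: 88 samples in 2 dimensions, stress-1 = 0.1899
#>   (10 random starts)

calls <- classify_outcomes(bc, sim$metadata)
count(calls, call)
#> # A tibble: 2 x 2
#>   call               n
#> 1 no_change         57
#> 2 total_adoption     1
```

At the default 5% invasion fraction, 57 of 58 transplants are called
`no_change` and the modal call is `no_change` in all 20 design cells —
transplanted communities keep looking like their origin sites. The
environmental panel on the packaged site table shows the gradient
structure the ordination recovers:

```r
sites <- marsh_sites()
mantel(env_difference_matrix(sites, "air_temp"),
       geographic_distance_matrix(sites), exhaustive = TRUE)
#> Mantel test (greater, exhaustive): M = 0.9668, p = 0.008333
#>   (n = 5 labels, 120 permutations)
```

Temperature differences and geographic distance are almost perfectly
correlated along the latitudinal gradient (M = 0.97, the exact-permutation
floor p = 1/120), which is why the scan treats the two as separate,
partially confounded axes.

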