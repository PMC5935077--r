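---
title: "Methods: reciprocal-transplant microbiome analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: reciprocal-transplant microbiome analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(marshtransplant)
```

# The experiment this package analyses

A reciprocal sediment-transplant experiment moves intact cores between every
ordered pair of marsh sites along an environmental gradient, simulating a
mass dispersal event. The design analysed here is fully factorial over five
US East Coast *Spartina alterniflora* salt marshes (WB, PI, JR, RC, AB,
north to south): triplicate cores per (origin, destination) cell, including
cores re-planted into their own site (*replant controls*), plus triplicate
freshly collected, never-moved cores per site at recovery time (*pristine
controls*). With two unrecovered cores the realised design has 88 samples.
Each sample is read out as a 16S rRNA gene OTU table (operational taxonomic
units clustered at 97% identity).

Four outcomes are possible for a transplanted community relative to the
control communities: it can look unchanged from its origin site
(**no change**), indistinguishable from its destination site (**total
adoption**), intermediate between the two (**host shift**), or unlike
either (**random shift**). The package operationalises this question with
three analysis layers — community-level matrix statistics, a per-OTU
directional regression scan, and a formal outcome classifier — plus a
ground-truth simulator so every layer can be validated end to end without
sequencing data.

# Community processing

Counts are first rarefied to an even depth (multivariate hypergeometric
subsampling without replacement; `rarefy()`), because Bray–Curtis
dissimilarity and richness are only comparable at equal library sizes.
Singletons — OTUs with exactly one read in the whole table — are removed
after rarefaction (`remove_singletons()`): a post-rarefaction singleton
carries no reproducible signal. Further operations (`top_n_otus()`,
`prevalence_filter()`, `aggregate_display_taxa()`, `relative_abundance()`)
are thin, order-explicit transformations; ties in abundance ranks are
broken lexicographically on OTU id and reported, so every pipeline run is
reproducible.

The prevalence filter uses a strict inequality: an OTU is kept when it
occurs in strictly more than `min_fraction` of samples, so the integer
threshold is the smallest k with k/n > `min_fraction` — 84 of 88 samples
at the default 0.95.

# Matrix statistics

Community dissimilarity is Bray–Curtis,
`BC(x, y) = 1 − 2·Σ min(x_k, y_k) / (Σ x_k + Σ y_k)`, computed on
rarefied counts (where it simplifies to `1 − Σ min / depth`). Geographic
distance is great-circle (haversine) on a 6371 km sphere; the analysis
needs only rank-consistent distances, so the choice of geodesic is
inconsequential. Environmental difference matrices are absolute pairwise
differences in each variable's native units.

The Mantel statistic M is the Pearson correlation of the strictly-upper
triangles of two distance matrices; significance comes from jointly
permuting one matrix's row/column labels. The default is one-sided
(greater), the convention of the classical Mantel methodology, with 999
permutations; with five sites (10 pairs) the package instead enumerates
all 120 label permutations (`exhaustive = TRUE`) for an exact p-value.
Matrix regression is ordinary least squares on the same upper-triangle
pairs, so its R² is exactly M² — an identity the test suite asserts to
1e-12. For the distance-decay analysis of controls against geographic
distance, distance matrices may be natural-log transformed off-diagonal
(`transform_matrix()`, with an explicit pseudocount when zeros are
possible); environmental panels default to untransformed values, with the
transform available by flag, since the skew-reduction step is only
motivated for the community-vs-distance comparison.

Non-metric multidimensional scaling minimises Kruskal stress-1,
`sqrt(Σ (d − d̂)² / Σ d²)`, where d are configuration distances and d̂
their monotone (pool-adjacent-violators) regression onto the rank order of
the input dissimilarities, with primary tie handling (tied input values
carry no mutual constraint). The optimiser is vegan's monotone-regression
nMDS engine restarted from random configurations plus one classical-scaling
start, keeping the lowest-stress solution; `kruskal_stress()` and `pava()`
expose the objective so the tests can check it against brute-force
oracles independently of the optimiser.

# The indicator-OTU regression scan

The scan asks, for each sufficiently prevalent OTU and each environmental
variable, whether the OTU's distribution across samples tracks the
*directional environmental change* each transplant experienced.

* The response y for a sample is the OTU's **share of its own grand
  total** — observed count divided by the OTU's total count over all
  samples (`otu_percent_of_total()`). These shares sum to one across
  samples, giving every OTU's regression the same spatial scale
  regardless of absolute abundance. Internally y is a proportion;
  percent is presentation only.
* The predictor x is the **ln-scale delta** of the variable from origin
  to destination: `ln v_destination − ln v_origin` for temperature,
  percent nitrogen and salinity (`env_delta()`). The delta is
  antisymmetric — reversing a transplant's direction flips the sign —
  and zero for controls, which enter every regression at x = 0. The ln
  transform puts variables with different units on comparable relative
  scales. For WB to AB temperature the delta is
  `ln(24.2) − ln(17.1) = 0.347`.
* Geographic distance has no direction and is zero for same-site
  samples, so its delta is `ln(1 + d_km)` by default (symmetric, zero at
  home; `raw_symmetric` available). Percent carbon is excluded by
  default because it is collinear with nitrogen across these sites.
* Each (OTU, variable) dataset is fitted by ordinary least squares with
  the two-sided Student-t test of slope = 0 (n − 2 degrees of freedom).
  Family-wise error is controlled by Bonferroni: the per-test threshold
  is `alpha / (n_surviving_OTUs × n_variables)` with family alpha 0.001.
  With 63,337 OTUs and 4 variables this reproduces the canonical
  3.9e-9; for a synthetic table the count of OTUs actually tested (after
  prevalence curation) is used and reported, so either convention can be
  reproduced.

Three conventions required decisions the source analysis leaves open, and
the package fixes them explicitly: (i) the worked ln-delta example above
evaluates to 0.347, not the sometimes-quoted 0.296 — the package follows
the formula; (ii) all 88 samples, controls included, enter each regression
(the prevalence curation is defined against the full 88-sample universe,
implying the same universe for the regressions); (iii) the corrected alpha
is computed from the post-curation OTU count actually tested, with the
test count reported alongside.

# The transplant-outcome classifier

The four verbal outcomes become a deterministic rule over Bray–Curtis
distances. For a transplant sample, let d_o and d_d be its mean
dissimilarity to the origin-site and destination-site pristine-control
clouds, `baseline_s` the mean pairwise dissimilarity within site s's
controls, `separation(o, d)` the mean dissimilarity between the two
control clouds, and ε = τ·baseline with τ = 1.5 by default:

* **no_change** if d_o ≤ ε_o and d_o ≤ d_d;
* **total_adoption** if d_d ≤ ε_d and d_d < d_o;
* **host_shift** otherwise, if max(d_o, d_d) ≤ separation(o, d);
* **random_shift** otherwise.

The rule partitions every (d_o, d_d) configuration; ties go to no change,
the null outcome. τ is a tolerance multiplier on natural within-site
dispersion — 1.5 says a community is "identical" to a control cloud if it
sits within one-and-a-half times the cloud's own spread. It is a package
default, not an empirical estimate; all stored distances are returned with
each call so any other τ can be re-derived without recomputation.
Pristine controls define the reference clouds (they are the undisturbed
end-state); `controls = "both"` pools replants as well.

# The synthetic-data generator

`simulate_dataset()` generates the full factorial design with known ground
truth. Expected per-site profiles come from a log-normal baseline
(`sigma = 0.7`, a moderately uneven community with a few-percent top OTU),
modified by region- and site-level multiplicative perturbations; each
sample's expected profile is the invasion mixture
`(1 − π)·θ_origin + π·θ_destination`; planted indicator OTUs are
multiplied by `exp(β·Δv)` before renormalisation (keeping θ a simplex and
matching the scan's log-linear detection model); counts are
Dirichlet-multinomial with concentration c = 1500 at depth 14,376 (the
study's even rarefaction depth) — clear extra-multinomial scatter between
replicate cores, as real marsh replicates show. The two unrecovered cores
are modelled as design drops, not missing data. π defaults to 0.05: the
experiment found communities resistant to invasion.

The spatial structure is a nested decomposition on the log scale, designed
so that the generator is *a true null for the scan except where indicators
are planted*:

* a **region effect** (north = WB, PI; south = JR, RC, AB) shared by all
  sites of a region — the latitudinal signature that ordination should
  recover;
* **site deviations** centred to zero within each region — local
  idiosyncrasy that separates sites without re-encoding the gradient;
* both effects are **bounded** (uniform on the log scale) and scaled per
  OTU to a constant multiple of that OTU's replicate-level noise
  (sd ∝ 1/√(c·θ), capped), so spatial structure is an aggregate of many
  modest shifts and no single unplanted taxon is resolvable as an
  environmental responder;
* site deviations are drawn **orthogonal to the within-region salinity
  pattern**: temperature and nitrogen follow the regional gradient and
  are represented by the region term, but salinity varies site-to-site
  within region (JR's estuarine freshening), so unconstrained site
  idiosyncrasy would plant accidental salinity responders in what is
  meant to be a null community.

A pure baseline-times-region construction would make all sites within a
region identical in expectation, leaving within-region transplants with
origin and destination clouds that are statistically indistinguishable —
the site term exists precisely so the classifier's question is answerable.

Indicator β defaults (±1.15 temperature, −0.42 nitrogen, +0.42 salinity,
0.075 ln-distance) were calibrated once so that a planted indicator's
realised regression R² falls in the 0.4–0.6 range — the strength regime
the scan is meant to detect; planted OTUs get a baseline share of 3%, in
the prevalence regime of real indicator taxa. Effect sizes for real
indicator organisms are not identifiable from a single experiment, so
these are calibration choices of the generator, not estimates.

What the generator does *not* emulate: mechanistic ecology (growth,
seasonality, succession), taxon-specific dispersion, phylogenetic
structure among OTUs, spatial structure within a core, or compositional
artefacts of PCR and primer bias. Passing tests therefore show that the
pipeline recovers the statistical structure the analysis assumes —
regional clustering, origin fidelity, planted log-linear responders —
not that it would recover any particular biological signal from real
sequence data.

# Numerical choices and degenerate inputs

* Rarefaction errors on samples below depth (naming the sample) unless
  `drop_shallow = TRUE`, which removes them with a warning.
* A perfect regression fit (zero residual variance) reports p = 0 with a
  degeneracy flag rather than dividing by zero; zero predictor variance
  is an error.
* Distance matrices are validated to symmetry 1e-9 (the worst cell pair
  is named) and an exactly zero diagonal; the diagonal is excluded from
  all statistics and from the ln transform.
* Permutation p-values use the `(1 + exceedances) / (1 + permutations)`
  convention, so p ≥ 1/(n_permutations + 1) and exact-zero p-values are
  impossible; exhaustive enumeration replaces sampling for n ≤ 7 labels.
* Kruskal stress orders tied dissimilarities by configuration distance,
  which implements primary tie handling exactly within PAVA.
* All stochastic operations take a `seed` and are bit-reproducible; seeds
  are applied via an isolated RNG scope, leaving the caller's RNG state
  untouched.

# Validation scale

The test suite and the acceptance script exercise the pipeline at
desk-scale sizes chosen to keep every property statistically decidable in
seconds to minutes: 300 OTUs × 88–90 samples, scan properties at depth
5,000 and classifier/ordination properties at the full design depth of
14,376, with 20-seed replication for stochastic properties and 500
replicates (199 permutations) for the Mantel type-I error check. The
reported study-scale quantities that need the original deposited data
(tens of thousands of OTUs) are out of desk scope; the scan applies
unchanged to such tables since all per-OTU work is vectorised.

# Known limitations

* The outcome classifier's τ and the host-shift "betweenness" rule are a
  formalisation of verbal hypotheses; other formalisations (e.g.
  PERMANOVA-based tests) are deliberately out of scope.
* The scan's directional deltas are confounded with origin-site identity
  in any factorial transplant design: an OTU that simply differs between
  origin sites can correlate with a directional delta without responding
  to the environment. The generator is constructed so unplanted taxa do
  not carry such structure; on real data this confound is a caveat of
  the method itself, not of the implementation.
* With five sites the environmental Mantel panel has 10 pairs and an
  exact permutation floor of p = 1/120; printed significance at the 0.05
  level is the best attainable resolution.
* No phylogeny-aware dissimilarities (UniFrac) — no tree exists in this
  design — and no BIOM import; tab-separated text is the interchange
  format.
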