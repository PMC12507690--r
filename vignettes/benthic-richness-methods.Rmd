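---
title: "Benthic richness surfaces from occurrence records: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benthic richness surfaces from occurrence records: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bathyrich)
```

## The problem

Collection records for benthic marine invertebrates are abundant but
extremely uneven: sampling concentrates on north-temperate shallow margins,
roughly a third of locality records lack depths, and misidentified or
mis-georeferenced records place species far outside their described ranges.
`bathyrich` turns such records into defensible latitude x depth species
richness surfaces and then asks what drives them. The pipeline has five
stages:

1. **Cleaning.** Records are filtered by source tag, de-duplicated,
   depth-imputed from bathymetry, and validated against a catalogue of
   described depth limits, latitudinal limits and known range disjunctions.
   Records outside a species' described range, on land, or from hadal
   depths (> 6,000 m) are removed.
2. **Informed interpolation.** Each species' latitudinal gaps between
   records are bridged only where the sea floor offers depths inside the
   species' catalogued bathymetric limits and no catalogued disjunction
   (e.g. an anti-tropical gap) intervenes.
3. **Surfaces.** Occupancy is summed into richness grids on 1-degree
   latitude bins with depth bins of 10 m (shallow, 0–200 m), 50 m (bathyal,
   200–2,000 m) and 200 m (lower bathyal and abyssal, 2,000–6,000 m), with
   matching effort grids and an interpolation-uncertainty map.
4. **Beta diversity.** Shallow faunas (< 200 m) are allocated to province
   rectangles, compared with the Sorenson coefficient, and clustered by
   UPGMA.
5. **Driver inference.** Sea-floor environmental fields are averaged into
   1-degree x 100-m cells; richness is modelled with all-subsets Poisson
   regression under a log-effort offset and with random forests, and the
   partial dependence of deep-sea richness on temperature is scanned for a
   thermal threshold.

Because real compilations cannot be redistributed and are too large for
routine testing, the package ships a synthetic-world generator whose output
has exactly the statistical pathologies listed above and an exported ground
truth, so every stage is testable end to end.

## Informed interpolation

For one species, let the observed 1-degree bins be $O$, the catalogued
latitudinal limits $[\ell, u]$, the catalogued depth interval $[d_-, d_+]$,
and the per-latitude sea-floor envelope $[e_-(b), e_+(b)]$ (the minimum and
maximum floor depth inside the band, estimated by sampling a 10 x 10 point
lattice in every 1-degree cell and taking the nearest-node depth at each
point). Candidate bins span $[\min O, \max O] \cap [\ell, u]$. A candidate
$b$ is *blocked* when it lies inside a catalogued exclusion band or when
$[e_-(b), e_+(b)] \cap [d_-, d_+] = \emptyset$. Blocked bins split the
candidate run into segments; segments containing no observation are
discarded, never bridged. Within an occupied bin the species occupies the
depth bins meeting $[d_-, \min(d_+, e_+(b))]$.

Two policies are worth stating explicitly:

* **Observed bins always count.** A bin holding a validated record is
  occupied even if the (longitudinally aggregated) envelope would block it:
  direct evidence overrides inference. Without this rule a raw cube could
  contain cells the interpolated cube lacks, which would make the
  uncertainty map (below) ill-defined.
* **The raw cube is capped by the same envelope.** Raw occupancy fills each
  observed latitude's catalogued depth interval, capped at the local
  envelope maximum exactly as interpolation is. Both flavours therefore
  agree cell-for-cell at observed latitudes, and the interpolated cube
  contains the raw cube everywhere — the invariant the uncertainty measure
  $100\,(I - R)/I$ requires.

Envelopes are computed, by default, over each species' observed
longitudinal extent padded by 1 degree rather than over all longitudes;
gating a Pacific species' interpolation on Atlantic sea floor would be
meaningless. A `lon_gating = "global"` switch restores whole-world
envelopes.

## Beta diversity

Provinces are compared with the Sorenson coefficient
$S = 100 \cdot 2a / (2a + b + c)$ (shared, and each side's unshared,
species counts). Clustering runs on the dissimilarity $D = 100 - S$ — an
affine map that preserves topology — with classical UPGMA: merge the
closest pair at height $D/2$, update distances by size-weighted averages,
break ties by the lowest (row, column) index so results are deterministic.
Provinces below a species-count floor are excluded before clustering;
near-empty faunas attach essentially at random and only add noise to the
dendrogram. Newick export writes branch lengths as height differences, so
an independent parser reproduces the cophenetic matrix exactly.

## Driver models

The response is per-latitude **maximum** richness within a depth stratum
(shallow / bathyal / abyssal), with environmental predictors averaged over
the same cells. Using the per-latitude maximum, rather than every
(latitude, depth) cell, matters: within a stratum, richness declines with
depth for purely geometric reasons (species' depth limits and the floor's
depth distribution), and any depth-correlated predictor would otherwise
absorb that trend.

Two engines are fitted. All-subsets Poisson regression with a log-effort
offset ranks every predictor subset by AIC; standard errors can be inflated
by the AR(1) factor $\sqrt{(1+\rho)/(1-\rho)}$, with $\rho$ the lag-1
autocorrelation of Pearson residuals along latitude — a simple,
transparent correction for the serial dependence of adjacent latitudinal
counts. Random forests (1,000 trees, `mtry` 3 by default) are trained on a
70% split; %IncMSE importance is the percentage MSE increase when one
predictor is permuted in the held-out 30%, averaged over 10 permutations.
Held-out permutation (rather than out-of-bag) keeps the importance measure
tied to the declared train:test protocol; an OOB flag exists.

Collinear predictors are screened before modelling: among pairs with
$|r| > 0.7$ (strict), the configured victim is dropped — silicate first,
then phosphate — mirroring the usual treatment of the nutrient block.
Predictors for the linear models are centred and scaled per stratum
(centring-only via a flag); forests run on absolute values.

### Thermal-threshold detection

The partial dependence of abyssal richness on temperature is fitted with a
two-segment piecewise-linear model over a candidate-breakpoint grid (0.1
degC spacing, matching the precision at which such thresholds are
reported). The two segments are fitted **independently**, allowing a jump
at the join. This nests the continuous hinge (a noiseless hinge is
recovered at its joint exactly) but also handles the shape a hard
ecological threshold actually produces — near-zero richness below the
threshold and a plateau above it, i.e. a step. A continuous hinge cannot
represent a step, and its best-RSS join lands mid-plateau, well above the
true threshold; the independent-segment fit recovers the generated
threshold to within the grid spacing. A curve whose two-segment
fit improves on a single line by less than 5% of its RSS is flagged
unidentified (a linear partial dependence has no breakpoint). Uncertainty
comes from 200 bootstrap resamples of the curve points.

## The synthetic-world generator

The generator is first-class, tested code; its defaults are the study
conditions everything else is validated against.

* **Bathymetry.** Three meridional ocean sectors bounded by coastlines:
  a land strip, a shelf reaching 200 m about 1.25 degrees off the coast, a
  slope to ~4,400 m by 2.5 degrees, and an abyssal plain with smooth seeded
  relief (sectors must be at least ~6 degrees wide for an abyssal plain to
  exist). The Arctic (north of 70 N) is generated at 45% depth, mirroring
  its real shallowness. Worlds are byte-for-byte deterministic under the
  config seed.
* **Environment.** Temperature is a deep profile crossing the configured
  threshold at |lat| = 60 plus a surface-intensified layer decaying over
  ~500 m, floored at -1.9 degC; NPP peaks at temperate latitudes (distinct,
  by design, from temperature's equatorial peak, so the two drivers are
  separable); POC flux is the Martin-curve export
  $0.1\,\mathrm{NPP}\,(z/100)^{-0.858}$ of surface NPP to the floor;
  salinity is near-constant with one step at 1,500 m (a water-mass proxy);
  nitrate and silicate are built collinear ($r > 0.7$) to exercise the
  screen. Nuisance fields carry only weak latitudinal structure; strong
  smooth nuisance fields would act as spatial coordinates that a forest
  can memorise, confounding importance recovery.
* **Assemblage.** Species draw one of six archetypes (tropical/anti-tropical
  shelf, tropical/bimodal bathyal, cosmopolitan abyssal, polar endemic) as
  latitude x depth rectangles, then clip to habitable bins. A bin is
  habitable only if at least one sea-floor node in the species' realm
  sector lies inside its depth window — range overlap with the envelope is
  not enough, since a bin whose floor brackets but never enters the window
  holds no habitat and could never yield a record. With a thermal clip
  enabled, species living wholly below 2,000 m are additionally restricted
  to latitudes with deep-water temperature at or above the threshold;
  with a placement bias, range centres are drawn proportionally to a named
  environmental field to the 4th power (and ranges narrowed), producing
  worlds whose richness gradient is genuinely driven by a known variable.
* **Sampling.** Records are drawn multinomially over (species, node) pairs
  with weight $\exp(\beta\,[g_{lat} + g_{depth}])$, where the modes sit at
  45 N and at the surface and $\beta$ is the effort-bias strength (0 =
  uniform). The expected-count field integrates exactly to the configured
  sample size. A third of depths are withheld uniformly at random —
  the generator states only the missingness rate, deliberately, because
  nothing more is known about its structure.

What the generator does **not** emulate: realistic coastline geometry,
ocean circulation, temporal dynamics of collection effort, taxonomic
mis-identification structure beyond the planted-contaminant mechanism, and
spatially structured depth missingness. Tests passing on these worlds show
the pipeline's rules and estimators are implemented correctly and
recoverable under known truth — not that any particular empirical pattern
in real data is correct.

## Numerical choices and degenerate inputs

* Latitude bins are half-open $[b, b+1)$ labelled by the southern edge;
  depth bins are half-open with a species' closed depth interval
  intersecting bin $[l, u)$ iff $l < d_+$ and $u > d_-$ (so a 0–100 m
  species fills exactly ten 10-m bins). A degenerate depth interval falls
  back to the bin containing it.
* Report percentages round half-up to one decimal, the convention of the
  compilations these reports mirror.
* Sorenson similarity of two empty faunas is an error, not 100.
* A zero-variance predictor is centred but not scaled (flagged), and is
  excluded from collinearity screening.
* Forests and bootstraps are reproducible under explicit seeds; the
  generator never disturbs the caller's RNG stream.

## Problem sizes

The test suite and the acceptance script run on compact study conditions
chosen to keep the whole pipeline exercised: worlds of 160–300 species on
18–21 degrees of longitude at 0.5-degree bathymetric resolution with
6,000–12,000 records, 20-seed replicate batteries for the stochastic
recoveries, and 200 random instances for the interpolation oracle. These
sizes give the recovery statistics comfortable margins while keeping a
full run in minutes; they are scale models of the global setting (full
longitude, hundreds of thousands of records), not reproductions of it.

## Known limitations

* The AR(1) inflation corrects standard errors, not coefficients, and
  assumes a single autocorrelation scale along latitude.
* The Poisson pseudo-r2 is the squared correlation of fitted and observed
  values, labelled as such wherever reported.
* No multiple-testing correction is applied across strata or regions;
  per-model z-tests are reported as-is.
* Range interpolation never extrapolates beyond observed latitudinal
  extremes, so a species' recovered span is conservative where its range
  edges are unsampled.
* Province geometries are rectangles; real ecoregion polygons would slot
  into `assign_species()` through the same interface.
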