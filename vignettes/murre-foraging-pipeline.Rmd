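---
title: "Methods: the murre foraging biologging pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the murre foraging biologging pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the models, the tunable parameters, the
numerical choices, and the limits of the `murreforage` analysis chain.
It is the package's own account of its methods; every number shown by
the code examples in the README is produced by running the package.

## The behaviour model

Thick-billed murres at a breeding colony cycle through four behaviours
that leave distinct biologger signatures: resting at the colony (zero
wing-beat, zero depth, distance pinned at the colony), commuting flight
(~8–9 Hz wing-beats), surface swimming, and diving. We classify each
GPS fix with a hidden Markov model over
`{COLONY, FLY, SWIM, DIVE}` observing four channels: wing-beat
frequency (Hz), pitch (degrees), per-fix depth (m) and distance from
the colony (km).

**Emission families.** The three non-negative channels contain exact
zeros with high probability in most states (depth is exactly zero
outside dives, wing-beat zero when not flying), so each uses a
zero-inflated gamma: a point mass `pi0` at zero and a
`gamma(shape, rate)` density on the positive part. Pitch is normal.
Channels are conditionally independent given the state. These families
are a package design choice — the field standard is to pick emission
families per data stream, and zero inflation handles the exact zeros
natively rather than through ad hoc jitter.

**Stream fusion.** The GPS stream (1 fix per 1 or 3 min) and the depth
stream (1 Hz) have different rates. Depth is summarized to the fix
interval (maximum depth within the interval) before classification, so
the HMM sees one observation row per fix. The full-rate depth trace is
still used for dive detection.

**Fitting and decoding.** `fitHMM()` runs Baum–Welch EM over multiple
deployments as independent sequences sharing one parameter set. The
M-step for the zero-inflated gamma solves the weighted gamma likelihood
equation `log(shape) - digamma(shape) = s` by Newton iteration to
convergence; the shape is capped at `1e4` because a channel whose
positive support collapses to a point would otherwise spike the density
without bound (the usual unbounded-likelihood degeneracy of
continuous mixtures). Within that constrained family the M-step is an
exact maximizer, so the total log-likelihood is non-decreasing — the
package asserts this at every iteration and aborts on violation. A
state whose total responsibility falls below `1e-8` raises a
degenerate-state error naming the state. Initialization is either a
hand-specified model (`defaultHMMSpec()`) or k-means on the channels
(`initialSpecKmeans()`), with optional seeded random restarts.
`decodeBehavior()` is exact Viterbi (ties broken toward the earlier
state in the fixed order COLONY < FLY < SWIM < DIVE, for determinism),
and the reported log-likelihood is the scaled forward marginal.
`decodeFleet()` runs the same recursions jointly over a fleet of
equal-length deployments and is bit-identical to per-bird decoding.

Both the forward likelihood and the Viterbi path are tested against
exhaustive enumeration over all state paths on short sequences (200
random 2–4-state models), and EM is tested for transition recovery
within ±0.05 on 20 simulated two-day deployments.

## Trips, dives, bouts and the foraging rule

- **Dive detection** (`detectDives`): a dive is a maximal run of 1 Hz
  depth samples at or below `diveDepthThresholdM` (default 1 m — ten
  times the 0.1 m sensor resolution; the threshold is a package choice,
  exposed in the configuration). Runs separated by at least one surface
  second are distinct dives.
- **Bouts** (`groupBouts`): a new bout starts when the surface gap
  between consecutive dives exceeds the post-dive interval (default
  5 min). A gap *exactly* equal to the interval stays in-bout; the
  boundary convention is stated because the defining criterion alone
  does not fix it.
- **Trips** (`segmentTrips`): maximal intervals of non-COLONY decoded
  behaviour. Trips cut by a deployment edge are flagged truncated; they
  contribute dives and distance but are excluded from duration-based
  means.
- **Foraging classification** (`classifyForaging`): a trip is foraging
  if it has more than one dive, or exactly one dive strictly deeper
  than 18.1 m (the across-year median maximum dive depth); single
  shallow dives near the colony are treated as preening, not foraging.
- **Deployment summaries** (`summarizeDeployment`): five foraging
  metrics over foraging trips and eight diving metrics over dives in
  foraging trips (a switch allows all dives, since the source analyses
  do not state which convention they used); per-day rates divide by
  deployment days; metrics are reported missing — not zero — when no
  foraging trips or dives exist.
- **Behavioural sexing** (`sexFromAttendance`): females sit on the nest
  between 23:30 and 03:30, males between 11:30 and 15:30. The clock for
  these windows is not fixed by the rule itself; the package uses local
  solar time, `UTC + longitude/15`, as the reproducible choice, and
  operationalizes "consistently" as ≥ 80% of window fixes in COLONY on
  every observed night (configurable). A bird satisfying both or
  neither window is UNDETERMINED, as is any deployment under 24 h.

## Energetics

`dee()` computes activity-budget daily energy expenditure with
per-activity rates (kJ/h) of 32 (colony), 532.8 (flying), 100.8
(swimming) and 97.2 (diving), scaled by 24 over the deployment
duration. Each fix contributes its inter-fix interval to its decoded
state; the last fix contributes the median interval. Time not covered
by the four behaviours contributes zero energy but stays in the
denominator (gaps are not addressed by the defining equation; the
alternative — renormalizing over classified time — is exposed as a
flag).

## Space use

Dive-state fixes are projected to an azimuthal-equidistant plane
centred on the colony (the projection is a package choice; radial
distances from the colony are preserved exactly, which is the relevant
geometry for a central-place forager). `kdeUD()` places an isotropic
bivariate normal kernel of SD `h` on each point, evaluated on a grid of
800 m cells padded three bandwidths beyond the point bounding box, and
renormalizes so the density integrates to exactly 1. The default
bandwidth is the ad hoc reference rule
`h_ref = ((sd_x + sd_y)/2) n^(-1/6)`.

Isopleths are computed by ranked-cell accumulation: the area of the
smallest set of cells reaching the target fraction of the mass. This
makes nesting (50% ⊆ 95%) automatic and avoids contouring ambiguity.

Bhattacharyya affinity is `sum(sqrt(p1 * p2)) * cell^2` on a common
grid. Because the source definition compares the *95% utilization
distributions*, the default masks both UDs to their 95% isopleths and
renormalizes before the sum; whether the originals renormalized is not
stated, so the unmasked variant is one flag away
(`maskFraction = NULL`). UDs on different grids are resampled to the
union extent at the finer cell size by nearest-cell lookup and
renormalized.

## Environmental covariates

`radiusMask()` selects raster cells whose centres lie within a
great-circle radius (default 130 km, the maximum foraging range) of the
colony, boundary inclusive. `deploymentMean()` averages the masked
cells over every calendar day intersecting the deployment window —
partial days count, since the averaging definition gives no partial-day
rule — excluding missing cells. Weighting is unweighted by default
(cos-latitude area weighting is a flag); at 130 km scale the difference
is far below the field noise. All distances in the package use the
haversine formula on a 6371 km sphere: the projection used by the
original processing is unstated, and the sphere-vs-ellipsoid error at
this scale is under 0.5%.

## PCA, rotation and scores

`pcaKaiser()` runs PCA on the correlation matrix (metrics are
standardized to zero mean, unit variance), retains components with
eigenvalue above the Kaiser threshold (default 1), and varimax-rotates
when two or more are retained. The rotation (`varimaxRotate`) is the
classical iterative pairwise-planar-angle algorithm with Kaiser row
normalization; the criterion trace is returned and non-decreasing, and
orthogonality preserves per-variable communalities to 1e-10. It is
cross-checked in the tests against `stats::varimax` as an independent
reference, never used as the implementation.

Two conventions are fixed because the underlying quantities are
arbitrary up to them: each component's largest-magnitude loading is
made positive (published loading signs depend on an unrecoverable
convention; interpretation is invariant), and scores use the regression
method, `Z %*% solve(R) %*% L`, with a pseudo-inverse so rank-deficient
correlation matrices (perfectly correlated metrics) still score. The
"strongly loaded" reporting cutoff is |loading| ≥ 0.5, configurable,
since no numeric cutoff is stated in the source. The PCA pools all
deployments per metric set by default; stratified runs are a matter of
subsetting the input table.

## Biomarkers and model selection

The foraging-success score is `delta = log(post) − log(pre)` in natural
logs ("log" without a base is read as natural). Assay QC follows the
standard control-sample definitions: intra-assay CV is the mean over
plates of within-plate `100 sd/mean`; inter-assay CV is `100 sd/mean`
of plate means.

The model-selection layer mirrors the field workflow: VIF/GVIF
screening (`car::vif`; a 1-df term fails above 5, a multi-df term when
`GVIF^(1/(2 df))` exceeds 2.2; offenders removed iteratively,
interactions before main effects, worst first), maximum-likelihood fits
of every candidate (`lme4` mixed models with a bird random intercept
when repeats exist, otherwise `lm`), AICc ranking with
`AICc = −2 logLik + 2k + 2k(k+1)/(n−k−1)` where `k` counts fixed
effects plus variance components (conventions differ, so the choice is
stated), Akaike weights, a likelihood-ratio ANOVA of the top model
against the null, Nakagawa marginal and conditional R², and a REML
refit with Satterthwaite t-statistics via `lmerTest` (the denominator
degrees-of-freedom method is a documented choice). A singular REML
refit falls back to the fixed-effects model and is flagged. No
multiple-testing correction is applied across responses, matching the
per-model workflow it reimplements.

## The synthetic generator

`simulateDeployments()` emulates the study protocol: ~2-day
deployments, GPS fixes every 180 s (60 s allowed), a colony at
62.95°N / 82.01°W, about two foraging trips per bird-day of ~6 h,
lognormal maximum dive depths with log-location `log(18)` (median
18 m), dives packed into bouts with 20–100 s surface gaps (within the
5-min criterion) and bouts separated by longer gaps, sex-specific diel
colony attendance in local solar time, and wing-beat/pitch drawn from
the generating HMM's per-state emissions. Within-trip behaviour
switches between swimming and diving by the scenario's Markov chain,
bracketed by forced flight commutes — a first-order chain at fix
resolution, matching the decoder's model class so parameter-recovery
tests are well-posed. Trip scheduling is a renewal process whose gap
mean is corrected for trip duration and the expected delay when a start
would fall inside the attendance window, so the realized trips/day
matches the nominal rate.

Planted effects enter twice, both recoverable by the inference layer:
multiplicatively on the per-bird trip rate
(`rate_i = rate * exp(effect * z_i)`) and additively on the biomarker
log-ratio (`log(post) = log(pre) + sum(effect * covariate) +
N(0, noiseSd)`). The seasonal ice and SST covariates follow the same
deterministic curves as the simulated rasters (ice declining, SST
rising over June 15 – August 15), so covariates extracted through
`envCovariates()` recover the planted values up to raster noise.

What the generator does **not** emulate — and hence what passing tests
do not demonstrate about real data: GPS error and fix loss, dive-shape
variety (dives render as symmetric V profiles, the simplest shape with
unambiguous maximum depth and duration), prey patches and
autocorrelated foraging site fidelity, weather-driven behaviour, and
oceanographically realistic ice dynamics. Default scenario values not
fixed by the emulated protocol (trip rate 2/day, mean trip duration
6 h, bout size ~8, biomarker noise SD 0.2) were chosen once as
field-plausible magnitudes for this species and are not tuned.

## Problem sizes and determinism

Every stochastic routine takes or derives from an explicit integer
seed, and identical seeds give bit-identical output. The test suite
exercises the chain at sizes chosen to make sampling error small
relative to the tested tolerances while keeping the default run quick:
exhaustive-oracle HMM checks on sequences up to length 10 (path spaces
up to ~3×10⁵), EM recovery on 20 × 960-fix deployments, KDE convergence
at n = 2000 points, and the end-to-end planted-effect check on 100
seeds × 100 birds decoded with `decodeFleet()`.

## Known limitations

- The HMM is first-order Markov at the fix interval: no semi-Markov
  dwell times, no covariate-dependent transitions.
- Raw accelerometry is out of scope; wing-beat frequency and pitch
  arrive as per-fix features.
- The isopleth areas are cell-count areas, not smoothed contour
  polygons; at 800 m cells the difference is one cell ring.
- LMM support covers the single random intercept used by the workflow;
  crossed or nested random effects are not implemented.
- The CLI is intentionally absent: the package's functions, this
  vignette and `scripts/acceptance.R` are the interface.
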