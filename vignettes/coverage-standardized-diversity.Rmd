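---
title: "Coverage-standardized diversity, turnover and drivers: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coverage-standardized diversity, turnover and drivers: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(quorumdiv)
```

This vignette is the package's account of its methods: the estimators it
implements, the assumptions behind them, the parameters that matter, the
numerical conventions, and what the synthetic benchmarks do and do not
demonstrate.

## The data model and time binning

The unit of observation is the *occurrence*: one published, genus-level
body-fossil record tied to a collection (a locality/horizon sample), a
publication, optionally a geological formation, and an age range
`[min_ma, max_ma]` in Ma. Genus names are canonicalized before counting:
open-nomenclature qualifiers ("aff.", "cf.", "?") are stripped so
qualified material counts under its genus, parenthetical subgenera are
removed, whitespace is collapsed and case is folded. Only these
documented qualifiers are handled; informal designations such as
"ex gr." pass through as-is.

Bins are closed intervals `[top_ma, base_ma]`, contiguous and ordered
oldest-first. An occurrence enters a bin only if its entire age range
lies inside it (inclusive at both boundaries); anything spanning a
boundary stays unassigned. This is deliberately conservative: it trades
sample size for the guarantee that no occurrence is counted in two bins
and that temporally uncertain material never smears across intervals. A
degenerate range that is exactly the point shared by two bins goes to the
*older* bin — the same convention by which a stage includes its base —
so the assignment is deterministic.

Two conventions differ on purpose for empty bins: diversity metrics
report `NA` (an empty bin is a gap in knowledge, not zero diversity),
while sampling proxies (formation and collection counts) report 0,
because a proxy counts opportunities to sample and an interval genuinely
can offer none. Realm tallies of proxies are not exclusive: a formation
that has yielded both marine and non-marine fossils counts toward both
realms' formation counts, since it represents an opportunity to sample
each.

Regions outside the six canonical levels (Africa, Asia, Europe,
SouthAmerica, NorthAmerica, Other) map to `Other` and participate in
global analyses only; regional partitions exclude them.

The built-in Jurassic–Cretaceous stage scheme uses Gradstein et al.
(2012) boundary ages (201.3–66.0 Ma). For the coarser scheme the
literature says only "approximately equal 10 Myr bins"; this package
divides the same span uniformly into 14 bins of ~9.66 Myr
(`jk_tenmyr_bins()`). Analyses tied to a specific published binning
should supply their own scheme via `read_bin_scheme()`.

## Good's *u* and SQS

Coverage of a bin's sample is estimated by Good's
`u = 1 − n1/N`: `N` occurrences, `n1` singleton genera. By default a
singleton has exactly one occurrence; `singleton_mode = "by_reference"`
instead counts genera known from a single publication, which guards
against one intensively published locality inflating apparent coverage.
`u` is `NA` for empty bins and 0 when every genus is a singleton.
The default estimate is the direct formula on the whole bin;
randomized-subsample averaging of `u` exists in the literature but the
subsample size is never stated, so the deterministic formula is the
default here.

An SQS trial draws *collections* — not individual occurrences — in
random order. The draw unit matters because the publication rule operates
on collections: whenever a collection from a new publication is drawn,
further collections from that publication are drawn until three have been
selected or the publication is exhausted (`pubs_cap`, default 3). This
mimics the clumped way the literature samples localities, and damps the
influence of single monographs. After each collection, every genus not
seen before in the trial adds its *share* — its occurrence frequency in
the whole bin — to accumulated coverage; the trial stops when coverage
reaches the target and reports the number of distinct genera drawn.

With deflation on (default), the stopping target is `q/u` rather than
`q`: the summed raw shares of a full bin equal 1 by construction while
the bin's true coverage of the underlying frequency distribution is only
about `u`, so a raw target of `q` would overshoot in well-sampled bins.
A consequence is that bins with `u < q` can never reach the target and
are automatically reported `NA`, which is exactly the "sampling failure"
convention used when reporting standardized curves. Trials are failures,
not zeros, in that case; a bin is `NA` when all trials fail, and partial
failures average the successful trials only.

`exclude_dominant` (off by default) drops the single most frequent genus
from coverage accumulation and adds one to the returned richness — a
variant used to blunt the influence of a hyper-dominant taxon. It is
provided for sensitivity work, not as the default, because published
descriptions of the modified procedure are incomplete.

Randomness: one integer seed in `sqs_config()`; each bin (and each
bootstrap resample) derives its own substream deterministically, so
results do not depend on the order in which bins are processed, and
identical configs are bit-for-bit reproducible.

The bootstrap resamples collections with replacement to the original
collection count, re-estimates coverage per resample, reruns the whole
SQS estimate, and reports percentile intervals of the resample means.
A bin with one collection collapses to a zero-width interval. The test
suite checks calibration against the long-run SQS mean of a known
generative process at 15 collections per bin; with many fewer collections
percentile intervals undercover, as small-sample bootstraps generally do.

## Turnover rates

`compile_taxon_ranges()` builds per-genus first/last appearance bins and
the set of bins with actual samples; range-through presence fills
internal gaps. Foote boundary-crosser tallies per bin — `Nbt` (cross
both boundaries), `NbL` (enter, last appear), `NFt` (first appear, leave),
`NFL` (confined singletons) — give
`q = −ln(Nbt/(Nbt+NbL))` and `p = −ln(Nbt/(Nbt+NFt))`, `NA` when no taxon
crosses both boundaries. Singletons are tallied but never enter either
rate, so no extra singleton culling is applied. Rates are per bin by
default with a `per_myr` flag, since the stages around the J/K boundary
are of similar length (3.8–5.3 Myr); both variants are available because
published analyses rarely state which they used.

Three-timer rates use sampled bins only (no range-through):
`μ_i = ln(2tb_i/3t_i) + ln(Ps_{i+1})` and
`λ_i = ln(2ta_i/3t_i) + ln(Ps_{i−1})`, where `2tb`/`2ta` count genera
sampled in the bin and its older/younger neighbour, `3t` in all three,
and `Ps = 3t/(3t+pt)` is the implied sampling probability (`pt` counts
genera sampled either side but not within). Which neighbour's `Ps`
corrects which rate follows the convention fixed here: the correction
compensates for taxa that survived (or already existed) but were missed
in the adjacent bin whose sampling is in question. Where a bin's
`3t + pt = 0` the pooled `Σ3t/(Σ3t+Σpt)` substitutes; end bins, lacking a
neighbour, are always `NA`. Under complete sampling the two estimators
are algebraically identical on a discrete birth–death record, which the
test suite exploits as a cross-check.

## Driver models

Environmental series at stage resolution are rebinned by the unweighted
arithmetic mean of points whose stage midpoints `(base+top)/2` fall in
each target bin. Every series — response and candidates — is then
detrended by a maximum-likelihood AR(1) fit with intercept
(`stats::arima(order = c(1,0,0), method = "ML")`). ML fitting is the
point: internal `NA`s are handled by the Kalman likelihood rather than
imputed as zeros, which matters for curves with sampling gaps. At least
4 observed points are required; constant series short-circuit to zero
residuals; near-unit-root series that leave the ML Hessian singular are
refit without the stationarity transform (and by CSS-ML if the
coefficient still sits at the boundary).

Each candidate's residuals enter an OLS regression against the response
residuals over jointly observed bins. Model support uses
`AICc = −2L + 2k + 2k(k+1)/(n−k−1)` with `k = 3` (intercept, slope,
residual variance) — the literature states AICc but not `k`, so it is
fixed and documented here — and a minimum of `n = 5` joint observations
so the correction term stays positive. Candidates below the minimum are
reported `NA` and excluded from weight normalization; Akaike weights sum
to one over the remaining set, and both the raw log-likelihood and the
relative likelihood `exp(−Δ/2)` are emitted since published tables are
ambiguous about which they print. Pearson and Spearman tests run on the
same residual pairs; Benjamini–Hochberg adjustment applies within
*families* of tests, by default all tests sharing one response curve —
the family partition is configurable because published analyses rarely
enumerate theirs.

## The synthetic generator

`simulate_true_world()` runs a discrete birth–death: per bin, each taxon
survives with probability `1 − mu` and new taxa are Poisson with mean
`lambda × richness`. Note `mu` is a per-bin *probability*; the matching
per-capita rate recovered by the estimators is `−ln(1 − mu)`.
`simulate_fossil_record()` layers on the sampling structure the
estimators assume: collections clustered into publications (heavy-tailed
publications per bin, skewed collections per publication, exercising the
three-per-publication rule), occurrences drawn from the living taxa under
a geometric (default parameter 0.5, singleton-heavy, stressing Good's
*u*) or lognormal rank-abundance distribution, per-bin effort
multipliers, and age ranges strictly inside the generating bin so strict
binning loses nothing. `simulate_driver_series()` constructs a driver
with `richness = a·driver + AR(1) noise` plus independent AR(1) decoys.

What the generator does *not* emulate: spatial structure and
palaeogeography, heterogeneous taxon-level preservation, age-model error
that straddles bin boundaries (real compilations lose a third of
occurrences to strict binning; synthetic records lose none), taxonomic
error, and Lagerstätten-style correlated preservation. Passing benchmarks
therefore show the estimators behave as designed under their own
assumptions — not that real curves are unbiased.

## Benchmark designs and problem sizes

The test suite fixes these study conditions:

- *Enumeration oracle*: bins of ≤ 5 collections, where the expectation
  over all collection orderings is computed exactly and compared with the
  Monte-Carlo mean at 10,000 trials (agreement within 1%).
- *Estimator-bias experiment*: constant true richness of 1200 genera,
  lognormal rank abundance (`sdlog = 2.5`), 25 collections × Poisson(8)
  occurrences per bin, effort ramp ×1→×3 across 10 bins, 100 replicate
  records. The genus pool is large and heavy-tailed on purpose: raw TDE
  stays effort-driven (≥ 2-fold median variation) while coverage stays
  above the 0.6 quorum in every bin; flatness of SQS is judged on
  per-bin medians across replicates (within 15% of flat), which isolates
  estimator bias from single-record noise.
- *Rate recovery*: 250-taxon birth–death record, extinction probability
  0.2/bin, completely sampled; both estimators' median absolute error
  against `−ln(0.8)` over interior bins.
- *Driver recovery*: 15-bin worlds, true coefficient 0.8, noise scaled to
  SNR 2.5, 4 decoys, 200 replicates (top weight to the true driver
  ≥ 80% of the time); null calibration with 6 decoy-only candidates —
  six, matching the size of a typical environmental candidate set — over
  200 replicates (no decisive weight > 0.5 in ≥ 70%).
- *AR(1) recovery*: 500 series of length 200 at `phi = 0.7`; Wald 95%
  intervals cover the truth ≥ 90% of the time.

`scripts/acceptance.R` recomputes all of these from scratch under a
user-supplied seed.

## Known limitations

- SQS returns trial means; between-trial SD understates real uncertainty,
  which is why the bootstrap exists. Percentile intervals undercover for
  bins with very few collections.
- Three-timer rates are undefined at scheme ends and degrade quickly when
  within-bin sampling is sparse; the analysis scripts show this
  deliberately on an incompletely sampled record.
- AICc comparison with `n` around 12–15 bins has real false-confidence
  mass: even with no true driver, one of six candidates draws weight
  > 0.5 in roughly a third of replicates. Weights should be read as
  relative support within the candidate set, never as posterior
  probabilities of a causal claim.
- Genus canonicalization is string-level only; synonymy resolution is out
  of scope.
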