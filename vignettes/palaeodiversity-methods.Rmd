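---
title: "Methods: sampling-corrected palaeobiodiversity through the J/K transition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sampling-corrected palaeobiodiversity through the J/K transition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crocdiv)
```

## The problem

The crocodyliform fossil record through the Jurassic/Cretaceous (J/K,
~145 Ma) transition is heavily and unevenly sampled: some intervals are
documented by hundreds of collections, others by a handful of singleton
occurrences. Raw per-bin taxon counts (the taxonomic diversity estimate,
TDE) therefore confound genuine diversity dynamics with sampling effort.
`crocdiv` implements the standard battery of corrections used to read
through this noise — coverage-standardised subsampling (SQS), phylogenetic
diversity on time-scaled trees (PDE), sampling-corrected extinction and
origination rates — together with maximum-likelihood model comparison of
candidate environmental drivers, and a synthetic fossil-record generator
with known truth against which every estimator in the package is validated.

## Time bins

Two built-in schemes span 201.3-66 Ma: `stage_bins()` (23 Jurassic +
Cretaceous stages, GTS2012 boundary ages) and `tenmyr_bins()` (14 composite
bins, J1-J6 and K1-K8, formed by pooling adjacent stages into roughly
10-Myr blocks; the groupings are approximations since stage durations do
not divide evenly). J6 is the Tithonian, K1 the Berriasian-Valanginian,
K2 the Hauterivian-Barremian. Every analysis takes the scheme as an
argument, so alternative boundary tables (e.g. newer timescale calibrations)
are drop-in via `read_bin_scheme()`.

Bins are half-open with the older bound inclusive: an age `a` lies in the
bin with bounds `(older, younger]` in age terms, so an occurrence dated
exactly to a boundary belongs to the younger-starting bin whose older bound
it equals, and nothing is double counted. The youngest bin additionally
contains its own younger bound. Under the `constrained` binning policy an
occurrence is kept only when its whole age range fits one bin; under
`unconstrained` it is kept with its full candidate-bin set, and stochastic
consumers (the SQS trials) resolve the ambiguity independently per trial by
a uniform draw — temporally uncertain occurrences contribute without ever
being counted twice.

## Coverage-standardised diversity (SQS)

Comparing raw richness between bins of unequal sampling is meaningless;
SQS instead standardises bins to equal *coverage* — the share of the
underlying occurrence frequency distribution accounted for by the taxa
drawn. Coverage of a bin's observed record is estimated by Good's u,
`1 - s1/O` (singletons over occurrences), optionally in the
dominant-corrected form `1 - s1/(O - n_dominant)`.

A subsampling trial draws whole collections in random order; each newly
encountered taxon credits its frequency share once; drawing stops when the
accumulated share reaches `q/u`, so that the quorum `q` refers to coverage
of the *true* frequency distribution rather than the observed one. The
reported value is the count of qualifying taxa drawn, averaged over trials.
Defaults follow the published algorithm and the study design this package
re-implements:

* quorum `q = 0.4`, 1000 trials (the plain dialect defaults to 100
  replicates of 1000 trials, with per-replicate means retained);
* the most frequent (dominant) taxon is **counted** in the tally but its
  share is **withheld** from the quorum accumulation, with the remaining
  shares taken relative to the non-dominant total and u computed in the
  dominant-corrected form. Without this, a single very abundant taxon can
  satisfy the quorum on its own and truncate every subsample — the exact
  pathology the published method guards against. Both behaviours are
  config flags (`dominant_share`, `correct_dominant`);
* in-bin singletons are excluded from the tally (`exclude_singletons`),
  a singleton being a taxon with one *occurrence* in the bin (not one
  collection);
* the `throttled` dialect additionally caps publication pressure: once a
  collection from a new publication is drawn, further collections from
  that publication are drawn until exactly `pubs_cap = 3` have been
  selected, and capped publications contribute no more. The `plain`
  dialect has no such restriction; the two coincide whenever no
  publication exceeds the cap, which the tests verify by exhaustive
  enumeration of draw orders.

Bins whose coverage is undefined (empty), zero (all singletons — which
does happen in the real record) or below the quorum return `NA` rather
than a downward-biased number.

## Phylogenetic diversity (PDE)

PDE counts, per bin, the lineages implied by a time-scaled tree: every
edge, extended at the tips to each taxon's last appearance, contributes to
the bins its span intersects. Ghost lineages — branch segments older than
their taxon's first appearance — are counted automatically, so PDE is
bounded below by the sampled in-bin count.

Trees are dated a posteriori from tip first appearances: each node takes
the oldest FAD among its descendants, which necessarily creates zero-length
branches along the path to the taxon that dates each node. Three policies
deal with polytomies and zero branches:

* **equal** — topology untouched; each run of zero-length branches shares,
  equally, the duration of the first ancestral branch of positive length.
  The stem above the root (default `root_extension = 5` Myr; the value is
  arbitrary, carried in the output metadata, and only stretches the oldest
  lineage) supplies slack at the root. Runs are processed shallowest-first
  in a canonical order so the result is invariant to tip input order; when
  no ancestral slack exists the branch stays at zero and is flagged.
* **random** — polytomies resolved uniformly at random, then basic dating.
* **ordered** — polytomies resolved so lineages branch in order of first
  appearance (oldest first, a caterpillar), ties broken at random.

The headline PDE is the mean of the three policies, the stochastic two
averaged over `n_resolutions = 100` seeded resolutions each
(`pde_estimate()`). Genus-level analyses collapse species tips to one
lineage per genus spanning the pooled genus range (`collapse_to_genus()`;
keeping the earliest species' own range instead is a flag). Tips lacking a
last appearance are treated as point occurrences (`lad = fad`).

## Extinction and origination rates

`range_chart()` builds taxon-by-bin `sampled` and `range_through`
matrices. Two rate families are computed from them, both per-taxon and
per-interval:

* **Three-timer** rates correct for incomplete sampling:
  `mu(i) = ln(2T_bot(i)/3T(i)) + ln(Ps(i+1))` and
  `lambda(i) = ln(2T_top(i)/3T(i)) + ln(Ps(i-1))`, with `Ps = 3T/(3T+PT)`
  the per-bin sampling probability estimated from part-timers. The
  correction bin follows the standard formulation (the following bin for
  extinction, the preceding for origination); a pooled-Ps variant is a
  config option. Log corrections can push estimates negative; these clamp
  to zero with a flag.
* **Boundary-crosser (per-capita)** rates take the record literally:
  `q(i) = -ln(N_bt/(N_bt+N_bL))`, `p(i) = -ln(N_bt/(N_bt+N_Ft))`,
  ignoring single-interval taxa. They are conservative but back-smear
  extinctions and inflate near the series edges under incomplete sampling
  — a contrast the acceptance tests measure directly. Duration
  normalisation (`per_myr`) is off by default for three-timer rates
  (per-interval, as defined) and available for boundary-crosser rates
  where bins are unequal.

## Environmental driver models

Candidate covariates (sea level, del18O, del13C, del34S, 87Sr/86Sr,
formation counts, outcrop area, invertebrate diversity, ...) are
AR1-detrended before use: `x_t = c + phi x_{t-1} + e_t` is fitted by
Gaussian maximum likelihood conditional on the first observation (the
conditional ML is exactly least squares on the lagged pairs, a deliberate
simplification over the exact AR1 likelihood), and the residuals `e_t`
carry forward. Only the predictors are detrended by default — the
biodiversity response is used as-is — with double-detrending available as
a sensitivity flag.

Each candidate model (intercept-only null, every single predictor, every
pair when `combos = 2`) is fitted by ML Gaussian regression and ranked by
`AICc = -2 logL + 2k + 2k(k+1)/(n-k-1)`, where `k` counts intercept,
slopes and the residual variance. Akaike weights normalise support over
the candidate set. Bins with undefined response (e.g. zero-coverage bins)
drop listwise per candidate, so `n` varies by row and is reported; a
candidate with `n <= k+1` is skipped. `driver_report()` adds Pearson and
Spearman correlations per (metric, predictor) pair and flags a result
"strong" when the predictor carries the top weight *and* both correlation
p-values fall below 0.05 — the gate is tunable since different studies
draw the line differently. The likelihood column is `logL` (not -2logL),
recorded in the table's documentation.

## The synthetic fossil record

`simulate_ranges()` runs a discrete-bin birth-death process with bins as
unit intervals: a taxon alive in bin i dies there with probability
`1 - exp(-mu_i)`; new taxa arise as `Poisson(S_i (exp(lambda_i)-1))` with
`S_i` the standing diversity entering the bin. The `exp(lambda)-1` birth
intensity (rather than `lambda` itself) is chosen so that `lambda` is the
per-capita per-interval origination rate exactly as the boundary-crosser
and three-timer estimators define it: the expected fraction of
top-boundary crossers that originated within the bin is `1 - exp(-lambda)`.
Newborns take a full-bin survival draw — a convention that keeps the
per-interval rates exact at the cost of a slight inconsistency with their
uniform within-bin origination times. Event times are uniform within bins;
survivors at the end of the scheme are censored there.

`simulate_occurrences()` then samples the record: occurrence counts per
taxon-bin are `Poisson(r_i a_ij)`, where `r_i` is the per-bin sampling
intensity and `a_ij` a lognormal per-taxon-per-bin relative abundance
(log-sd 1.5, mean 1) — the skewed abundance distribution that
coverage-standardisation exists to handle; without it, raw counts are
nearly unbiased and comparing estimators is uninformative. Abundances are
redrawn per bin because a genus's relative abundance is not expected to
persist across multi-Myr intervals. Occurrences are clustered into
collections with lognormally skewed sizes and collections into
publications; the *number* of collections scales with the occurrence count
(mean 2.5 occurrences per collection, ~4 collections per publication),
matching real occurrence databases where better-sampled intervals yield
more collections, not bigger ones. (An early design with a fixed
collection pool per bin was rejected: collection size then grows with
sampling intensity and a single drawn collection can sweep in much of the
fauna, degrading SQS into a measure of occurrences-per-collection.)
A positive `age_smear` widens each occurrence's age range symmetrically,
creating the boundary-straddling records that exercise the unconstrained
policy.

`simulate_tree()` builds a topology consistent with origination order
(each new taxon buds from a uniformly chosen earlier taxon) and can
collapse a stated fraction of nodes into polytomies.
`simulate_driver_response()` couples a response to one covariate's AR1
residuals (`y = beta e_t + AR1(phi, sigma)` noise).

### The J/K-like scenario

`jk_scenario()` fixes the study conditions used throughout the tests:
200 initial taxa on the 14-bin scheme; background rates mu = lambda =
0.15 per interval; an origination ramp (lambda = 0.25) through J4-J6; a
single extinction pulse mu = 0.8 in J6; suppressed origination
(lambda = 0.05) through K1-K3; a strongly uneven sampling field
(r between 1.2 and 15 across bins, a ~12-fold range) with a five-fold
drop after the event (J6 at 15, K1-K2 at 3). Intensities are set high
enough that even the degraded post-event bins normally retain coverage
above the 0.4 quorum: the scenario's purpose is to compare estimators
where both are defined, and zero-coverage behaviour is exercised by
dedicated degenerate-input tests instead.

What the generator does *not* emulate: spatial structure and
palaeogeography, taxonomic error and synonymy, trait- or age-dependent
extinction, correlated sampling between adjacent bins, and real
collection-level taphonomy. Passing tests therefore demonstrate that the
estimators recover truth under the stated statistical structure, not that
any particular empirical curve is correct.

## Numerical choices and degenerate inputs

* Subsampling stops when the accumulated share reaches the target minus
  1e-12 (guarding float drift); trials on bins below quorum return `NA`.
* Equal-method redistribution treats branches shorter than 1e-8 Myr as
  zero; ties in slack contention resolve in a canonical
  (input-order-independent) order, alphabetical by the child clade's
  first tip label.
* Three-timer and boundary-crosser rates propagate `NA` where any needed
  count is zero (edge bins, empty bins, `N_bt = 0`); negative three-timer
  estimates clamp to zero with a flag rather than reporting negatives.
* A constant covariate has no identifiable AR1 coefficient: residuals are
  returned as zeros with a `constant` flag; correlation tests on
  zero-variance series return `NA` with a `degenerate` flag.
* All stochastic stages derive per-stage seeds from one master seed by a
  stable string hash (`stage_seed()`), so a pipeline rerun with the same
  configuration is byte-identical while stages remain individually
  reproducible.

## Problem sizes used in the validation suite

The shipped tests run at desk scale, chosen to keep each check's
Monte-Carlo error well inside its assertion margin: 20 seeds for the
estimator-vs-raw-counts and rate-recovery experiments (200 initial taxa);
1000 initial taxa for the undersampling bias comparison, where a smaller
record would let per-seed estimator variance mask the bias being measured;
1000 seeded small trees for the dating and ghost-lineage sweeps; 100
seeds for driver-model recovery over 14 bins; SQS at 100-1000 trials per
bin. `scripts/acceptance.R` recomputes the headline quantities from
scratch at these sizes.

## Known limitations

* The SQS dialects follow the published verbal descriptions; third-party
  scripts differ in small undocumented details (e.g. the exact handling of
  a quorum reached mid-publication-run), so numerical agreement with any
  particular legacy implementation is expected only up to such choices,
  all of which are exposed as flags here.
* PDE counts tree edges as lineages; under basic dating of random/ordered
  resolutions, stacked zero-length edges in a bin each count once, which
  can inflate PDE in old, poorly resolved parts of the tree — one reason
  the reported PDE averages the three dating policies.
* The conditional-ML AR1 fit drops the first observation's stationary
  density; for the short series typical of stage-level analyses this can
  differ noticeably from the exact likelihood, but keeps AICc values
  comparable across candidates by construction.
* Dataset-composition figures from the original study (occurrence,
  genus and collection counts per realm) require its archived occurrence
  dataset and supertree, which are inputs to — not products of — this
  package.
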