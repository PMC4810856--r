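# crocdiv

Sampling-corrected palaeobiodiversity analysis for the Jurassic–Cretaceous
crocodyliform fossil record — and, more generally, for any occurrence-based
fossil dataset binned into geological time intervals.

Raw per-bin taxon counts confound diversity with sampling effort. This
package implements the standard corrections used to read through that
noise, plus the model-comparison machinery to ask *why* diversity changed:

- **TDE** — uncorrected taxonomic diversity (distinct genera/species per bin);
- **SQS** — shareholder quorum subsampling: richness standardised to equal
  coverage of the occurrence frequency distribution, estimated by Good's
  *u* = 1 − *s₁*/*O*. Collections are drawn at random until the drawn taxa's
  accumulated frequency share reaches *q*/*u* (baseline quorum *q* = 0.4),
  in two dialects: publication-throttled (at most 3 collections per
  publication) and plain;
- **PDE** — phylogenetic diversity from time-scaled trees: per-bin lineage
  counts including ghost lineages, under equal / random / ordered polytomy
  handling, reported as the three-method mean;
- **Rates** — three-timer extinction/origination,
  *μ*ᵢ = ln(2T\_bot/3T) + ln(*P*ₛ(i+1)), with the part-timer sampling
  correction, and literal-reading boundary-crosser (per-capita) rates
  *q*ᵢ = −ln(N_bt/(N_bt+N_bL));
- **Drivers** — AR1-detrended environmental covariates compared against any
  diversity series by maximum-likelihood regression, ranked by
  AICc = −2 logL + 2k + 2k(k+1)/(n−k−1) and Akaike weights, with Pearson
  and Spearman correlation tests;
- **Synthetic records** — a discrete-bin birth–death generator with skewed
  taxon abundances, collection/publication clustering and per-bin sampling
  intensities, so every estimator is validated against known truth.

## Worked example

Simulate the built-in J/K-like scenario (an end-Jurassic extinction pulse
with a five-fold post-event sampling drop on a strongly uneven sampling
field), then compare the raw count against the coverage-standardised
estimate:

```r
library(crocdiv)
scheme <- tenmyr_bins()                      # J1-J6, K1-K8, 201.3-66 Ma
sim    <- simulate_scenario(jk_scenario(), seed = 1)
binned <- assign_to_bins(sim$occurrences, scheme, "constrained")
raw    <- tde(binned)
sq     <- sqs_estimate(binned, sqs_config(trials = 200, seed = 42))

data.frame(bin = scheme$label, truth = sim$truth$richness,
           tde = raw$value, u = round(sq$u, 2),
           sqs = round(sq$mean, 1), sd = round(sq$sd, 2))
#>  bin truth tde    u  sqs   sd
#>   J1   238 105 0.85 23.9 2.73
#>   J2   237 178 0.98 27.0 3.87
#>   J3   242 111 0.77 30.8 2.13
#>   J4   269 229 0.99 24.9 4.35
#>   J5   284 148 0.90 28.7 3.35
#>   J6   317 274 0.99 35.4 5.28
#>   K1   141  89 0.89 16.4 2.76
#>   K2   126  73 0.91 16.8 3.67
#>   ...
```

`truth` is the generator's standing richness, `tde` the raw in-bin genus
count (note how it whipsaws with the sampling field — J3 and J5 are not
really diversity lows), `u` the per-bin coverage, and `sqs` the mean
subsampled richness at quorum 0.4 over 200 trials with its standard
deviation. The quantity of interest, the diversity decline across the J/K
boundary (J6 → K1):

```r
#> TDE decline J6->K1: 68%; SQS decline: 54%; truth: 56%
```

The raw count overstates the crash (the post-event bins are also the
worst-sampled ones); the coverage-standardised estimate lands next to the
truth. Extinction and origination rates from the same record:

```r
r3 <- three_timer_rates(timer_counts(range_chart(binned)))
#>  bin    mu lambda
#>   J5 0.276  0.213
#>   J6 0.744  0.251      <- extinction pulse (true per-interval rate 0.8)
#>   K1 0.229  0.143
#>   K2 0.000  0.000      <- origination suppressed through K1-K3
```

Driver analysis against environmental covariate series, and the
whole-pipeline interface, follow the same pattern:

```r
rep <- driver_report(list(SQS = sq$mean), env_series_list)   # AICc weights + correlations
run_pipeline("config.yaml")                                  # YAML-driven, byte-reproducible
```

See the methods vignette (`vignettes/palaeodiversity-methods.Rmd`) for the
models, defaults and numerical conventions, and what the synthetic
generator does and does not emulate.

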