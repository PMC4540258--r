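# fadiet — diet inference from fatty acid signatures

`fadiet` estimates what an opportunistic predator eats from the fatty
acid (FA) composition of its adipose tissue.  It was built around the
Illinois river otter (*Lontra canadensis*) study system — a predator of
fishes, molluscs, frogs and crayfish — and implements the full analysis
chain of a quantitative fatty acid signature analysis (QFASA) study:

* **Signatures** — compositional FA signature libraries over up to 60
  bins: closure, zero replacement, group summaries in percent by mass,
  the predominant-FA statistic, and lossless CSV round-trip.
* **Peaks** — assignment of unidentified gas-chromatography peaks to FA
  bins by one-dimensional k-means on retention times, 1000 random
  restarts, keeping the run with the greatest variance explained
  (SS_between / SS_total).
* **Ordination** — correlation-matrix PCA on FA proportions,
  FA–component correlations, and per-component one-way ANOVA with
  Tukey-HSD-adjusted pairwise group comparisons.
* **QFASA** — diet proportions estimated by minimizing the symmetrized
  Kullback–Leibler distance between the predator signature *y* and a
  convex mixture of prey-taxon mean signatures,

  d(y, ŷ) = Σₖ (yₖ − ŷₖ) ln(yₖ / ŷₖ),  ŷ = close(c ⊙ M p),

  over the diet simplex p (Newton on a softmax reparameterization with
  an active-face polish), with per-FA calibration coefficients c
  (identity by default) and bootstrap means and standard errors over
  500 resamples of both predators and prey.
* **Synthetic studies** — a generator that reproduces the statistical
  structure of the study system (nine group signatures with published
  means and spreads, predators as noisy convex mixtures with known true
  diets, peak tables with known bin structure) so every stage is
  testable end to end.

## Worked example

Simulate a study at the otter system's sample sizes (46 predators whose
true diet is 37.7% fish, 32.0% mollusc, 27.3% frog, 3.0% crayfish; prey
libraries at the sampling-design counts) and recover the diet:

```r
library(fadiet)

study <- simulate_study(seed = 11)          # prey + predators + true diet
est <- bootstrap_diet(study$predators, study$prey, reps = 500, seed = 12)
est
#> diet_estimate (bootstrap, 500 reps):
#>   crayfish     6.4 +/- 4.4% (SE)
#>   frog        26.4 +/- 4.3% (SE)
#>   mollusc     31.7 +/- 2.7% (SE)
#>   fish        35.5 +/- 3.7% (SE)
```

Each taxon's line is the bootstrap mean diet proportion with its
standard error: the estimator recovers the simulated truth to within a
few points per taxon and ranks the rare component (crayfish) last.
Ordination separates molluscs from every other taxon on the first
principal component:

```r
pca <- run_pca(study$prey)
anova_tukey(pca, components = 1)
#>   component group_a  group_b     diff p_adj
#> 3       PC1 mollusc crayfish 6.011001 1e-16   (mollusc rows shown)
#> 5       PC1 mollusc     fish 4.520849 1e-16
#> 6       PC1 mollusc     frog 7.227138 1e-16
```

The packaged reference table reproduces the study's headline
composition statistic — the sample-size-weighted grand mean share of
the four predominant FA (16:0, 16:1, 18:0, 18:1) across all nine
groups:

```r
predominant_fa_reference()
#> [1] 55.98257
```

Peak binning on a synthetic 60-bin chromatogram set with realistic
retention drift recovers the true bins exactly:

```r
pt <- simulate_peak_tables(10, k = 60, spacing = 1, jitter_sd = 0.02, seed = 3)
assign_peaks(pt$peaks, k = 60, restarts = 1000, seed = 4)
#> peak_assignment: 60 bins, 1000 restarts, VE = 1.0000
```

A thin command-line wrapper over the same functions lives at
`inst/cli/fadiet.R` (subcommands `simulate`, `assign-peaks`, `pca`,
`estimate-diet`, `summarize`, `predominant-fa`, `pipeline`).

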