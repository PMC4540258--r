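---
title: "Diet inference from fatty acid signatures: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Diet inference from fatty acid signatures: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fadiet)
```

## The problem

A predator's adipose fatty acid (FA) composition reflects its diet
integrated over weeks to months, because many dietary FA are deposited
with limited modification.  Quantitative fatty acid signature analysis
(QFASA) exploits this: given mean FA signatures for a set of candidate
prey taxa, the diet is estimated as the mixing vector that makes the
modelled mixture of prey signatures as close as possible to the
predator's signature.  `fadiet` implements this chain for the river otter
(*Lontra canadensis*) study system — an opportunistic predator of fishes,
molluscs, amphibians and crayfish — together with the upstream steps
(chromatographic peak binning, signature management, ordination) and a
synthetic-data generator that makes every stage testable without raw
per-individual data, which were never deposited for this system.

## Compositional signatures

A signature is a composition: non-negative proportions over a fixed,
ordered set of FA bins summing to one (closure).  Internally everything
is a fraction; summaries and reports use percent by mass, the
conventional presentation.  Two operations matter numerically:

* **Closure** (`normalize_composition`) after any transformation.
* **Zero replacement** (`replace_zeros`): log-ratio distances are
  undefined at zero, so entries below `eps` receive an additive `eps` and
  the composition is re-closed, `y = (x + eps [x < eps]) / Z`.  The
  default `eps = 1e-5` sits two orders of magnitude below the 0.1 percent
  resolution at which signature tables are printed, so replacement never
  distorts a printed value while keeping every log term finite.
  `estimate_diet` and `bootstrap_diet` apply replacement *only when a
  signature actually contains non-positive entries*: a strictly positive
  signature passes through unchanged.  This matters for exactness — a
  predator that is literally a mixture of the basis signatures would
  otherwise be perturbed a second time by the floor already present in
  the basis, putting an artificial floor (around `7e-6`) under the
  achievable distance.

The packaged reference table (`reference_signatures()`) carries the
group-level means and standard deviations for nine groups (otter tail
and footpad adipose, crayfish, frogs, molluscs, and fish of four orders)
over 29 identified FA.  The identified bins sum to roughly 94 percent
per group; the remainder is mass in unidentified chromatographic bins,
pooled here into a single `other` bin (sd 0) so that every column is a
closed composition.  How that mass distributes over individual
unidentified bins is unknown — pooling is a modelling choice recorded in
the generator's output metadata.  Sample sizes follow the per-species
sampling design (the fish total is 90 across 15 species; a figure legend
in the source material gives a smaller fish count, and the sampling
table is taken as authoritative).

## Peak-to-bin assignment

Retention times drift between chromatographic runs, so peaks not matched
to a standard are pooled across runs and clustered on retention time
into `k = 60` bins (the estimated number of distinct FA) with
one-dimensional k-means.  Lloyd's algorithm is restarted `restarts = 1000`
times from uniform-random centroids on the observed retention-time
range, and the run maximizing variance explained,
SS~between~/SS~total~, is kept.  Numerical choices:

* Nearest-centroid assignment in 1-D is interval search on midpoints
  between sorted centroids; a value exactly on a midpoint goes to the
  lower-retention-time centroid (deterministic tie-break).
* Empty clusters are re-seeded at the value farthest from its nearest
  centroid, keeping `k` fixed as the 60-bin target requires.
* If all values coincide, SS~total~ = 0 and VE is defined as 1: the
  clustering is vacuous, not failed.
* One master seed drives the restart stream, so best-of-*n* results are
  reproducible and nested in *n*.

Known-standard peaks are pinned to their labels and excluded from
clustering by default (`cluster_known = TRUE` reverses this; whether the
original analysis clustered them is not stated).

## Ordination and group tests

`run_pca` treats each FA proportion as a variable.  The default is
correlation-matrix PCA (`standardize = TRUE`), matching the default
behaviour of the PCA implementation the study system's analysis used;
whether proportions were scaled there is unstated, so this is an
assumption, with covariance PCA behind a flag.  Constant bins are
dropped with a message before standardization.  Component signs are
fixed so the largest-magnitude loading is positive.  FA–component
correlations are plain Pearson correlations of each retained bin with
each score column (for standardized PCA these equal loading times the
square root of the eigenvalue).

`anova_tukey` runs a one-way ANOVA of each of the first five component
scores on group and adjusts all pairwise comparisons with Tukey's HSD
(studentized-range distribution).  Five components mirror the original
analysis, which did not analyze higher components.  Adjusted p values
are floored at `1e-16` because the studentized-range tail is not
reliable below that.  With two groups the Tukey p equals the pooled-t
p (the `q = t * sqrt(2)` identity), which the tests verify to `1e-10`.

## Diet estimation

With prey-taxon mean signatures as columns of `M` and per-FA calibration
coefficients `c` (identity by default — FA metabolism of otters is
unknown, so no correction is defensible), the modelled predator
signature for diet `p` on the simplex is

$$\hat y = \mathrm{close}(c \odot M p),$$

and the estimate minimizes the symmetrized Kullback–Leibler distance

$$d(y, \hat y) = \sum_k (y_k - \hat y_k)\,\ln(y_k / \hat y_k),$$

which is non-negative, zero iff the compositions coincide, and gives
greater weight to rare FA than squared-error distances.  A one-sided
(directed) form is available for sensitivity analysis.

**Optimization.**  The simplex constraint is removed by a softmax
reparameterization with the last logit pinned at zero (no flat
direction).  With identity calibration the objective is convex in `p`
(`yhat` is then linear in `p`), and the exact Hessian is cheap:
`M' diag(1/yhat + y/yhat^2) M` mapped through the softmax Jacobian.
Supplying it matters: prey signatures are near-collinear, the objective
has extremely flat valleys, and quasi-Newton steps stall in them where
Newton steps do not.  Solutions on the simplex boundary (a taxon
estimated at zero) leave the softmax coordinates ill-conditioned, so the
solver finishes with a face polish: coordinates below `1e-6` are
removed, the reduced problem is re-solved on the active face, and the
simplex KKT conditions are checked (equal gradients on the support, no
smaller gradient off it), re-admitting any violating taxon.  This makes
estimates exact on faces and equivariant to taxon reordering to machine
precision.  The barycenter start always runs; `restarts` random starts
(default 10 in `estimate_diet`) guard the non-convex calibrated case.
Convergence uses a relative objective tolerance of `1e-12` plus an
absolute stop at `1e-14`, comfortably below the `1e-10` exactness the
recovery checks assert.

**Bootstrap.**  `bootstrap_diet` resamples predators with replacement
and prey individuals with replacement within each taxon (both sides by
default; one-sided schemes behind `scheme`), rebuilds taxon means,
estimates the replicate diet, and reports mean and standard deviation
over (by default 500) replicates.  Only tail-adipose predators enter the
pipeline stage: footpad adipose is cold-adapted tissue with a distinct,
diet-biased signature.

**Fit unit.**  Whether the original analysis fitted each otter and
averaged, or fitted the mean otter signature, is not stated.  The
package default fits the *mean signature of the resampled predators* in
each replicate.  The alternative — fitting every individual and
averaging the simplex-constrained estimates — was implemented
(`unit = "individual"`) and measured: under individual-level signature
noise at the reference spread, it inflates rare prey systematically
(with 400 simulated predators fitted against the exact generating basis,
crayfish averaged 13 percent against a truth of 3 percent), a bias that
no sample size removes because it is a property of averaging
boundary-censored estimates.  Fitting the replicate mean lets the noise
average out *before* the nonlinear fit and recovers small components
without that inflation; the bootstrap still propagates both predator and
prey sampling variability into the standard errors.

## The synthetic-study generator

The generator emulates the statistical structure the analysis assumes,
at the study's sample sizes (46 tail otters; prey groups at their
sampling-design counts):

* **Individuals** (`simulate_individuals`): each FA is drawn from a
  lognormal moment-matched to the printed mean and sd (a
  logistic-normal scheme: a normal perturbation on the log scale,
  followed by closure).  Bins with sd 0 reproduce the mean exactly;
  bins with mean 0 stay zero and are handled downstream by zero
  replacement.  Closure makes the matching approximate: constant bins
  shift by order Var(S)/S² (well under 0.2 percentage points here), and
  bins whose sd exceeds their mean get heavy tails, so their *sample*
  sds are volatile at any realistic n.  The group-summary round trip
  in the tests quantifies both effects.
* **Predators** (`simulate_predators`): each predator mixes freshly
  resampled taxon means (rebuilt from draws at the taxon's full
  reference sample size) at the true diet, then receives per-FA
  lognormal noise whose sd is the diet-weighted reference sd
  (`noise_scale` rescales it; 0 gives deterministic mixtures).
* **Peak tables** (`simulate_peak_tables`): `k` true centers a fixed
  spacing apart, per-run normal retention jitter, flat-Dirichlet areas.

What passing tests show — and what they do not: the generator draws
bins independently before closure, so it reproduces marginal means and
spreads but not the between-FA correlation structure of real
signatures; it models no seasonal or geographic drift, no species-level
heterogeneity within a prey group beyond what the group sd carries, and
no predator metabolism (calibration is identity in both generator and
estimator, so the recovery checks cannot detect calibration error).
Recovery at the study scale therefore demonstrates internal consistency
of the estimator under the stated noise model, not field accuracy.

## Problem sizes used by the checks

The package's acceptance checks run end to end in a few minutes: 20
replicate studies of 46 predators with 500 bootstrap replicates for diet
recovery (mean absolute error per taxon at or below 0.03–0.04, crayfish
ranked smallest in every study), 1000-restart peak assignment at 60 bins
over 5 seeds (exact bin recovery, VE > 0.999), 100 replicate prey
libraries for the PC1 mollusc-separation property, and exhaustive
simplex grids at step `1e-3` (acceptance) and `1e-4` (two-taxon tests)
as optimizer oracles.

## Known limitations

* Printed group summaries, not raw individuals, parameterize the
  generator; reproducing the original per-individual PCA percentages is
  impossible from printed data, and the ordination checks are therefore
  property-based (separation rates), not value-based.
* The predominant-FA statistic weights group means by sample size; it
  equals the all-sample mean only up to the rounding of the printed
  group means.
* Identity calibration means estimated diets are proportional
  representations of prey signatures, an upper-bound style inference;
  with real metabolism the mixture model is misspecified in ways the
  identity-calibrated bootstrap cannot see.
* The symmetrized KL objective with calibration differing from identity
  is not provably convex; random restarts are a guard, not a proof.
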