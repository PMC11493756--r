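---
title: "Methods: pool-seq scans, diversity, structure and demographic inference in poolscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pool-seq scans, diversity, structure and demographic inference in poolscape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`poolscape` analyses pooled whole-genome sequencing of a structured
metapopulation: a dozen demes in two habitat clusters (an invaded,
calcium-rich habitat and a low-calcium refuge), 40 diploids per pool, read
depth around 30–40x. This vignette explains the models behind each stage,
the tunable parameters, the numerical choices, and what the synthetic-data
tests do and do not establish about real data.

## The two-stage sampling model

Every estimator in the package treats a pooled allele count as the outcome
of two sampling layers: `2 * nPool` chromosomes drawn from the deme, then
reads drawn (binomially, with an optional symmetric error flip
`p' = p(1-e) + (1-p)e`) from the pool. The effective number of chromosomes a
depth `C` represents from a pool of `n` haploids is
`n_eff = (nC - 1)/(n + C)`, bounded by both `n` and `C`. The pool-corrected
site heterozygosity `h = C/(C-1) * n/(n-1) * 2f(1-f)` is exactly unbiased
under this model; each factor undoes one layer's downward bias.

## SNP filters

`filterSnps()` applies, in order: drop multiallelic sites; keep sites with
every pool's depth in `[minCov, maxCov]` (defaults 5 and 300); require at
least `minCount = 2` reads per allele summed over pools (removing
singleton-supported alleles); require pooled minor-allele frequency at least
`minMaf = 0.0125` (one chromosome in a pool of 80). Thresholds are
inclusive at the boundary, so a pooled MAF of exactly 0.0125 is retained —
an arbitrary but documented convention. The MAF is computed on reads pooled
across populations, matching the singleton-removal reading of the threshold.

## The scaled covariance matrix and the scans

For SNP `l` with per-pool frequencies `p_lj` and unweighted mean `pbar_l`,
the standardised deviation is `x_lj = (p_lj - pbar_l)/sqrt(pbar_l(1-pbar_l))`
and `Omega = (1/L) sum_l x_l x_l'` summarises shared history: positive
entries for pools that drift together, negative across diverged clusters.
Because the deviations are centred on their own mean they sum to zero, so
this moment estimator has rank `J - 1` and a small ridge
(`1e-6 * trace/J`, doubled until comfortably invertible) makes it positive
definite. A consequence worth stating plainly: the mean of
`XtX = x' Omega^{-1} x` over SNPs is exactly `J - 1`, one less than the
`chi^2(J)` reference used for the bilateral p-value. We keep the `chi^2(J)`
reference — the field's convention for this statistic with `J` populations —
and verified by simulation that the bilateral outlier rate at `p < 0.001`
stays inside the binomial 99% band: the upper tail is slightly conservative
and the lower tail slightly liberal, in balance. The package's tests assert
the provable mean `J - 1` rather than `J`.

The C2 statistic projects `x_l` onto a centred +/-1 group contrast `c` and
rescales by `c' Omega c`; it is `chi^2(1)` under neutrality and suited to a
binary covariable (predator presence). For a continuous covariable (the
calcium gradient) the package uses a deterministic generalised-least-squares
regression under Omega: `beta = (k' Omega^{-1} x)/(k' Omega^{-1} k)`,
`z^2 = beta^2 (k' Omega^{-1} k) ~ chi^2(1)`. This replaces Monte-Carlo Bayes
factors with the same regression-model family evaluated in closed form; the
default "decisive" stringency for this scan is a recalibrated q-value below
0.001, deliberately stricter than the 0.01 FDR used elsewhere.

The quasibinomial GLM scan refits each SNP's frequencies on a binary
covariable with counts rescaled to `n_eff` and one read added to empty
cells. With a single binary predictor the IRLS fixed point is closed-form
(group-wise weighted frequencies), which the implementation exploits,
vectorised across SNPs; the slope is tested against a t reference with
`J - 2` degrees of freedom and the Pearson dispersion. Population structure
the GLM cannot model inflates (or deflates) its null statistics; the
empirical-null recalibration divides the implied `chi^2(1)` quantiles by the
genomic inflation factor `lambda` (median observed over 0.4549) before
mapping back to p-values.

Candidates per covariable are SNPs significant in both the Omega-based scan
and the recalibrated GLM scan, not significant for the other covariable
(uniqueness — with two confounded covariables a SNP assigned to both is
uninterpretable), and direction-consistent. The consistency rule is a
declared convention, not a reconstruction of any published rule: the two
methods' effect signs must agree, and in each covariable group at least
`ceiling(5/6)` of the group's populations must lie on the model-implied side
of the across-population mean frequency.

### What the calibration tests show

The distributional claims (mean statistics, KS uniformity, binomial-band
type-I rates) are verified on an exchangeable neutral island configuration:
equal within- and between-cluster migration, no bottleneck, no selection.
Under the package's default clustered demography the Omega-based scans stay
calibrated (Omega absorbs the structure) but the recalibrated GLM becomes
conservative in the far tail — median-matching cannot fix the tail shape
distortion of a strongly hierarchical null, only its scale. This mirrors
what genomic control can and cannot do on real data.

## Diversity statistics

Windowed `pi` is the mean pool-corrected site heterozygosity over covered
sites (depth at least 20 by default). Watterson's theta divides the count of
segregating sites by the summed per-site visibility factors
`A(d, n) = sum_i (1/i) (1 - (i/n)^d - (1 - i/n)^d)`: the expected
segregating-site yield of one site at depth `d` per unit theta, which makes
the estimator unbiased under the two-stage model. An earlier design —
`S / (sites * a1(n_eff))` — left theta biased upward by about 3%, enough to
push mean Tajima's D to -0.16 at neutral equilibrium; the visibility-factor
denominator centres D near zero. Tajima's D uses the `pi - theta_W` contrast
on the window total scale over the standard variance constants evaluated at
the floored median `n_eff`; its coverage floor is 13, read as "depth at
least a third of the pool size of 40" so the corrected estimator stays
defined. Windows whose covered fraction of assayed sites falls below 0.05
report missing values, never zero. The covered fraction is defined against
the sites present in the object (for real sync data that is every sequenced
position; for the thinned synthetic representation it is the assayed sites).

## Population structure

Pairwise F_ST is identity-based: within-pool identity `Q1 = 1 - h`,
between-pool identity `Q2 = 1 - [f_i(1-f_j) + f_j(1-f_i)]`, multilocus
estimate `sum(Q1bar - Q2)/sum(1 - Q2)` (ratio of sums; pair mean `Q1bar`).
Its consistency is established against the same quantity computed from the
simulator's true deme frequencies, not against a published decomposition.
UPGMA uses average-linkage `hclust` (ties broken by smallest index) and
bootstrap support resamples SNPs with replacement. Mantel tests delegate to
`vegan::mantel` — Pearson correlation of off-diagonal entries, one-sided
(positive-association) permutation p — on `F_ST/(1-F_ST)` against log river
distance (isolation by distance) or the squared Mahalanobis environmental
distance over (calcium, predator) pairs (isolation by environment).
Geographic distances are supplied river-path distances; nothing is computed
from coordinates. The Forstner-Moonen distance
`sqrt(sum log^2 lambda_i)` over generalized eigenvalues compares covariance
matrices (e.g., Omega replicates).

## Demographic inference

Seven two-population models share an ancestral population (relative size 1)
splitting `T_S` coalescent units before the most recent epoch, with constant
asymmetric migration after the split: plain splits with no, symmetric or
asymmetric migration (theta profiled analytically), and bottleneck models in
which the bottleneck age is fixed at `gB = 12` generations before sampling
(one generation per year), making `theta = 4 mu L_eff` an explicit free
parameter because it sets the reference size `N_ref = theta/(4 mu L_eff)`
that converts generations into coalescent time, `T_B = gB/(2 N_ref)`,
recomputed at every likelihood evaluation. The mutation rate defaults to
`7.6e-9` per site per year; `L_eff` is the analysed length times the SNP
retention fraction. Free-parameter counts are 10, 8, 8, 7, 5, 4, 3. An
eighth model (bottlenecks in both demes, recovery only in the invaded one)
ships behind `includeAlternative = TRUE` and is excluded from the default
comparison. Migration parameters are scaled so that the per-lineage backward
migration rate is `M/2`; the reported gene-flow summaries are `2Nm = M/2`,
classified as negligible below 0.05, low in [0.05, 5.5], high above
(inclusive at the boundaries).

The folded joint SFS is built by hypergeometric downsampling of reads to the
declared haploid sample sizes (default 20 + 20 — a desk-scale choice, not
the pools' 80), keeping SNPs inside both pools' coverage interquartile range,
dropping scan outliers and uninformative sites, folding, and masking cells
with minor-allele totals of 5 or fewer plus the monomorphic corners.

A limitation worth knowing: with that default mask and 20 + 20 haploids the
asymmetric-migration split model is ridge-unidentified — a large refuge size
with near-zero refuge-bound migration reproduces the unmasked spectrum of
the generating parameters to within Monte-Carlo error, because the masked
low-frequency cells are where the refuge-size signal lives. The package's
parameter-recovery experiment therefore masks only the monomorphic corners
(its synthetic counts are exact, so the low-confidence rationale for the
mask does not apply); fits to masked empirical spectra should be read as
constraining compounds of (size, migration, time) rather than each
parameter separately, which is also why gene flow is summarised as `2Nm`.

### The expected-SFS engine and its numerics

The expected spectrum is Monte-Carlo: `n1 + n2` lineages traced backward
through piecewise-constant epochs (exponential recovery discretised into 16
slices at geometric-mean sizes), with expected entry
`mu_ij = (theta/2) E[t_ij]` over the mean branch length subtending `i`
pop-1 and `j` pop-2 lineages. Three numerical choices matter:

1. **Per-replicate RNG streams.** Each genealogy draws from its own stream
   derived from `(seed, rep)`. With one shared stream a tiny parameter
   change desynchronises every subsequent replicate and the likelihood
   surface becomes white noise at small scales; per-replicate streams keep
   it near-continuous under common random numbers.
2. **Rao-Blackwellised waiting times.** The estimate accumulates the
   conditional expectation of each holding time given the lineage
   configuration (`(1 - exp(-R tau))/R` against an epoch boundary, `1/R`
   otherwise) while the sampled time drives the state. This removes the
   exponential holding-time noise entirely — in a no-migration epoch the
   per-level contributions are exact.
3. **Second-order bias correction.** `E[k log(mu_hat)]` sits below
   `k log(mu)` by about `k Var(mu_hat)/(2 mu^2)`, so a noisy likelihood
   systematically favours parameter regions where the estimator happens to
   have low relative variance. The engine tracks per-cell Monte-Carlo
   variances and `compositeLoglik()` adds the correction, capped at `0.1 k`
   per cell — beyond that the Taylor expansion is meaningless and an
   uncapped correction would reward regions where the estimate is pure
   noise.

The composite likelihood is Poisson over unmasked cells; for profiled-theta
models the analytic maximiser `theta_hat = sum(k)/sum(m)` scales the model
spectrum first. Composite likelihoods of linked SNPs are compared directly —
never through AIC — and ties are reported as ties.

### Optimisation

The surface has long curved valleys (refuge size, split time and refuge-bound
migration trade off) on which plain Nelder-Mead stalls far from the optimum
even when a monotone ascent path exists. `fitModel()` therefore runs, in log
space: a coarse random-search stage; repeated local runs of Hooke-Jeeves
pattern search followed by a Nelder-Mead refinement; restarts cycling between
perturbations of the best point, the next-ranked global candidate, and a
coordinate kick (one parameter redrawn from its bounds) that moves along
ridges; and a re-scoring of every run endpoint at five-fold Monte-Carlo
precision, because working-precision optima can be reordered by residual
noise. Convergence keeps the standard rule — at least three runs within 1%
of the best (re-scored) log-likelihood, with a 30-run cap — and an
unconverged fit is returned flagged, never hidden. Parameters are floored
at 1e-3 during optimisation: in log space a rate that reaches (near) zero
freezes, because multiplicative steps cannot leave it, and 1e-3 is
indistinguishable from zero at any realistic data size. Parameters are not
converted into natural units (individuals, years); only the dimensionless
`2Nm` summaries are derived.

Uncertainty comes from a block bootstrap: fixed 1e5-bp chunks resampled with
replacement, the SFS rebuilt, the model refit with a reduced budget from the
full-data estimate, and 2.5/97.5 percentile intervals reported. This
replaces curvature-based (sandwich) uncertainties, whose score derivatives
are unstable on a Monte-Carlo surface.

## The synthetic metapopulation

`simulateMetapopulation()` is a discrete-generation forward Wright-Fisher
simulation: a neutral panmictic burn-in (100 generations at the summed deme
size), a cluster split 200 generations before sampling, conservative
island-style migration (rows renormalised; defaults 0.02 within and 0.002
between clusters), genic selection (`s = 0.1` at 2% of loci by default) with
habitat-dependent sign tied to either the predator indicator or the calcium
gradient, and a bottleneck 12 generations before sampling in the invaded
demes (10% of the deme size retained, exponential recovery to the present).
Deme size defaults to 400 diploids and the census sizes and migration rates
are free choices of the generator — the real system's values are unknown —
so recovery tests establish internal consistency, not field realism. The
calcium covariable is constructed to correlate with the predator indicator
at exactly `rhoEnv = 0.71` by mixing the standardised indicator with a fixed
orthogonal gradient: the two covariables are confounded to a controlled
degree, which is precisely what the uniqueness filter must cope with.
`simulatePoolReads()` adds the two sampling layers with symmetric biallelic
error (default 0.001); sites are laid out every 100 bp on 1-Mb synthetic
scaffolds so windowed and block-resampling code paths see realistic
coordinates.

What passing tests show: the estimators are unbiased under the declared
sampling model, the scans are calibrated under exchangeable neutrality, the
F_ST estimator tracks truth, planted selection is recovered, and the
demographic machinery can re-identify generating parameters from its own
model class at desk scale (sample sizes of 20 haploids, tens of thousands of
SNPs, a few times 1e4 genealogies per evaluation). What they do not show:
robustness to misaligned reads, reference bias, indel contamination, linked
selection, or histories outside the seven-model class — none of which the
generator emulates.

## Problem sizes

Test-suite simulations use 3,000–15,000 loci, 12 demes, coverage 35x;
calibration suites run one scan on about 15,000 filtered SNPs; the
parameter-recovery experiment fits a 5-parameter model to roughly 20,000
SNPs (theta = 1e4) at 6,000 genealogies per evaluation with 30,000 for
re-scoring. These sizes were chosen so the full suite runs in minutes on a
laptop core while leaving the Monte-Carlo error clearly inside each test's
assertion band.
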