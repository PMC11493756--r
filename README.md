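# poolscape

Pool-seq population genomics for structured metapopulations along
environmental gradients.

`poolscape` implements, as one tested R toolchain, the analyses needed to ask
whether a native population facing an invasive predator is locally adapted,
demographically damaged, and reachable by gene flow from refuge habitats —
using pooled whole-genome sequencing of a dozen populations rather than
individual genotypes:

* **Pool-seq I/O and filtering** — popoolation2-style `sync` files, the
  standard site filters (minimum allele count 2, per-pool coverage 5–300,
  pooled minor-allele frequency ≥ 0.0125), and pool-seq sample-size
  arithmetic (n_eff = (nC − 1)/(n + C)).
* **Genome scans for selection** — the scaled covariance matrix Ω of
  standardised population allele frequencies; the Ω-corrected XtX
  differentiation statistic with a bilateral χ²(J) test; the C2 contrast
  statistic for binary covariables (χ²(1)); a generalised-least-squares
  association scan for continuous covariables; a quasibinomial GLM scan on
  n_eff-rescaled counts; genomic-control recalibration (inflation factor λ);
  Storey q-values; and candidate intersection with uniqueness and
  direction-consistency filters.
* **Diversity** — pool-corrected π, Watterson θ and Tajima's D in
  non-overlapping 100 kb windows, observed heterozygosity, and Welch t /
  Hedges' g habitat contrasts.
* **Population structure** — identity-probability pairwise F_ST (ratio of
  sums, two-stage pool correction), UPGMA trees with SNP bootstrap support,
  Mantel tests of isolation by distance (F_ST/(1−F_ST) vs log river
  distance) and by environment (squared Mahalanobis distance), and the
  Förstner–Moonen distance between covariance matrices.
* **Demographic inference** — seven competing two-population histories
  (split with no/symmetric/asymmetric migration; bottlenecks in one or both
  demes, with or without exponential recovery; the bottleneck age fixed at
  12 generations so θ = 4μL is an explicit parameter) fitted to a folded,
  masked joint site-frequency spectrum by maximum Poisson composite
  likelihood over a Monte-Carlo structured-coalescent expected SFS (Rcpp),
  with block-bootstrap confidence intervals and 2N_e·m gene-flow classes.
* **Synthetic truth** — a forward Wright–Fisher metapopulation simulator
  (12 demes in two habitat clusters, divergent selection tied to two
  confounded covariables, a recent bottleneck in invaded demes) plus a
  two-stage pooled-read sampler, so every stage is testable against known
  truth without any external data.

## Worked example

```r
library(poolscape)

cfg <- runConfig(seed = 1L,
                 sim = list(nLoci = 5000L),
                 nBootTree = 200L,
                 demoModels = c("split_no_mig", "split_even_mig"),
                 demoNReps = 2000L, demoMaxRuns = 4L)
res <- runPipeline(cfg, verbose = FALSE)
s <- res$summary

s$nSnpsRetained
#> [1] 4961
round(s$lambda, 2)
#> calcium    goby
#>    1.67    2.47
s$nCandidates
#> calcium    goby
#>       0      33
round(s$fst[1, 2], 4)
#> [1] 0.0457
round(unlist(s$effectSizes$pi), 3)
#>      g     lo     hi      p
#> -4.431 -6.534 -2.328  0.000
s$modelRanking
#>            model    logLik k converged rank
#> 1 split_even_mig -388.7051 4      TRUE    1
#> 2   split_no_mig -394.8465 3     FALSE    2
round(s$ibd$r2, 3); s$ibd$p
#> [1] 0.258
#> [1] 9e-04
```

Reading: of 5000 simulated loci, 4961 SNPs survive the pool-seq filters.
The genomic inflation factors lambda > 1 reflect the hierarchical structure
the quasibinomial GLM cannot see; the empirical-null recalibration absorbs
it. The scans recover 33 unique predator-linked candidates (2% of loci were
planted under selection, split between the two covariables; at the default
0.71 covariable correlation the calcium set is emptied by the stricter
regression stringency plus the uniqueness filter - lower `rhoEnv` to watch
it fill). Neutral-SNP F_ST between the first two demes is about 0.046;
nucleotide diversity is clearly lower in the bottlenecked invaded demes
(Hedges' g of -4.4: this generator's bottleneck retains 10% of the deme for
12 generations); isolation by distance is significant (Mantel r2 = 0.26);
and the model comparison prefers a split with migration over a split
without, as simulated.

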