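# shared fixture builders and independent oracles

# PoolCounts straight from a frequency matrix at fixed depth (no noise in
# depth; binomial reads only)
pcFromFreqs <- function(freqs, depth = 50L, nChr = 80L, seed = 1L) {
  set.seed(seed)
  freqs <- as.matrix(freqs)
  L <- nrow(freqs); J <- ncol(freqs)
  alt <- matrix(rbinom(L * J, depth, as.vector(freqs)), L, J)
  PoolCounts(rep("s1", L), seq_len(L), matrix(depth, L, J) - alt, alt,
             poolHaploids = nChr)
}

# neutral-equilibrium pooled sites: true frequencies are pool-of-nChr draws
# from the standard neutral SFS (P(class i) = theta/i), reads on top.
# E[site pi] = theta exactly under this construction.
neutralEquilibriumSites <- function(nSites, theta, nChr = 80L,
                                    depthMean = 35, seed = 1L) {
  set.seed(seed)
  a1 <- sum(1 / seq_len(nChr - 1))
  seg <- runif(nSites) < theta * a1
  i <- rep(0L, nSites)
  if (any(seg))
    i[seg] <- sample.int(nChr - 1, sum(seg), replace = TRUE,
                         prob = (1 / seq_len(nChr - 1)))
  dep <- rpois(nSites, depthMean)
  alt <- rbinom(nSites, dep, i / nChr)
  PoolCounts(rep("s1", nSites), seq_len(nSites),
             matrix(dep - alt, ncol = 1), matrix(alt, ncol = 1),
             poolHaploids = nChr)
}

# independent brute-force Wright-Fisher island simulator (deliberately
# written as a per-deme loop, no shared code with simulateMetapopulation)
bruteForceIslandFreqs <- function(nLoci, nDemes, N2, m, nGen, seed) {
  set.seed(seed)
  p0 <- runif(nLoci, 0.1, 0.9)
  p <- matrix(p0, nLoci, nDemes)
  for (g in seq_len(nGen)) {
    tot <- rowSums(p)
    pnew <- p
    for (d in seq_len(nDemes)) {
      pOther <- (tot - p[, d]) / (nDemes - 1)
      pm <- (1 - m) * p[, d] + m * pOther
      pnew[, d] <- rbinom(nLoci, N2, pm) / N2
    }
    p <- pnew
  }
  p
}

# multilocus FST from true deme frequencies (identity probabilities,
# ratio of sums) -- the oracle the read-based estimator is checked against
fstFromTrueFreqs <- function(p) {
  J <- ncol(p)
  poly <- rowSums(p) > 0 & rowSums(p) < J
  p <- p[poly, , drop = FALSE]
  num <- den <- 0
  for (i in seq_len(J - 1)) for (j in (i + 1):J) {
    Q2 <- 1 - (p[, i] * (1 - p[, j]) + p[, j] * (1 - p[, i]))
    Q1 <- 1 - (p[, i] * (1 - p[, i]) + p[, j] * (1 - p[, j]))
    num <- num + sum(Q1 - Q2)
    den <- den + sum(1 - Q2)
  }
  num / den
}

binomBand <- function(n, p, level = 0.99) {
  qbinom(c((1 - level) / 2, 1 - (1 - level) / 2), n, p) / n
}

# a small exchangeable neutral dataset shared by the scan calibration
# tests (cached per (nLoci, seed) so repeated blocks reuse it)
.fixtureCache <- new.env(parent = emptyenv())
neutralScanFixture <- function(nLoci = 15000L, seed = 42L) {
  key <- paste0("n", nLoci, "s", seed)
  if (!is.null(.fixtureCache[[key]])) return(.fixtureCache[[key]])
  sc <- simConfig(nLoci = nLoci, s = 0, pSelected = 0,
                  mWithin = 0.02, mBetween = 0.02,
                  bottleneckSeverity = 1, seed = seed)
  sim <- simulateMetapopulation(sc)
  pc <- simulatePoolReads(sim$freqs, coverageMean = 35, seed = seed + 1L)
  out <- list(config = sc, pc = filterSnps(pc), covars = covariateTable(sc))
  .fixtureCache[[key]] <- out
  out
}
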