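test_that("the model registry has the declared free-parameter counts", {
  mods <- demographicModels()
  expect_named(mods, c("bottleneck_growth_both", "bottleneck_growth_invaded",
                       "bottleneck_both", "bottleneck_invaded",
                       "split_uneven_mig", "split_even_mig", "split_no_mig"))
  expect_equal(unname(vapply(mods, `[[`, 0L, "k")), c(10L, 8L, 8L, 7L, 5L, 4L, 3L))
  # theta is explicit exactly in the fixed-bottleneck-time models
  expect_equal(unname(vapply(mods, `[[`, "", "thetaMode")),
               c(rep("explicit", 4), rep("profiled", 3)))
  # the untested alternative model is opt-in only
  expect_true("bottleneck_both_growth_invaded" %in%
                names(demographicModels(includeAlternative = TRUE)))
})

test_that("folding is idempotent, conserves mass and commutes with masking", {
  set.seed(5)
  m <- matrix(rpois(9 * 7, 20), 9, 7)
  f1 <- foldSfs(m)
  expect_equal(sum(f1), sum(m))
  expect_equal(foldSfs(f1), f1)
  # the mask keeps nothing at or below maskMax and masks the corners
  mask <- poolscape:::.foldedMask(8, 6, 2L)
  keep <- !mask
  tot <- outer(0:8, 0:6, "+")
  expect_true(all(tot[keep] > 2))          # nothing at or below maskMax kept
  expect_true(mask[1, 1] && mask[9, 7])    # corners masked
})

test_that("effective length is the SNP-retention fraction of the analysed length", {
  expect_equal(effectiveLength(1e9, 1e6, 2e7), 5e7)
  expect_equal(effectiveLength(123, 5, 5), 123)
  expect_equal(effectiveLength(1e9, 2e6, 2e7), 2 * effectiveLength(1e9, 1e6, 2e7))
})

test_that("buildSfs projects, folds and masks a pooled dataset", {
  set.seed(9)
  freqs <- matrix(runif(4000, 0.05, 0.95), 2000, 2)
  pc <- simulatePoolReads(freqs, coverageMean = 60, seed = 2L)
  sfs <- buildSfs(pc, c(1, 2), n1 = 10L, n2 = 10L, maskMax = 2L,
                  coverageQuartileFilter = FALSE, seed = 5L)
  expect_s4_class(sfs, "Folded2DSFS")
  expect_equal(dim(sfs@counts), c(11L, 11L))
  expect_true(sfs@mask[1, 1] && sfs@mask[11, 11])
  # monomorphic input contributes nothing informative
  mono <- simulatePoolReads(matrix(0, 500, 2), coverageMean = 60,
                            errorRate = 0, seed = 3L)
  expect_error(buildSfs(mono, c(1, 2), n1 = 10L, n2 = 10L,
                        coverageQuartileFilter = FALSE, seed = 4L),
               "empty|masked")
  # identical seed, identical SFS
  sfs2 <- buildSfs(pc, c(1, 2), n1 = 10L, n2 = 10L, maskMax = 2L,
                   coverageQuartileFilter = FALSE, seed = 5L)
  expect_identical(sfs@counts, sfs2@counts)
})

test_that("the projected SFS matches the direct multinomial projection oracle", {
  # known pool frequencies, deep uniform coverage: projection of reads to
  # n haploids should match binomial sampling from the frequencies
  set.seed(31)
  L <- 40000L; n <- 8L
  p <- runif(L, 0.1, 0.9)
  pc <- simulatePoolReads(cbind(p, p), nPool = 40L, coverageMean = 80,
                          errorRate = 0, seed = 32L)
  sfs <- buildSfs(pc, c(1, 2), n1 = n, n2 = n, maskMax = 0L,
                  coverageQuartileFilter = FALSE, seed = 33L)
  marg1 <- rowSums(sfs@counts)   # folded marginal of population 1
  # oracle: two-stage binomial (pool of 80 then n draws), folded the same
  # way, by direct simulation with an independent code path
  poolF <- rbinom(L, 80, p) / 80
  i1 <- rbinom(L, n, poolF)
  i2 <- rbinom(L, n, rbinom(L, 80, p) / 80)
  keepMinor <- function(i, j) {
    tot <- i + j; ct <- 2 * n - tot
    ifelse(tot < ct | (tot == ct & i <= n - i), i, n - i)
  }
  inf <- !((i1 == 0 & i2 == 0) | (i1 == n & i2 == n))
  om <- tabulate(keepMinor(i1[inf], i2[inf]) + 1L, n + 1L)
  tot <- sum(marg1)
  expect_gt(tot, 1000)
  frac <- marg1 / tot
  ofrac <- om / sum(om)
  expect_lt(max(abs(frac - ofrac)), 4 * sqrt(max(ofrac * (1 - ofrac)) / sum(om)))
})

test_that("the expected SFS reproduces the panmictic theta/i closed form within 2 percent", {
  # a split at time ~0 with equal sizes is a panmictic sample of n1+n2:
  # the folded marginal by total minor count k is theta/k + theta/(n-k)
  mods <- demographicModels()
  m <- mods$split_even_mig
  n1 <- 8L; n2 <- 8L; n <- n1 + n2
  es <- expectedSfs(m, c(nu1 = 1, nu2 = 1, TS = 1e-3, mSym = 1),
                    n1, n2, nReps = 1e5, seed = 17L, theta = 2)
  tot <- outer(0:n1, 0:n2, "+")
  got <- vapply(1:(n %/% 2), function(k) sum(es[tot == k]), numeric(1))
  theo <- vapply(1:(n %/% 2), function(k) {
    if (k < n - k) 2 / k + 2 / (n - k) else 2 / k
  }, numeric(1))
  expect_lt(max(abs(got / theo - 1)), 0.02)
})

test_that("the expected SFS is deterministic under a fixed seed and linear in theta", {
  mods <- demographicModels()
  m <- mods$split_uneven_mig
  p <- c(nu1 = 1, nu2 = 0.5, TS = 0.4, mIR = 1, mRI = 0.2)
  a <- expectedSfs(m, p, 6L, 6L, nReps = 2000L, seed = 5L, theta = 1)
  b <- expectedSfs(m, p, 6L, 6L, nReps = 2000L, seed = 5L, theta = 1)
  expect_identical(unclass(a), unclass(b))
  d <- expectedSfs(m, p, 6L, 6L, nReps = 2000L, seed = 5L, theta = 2)
  expect_equal(unclass(d), unclass(2 * a), ignore_attr = TRUE)
  pBad <- p; pBad["nu1"] <- -1
  expect_error(expectedSfs(m, pBad, 6L, 6L), "bounds")
})

test_that("symmetric-island expected SFS agrees with an independent plain-R coalescent", {
  # oracle: naive discrete-event structured coalescent written separately
  nvSim <- function(n1, n2, nu, M, TS, reps, seed) {
    set.seed(seed)
    tlen <- matrix(0, n1 + 1, n2 + 1)
    for (r in seq_len(reps)) {
      lin <- data.frame(deme = rep(c(1, 2), c(n1, n2)),
                        a = rep(c(1, 0), c(n1, n2)),
                        b = rep(c(0, 1), c(n1, n2)))
      t <- 0
      while (nrow(lin) > 1) {
        k1 <- sum(lin$deme == 1); k2 <- sum(lin$deme == 2)
        merged <- t >= TS
        if (merged) { lin$deme <- 1; k1 <- nrow(lin); k2 <- 0 }
        rc <- c(k1 * (k1 - 1) / 2 / nu, k2 * (k2 - 1) / 2 / nu)
        rm <- if (merged) c(0, 0) else c(k1 * M / 2, k2 * M / 2)
        R <- sum(rc, rm)
        dt <- rexp(1, R)
        if (!merged && t + dt > TS) { t <- TS; next }
        tlen <- tlen + dt * unname(as.matrix(table(
          factor(lin$a, 0:n1), factor(lin$b, 0:n2))))
        t <- t + dt
        ev <- sample.int(4, 1, prob = c(rc, rm) / R)
        if (ev <= 2) {
          ids <- which(lin$deme == ev)
          pr <- sample(ids, 2)
          lin$a[pr[1]] <- lin$a[pr[1]] + lin$a[pr[2]]
          lin$b[pr[1]] <- lin$b[pr[1]] + lin$b[pr[2]]
          lin <- lin[-pr[2], ]
        } else {
          from <- ev - 2
          id <- sample(which(lin$deme == from), 1)
          lin$deme[id] <- 3 - from
        }
      }
    }
    tlen / reps
  }
  mods <- demographicModels()
  m <- mods$split_even_mig
  p <- c(nu1 = 1, nu2 = 1, TS = 0.8, mSym = 2)
  n1 <- 4L; n2 <- 4L
  es <- expectedSfs(m, p, n1, n2, nReps = 3e4, seed = 3L, theta = 2)
  oracleT <- nvSim(n1, n2, 1, 2, 0.8, 3000L, 44L)
  oracleSfs <- foldSfs(oracleT)        # theta/2 * E[t] with theta = 2
  use <- oracleSfs > 0.01
  relDiff <- abs(es[use] - oracleSfs[use]) / oracleSfs[use]
  # the plain-R oracle runs 3000 genealogies; its own MC error dominates
  expect_lt(median(relDiff), 0.1)
})

test_that("composite likelihood attains its maximum at the observed counts and honours the mask", {
  counts <- matrix(c(0, 5, 3,
                     2, 7, 1,
                     0, 4, 0), 3, 3, byrow = TRUE)
  counts <- foldSfs(counts)
  mask <- poolscape:::.foldedMask(2, 2, 0L)
  obs <- new("Folded2DSFS", counts = counts, mask = mask,
             sampleSizes = c(2L, 2L), totalLength = 1e4, snpsUsed = sum(counts),
             snpsTotal = 100)
  llSelf <- compositeLoglik(obs, counts + (counts == 0) * 1e-12, "explicit")
  # direct Poisson formula on the unmasked cells
  k <- counts[!mask]
  direct <- sum(ifelse(k > 0, k * log(k) - k - lgamma(k + 1), 0))
  expect_equal(as.numeric(llSelf), direct, tolerance = 1e-8)
  # any perturbation of an unmasked cell lowers it
  worse <- counts; worse[!mask] <- worse[!mask] * 1.3 + 0.1
  expect_lt(as.numeric(compositeLoglik(obs, worse, "explicit")), direct)
  # masked cells are ignored entirely
  junk <- counts; junk[mask] <- 99
  expect_equal(as.numeric(compositeLoglik(obs, junk + (junk == 0) * 1e-12,
                                          "explicit")),
               direct, tolerance = 1e-8)
  # profiled theta maximises the likelihood in the scale direction
  ms <- counts * 0.37 + (counts == 0) * 1e-12
  llP <- compositeLoglik(obs, ms, "profiled")
  th <- attr(llP, "theta")
  for (f in c(0.99, 1.01)) {
    expect_lt(as.numeric(compositeLoglik(obs, ms * th * f, "explicit")),
              as.numeric(llP) + 1e-9)
  }
})

test_that("gene-flow classes use the published inclusive boundaries", {
  expect_equal(classifyGeneFlow(c(0.04, 0.05, 5.5, 5.6)),
               c("negligible", "low", "low", "high"))
})

test_that("model ranking is strict by log-likelihood, reports ties, ignores input order", {
  mkFit <- function(model, ll) {
    structure(list(model = model, logLik = ll, converged = TRUE),
              class = "DemographicFit")
  }
  fits <- list(mkFit("split_no_mig", -120), mkFit("split_uneven_mig", -100),
               mkFit("split_even_mig", -100))
  rk <- compareModels(fits)
  expect_equal(rk$model[1:2], c("split_even_mig", "split_uneven_mig"))
  expect_equal(rk$rank[1:2], c(1L, 1L))   # tie shared
  expect_equal(rk$rank[3], 3L)
  rk2 <- compareModels(rev(fits))
  expect_equal(rk2$logLik, rk$logLik)
})

test_that("the block bootstrap honours its degenerate contracts", {
  # data: one scaffold of identical repeated chunks, two pools
  set.seed(41)
  chunkFreq <- runif(200, 0.2, 0.8)
  freqs <- matrix(rep(chunkFreq, 20), ncol = 1)
  freqs <- cbind(freqs, freqs)
  pc <- simulatePoolReads(freqs, coverageMean = 60, seed = 42L,
                          spacing = 500L, scaffoldLength = 1e5)
  # -> 4000 sites at 500 bp spacing = 20 chunks of 1e5 bp
  sfs <- buildSfs(pc, c(1, 2), n1 = 6L, n2 = 6L, maskMax = 0L,
                  coverageQuartileFilter = FALSE, seed = 43L)
  fit <- suppressWarnings(fitModel(sfs, "split_no_mig", nReps = 800L,
                                   nRepsPolish = 1600L, seed = 3L,
                                   maxRuns = 1L, minRuns = 1L, maxit = 150L))
  # B = 1: the percentile interval collapses onto the single refit
  b1 <- suppressWarnings(blockBootstrap(pc, c(1, 2), fit,
                                        sfsArgs = list(n1 = 6L, n2 = 6L,
                                                       maskMax = 0L,
                                                       coverageQuartileFilter = FALSE),
                                        B = 1L, refitRuns = 1L, seed = 9L))
  expect_equal(unname(b1$ci[1, ]), unname(b1$ci[2, ]))
  expect_equal(unname(b1$ci[1, ]), unname(b1$estimates[1, ]))
  # near-identical chunks: intervals are narrow relative to the estimate
  b <- suppressWarnings(blockBootstrap(pc, c(1, 2), fit,
                                       sfsArgs = list(n1 = 6L, n2 = 6L,
                                                      maskMax = 0L,
                                                      coverageQuartileFilter = FALSE),
                                       B = 6L, refitRuns = 1L, seed = 10L))
  width <- b$ci[2, ] - b$ci[1, ]
  expect_true(all(width / pmax(fit$params, 0.1) < 0.8))
  expect_error(blockBootstrap(pc[1:10, ], c(1, 2), fit), "chunks")
})
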