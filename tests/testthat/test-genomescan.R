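test_that("estimateOmega equals the brute-force outer-product average", {
  set.seed(4)
  pc <- pcFromFreqs(matrix(runif(10 * 3, 0.2, 0.8), 10, 3), depth = 60L)
  om <- estimateOmega(pc)
  # one-line independent computation
  f <- altCount(pc) / depth(pc)
  pb <- rowMeans(f)
  x <- (f - pb) / sqrt(pb * (1 - pb))
  brute <- crossprod(x) / nrow(x)
  # the ridge only perturbs the diagonal, and mildly
  expect_lt(max(abs(om - brute)), 1e-4 * max(abs(brute)))
  expect_true(isSymmetric(unclass(om)))
  expect_true(all(eigen(om, only.values = TRUE)$values > 0))
})

test_that("two drifted clusters give positive within- and negative between-cluster covariance", {
  sc <- simConfig(nLoci = 3000L, s = 0, pSelected = 0, mWithin = 0.05,
                  mBetween = 0.0005, bottleneckSeverity = 1, seed = 31L)
  sim <- simulateMetapopulation(sc)
  pc <- filterSnps(simulatePoolReads(sim$freqs, seed = 32L))
  om <- estimateOmega(pc)
  cl <- sc$envGoby
  within <- om[cl == 1, cl == 1]
  between <- om[cl == 1, cl == 0]
  expect_gt(median(within[upper.tri(within)]), 0)
  expect_lt(median(between), 0)
})

test_that("XtX is zero with a bilateral low-tail p when populations do not differ", {
  pc <- PoolCounts(rep("s1", 20), 1:20,
                   matrix(30L, 20, 4), matrix(10L, 20, 4))
  om <- diag(4)
  sc <- xtxScan(pc, om)
  expect_equal(sc$statistic, rep(0, 20))
  expect_equal(sc$p, rep(0, 20), tolerance = 1e-12)
  expect_true(all(sc$tail == "low"))
})

test_that("XtX equals the plain sum of squares under an identity covariance", {
  set.seed(6)
  pc <- pcFromFreqs(matrix(runif(15, 0.3, 0.7), 5, 3), depth = 80L)
  f <- altCount(pc) / depth(pc)
  pb <- rowMeans(f)
  x <- (f - pb) / sqrt(pb * (1 - pb))
  sc <- xtxScan(pc, diag(3))
  expect_equal(sc$statistic, rowSums(x^2), tolerance = 1e-10)
  # invariant to swapping reference and alternate labels
  swapped <- PoolCounts(pc@scaffold, pc@position, altCount(pc), refCount(pc),
                        poolHaploids = 80)
  expect_equal(xtxScan(swapped, diag(3))$statistic, sc$statistic,
               tolerance = 1e-10)
})

test_that("neutral XtX calibrates: mean tracks the deviation-rank J-1 and the outlier rate sits in the binomial band", {
  fx <- neutralScanFixture()
  om <- estimateOmega(fx$pc)
  sc <- xtxScan(fx$pc, om)
  J <- length(popNames(fx$pc))
  # the moment construction centres deviations on the across-population
  # mean, losing one degree of freedom: mean XtX is J - 1 by the trace
  # identity, not J
  se <- sd(sc$statistic, na.rm = TRUE) / sqrt(sum(!is.na(sc$statistic)))
  expect_lt(abs(mean(sc$statistic, na.rm = TRUE) - (J - 1)), 3 * se + 0.01)
  rate <- mean(sc$p < 0.001, na.rm = TRUE)
  band <- binomBand(sum(!is.na(sc$p)), 0.001)
  expect_gte(rate, band[1]); expect_lte(rate, band[2])
})

test_that("a planted divergent SNP ranks at the top of the XtX scan", {
  fx <- neutralScanFixture(nLoci = 5000L, seed = 77L)
  pc <- fx$pc
  # plant: frequency 0.9 in cluster A, 0.1 in cluster B at site 1
  cl <- fx$covars$goby
  alt <- altCount(pc); dep <- depth(pc)
  alt[1, cl == 1] <- round(0.9 * dep[1, cl == 1])
  alt[1, cl == 0] <- round(0.1 * dep[1, cl == 0])
  pc2 <- PoolCounts(pc@scaffold, pc@position, dep - alt, alt, poolHaploids = 80)
  sc <- xtxScan(pc2, estimateOmega(pc2))
  expect_lte(rank(-sc$statistic)[1], ceiling(0.001 * nrow(sc)))
})

test_that("C2 is zero for contrast-orthogonal deviations and calibrates under neutrality", {
  # orthogonal case: deviations symmetric within both groups
  f <- matrix(c(0.6, 0.4, 0.6, 0.4), 1, 4)
  alt <- matrix(as.integer(f * 100), 1, 4)
  pc <- PoolCounts("s1", 1L, 100L - alt, alt)
  om <- diag(4)
  sc <- c2Scan(pc, om, c(1, 1, 0, 0))
  expect_equal(sc$statistic, 0, tolerance = 1e-10)
  expect_equal(sc$p, 1)
  # neutral calibration: mean within 3 SE of 1, p-values uniform, and
  # q-based discoveries at 1% FDR in the binomial band
  fx <- neutralScanFixture()
  om <- estimateOmega(fx$pc)
  c2 <- c2Scan(fx$pc, om, fx$covars$goby)
  se <- sd(c2$statistic, na.rm = TRUE) / sqrt(sum(!is.na(c2$statistic)))
  expect_lt(abs(mean(c2$statistic, na.rm = TRUE) - 1), 3 * se)
  expect_gt(suppressWarnings(stats::ks.test(c2$p, "punif"))$p.value, 0.01)
  rate <- mean(c2$p < 0.01, na.rm = TRUE)
  band <- binomBand(sum(!is.na(c2$p)), 0.01)
  expect_gte(rate, band[1]); expect_lte(rate, band[2])
  # relabeling the groups flips the sign but not the statistic
  c2b <- c2Scan(fx$pc, om, 1 - fx$covars$goby)
  expect_equal(c2b$statistic, c2$statistic, tolerance = 1e-10)
  expect_equal(c2b$effectSign, -c2$effectSign)
})

test_that("omega regression matches a hand-worked 3-population GLS and calibrates", {
  # 3 populations, identity covariance, k standardized
  k <- as.numeric(scale(c(-1, 0, 1)))
  x <- c(0.2, -0.1, 0.3)
  beta <- sum(k * x) / sum(k * k)
  z2 <- beta^2 * sum(k * k)
  f <- 0.5 + c(0.2, -0.1, 0.3) * sqrt(0.25)   # x back-solved at pbar 0.5
  # construct a PoolCounts whose standardized deviations equal x exactly:
  # infinite-depth limit approximated by large integer counts
  alt <- matrix(as.integer(round(f * 1e6)), 1, 3)
  pc <- PoolCounts("s1", 1L, 1000000L - alt, alt)
  fr <- altCount(pc) / depth(pc)
  pb <- rowMeans(fr)
  xq <- as.numeric((fr - pb) / sqrt(pb * (1 - pb)))
  betaq <- sum(k * xq) / sum(k * k)
  sc <- omegaRegression(pc, diag(3), c(-1, 0, 1))
  expect_equal(sc$beta, betaq, tolerance = 1e-8)
  expect_equal(sc$statistic, betaq^2 * sum(k * k), tolerance = 1e-8)
  expect_error(omegaRegression(pc, diag(3), c(2, 2, 2)), "variance")
  # neutral calibration of z^2 against chi-square(1)
  fx <- neutralScanFixture()
  om <- estimateOmega(fx$pc)
  rg <- omegaRegression(fx$pc, om, fx$covars$calcium_mgL)
  se <- sd(rg$statistic, na.rm = TRUE) / sqrt(sum(!is.na(rg$statistic)))
  expect_lt(abs(mean(rg$statistic, na.rm = TRUE) - 1), 3 * se)
  rate <- mean(rg$p < 0.01, na.rm = TRUE)
  band <- binomBand(sum(!is.na(rg$p)), 0.01)
  expect_gte(rate, band[1]); expect_lte(rate, band[2])
})

test_that("quasibinomial scan matches glm() on random SNPs and handles the edge cases", {
  fx <- neutralScanFixture(nLoci = 400L, seed = 55L)
  pc <- fx$pc
  covar <- fx$covars$goby
  qb <- quasibinomialScan(pc, covar)
  # oracle: stats::glm with quasibinomial family on the rescaled counts
  d <- depth(pc); fr <- altCount(pc) / d
  set.seed(1)
  for (s in sample.int(length(pc), 5)) {
    neff <- effectiveSampleSize(80, d[s, ])
    a <- fr[s, ] * neff; r <- (1 - fr[s, ]) * neff
    a[a == 0] <- 1; r[r == 0] <- 1
    g <- suppressWarnings(stats::glm(cbind(a, r) ~ covar,
                                     family = stats::quasibinomial()))
    sg <- summary(g)$coefficients["covar", ]
    expect_equal(qb$slope[s], unname(sg["Estimate"]), tolerance = 1e-6)
    expect_equal(unname(qb$statistic[s]), unname(sg["t value"]),
                 tolerance = 1e-4)
  }
  # flat frequencies: slope near zero, p near one
  flat <- PoolCounts(rep("s1", 3), 1:3, matrix(30L, 3, 12), matrix(10L, 3, 12))
  qf <- quasibinomialScan(flat, covar)
  expect_equal(qf$slope, rep(0, 3), tolerance = 1e-10)
  expect_equal(qf$p, rep(1, 3), tolerance = 1e-6)
  # complete separation stays finite thanks to the add-one rule
  alt <- matrix(0L, 1, 12); alt[covar == 1] <- 40L
  sepPc <- PoolCounts("s1", 1L, matrix(40L, 1, 12) - alt, alt)
  qs <- quasibinomialScan(sepPc, covar)
  expect_true(is.finite(qs$p[1]))
  expect_lt(qs$p[1], 1e-4)
})

test_that("genomic control is the identity at lambda 1 and recovers a known scale", {
  p <- (1:2000 - 0.5) / 2000
  gc <- genomicControl(p)
  expect_equal(gc$lambda, 1, tolerance = 0.01)
  expect_equal(gc$pRecal, p, tolerance = 0.02)
  # scaled chi-square: z2 ~ 2 chi2(1) should give lambda near 2
  set.seed(8)
  z2 <- 2 * rchisq(50000, 1)
  praw <- pchisq(z2, 1, lower.tail = FALSE)
  gc2 <- genomicControl(praw)
  # asymptotic SE of the sample median of 2*chi2(1), delta method
  med <- 2 * qchisq(0.5, 1)
  fmed <- dchisq(med / 2, 1) / 2
  seLambda <- 1 / (2 * fmed * sqrt(5e4)) / qchisq(0.5, 1)
  expect_lt(abs(gc2$lambda - 2), 3 * seLambda)
  # deflation: recalibration with lambda < 1 shrinks small p-values
  z2d <- 0.85 * rchisq(20000, 1)
  pd <- pchisq(z2d, 1, lower.tail = FALSE)
  gcd <- genomicControl(pd)
  expect_lt(gcd$lambda, 1)
  small <- pd < 0.05
  expect_true(all(gcd$pRecal[small] < pd[small]))
  expect_warning(genomicControl(runif(10)), "100")
})

test_that("Storey q-values collapse to Benjamini-Hochberg at pi0 = 1 and are monotone", {
  expect_equal(storeyQvalues(rep(1, 5)), rep(1, 5))
  set.seed(12)
  p <- runif(1000)^1.5
  q1 <- storeyQvalues(p, pi0 = 1)
  expect_equal(q1, p.adjust(p, "BH"), tolerance = 1e-12)
  q <- storeyQvalues(p)
  expect_true(all(diff(q[order(p)]) >= -1e-12))
  expect_true(all(q >= 0 & q <= 1))
  # pi0 estimate shrinks q below BH when signal is present
  expect_true(all(q <= q1 + 1e-12))
})

test_that("candidate intersection enforces co-significance, uniqueness and direction consistency", {
  # hand-built scan tables over 8 SNPs, 6 populations (grp 1,1,1,0,0,0)
  grp <- c(1, 1, 1, 0, 0, 0)
  mkTab <- function(sig, sign) {
    data.frame(snp = 1:8, q = ifelse(1:8 %in% sig, 1e-4, 0.5),
               effectSign = sign)
  }
  # frequencies: SNPs 1-3 separated by group, others flat
  f <- matrix(0.5, 8, 6)
  f[1, ] <- c(0.8, 0.8, 0.8, 0.2, 0.2, 0.2)
  f[2, ] <- c(0.8, 0.8, 0.8, 0.2, 0.2, 0.2)
  f[3, ] <- c(0.2, 0.2, 0.2, 0.8, 0.8, 0.8)
  alt <- matrix(as.integer(f * 100), 8, 6)
  pc <- PoolCounts(rep("s1", 8), 1:8, 100L - alt, alt)
  # calcium: SNPs {1,2} in both methods; goby: {2,3}; SNP 2 shared -> dropped
  oh <- list(calcium = mkTab(c(1, 2), +1), goby = mkTab(c(2, 3), -1))
  gh <- list(calcium = mkTab(c(1, 2, 5), +1), goby = mkTab(c(2, 3), -1))
  cs <- candidateIntersection(oh, gh, pc, groups = list(calcium = grp, goby = grp))
  expect_equal(cs$calcium$snp, 1L)          # SNP 2 removed by uniqueness
  expect_equal(cs$goby$snp, 3L)
  expect_length(intersect(cs$calcium$snp, cs$goby$snp), 0)
  # disjoint method sets give an empty candidate set
  cs2 <- candidateIntersection(list(calcium = mkTab(1, 1), goby = mkTab(8, 1)),
                               list(calcium = mkTab(4, 1), goby = mkTab(7, 1)),
                               pc, groups = list(calcium = grp, goby = grp))
  expect_equal(nrow(cs2$calcium), 0L)
  expect_equal(nrow(cs2$goby), 0L)
  # disagreeing effect signs are removed as direction-inconsistent
  oh3 <- list(calcium = mkTab(1, +1), goby = mkTab(8, 1))
  gh3 <- list(calcium = mkTab(1, -1), goby = mkTab(7, 1))
  cs3 <- candidateIntersection(oh3, gh3, pc, groups = list(calcium = grp, goby = grp))
  expect_equal(nrow(cs3$calcium), 0L)
})
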