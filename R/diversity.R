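#' Pool-corrected per-site heterozygosity
#'
#' Unbiased estimator of expected heterozygosity 2p(1-p) under the two-stage
#' pool-seq sampling model (individuals into the pool, then reads from the
#' pool): h = depth/(depth-1) * nChr/(nChr-1) * 2 f (1-f), with f the
#' alternate read frequency.  Each factor undoes one sampling layer's
#' downward bias.
#'
#' @param alt alternate read count (vectorised).
#' @param depth total read depth.
#' @param nChr haploid pool size.
#' @return per-site heterozygosity estimates (NA where depth < 2).
#' @examples
#' sitePi(6, 20, 80)
#' @export
sitePi <- function(alt, depth, nChr) {
  f <- alt / depth
  h <- depth / (depth - 1) * nChr / (nChr - 1) * 2 * f * (1 - f)
  h[depth < 2] <- NA_real_
  h
}

## expected number of segregating-site "units" contributed by one site of
## depth d from a pool of n haploids, per unit theta: sum over frequency
## classes i of (1/i) * P(both alleles visible in d reads | pool class i).
## Makes S / sum(A) an unbiased per-site Watterson estimator under the
## two-stage sampling model.
.wattersonFactor <- function(depths, nChr) {
  ud <- sort(unique(depths))
  i <- seq_len(nChr - 1)
  q <- i / nChr
  av <- vapply(ud, function(d) sum((1 - q^d - (1 - q)^d) / i), numeric(1))
  av[match(depths, ud)]
}

## Tajima's D variance constants for sample size n (Tajima 1989)
.tajimaConstants <- function(n) {
  a1 <- sum(1 / seq_len(n - 1))
  a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  list(a1 = a1, e1 = c1 / a1, e2 = c2 / (a1^2 + a2))
}

#' Windowed diversity statistics for pooled data
#'
#' Computes, per non-overlapping window and population: nucleotide diversity
#' pi (mean pool-corrected site heterozygosity over covered sites),
#' Watterson's theta (segregating sites divided by the summed per-site
#' visibility factors A(d, n) = sum_i (1/i)(1 - (i/n)^d - (1-i/n)^d), which
#' makes the estimator unbiased under the two-stage pool/read sampling
#' model), and Tajima's D (the pi - theta_W contrast on the total scale
#' over sqrt(e1 S + e2 S (S-1)), variance constants evaluated at the
#' floored median n_eff).  A site is covered when its depth
#' is at least \code{minCov}; Tajima's D uses its own laxer bound
#' \code{minCovD} (coverage of at least a third of the pool size, so the
#' corrected estimator remains defined).  Windows where the covered
#' fraction of the window's assayed sites falls below \code{minFraction}
#' report NA.
#'
#' @param pc a \linkS4class{PoolCounts} object containing all sequenced
#'   sites (monomorphic sites count toward coverage with h = 0).
#' @param windowSize window length in bp (default 1e5).
#' @param minCov minimum depth for a covered site (default 20).
#' @param minCovD minimum depth for Tajima's D sites (default 13).
#' @param minFraction minimum fraction of the window covered (default 0.05).
#' @return data.frame with scaffold, start, end, pop, nSnps,
#'   fractionCovered, pi, thetaW, tajimaD.
#' @export
windowStats <- function(pc, windowSize = 1e5, minCov = 20L, minCovD = 13L,
                        minFraction = 0.05) {
  J <- length(popNames(pc))
  d <- depth(pc)
  a <- altCount(pc)
  win <- (pc@position - 1L) %/% as.integer(windowSize)
  key <- paste(pc@scaffold, win, sep = "\r")
  ukey <- unique(key)
  idxList <- split(seq_len(length(pc)), factor(key, levels = ukey))
  rows <- vector("list", length(ukey) * J)
  r <- 0L
  for (w in seq_along(ukey)) {
    idx <- idxList[[w]]
    scaf <- pc@scaffold[idx[1]]
    w0 <- win[idx[1]] * windowSize + 1
    for (j in seq_len(J)) {
      nChr <- poolHaploids(pc)[j]
      dj <- d[idx, j]; aj <- a[idx, j]
      covered <- dj >= minCov
      nCov <- sum(covered)
      frac <- nCov / length(dj)
      coveredD <- dj >= minCovD
      r <- r + 1L
      if (frac < minFraction) {
        rows[[r]] <- data.frame(scaffold = scaf, start = w0,
                                end = w0 + windowSize - 1, pop = popNames(pc)[j],
                                nSnps = NA_integer_, fractionCovered = frac,
                                pi = NA_real_, thetaW = NA_real_,
                                tajimaD = NA_real_)
        next
      }
      h <- sitePi(aj[covered], dj[covered], nChr)
      seg <- aj[covered] > 0 & aj[covered] < dj[covered]
      S <- sum(seg)
      pi <- sum(h) / nCov
      thetaW <- S / sum(.wattersonFactor(dj[covered], nChr))
      # Tajima's D on its own (laxer-coverage) site set
      tajD <- NA_real_
      if (sum(coveredD) > 0) {
        hD <- sitePi(aj[coveredD], dj[coveredD], nChr)
        segD <- aj[coveredD] > 0 & aj[coveredD] < dj[coveredD]
        SD <- sum(segD)
        thetaWD <- SD / sum(.wattersonFactor(dj[coveredD], nChr))
        ntilD <- max(2L, floor(median(effectiveSampleSize(nChr, dj[coveredD]))))
        if (SD > 0 && ntilD >= 4) {
          k <- .tajimaConstants(ntilD)
          # numerator on the total scale; variance constants at the
          # effective sample size (scale normalisation only)
          tajD <- (sum(hD) - thetaWD * sum(coveredD)) /
            sqrt(k$e1 * SD + k$e2 * SD * (SD - 1))
        }
      }
      rows[[r]] <- data.frame(scaffold = scaf, start = w0,
                              end = w0 + windowSize - 1, pop = popNames(pc)[j],
                              nSnps = S, fractionCovered = frac,
                              pi = pi, thetaW = thetaW, tajimaD = tajD)
    }
  }
  do.call(rbind, rows[seq_len(r)])
}

#' Genome-wide observed heterozygosity per population
#'
#' Mean pool-corrected site heterozygosity across all sites with depth of at
#' least \code{minCov}.
#'
#' @param pc a \linkS4class{PoolCounts} object.
#' @param minCov minimum depth per site (default 2).
#' @return named numeric vector, one value per population.
#' @export
observedHeterozygosity <- function(pc, minCov = 2L) {
  d <- depth(pc); a <- altCount(pc)
  J <- length(popNames(pc))
  out <- vapply(seq_len(J), function(j) {
    ok <- d[, j] >= minCov
    mean(sitePi(a[ok, j], d[ok, j], poolHaploids(pc)[j]))
  }, numeric(1))
  setNames(out, popNames(pc))
}

#' Two-group comparison with Welch's t and Hedges' g
#'
#' Welch's unequal-variance t-test plus the bias-corrected standardised mean
#' difference Hedges' g = Jc (m1 - m2)/s_pooled with the small-sample
#' correction Jc = 1 - 3/(4(n1+n2) - 9) and a normal-approximation 95\% CI.
#' Group 1 is the level of \code{grouping} sorted last (so with a 0/1
#' indicator, g > 0 means the indicator-1 group has the larger mean).
#'
#' @param values numeric vector of per-unit summaries.
#' @param grouping two-level factor/vector aligned with \code{values}.
#' @return list with hedgesG, ciLower, ciUpper, t, df, p, groupMeans,
#'   groupSds, n.
#' @examples
#' compareGroups(c(1, 2, 3, 2, 3, 4), c(1, 1, 1, 0, 0, 0))
#' @export
compareGroups <- function(values, grouping) {
  ok <- !is.na(values)
  values <- values[ok]; grouping <- grouping[ok]
  g <- factor(grouping)
  if (nlevels(g) != 2) stop("grouping must have exactly two levels")
  lv <- levels(g)
  x1 <- values[g == lv[2]]; x2 <- values[g == lv[1]]
  n1 <- length(x1); n2 <- length(x2)
  if (n1 < 2 || n2 < 2) stop("need at least two values per group")
  m1 <- mean(x1); m2 <- mean(x2); v1 <- var(x1); v2 <- var(x2)
  sp <- sqrt(((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2))
  Jc <- 1 - 3 / (4 * (n1 + n2) - 9)
  gh <- if (sp == 0) 0 else Jc * (m1 - m2) / sp
  seG <- sqrt((n1 + n2) / (n1 * n2) + gh^2 / (2 * (n1 + n2)))
  tt <- stats::t.test(x1, x2)
  list(hedgesG = gh, ciLower = gh - 1.959964 * seG, ciUpper = gh + 1.959964 * seG,
       t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value,
       groupMeans = c(m1, m2), groupSds = c(sqrt(v1), sqrt(v2)), n = c(n1, n2))
}
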