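## ---- Omega covariance and Omega-corrected scan statistics ----

## standardized allele-frequency deviations x_lj = (p_lj - pbar_l)/sqrt(pbar(1-pbar))
.standardizedDeviations <- function(pc) {
  f <- alleleFreq(pc)
  pbar <- rowMeans(f)
  keep <- is.finite(pbar) & pbar > 0 & pbar < 1 & !apply(!is.finite(f), 1, any)
  x <- (f[keep, , drop = FALSE] - pbar[keep]) / sqrt(pbar[keep] * (1 - pbar[keep]))
  list(x = x, keep = which(keep), dropped = sum(!keep))
}

#' Estimate the scaled covariance matrix of population allele frequencies
#'
#' Omega summarises shared population history: for each SNP the deviation of
#' each population's allele frequency from the across-population mean is
#' standardised by the binomial scale sqrt(pbar(1-pbar)); Omega is the
#' average outer product of these deviation vectors over SNPs.  Populations
#' with correlated histories show positive covariance; diverged clusters
#' show negative covariance between clusters.  SNPs monomorphic across all
#' pools carry no information and are excluded (count reported in the
#' \code{"droppedSnps"} attribute).  A ridge (epsilon = 1e-6 trace/J on the
#' diagonal, doubled as needed) guarantees positive definiteness.
#'
#' @param pc a \linkS4class{PoolCounts} object with at least as many SNPs as
#'   populations.
#' @return a J x J symmetric positive-definite matrix with population names.
#' @export
estimateOmega <- function(pc) {
  J <- length(popNames(pc))
  if (J < 2) stop("need at least two populations")
  sd <- .standardizedDeviations(pc)
  if (nrow(sd$x) < J) stop("need at least as many informative SNPs as populations")
  omega <- crossprod(sd$x) / nrow(sd$x)
  eps <- 1e-6 * sum(diag(omega)) / J
  # ridge until the matrix is comfortably invertible (the moment estimator
  # is rank-deficient by one: deviations from the mean sum to zero)
  while (inherits(try(chol(omega), silent = TRUE), "try-error") ||
         rcond(omega) < 1e-10) {
    omega <- omega + diag(eps, J)
    eps <- eps * 2
  }
  dimnames(omega) <- list(popNames(pc), popNames(pc))
  attr(omega, "droppedSnps") <- sd$dropped
  omega
}

## shared machinery: x matrix aligned to pc rows (NA rows for dropped SNPs)
.xMatrix <- function(pc) {
  sd <- .standardizedDeviations(pc)
  x <- matrix(NA_real_, length(pc), length(popNames(pc)))
  x[sd$keep, ] <- sd$x
  x
}

.checkOmega <- function(omega, J) {
  if (!isTRUE(all.equal(omega, t(omega), tolerance = 1e-8)))
    stop("omega must be symmetric")
  inv <- try(solve(omega), silent = TRUE)
  if (inherits(inv, "try-error"))
    stop("omega is singular: re-estimate with ridge regularization (estimateOmega)")
  inv
}

#' XtX differentiation scan
#'
#' XtX is an Omega-corrected SNP-specific differentiation statistic: the
#' squared Mahalanobis length of the standardised allele-frequency deviation
#' vector, chi-squared with J degrees of freedom under neutrality.  The
#' bilateral p-value flags both tails: large XtX resembles divergent
#' (positive) selection, small XtX resembles balancing selection.
#'
#' @param pc a \linkS4class{PoolCounts} object.
#' @param omega J x J covariance matrix from [estimateOmega()].
#' @param pOutlier bilateral p-value threshold flagging outliers
#'   (default 0.001).
#' @return data.frame with snp, statistic, p (bilateral), outlier flag and
#'   tail ("high" = divergent-like, "low" = balancing-like).
#' @export
xtxScan <- function(pc, omega, pOutlier = 0.001) {
  J <- length(popNames(pc))
  inv <- .checkOmega(omega, J)
  x <- .xMatrix(pc)
  xtx <- rowSums((x %*% inv) * x)
  lower <- pchisq(xtx, df = J)
  p <- 2 * pmin(lower, 1 - lower)
  data.frame(snp = seq_len(length(pc)), statistic = xtx, p = p,
             outlier = !is.na(p) & p < pOutlier,
             tail = ifelse(lower >= 0.5, "high", "low"))
}

#' C2 contrast scan for a binary covariable
#'
#' The C2 statistic projects each SNP's standardised deviation vector onto a
#' centred +/-1 group contrast and rescales by the contrast's variance under
#' Omega: C2 = (c'x)^2 / (c' Omega c), chi-squared with 1 df under
#' neutrality.  Suited to presence/absence covariables.
#'
#' @param pc a \linkS4class{PoolCounts} object.
#' @param omega covariance matrix from [estimateOmega()].
#' @param contrast binary (0/1 or logical) group membership per population;
#'   both levels must be present.
#' @return data.frame with snp, statistic, p, effectSign (sign of the
#'   contrast projection: +1 means higher alternate frequency in the group
#'   coded 1) and q (Storey q-values).
#' @export
c2Scan <- function(pc, omega, contrast) {
  J <- length(popNames(pc))
  contrast <- as.numeric(contrast)
  if (length(contrast) != J) stop("contrast must have one entry per population")
  if (length(unique(contrast)) != 2) stop("contrast must have exactly two levels")
  cvec <- ifelse(contrast == max(contrast), 1, -1)
  cvec <- cvec - mean(cvec)
  inv <- .checkOmega(omega, J)
  x <- .xMatrix(pc)
  num <- as.vector(x %*% cvec)
  den <- as.numeric(cvec %*% omega %*% cvec)
  c2 <- num^2 / den
  p <- pchisq(c2, df = 1, lower.tail = FALSE)
  data.frame(snp = seq_len(length(pc)), statistic = c2, p = p,
             effectSign = sign(num), q = storeyQvalues(p))
}

#' Omega-corrected association with a continuous covariable
#'
#' Generalised-least-squares regression of each SNP's standardised
#' deviation vector on a standardised covariable under the Omega covariance:
#' beta = (k' Omega^-1 x)/(k' Omega^-1 k) with variance 1/(k' Omega^-1 k);
#' z^2 = beta^2 (k' Omega^-1 k) is chi-squared with 1 df under the null.
#' This is the deterministic association scan for covariables measured on a
#' continuous scale (e.g. a calcium gradient).
#'
#' @param pc a \linkS4class{PoolCounts} object.
#' @param omega covariance matrix from [estimateOmega()].
#' @param covar numeric covariable per population; standardised internally
#'   to mean 0 and variance 1.
#' @return data.frame with snp, beta, statistic (z^2), p, effectSign and q.
#' @export
omegaRegression <- function(pc, omega, covar) {
  J <- length(popNames(pc))
  if (length(covar) != J) stop("covar must have one entry per population")
  if (sd(covar) == 0) stop("covariable has zero variance")
  k <- as.numeric(scale(covar))
  inv <- .checkOmega(omega, J)
  kOk <- as.numeric(k %*% inv %*% k)
  beta <- as.vector(.xMatrix(pc) %*% (inv %*% k)) / kOk
  z2 <- beta^2 * kOk
  p <- pchisq(z2, df = 1, lower.tail = FALSE)
  data.frame(snp = seq_len(length(pc)), beta = beta, statistic = z2, p = p,
             effectSign = sign(beta), q = storeyQvalues(p))
}

#' Quasibinomial GLM scan of allele frequencies on a binary covariable
#'
#' Fits, per SNP, a quasibinomial logistic regression of allele frequency on
#' the binary covariable, with allele counts rescaled to the pool-seq
#' effective sample size n_eff = (n C - 1)/(n + C) and one read added to
#' zero cells.  With a single binary predictor the IRLS fixed point is
#' closed-form (group-wise weighted frequencies), which this implementation
#' uses, vectorised across SNPs; the dispersion is the Pearson chi-square
#' over J - 2 df and the slope is tested against a t reference with J - 2
#' df.  Under neutrality p-values are approximately uniform; residual
#' structure is absorbed afterwards by [genomicControl()].
#'
#' @param pc a \linkS4class{PoolCounts} object.
#' @param covar binary (0/1) covariable per population.
#' @param addOne add one to zero count cells after rescaling (default TRUE).
#' @return data.frame with snp, slope (log-odds difference, group 1 minus
#'   group 0), statistic (t), p, effectSign.
#' @export
quasibinomialScan <- function(pc, covar, addOne = TRUE) {
  J <- length(popNames(pc))
  covar <- as.numeric(covar)
  if (length(covar) != J) stop("covar must have one entry per population")
  if (!all(covar %in% 0:1) || length(unique(covar)) != 2)
    stop("covar must be binary 0/1 with both levels present")
  if (J < 4) stop("need at least 4 populations for a J-2 df dispersion")
  d <- depth(pc)
  f <- altCount(pc) / pmax(d, 1)
  neff <- matrix(0, nrow(d), ncol(d))
  for (j in seq_len(J)) neff[, j] <- effectiveSampleSize(poolHaploids(pc)[j], pmax(d[, j], 1))
  a <- f * neff          # rescaled alternate counts
  r <- (1 - f) * neff    # rescaled reference counts
  if (addOne) { a[a == 0] <- 1; r[r == 0] <- 1 }
  n <- a + r
  g1 <- covar == 1
  # group-wise weighted MLE frequencies
  p1 <- rowSums(a[, g1, drop = FALSE]) / rowSums(n[, g1, drop = FALSE])
  p0 <- rowSums(a[, !g1, drop = FALSE]) / rowSums(n[, !g1, drop = FALSE])
  pfit <- matrix(0, nrow(a), J)
  pfit[, g1] <- p1; pfit[, !g1] <- p0
  # Pearson dispersion over J - 2 df
  pearson <- rowSums((a - n * pfit)^2 / (n * pfit * (1 - pfit)))
  disp <- pearson / (J - 2)
  slope <- qlogis(p1) - qlogis(p0)
  W1 <- rowSums((n * pfit * (1 - pfit))[, g1, drop = FALSE])
  W0 <- rowSums((n * pfit * (1 - pfit))[, !g1, drop = FALSE])
  se <- sqrt(disp * (1 / W1 + 1 / W0))
  # zero Pearson dispersion (all pools in a group identical) collapses the
  # t denominator; a floor keeps flat SNPs at p ~ 1 and perfectly
  # separated SNPs at the epsilon floor instead of 0/0
  tstat <- slope / pmax(se, 1e-8)
  p <- 2 * pt(abs(tstat), df = J - 2, lower.tail = FALSE)
  bad <- !is.finite(tstat)
  p[bad] <- NA_real_
  p <- pmax(p, .Machine$double.eps)
  data.frame(snp = seq_len(length(pc)), slope = slope, statistic = tstat,
             p = p, effectSign = sign(slope), converged = !bad)
}

#' Genomic-control recalibration of p-values to an empirical null
#'
#' Converts each p-value to its chi-squared(1) quantile, estimates the
#' genomic inflation factor lambda as the ratio of the median observed
#' statistic to the theoretical null median (0.4549364), and maps the
#' rescaled statistics back to upper-tail p-values.  lambda > 1 indicates
#' inflation (structure not captured by the model); lambda < 1 deflation.
#'
#' @param pRaw vector of raw p-values in (0, 1].
#' @return list with \code{lambda} and \code{pRecal} (same length as input;
#'   NAs propagate).
#' @export
genomicControl <- function(pRaw) {
  ok <- !is.na(pRaw)
  if (any(pRaw[ok] <= 0 | pRaw[ok] > 1)) stop("p-values must lie in (0, 1]")
  if (sum(ok) < 100) warning("fewer than 100 p-values: lambda estimate is unstable")
  z2 <- qchisq(pRaw, df = 1, lower.tail = FALSE)
  lambda <- median(z2[ok]) / qchisq(0.5, df = 1)
  pRecal <- pchisq(z2 / lambda, df = 1, lower.tail = FALSE)
  list(lambda = lambda, pRecal = pRecal)
}

#' Storey q-values
#'
#' Estimates the null proportion pi0 from the p-value density above 0.5
#' (pi0 = min(1, #\{p > 0.5\} / (0.5 m))) and converts each p-value into a
#' q-value, q_(i) = pi0 m p_(i) / i with the cumulative-minimum enforcement.
#' With pi0 = 1 the procedure reduces exactly to Benjamini-Hochberg.
#'
#' @param p vector of p-values in [0, 1] (NAs propagate).
#' @param pi0 optional fixed null proportion; default: estimate from p.
#' @return q-values, same length and order as \code{p}.
#' @export
storeyQvalues <- function(p, pi0 = NULL) {
  out <- rep(NA_real_, length(p))
  ok <- which(!is.na(p))
  pv <- p[ok]
  if (any(pv < 0 | pv > 1)) stop("p-values must lie in [0, 1]")
  m <- length(pv)
  if (m == 0) return(out)
  if (is.null(pi0)) pi0 <- min(1, sum(pv > 0.5) / (0.5 * m))
  o <- order(pv, decreasing = TRUE)
  q <- pi0 * m * pv[o] / rank(pv, ties.method = "max")[o]
  q <- pmin(1, cummin(q))
  out[ok[o]] <- q
  out
}

#' Candidate intersection across scan methods with consistency filtering
#'
#' Combines, per covariable, the Omega-based association scan with the
#' quasibinomial GLM scan: a candidate must be significant in both, must not
#' be significant for the other covariable's intersection (uniqueness), and
#' must pass a direction-consistency rule: (a) the two methods' effect signs
#' agree, and (b) in each covariable group at least ceiling(5/6 of the
#' group's populations) lie on the model-implied side of the
#' across-population mean frequency.
#'
#' @param omegaHits,glmHits named lists (one element per covariable) of
#'   scan data.frames carrying \code{snp}, \code{q} (or \code{p}) and
#'   \code{effectSign}; \code{omegaHits} from [c2Scan()] /
#'   [omegaRegression()], \code{glmHits} from [quasibinomialScan()] with
#'   recalibrated q-values added as column \code{q}.
#' @param pc the \linkS4class{PoolCounts} the scans were run on.
#' @param groups named list (per covariable) of binary group membership per
#'   population (continuous covariables are split at their median).
#' @param fdr q-value threshold for the GLM and C2 scans (default 0.01).
#' @param omegaFdr q-value threshold for the Omega-regression scan
#'   (default 0.001, a deliberately stricter "decisive" stringency).
#' @param omegaIsRegression named logical: TRUE where the Omega scan is the
#'   regression (stricter threshold applies).
#' @return named list of data.frames (snp, directionConsistent, unique);
#'   the candidate sets of the two covariables are disjoint.
#' @export
candidateIntersection <- function(omegaHits, glmHits, pc, groups,
                                  fdr = 0.01, omegaFdr = 0.001,
                                  omegaIsRegression = NULL) {
  covs <- names(omegaHits)
  stopifnot(identical(sort(covs), sort(names(glmHits))),
            all(covs %in% names(groups)))
  if (is.null(omegaIsRegression))
    omegaIsRegression <- setNames(rep(FALSE, length(covs)), covs)
  f <- alleleFreq(pc)
  fbar <- rowMeans(f)
  sigSet <- function(tab, thr) tab$snp[!is.na(tab$q) & tab$q < thr]
  inter <- lapply(covs, function(cv) {
    thr <- if (isTRUE(omegaIsRegression[[cv]])) omegaFdr else fdr
    intersect(sigSet(omegaHits[[cv]], thr), sigSet(glmHits[[cv]], fdr))
  })
  names(inter) <- covs
  shared <- Reduce(intersect, inter)
  out <- lapply(covs, function(cv) {
    snps <- setdiff(inter[[cv]], shared)
    if (!length(snps))
      return(data.frame(snp = integer(), directionConsistent = logical(),
                        unique = logical()))
    sO <- omegaHits[[cv]]$effectSign[match(snps, omegaHits[[cv]]$snp)]
    sG <- glmHits[[cv]]$effectSign[match(snps, glmHits[[cv]]$snp)]
    signOk <- sO == sG & sO != 0
    grp <- groups[[cv]]
    if (!all(grp %in% 0:1)) grp <- as.integer(grp > median(grp))
    need1 <- ceiling(5 / 6 * sum(grp == 1))
    need0 <- ceiling(5 / 6 * sum(grp == 0))
    sepOk <- vapply(seq_along(snps), function(i) {
      l <- snps[i]
      dev <- f[l, ] - fbar[l]
      side <- sG[i] * dev            # model-implied: group1 above mean if slope>0
      sum(side[grp == 1] > 0) >= need1 && sum(-side[grp == 0] > 0) >= need0
    }, logical(1))
    keep <- signOk & sepOk
    data.frame(snp = snps[keep],
               directionConsistent = rep(TRUE, sum(keep)),
               unique = rep(TRUE, sum(keep)))
  })
  names(out) <- covs
  attr(out, "removed") <- lapply(covs, function(cv) {
    setdiff(inter[[cv]], c(shared, out[[cv]]$snp))
  })
  out
}
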