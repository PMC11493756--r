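#' Pairwise pool-aware FST matrix
#'
#' Identity-probability estimator with the two-stage pool correction: per
#' SNP and pool the within-pool identity is Q1 = 1 - h (h from [sitePi()]),
#' the between-pool identity for a pair is Q2 = 1 - [f_i(1-f_j) +
#' f_j(1-f_i)], and the multilocus estimate is the ratio of sums
#' FST = sum(Q1bar - Q2) / sum(1 - Q2) over SNPs (Q1bar = pair mean of Q1).
#' SNPs with zero depth in either pool of a pair are skipped for that pair.
#'
#' @param pc a \linkS4class{PoolCounts} object.
#' @param snpIds optional site subset (e.g. non-outliers from a scan);
#'   default: all sites.
#' @return J x J symmetric matrix, zero diagonal, population names attached.
#' @export
pairwiseFst <- function(pc, snpIds = NULL) {
  J <- length(popNames(pc))
  if (J < 2) stop("need at least two populations")
  d <- depth(pc); a <- altCount(pc)
  if (!is.null(snpIds)) {         # may repeat sites (bootstrap resamples)
    d <- d[snpIds, , drop = FALSE]
    a <- a[snpIds, , drop = FALSE]
  }
  if (nrow(d) == 0) stop("empty SNP subset")
  f <- a / d                                    # NaN at zero depth
  h <- matrix(0, nrow(d), J)
  for (j in seq_len(J)) h[, j] <- sitePi(a[, j], d[, j], poolHaploids(pc)[j])
  Q1 <- 1 - h
  out <- matrix(0, J, J, dimnames = list(popNames(pc), popNames(pc)))
  for (i in seq_len(J - 1)) for (j in (i + 1):J) {
    ok <- d[, i] >= 2 & d[, j] >= 2
    Q2 <- 1 - (f[ok, i] * (1 - f[ok, j]) + f[ok, j] * (1 - f[ok, i]))
    Q1b <- (Q1[ok, i] + Q1[ok, j]) / 2
    out[i, j] <- out[j, i] <- sum(Q1b - Q2) / sum(1 - Q2)
  }
  out
}

#' UPGMA tree from a distance matrix
#'
#' Average-linkage agglomeration; ties between merge candidates are broken
#' by the smallest population index (the default order of
#' \code{stats::hclust}).  The returned \code{ape::phylo} tree is
#' ultrametric with leaf depth equal to half the cophenetic distance.
#'
#' @param dist symmetric distance matrix (e.g. from [pairwiseFst()]).
#' @return an \code{ape} \code{phylo} object.
#' @export
upgmaTree <- function(dist) {
  hc <- hclust(as.dist(dist), method = "average")
  ape::as.phylo(hc)
}

#' Bootstrap support for UPGMA clades
#'
#' Resamples SNPs with replacement \code{nBoot} times, recomputes the FST
#' matrix and UPGMA tree, and reports for each internal node of the original
#' tree the fraction of bootstrap trees containing the same clade.
#'
#' @param pc a \linkS4class{PoolCounts} object.
#' @param snpIds optional site subset used for the tree.
#' @param nBoot number of bootstrap replicates (default 1000).
#' @param seed integer seed.
#' @return list with \code{tree} (phylo, node labels = support fractions)
#'   and \code{support} (numeric per internal node).
#' @export
bootstrapSupport <- function(pc, snpIds = NULL, nBoot = 1000L, seed = 1L) {
  if (!is.null(snpIds)) pc <- pc[snpIds, ]
  tree <- upgmaTree(pairwiseFst(pc))
  set.seed(seed)
  L <- length(pc)
  boots <- vector("list", nBoot)
  for (b in seq_len(nBoot)) {
    idx <- sample.int(L, L, replace = TRUE)
    boots[[b]] <- upgmaTree(pairwiseFst(pc, idx))
  }
  counts <- ape::prop.clades(tree, boots, rooted = TRUE)
  counts[is.na(counts)] <- 0
  support <- counts / nBoot
  tree$node.label <- format(support, digits = 3)
  list(tree = tree, support = support)
}

#' Mantel test between two distance matrices
#'
#' Pearson correlation of the off-diagonal entries with a one-sided
#' (positive-association) permutation p-value, delegating to
#' \code{vegan::mantel}.
#'
#' @param m1,m2 symmetric matrices with zero diagonals.
#' @param nPerm number of permutations (default 9999).
#' @param seed integer seed.
#' @param dropPairs optional integer vector of population indices to drop
#'   before testing (e.g. known outlying pairs).
#' @return list with r, r2, p, nPerm, seed.
#' @export
mantelTest <- function(m1, m2, nPerm = 9999L, seed = 1L, dropPairs = NULL) {
  if (!is.null(dropPairs)) {
    keep <- setdiff(seq_len(nrow(m1)), dropPairs)
    m1 <- m1[keep, keep]; m2 <- m2[keep, keep]
  }
  stopifnot(all(dim(m1) == dim(m2)))
  set.seed(seed)
  mt <- vegan::mantel(as.dist(m1), as.dist(m2), permutations = nPerm)
  list(r = unname(mt$statistic), r2 = unname(mt$statistic)^2,
       p = mt$signif, nPerm = nPerm, seed = seed)
}

#' Rousset's linearised genetic distance
#'
#' @param fst FST value(s) or matrix.
#' @return fst / (1 - fst), elementwise.
#' @export
ibdTransform <- function(fst) fst / (1 - fst)

#' Squared Mahalanobis environmental distance between populations
#'
#' Distance computed on the (calcium, predator-indicator) covariable pairs
#' under their across-population covariance.
#'
#' @param covars data.frame or matrix with one row per population and the
#'   environmental covariables as columns.
#' @return symmetric matrix of squared Mahalanobis distances.
#' @export
envDistance <- function(covars) {
  x <- as.matrix(covars)
  S <- cov(x)
  if (all(S == 0)) return(matrix(0, nrow(x), nrow(x)))
  Sinv <- solve(S)
  J <- nrow(x)
  out <- matrix(0, J, J)
  for (i in seq_len(J - 1)) for (j in (i + 1):J) {
    dv <- x[i, ] - x[j, ]
    out[i, j] <- out[j, i] <- as.numeric(dv %*% Sinv %*% dv)
  }
  rownames(out) <- colnames(out) <- rownames(x)
  out
}

#' Forstner-Moonen distance between covariance matrices
#'
#' FMD(A, B) = sqrt(sum_i log^2 lambda_i) over the generalized eigenvalues
#' lambda_i of (A, B).  Zero iff A = B; symmetric in its arguments.
#'
#' @param omega1,omega2 symmetric positive-definite matrices of equal
#'   dimension.
#' @return non-negative scalar distance.
#' @examples
#' fmd(diag(3), 2 * diag(3))   # sqrt(3) * log(2)
#' @export
fmd <- function(omega1, omega2) {
  stopifnot(all(dim(omega1) == dim(omega2)))
  ev <- eigen(solve(omega2, omega1), only.values = TRUE)$values
  ev <- Re(ev)
  if (any(ev <= 0)) stop("matrices must be positive definite")
  sqrt(sum(log(ev)^2))
}
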