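#' @import methods
#' @importFrom stats median pchisq qchisq rbinom rpois runif rnorm sd var
#'   cor pt optim quantile setNames rhyper p.adjust cov qlogis
#'   mahalanobis as.dist hclust
#' @importFrom utils read.table write.table head tail
#' @useDynLib poolscape, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' PoolCounts: pooled allele counts at biallelic sites
#'
#' The central container for pool-seq data: per-site, per-population read
#' counts for the reference and alternate allele, together with site
#' coordinates and per-pool haploid sample sizes.  The two count matrices
#' have one row per site and one column per population; depth at a site is
#' \code{refCount + altCount}.  Positions are 1-based and strictly increasing
#' within a scaffold.
#'
#' @slot scaffold character vector, one entry per site.
#' @slot position integer vector of 1-based positions.
#' @slot refCount,altCount integer matrices, sites x populations.
#' @slot poolHaploids integer vector of haploid pool sizes (default 80:
#'   pools of 40 diploids).
#' @slot popNames character vector of population identifiers.
#' @slot multiallelic logical vector flagging sites where more than two
#'   nucleotides segregate above the parser's minimum count.
#'
#' @export
setClass("PoolCounts",
  representation(
    scaffold = "character",
    position = "integer",
    refCount = "matrix",
    altCount = "matrix",
    poolHaploids = "integer",
    popNames = "character",
    multiallelic = "logical"
  )
)

setValidity("PoolCounts", function(object) {
  msg <- character()
  L <- length(object@scaffold)
  J <- length(object@popNames)
  if (length(object@position) != L) msg <- c(msg, "position length != scaffold length")
  if (!all(dim(object@refCount) == c(L, J)) || !all(dim(object@altCount) == c(L, J)))
    msg <- c(msg, "count matrices must be sites x populations")
  if (length(object@poolHaploids) != J) msg <- c(msg, "poolHaploids length != population count")
  if (any(object@poolHaploids <= 1)) msg <- c(msg, "poolHaploids must exceed 1")
  if (L > 0 && (any(object@refCount < 0) || any(object@altCount < 0)))
    msg <- c(msg, "counts must be non-negative")
  if (length(object@multiallelic) != L) msg <- c(msg, "multiallelic flag length != site count")
  if (L > 1) {
    ord <- order(object@scaffold, object@position)
    d <- diff(object@position)
    same <- object@scaffold[-1] == object@scaffold[-L]
    if (any(same & d <= 0)) msg <- c(msg, "positions must be strictly increasing within a scaffold")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a PoolCounts object
#'
#' @param scaffold character vector of scaffold ids per site.
#' @param position integer vector of 1-based site positions.
#' @param refCount,altCount integer matrices (sites x populations) of reads
#'   carrying the reference and alternate allele.
#' @param poolHaploids haploid pool size(s); recycled across populations.
#' @param popNames population identifiers (default \code{pop1 ... popJ}).
#' @param multiallelic optional logical flag per site.
#' @return A \linkS4class{PoolCounts} object.
#' @examples
#' pc <- PoolCounts(scaffold = c("s1", "s1"), position = c(10L, 20L),
#'                  refCount = matrix(10L, 2, 3), altCount = matrix(5L, 2, 3),
#'                  poolHaploids = 80)
#' depth(pc)
#' @export
PoolCounts <- function(scaffold, position, refCount, altCount,
                       poolHaploids = 80L, popNames = NULL,
                       multiallelic = NULL) {
  refCount <- as.matrix(refCount)
  altCount <- as.matrix(altCount)
  storage.mode(refCount) <- "integer"
  storage.mode(altCount) <- "integer"
  J <- ncol(refCount)
  if (is.null(popNames)) popNames <- paste0("pop", seq_len(J))
  if (is.null(multiallelic)) multiallelic <- rep(FALSE, nrow(refCount))
  poolHaploids <- as.integer(rep_len(poolHaploids, J))
  new("PoolCounts",
    scaffold = as.character(scaffold), position = as.integer(position),
    refCount = refCount, altCount = altCount,
    poolHaploids = poolHaploids, popNames = as.character(popNames),
    multiallelic = as.logical(multiallelic))
}

#' @describeIn PoolCounts number of sites
#' @param x,object a \code{PoolCounts} object
#' @export
setMethod("length", "PoolCounts", function(x) length(x@scaffold))

#' Accessors for PoolCounts
#'
#' \code{refCount}, \code{altCount}, \code{depth}, \code{poolHaploids},
#' \code{popNames}, \code{siteInfo} and \code{alleleFreq} extract the
#' corresponding pieces of a \linkS4class{PoolCounts} object.
#' \code{alleleFreq} returns the per-site, per-population alternate read
#' frequency (NaN where depth is zero).
#'
#' @param x a \code{PoolCounts} object.
#' @name PoolCounts-accessors
NULL

#' @rdname PoolCounts-accessors
#' @export
refCount <- function(x) x@refCount
#' @rdname PoolCounts-accessors
#' @export
altCount <- function(x) x@altCount
#' @rdname PoolCounts-accessors
#' @export
depth <- function(x) x@refCount + x@altCount
#' @rdname PoolCounts-accessors
#' @export
poolHaploids <- function(x) x@poolHaploids
#' @rdname PoolCounts-accessors
#' @export
popNames <- function(x) x@popNames
#' @rdname PoolCounts-accessors
#' @export
siteInfo <- function(x) data.frame(scaffold = x@scaffold, position = x@position,
                                   multiallelic = x@multiallelic)
#' @rdname PoolCounts-accessors
#' @export
alleleFreq <- function(x) {
  d <- depth(x)
  f <- x@altCount / d
  f[d == 0] <- NaN
  f
}

#' @describeIn PoolCounts subset sites (i) and/or populations (j)
#' @param i,j site / population index
#' @param ... ignored
#' @param drop ignored
#' @export
setMethod("[", "PoolCounts", function(x, i, j, ..., drop = FALSE) {
  if (missing(i)) i <- seq_along(x@scaffold)
  if (missing(j)) j <- seq_along(x@popNames)
  new("PoolCounts",
    scaffold = x@scaffold[i], position = x@position[i],
    refCount = x@refCount[i, j, drop = FALSE],
    altCount = x@altCount[i, j, drop = FALSE],
    poolHaploids = x@poolHaploids[j], popNames = x@popNames[j],
    multiallelic = x@multiallelic[i])
})

setMethod("show", "PoolCounts", function(object) {
  cat("PoolCounts object\n",
      " sites:       ", length(object@scaffold), "\n",
      " populations: ", length(object@popNames), " (",
      paste(head(object@popNames, 4), collapse = ", "),
      if (length(object@popNames) > 4) ", ..." else "", ")\n",
      " pool sizes:  ", paste(unique(object@poolHaploids), collapse = "/"),
      " haploids\n", sep = "")
})

#' Folded joint site-frequency spectrum for a population pair
#'
#' Counts of SNPs by minor-allele copy number in each of two populations,
#' folded because the ancestral allele is unknown.  Cell (i, j) (0-based)
#' holds the number of sites with i minor copies in population 1 and j in
#' population 2; the mask flags cells excluded from the composite
#' likelihood (low-frequency cells and the two monomorphic corners).
#'
#' @slot counts numeric (n1+1) x (n2+1) matrix.
#' @slot mask logical matrix of the same shape; TRUE = excluded.
#' @slot sampleSizes integer vector (n1, n2) of haploid sample sizes.
#' @slot totalLength total sequence length the SNPs were called on (bp).
#' @slot snpsUsed,snpsTotal SNP bookkeeping for the effective-length formula.
#' @export
setClass("Folded2DSFS",
  representation(
    counts = "matrix",
    mask = "matrix",
    sampleSizes = "integer",
    totalLength = "numeric",
    snpsUsed = "numeric",
    snpsTotal = "numeric"
  )
)

setValidity("Folded2DSFS", function(object) {
  msg <- character()
  n1 <- object@sampleSizes[1]; n2 <- object@sampleSizes[2]
  if (!all(dim(object@counts) == c(n1 + 1, n2 + 1)))
    msg <- c(msg, "counts must be (n1+1) x (n2+1)")
  if (!all(dim(object@mask) == dim(object@counts)))
    msg <- c(msg, "mask shape must match counts")
  if (any(object@counts < 0)) msg <- c(msg, "counts must be non-negative")
  if (!object@mask[1, 1] || !object@mask[n1 + 1, n2 + 1])
    msg <- c(msg, "monomorphic corners must be masked")
  if (length(msg)) msg else TRUE
})

setMethod("show", "Folded2DSFS", function(object) {
  cat("Folded2DSFS: ", object@sampleSizes[1], " x ", object@sampleSizes[2],
      " haploids; ", sum(object@counts[!object@mask]),
      " SNPs in ", sum(!object@mask), " unmasked cells\n", sep = "")
})
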