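#' Read a sync file of pooled allele counts
#'
#' Parses the popoolation2 sync dialect: one line per site with scaffold,
#' 1-based position, reference base, then one "A:T:C:G:N:del" colon string
#' per population.  The two most frequent nucleotides summed across all
#' pools become the reference/alternate pair (the stated reference base is
#' used to orient them when it is one of the two); N and deletion counts
#' never contribute to depth.  Sites where a third nucleotide exceeds
#' \code{minCount} reads overall are flagged multiallelic.
#'
#' @param path path to a sync file (plain text, tab or whitespace separated).
#' @param poolHaploids haploid size per pool (default 80).
#' @param minCount read threshold above which a third allele flags the site
#'   as multiallelic (default 2).
#' @return A \linkS4class{PoolCounts} object.
#' @seealso [writeSync()], [filterSnps()]
#' @export
readSync <- function(path, poolHaploids = 80L, minCount = 2L) {
  if (!file.exists(path)) stop("sync file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    return(PoolCounts(character(), integer(),
                      matrix(0L, 0, 1), matrix(0L, 0, 1),
                      poolHaploids = poolHaploids))
  }
  fields <- strsplit(lines, "[ \t]+")
  nf <- lengths(fields)
  if (any(nf != nf[1]))
    stop("malformed sync line ", which(nf != nf[1])[1], ": expected ",
         nf[1], " columns, found ", nf[nf != nf[1]][1])
  J <- nf[1] - 3L
  if (J < 1) stop("sync file has no population columns")
  m <- do.call(rbind, fields)
  scaffold <- m[, 1]
  position <- suppressWarnings(as.integer(m[, 2]))
  if (anyNA(position)) stop("malformed position on line ", which(is.na(position))[1])
  refBase <- toupper(m[, 3])
  L <- length(scaffold)
  # counts[site, pop, nucleotide] for A,T,C,G (N/del parsed but dropped)
  cnt <- array(0L, dim = c(L, J, 4L))
  for (j in seq_len(J)) {
    parts <- strsplit(m[, j + 3L], ":", fixed = TRUE)
    if (any(lengths(parts) != 6L))
      stop("malformed count string on line ", which(lengths(parts) != 6L)[1],
           " (expected 6 colon-separated fields)")
    v <- suppressWarnings(as.integer(unlist(parts)))
    if (anyNA(v)) stop("non-integer count on line ",
                       ceiling(which(is.na(v))[1] / 6))
    v <- matrix(v, ncol = 6L, byrow = TRUE)
    cnt[, j, ] <- v[, 1:4]
  }
  tot <- apply(cnt, c(1, 3), sum)          # site x nucleotide totals
  nucs <- c("A", "T", "C", "G")
  ord <- t(apply(tot, 1, order, decreasing = TRUE))
  top1 <- ord[, 1]; top2 <- ord[, 2]
  # orient by the stated reference base where it is among the top two
  refIdx <- match(refBase, nucs)
  swap <- !is.na(refIdx) & refIdx == top2
  tmp <- top1[swap]; top1[swap] <- top2[swap]; top2[swap] <- tmp
  third <- ord[, 3]
  multi <- tot[cbind(seq_len(L), third)] > minCount
  refCount <- matrix(0L, L, J); altCount <- matrix(0L, L, J)
  for (j in seq_len(J)) {
    refCount[, j] <- cnt[cbind(seq_len(L), j, top1)]
    altCount[, j] <- cnt[cbind(seq_len(L), j, top2)]
  }
  PoolCounts(scaffold, position, refCount, altCount,
             poolHaploids = poolHaploids, multiallelic = multi)
}

#' Write a PoolCounts object as a sync file
#'
#' Reference counts are written in the A slot and alternate counts in the T
#' slot of the colon string (the sync format is nucleotide-resolved but a
#' biallelic PoolCounts only retains two alleles); \code{readSync} recovers
#' an identical object from the output.
#'
#' @param pc a \linkS4class{PoolCounts} object.
#' @param path output path.
#' @export
writeSync <- function(pc, path) {
  L <- length(pc)
  J <- length(popNames(pc))
  cols <- vapply(seq_len(J), function(j) {
    paste(refCount(pc)[, j], altCount(pc)[, j], 0L, 0L, 0L, 0L, sep = ":")
  }, character(L))
  if (L == 1) cols <- matrix(cols, nrow = 1)
  out <- cbind(pc@scaffold, pc@position, "A", cols)
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' SNP filtering for pooled counts
#'
#' Applies the standard pool-seq site filters: drop multiallelic sites, keep
#' sites where every population's depth lies in [\code{minCov},
#' \code{maxCov}], each retained allele has at least \code{minCount} reads
#' summed across populations, and the pooled minor-allele frequency (on read
#' counts summed over all pools) is at least \code{minMaf}.  All thresholds
#' are inclusive.  The number of sites removed by each rule (applied in
#' sequence) is recorded in the \code{"filterLog"} attribute.
#'
#' @param pc a \linkS4class{PoolCounts} object.
#' @param minCount minimum reads per allele summed across populations
#'   (default 2, removing singleton-supported alleles).
#' @param minCov,maxCov per-population depth bounds (defaults 5 and 300).
#' @param minMaf minimal pooled minor-allele frequency (default 0.0125,
#'   i.e. 1/80: a single chromosome in a pool of 80).
#' @param dropMultiallelic drop sites flagged multiallelic (default TRUE).
#' @return A filtered \code{PoolCounts}; attribute \code{filterLog} is a
#'   data.frame of per-rule removal counts.
#' @examples
#' pc <- PoolCounts(c("s1","s1"), c(1L, 2L),
#'                  refCount = matrix(c(10L, 1L, 9L, 0L), 2, 2),
#'                  altCount = matrix(c(5L, 9L, 6L, 8L), 2, 2))
#' filterSnps(pc, minCov = 5)
#' @export
filterSnps <- function(pc, minCount = 2L, minCov = 5L, maxCov = 300L,
                       minMaf = 0.0125, dropMultiallelic = TRUE) {
  stopifnot(minCov <= maxCov, minMaf >= 0, minMaf < 0.5)
  keep <- rep(TRUE, length(pc))
  log <- c(multiallelic = 0L, coverage = 0L, min_count = 0L, maf = 0L)
  if (dropMultiallelic) {
    drop <- keep & pc@multiallelic
    log["multiallelic"] <- sum(drop); keep <- keep & !drop
  }
  d <- depth(pc)
  covOk <- rowSums(d < minCov | d > maxCov) == 0
  drop <- keep & !covOk
  log["coverage"] <- sum(drop); keep <- keep & !drop
  refTot <- rowSums(refCount(pc)); altTot <- rowSums(altCount(pc))
  cntOk <- refTot >= minCount & altTot >= minCount
  drop <- keep & !cntOk
  log["min_count"] <- sum(drop); keep <- keep & !drop
  maf <- pmin(refTot, altTot) / pmax(refTot + altTot, 1)
  drop <- keep & maf < minMaf
  log["maf"] <- sum(drop); keep <- keep & !drop
  out <- pc[which(keep), ]
  attr(out, "filterLog") <- data.frame(rule = names(log), removed = unname(log))
  out
}

#' Effective sample size of a pooled read depth
#'
#' The number of distinct chromosomes a read depth C from a pool of n
#' haploids effectively represents: n_eff = (n C - 1) / (n + C).  It is
#' bounded by both n and C and increases in each.
#'
#' @param nChr haploid pool size (> 1).
#' @param depth read depth (>= 1); vectorised.
#' @return numeric vector of effective sample sizes.
#' @examples
#' effectiveSampleSize(80, 20)   # 15.99
#' @export
effectiveSampleSize <- function(nChr, depth) {
  if (any(nChr <= 1)) stop("nChr must exceed 1")
  if (any(depth < 1)) stop("effective sample size undefined at depth < 1")
  (nChr * depth - 1) / (nChr + depth)
}

#' Expected fold coverage of a sequencing library
#'
#' @param readLength read length in bp.
#' @param nReads number of (single-end) reads.
#' @param genomeLength haploid genome length in bp.
#' @return expected mean coverage, readLength * nReads / genomeLength.
#' @examples
#' expectedCoverage(125, 93.7e6, 382882063)  # ~30.6x
#' @export
expectedCoverage <- function(readLength, nReads, genomeLength) {
  stopifnot(readLength > 0, nReads > 0, genomeLength > 0)
  readLength * nReads / genomeLength
}
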