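#' Configuration for the synthetic metapopulation simulator
#'
#' Builds and validates the parameter list consumed by
#' [simulateMetapopulation()].  Defaults describe a 12-deme metapopulation in
#' two habitat clusters of six: one cluster invaded by a predator and
#' calcium-rich, the other a low-calcium refuge; a minority of loci are under
#' divergent selection tied to either the predator indicator or the calcium
#' gradient; invaded demes suffer a bottleneck 12 generations before
#' sampling (one generation per year), optionally with exponential size
#' recovery to the present.
#'
#' The calcium covariable is constructed so that its Pearson correlation with
#' the binary predator indicator equals \code{rhoEnv} exactly (default 0.71),
#' by mixing the standardised indicator with a fixed orthogonal gradient.
#' This makes the two covariables confounded to a controlled degree, which is
#' what the downstream association scans must cope with.
#'
#' @param nDemes number of demes (default 12; must be even).
#' @param demeSize diploid census size per deme (default 400).
#' @param splitGen generations before present at which the two habitat
#'   clusters diverged (default 200).
#' @param bottleneckGen generations before present of the bottleneck
#'   (default 12).
#' @param bottleneckDemes integer ids of demes hit by the bottleneck
#'   (default: the invaded cluster, demes 1..nDemes/2).
#' @param bottleneckSeverity fraction of deme size retained (default 0.1).
#' @param recovery logical: exponential recovery to the pre-bottleneck size
#'   by the present (default TRUE).
#' @param mWithin,mBetween per-generation migration rates within and between
#'   clusters (defaults 0.02 and 0.002).
#' @param nLoci number of unlinked loci (default 5000).
#' @param pSelected fraction of loci under divergent selection (default 0.02).
#' @param s selection coefficient at selected loci (default 0.1).
#' @param envCalcium optional per-deme calcium values (mg/L); by default
#'   constructed from \code{rhoEnv}.
#' @param envGoby optional per-deme 0/1 predator indicator; default: first
#'   half of demes invaded.
#' @param rhoEnv target Pearson correlation between calcium and the predator
#'   indicator (default 0.71).
#' @param ancestralGen neutral burn-in generations for the panmictic
#'   ancestral population before the split (default 100).
#' @param seed integer seed.
#' @return a validated list of class \code{"SimConfig"}.
#' @export
simConfig <- function(nDemes = 12L, demeSize = 400L, splitGen = 200L,
                      bottleneckGen = 12L, bottleneckDemes = NULL,
                      bottleneckSeverity = 0.1, recovery = TRUE,
                      mWithin = 0.02, mBetween = 0.002,
                      nLoci = 5000L, pSelected = 0.02, s = 0.1,
                      envCalcium = NULL, envGoby = NULL, rhoEnv = 0.71,
                      ancestralGen = 100L, seed = 1L) {
  nDemes <- as.integer(nDemes)
  if (nDemes < 2 || nDemes %% 2 != 0) stop("nDemes must be an even count >= 2")
  if (demeSize < 2) stop("demeSize must be at least 2 diploids")
  if (!is.finite(mWithin) || !is.finite(mBetween) ||
      mWithin < 0 || mWithin > 0.5 || mBetween < 0 || mBetween > 0.5)
    stop("migration rates must lie in [0, 0.5]")
  if (bottleneckSeverity <= 0 || bottleneckSeverity > 1)
    stop("bottleneckSeverity must lie in (0, 1]")
  if (pSelected < 0 || pSelected > 1) stop("pSelected must lie in [0, 1]")
  if (bottleneckGen >= splitGen) stop("bottleneckGen must precede splitGen")
  if (abs(rhoEnv) > 1) stop("rhoEnv must lie in [-1, 1]")
  half <- nDemes %/% 2
  if (is.null(envGoby)) envGoby <- c(rep(1L, half), rep(0L, nDemes - half))
  if (length(envGoby) != nDemes || !all(envGoby %in% 0:1))
    stop("envGoby must be a 0/1 vector of length nDemes")
  if (length(unique(envGoby)) < 2) stop("envGoby must have both levels")
  if (is.null(envCalcium)) {
    z <- as.numeric(scale(envGoby))
    e <- seq(-1, 1, length.out = nDemes)
    e <- e - z * sum(e * z) / sum(z * z)   # orthogonal gradient
    e <- as.numeric(scale(e))
    calStd <- rhoEnv * z + sqrt(1 - rhoEnv^2) * e
    envCalcium <- 29 + 8 * calStd
  }
  if (length(envCalcium) != nDemes) stop("envCalcium must have one value per deme")
  if (is.null(bottleneckDemes)) bottleneckDemes <- which(envGoby == 1L)
  cfg <- list(nDemes = nDemes, demeSize = as.integer(demeSize),
              splitGen = as.integer(splitGen),
              bottleneckGen = as.integer(bottleneckGen),
              bottleneckDemes = as.integer(bottleneckDemes),
              bottleneckSeverity = bottleneckSeverity, recovery = recovery,
              mWithin = mWithin, mBetween = mBetween,
              nLoci = as.integer(nLoci), pSelected = pSelected, s = s,
              envCalcium = envCalcium, envGoby = as.integer(envGoby),
              rhoEnv = rhoEnv, ancestralGen = as.integer(ancestralGen),
              seed = as.integer(seed))
  class(cfg) <- "SimConfig"
  cfg
}

## island-style migration matrix: row i = composition of deme i's gene pool
.migrationMatrix <- function(nDemes, cluster, mWithin, mBetween) {
  M <- matrix(0, nDemes, nDemes)
  for (i in seq_len(nDemes)) {
    same <- which(cluster == cluster[i] & seq_len(nDemes) != i)
    other <- which(cluster != cluster[i])
    if (length(same)) M[i, same] <- mWithin / length(same)
    if (length(other)) M[i, other] <- mBetween / length(other)
    M[i, i] <- 1 - sum(M[i, ])
  }
  if (any(M < 0)) M <- M / rowSums(pmax(M, 0))
  M
}

#' Simulate a structured metapopulation with known truth
#'
#' Discrete-generation forward Wright-Fisher simulation: a panmictic
#' ancestral population is burnt in neutrally, the two habitat clusters then
#' split and exchange migrants island-style (\code{mWithin} inside a
#' cluster, \code{mBetween} across), selected loci experience genic
#' selection with habitat-dependent sign, and the bottleneck demes shrink at
#' \code{bottleneckGen} generations before present (with optional
#' exponential recovery).  Each generation applies migration (deterministic
#' gene-pool mixing), then selection, then binomial drift.
#'
#' @param config a \code{SimConfig} from [simConfig()].
#' @return a list with elements \code{freqs} (nLoci x nDemes matrix of final
#'   allele frequencies) and \code{truth} (selected-locus table with
#'   covariable labels and signs, the generating parameters, and the final
#'   frequencies).
#' @export
simulateMetapopulation <- function(config) {
  stopifnot(inherits(config, "SimConfig"))
  set.seed(config$seed)
  L <- config$nLoci; D <- config$nDemes
  cluster <- ifelse(config$envGoby == 1L, 1L, 2L)
  # selected loci, split between the two covariables, random sign
  nSel <- round(config$pSelected * L)
  sel <- if (nSel > 0) sort(sample.int(L, nSel)) else integer()
  covarLab <- rep(c("goby", "calcium"), length.out = nSel)
  if (nSel > 0) covarLab <- sample(covarLab)
  selSign <- if (nSel > 0) sample(c(-1, 1), nSel, replace = TRUE) else numeric()
  # habitat direction per deme for each covariable
  dirGoby <- 2 * config$envGoby - 1
  dirCal <- ifelse(config$envCalcium > median(config$envCalcium), 1, -1)
  # per-locus, per-deme selection coefficient
  sMat <- matrix(0, L, D)
  if (nSel > 0) {
    for (k in seq_len(nSel)) {
      dirs <- if (covarLab[k] == "goby") dirGoby else dirCal
      sMat[sel[k], ] <- config$s * selSign[k] * dirs
    }
  }
  # ancestral panmictic burn-in
  Nanc <- 2L * config$demeSize * D
  p <- runif(L, 0.05, 0.95)
  for (g in seq_len(config$ancestralGen))
    p <- rbinom(L, Nanc, p) / Nanc
  freqs <- matrix(p, L, D)
  M <- .migrationMatrix(D, cluster, config$mWithin, config$mBetween)
  tM <- t(M)
  N2 <- rep(2L * config$demeSize, D)
  for (g in seq_len(config$splitGen)) {
    genBP <- config$splitGen - g            # generations before present after this step
    freqs <- freqs %*% tM                   # migration
    if (nSel > 0) {                         # genic selection: w_A = 1 + s
      w <- 1 + sMat
      freqs <- freqs * w / (1 + freqs * sMat)
    }
    N2g <- N2
    if (genBP < config$bottleneckGen) {     # bottleneck epoch
      Nb <- pmax(2, round(2 * config$demeSize * config$bottleneckSeverity))
      if (config$recovery) {
        frac <- (config$bottleneckGen - genBP) / config$bottleneckGen
        Ng <- round(Nb * (2 * config$demeSize / Nb)^frac)
      } else Ng <- Nb
      N2g[config$bottleneckDemes] <- pmax(2, Ng)
    }
    draw <- rbinom(L * D, rep(N2g, each = L), as.vector(freqs))
    freqs <- matrix(draw / rep(N2g, each = L), L, D)
  }
  truth <- list(
    selectedLoci = data.frame(locus = sel, covariable = covarLab,
                              sign = selSign),
    demographicParams = config,
    finalFreqs = freqs)
  list(freqs = freqs, truth = truth)
}

#' Simulate pooled sequencing reads from deme allele frequencies
#'
#' Two-stage sampling per site and deme: (1) a pool of \code{2 * nPool}
#' haploid genomes is drawn binomially from the deme allele frequency;
#' (2) read depth is Poisson with mean \code{coverageMean} and the alternate
#' read count is binomial from the pool frequency perturbed by sequencing
#' error, p' = p(1 - e) + (1 - p)e (errors flip between the two alleles of
#' the biallelic site).
#'
#' @param freqs loci x demes matrix of true alternate-allele frequencies.
#' @param nPool diploids per pool (default 40).
#' @param coverageMean expected read depth (default 35).
#' @param errorRate per-read miscall probability (default 0.001; must be
#'   below 0.5).
#' @param seed integer seed.
#' @param spacing bp between consecutive sites (default 100).
#' @param scaffoldLength scaffold length in bp used to lay sites out on
#'   synthetic scaffolds (default 1e6).
#' @return a \linkS4class{PoolCounts} object.
#' @export
simulatePoolReads <- function(freqs, nPool = 40L, coverageMean = 35,
                              errorRate = 0.001, seed = 1L,
                              spacing = 100L, scaffoldLength = 1e6) {
  freqs <- as.matrix(freqs)
  if (any(freqs < 0 | freqs > 1)) stop("frequencies must lie in [0, 1]")
  if (coverageMean <= 0) stop("coverageMean must be positive")
  if (errorRate < 0 || errorRate >= 0.5) stop("errorRate must lie in [0, 0.5)")
  set.seed(seed)
  L <- nrow(freqs); D <- ncol(freqs)
  nChr <- 2L * as.integer(nPool)
  poolF <- matrix(rbinom(L * D, nChr, as.vector(freqs)) / nChr, L, D)
  pErr <- poolF * (1 - errorRate) + (1 - poolF) * errorRate
  dep <- matrix(rpois(L * D, coverageMean), L, D)
  alt <- matrix(rbinom(L * D, as.vector(dep), as.vector(pErr)), L, D)
  ref <- dep - alt
  perScaf <- max(1L, floor(scaffoldLength / spacing))
  idx <- seq_len(L) - 1L
  scaffold <- sprintf("scaf%04d", idx %/% perScaf + 1L)
  position <- as.integer((idx %% perScaf) * spacing + 1L)
  PoolCounts(scaffold, position, ref, alt, poolHaploids = nChr)
}

#' Per-deme covariate table for a simulated metapopulation
#'
#' @param config a \code{SimConfig}.
#' @param riverSpacing distance in metres between consecutive demes along
#'   the river used for the default linear layout (default 5000).
#' @return a data.frame with pop_id, calcium_mgL, goby, pool_n_diploid and a
#'   \code{"riverDistance"} attribute holding the pairwise river-path
#'   distance matrix (m).
#' @export
covariateTable <- function(config, riverSpacing = 5000) {
  D <- config$nDemes
  pos <- seq_len(D) * riverSpacing
  dmat <- abs(outer(pos, pos, "-"))
  ids <- paste0("pop", seq_len(D))
  dimnames(dmat) <- list(ids, ids)
  out <- data.frame(pop_id = ids,
                    calcium_mgL = config$envCalcium,
                    goby = config$envGoby,
                    pool_n_diploid = 40L)
  attr(out, "riverDistance") <- dmat
  out
}
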