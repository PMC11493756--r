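## ---- Two-population demographic inference from the folded joint SFS ----

#' Registry of two-population demographic models
#'
#' Seven competing histories for a refuge (population 1) / invaded
#' (population 2) pair, all sharing an ancestral population of relative
#' size 1 that splits T_S (scaled time) before the most recent epoch.
#' Migration is asymmetric but constant after the split: \code{mIR} scales
#' gene flow from refuge into the invaded population (backward, invaded
#' lineages trace to the refuge) and \code{mRI} the reverse.  Models with a
#' bottleneck fix its age at \code{gB} generations before sampling, so the
#' mutation-scaled parameter theta = 4 mu L is an explicit free parameter
#' (it sets the reference size that converts generations into coalescent
#' time); models without a bottleneck profile theta analytically.
#'
#' Free-parameter counts: bottleneck_growth_both 10,
#' bottleneck_growth_invaded 8, bottleneck_both 8, bottleneck_invaded 7,
#' split_uneven_mig 5, split_even_mig 4, split_no_mig 3.
#'
#' @param includeAlternative also expose the untested alternative model
#'   (bottlenecks in both populations, recovery only in the invaded one;
#'   9 parameters), excluded from the default seven-model comparison.
#' @return named list of model definitions (parameter names, bounds,
#'   epoch builder, theta mode).
#' @export
demographicModels <- function(includeAlternative = FALSE) {
  num <- function(lo, hi) c(lo, hi)
  bSize <- num(1e-3, 50)      # relative sizes
  bTime <- num(1e-3, 10)      # scaled times
  bMig <- num(0, 20)          # scaled migration
  bTheta <- num(1, 1e7)
  mk <- function(name, params, bounds, thetaMode, epochs) {
    list(name = name, params = params, bounds = bounds,
         thetaMode = thetaMode, epochs = epochs, k = length(params))
  }
  # epoch builders return list(epochStart, size1, size2, mig12, mig21,
  # merged) in backward time; TB is NA for models without a bottleneck.
  # mig12 = per-lineage backward rate for refuge (deme 1) lineages = mRI/2;
  # mig21 = invaded (deme 2) lineages tracing to the refuge = mIR/2.
  expSlices <- function(t0, t1, nuFrom, nuTo, n = 16L) {
    # backward from t0 (recent) to t1: size nuFrom at t0 shrinking to nuTo
    br <- seq(t0, t1, length.out = n + 1L)
    mid <- (br[-1] + br[-(n + 1L)]) / 2
    list(start = br[-(n + 1L)],
         size = nuFrom * (nuTo / nuFrom)^((mid - t0) / (t1 - t0)))
  }
  bneckEpochs <- function(p, TB, growth1, growth2, bneck1, bneck2) {
    s1 <- if (bneck1) { if (growth1) NULL else p[["nu1B"]] } else p[["nu1"]]
    s2 <- if (bneck2) { if (growth2) NULL else p[["nu2B"]] } else p[["nu2"]]
    if (growth1 || growth2) {
      sl1 <- if (growth1) expSlices(0, TB, p[["nu1F"]], p[["nu1B"]])$size
      sl2 <- if (growth2) expSlices(0, TB, p[["nu2F"]], p[["nu2B"]])$size
      st <- expSlices(0, TB, 1, 1)$start
      n <- length(st)
      size1 <- if (growth1) sl1 else rep(s1, n)
      size2 <- if (growth2) sl2 else rep(s2, n)
    } else {
      st <- 0; size1 <- if (bneck1) p[["nu1B"]] else p[["nu1"]]
      size2 <- if (bneck2) p[["nu2B"]] else p[["nu2"]]
    }
    m12 <- rep(p[["mRI"]] / 2, length(st))
    m21 <- rep(p[["mIR"]] / 2, length(st))
    # pre-bottleneck epoch then ancestral merge
    list(epochStart = c(st, TB, TB + p[["TS"]]),
         size1 = c(size1, p[["nu1"]], 1),
         size2 = c(size2, p[["nu2"]], 1),
         mig12 = c(m12, p[["mRI"]] / 2, 0),
         mig21 = c(m21, p[["mIR"]] / 2, 0),
         merged = c(rep(FALSE, length(st) + 1L), TRUE))
  }
  splitEpochs <- function(p, msym = FALSE, nomig = FALSE) {
    mRI <- if (nomig) 0 else if (msym) p[["mSym"]] else p[["mRI"]]
    mIR <- if (nomig) 0 else if (msym) p[["mSym"]] else p[["mIR"]]
    list(epochStart = c(0, p[["TS"]]),
         size1 = c(p[["nu1"]], 1), size2 = c(p[["nu2"]], 1),
         mig12 = c(mRI / 2, 0), mig21 = c(mIR / 2, 0),
         merged = c(FALSE, TRUE))
  }
  models <- list(
    mk("bottleneck_growth_both",
       c("nu1", "nu2", "nu1B", "nu2B", "nu1F", "nu2F", "TS", "mIR", "mRI", "theta"),
       list(nu1 = bSize, nu2 = bSize, nu1B = bSize, nu2B = bSize,
            nu1F = bSize, nu2F = bSize, TS = bTime, mIR = bMig, mRI = bMig,
            theta = bTheta),
       "explicit",
       function(p, TB) bneckEpochs(p, TB, TRUE, TRUE, TRUE, TRUE)),
    mk("bottleneck_growth_invaded",
       c("nu1", "nu2", "nu2B", "nu2F", "TS", "mIR", "mRI", "theta"),
       list(nu1 = bSize, nu2 = bSize, nu2B = bSize, nu2F = bSize,
            TS = bTime, mIR = bMig, mRI = bMig, theta = bTheta),
       "explicit",
       function(p, TB) bneckEpochs(p, TB, FALSE, TRUE, FALSE, TRUE)),
    mk("bottleneck_both",
       c("nu1", "nu2", "nu1B", "nu2B", "TS", "mIR", "mRI", "theta"),
       list(nu1 = bSize, nu2 = bSize, nu1B = bSize, nu2B = bSize,
            TS = bTime, mIR = bMig, mRI = bMig, theta = bTheta),
       "explicit",
       function(p, TB) bneckEpochs(p, TB, FALSE, FALSE, TRUE, TRUE)),
    mk("bottleneck_invaded",
       c("nu1", "nu2", "nu2B", "TS", "mIR", "mRI", "theta"),
       list(nu1 = bSize, nu2 = bSize, nu2B = bSize, TS = bTime,
            mIR = bMig, mRI = bMig, theta = bTheta),
       "explicit",
       function(p, TB) bneckEpochs(p, TB, FALSE, FALSE, FALSE, TRUE)),
    mk("split_uneven_mig",
       c("nu1", "nu2", "TS", "mIR", "mRI"),
       list(nu1 = bSize, nu2 = bSize, TS = bTime, mIR = bMig, mRI = bMig),
       "profiled", function(p, TB) splitEpochs(p)),
    mk("split_even_mig",
       c("nu1", "nu2", "TS", "mSym"),
       list(nu1 = bSize, nu2 = bSize, TS = bTime, mSym = bMig),
       "profiled", function(p, TB) splitEpochs(p, msym = TRUE)),
    mk("split_no_mig",
       c("nu1", "nu2", "TS"),
       list(nu1 = bSize, nu2 = bSize, TS = bTime),
       "profiled", function(p, TB) splitEpochs(p, nomig = TRUE))
  )
  names(models) <- vapply(models, `[[`, "", "name")
  if (includeAlternative) {
    alt <- mk("bottleneck_both_growth_invaded",
              c("nu1", "nu2", "nu1B", "nu2B", "nu2F", "TS", "mIR", "mRI", "theta"),
              list(nu1 = bSize, nu2 = bSize, nu1B = bSize, nu2B = bSize,
                   nu2F = bSize, TS = bTime, mIR = bMig, mRI = bMig,
                   theta = bTheta),
              "explicit",
              function(p, TB) bneckEpochs(p, TB, FALSE, TRUE, TRUE, TRUE))
    models[[alt$name]] <- alt
  }
  models
}

#' Fold an unfolded joint SFS
#'
#' Merges each cell (i, j) with its complement (n1-i, n2-j), keeping the
#' cell whose total derived count is the minor one (ties kept at the
#' smaller first index; self-complementary cells untouched).  Folding a
#' folded matrix is the identity.
#'
#' @param mat (n1+1) x (n2+1) numeric matrix.
#' @return folded matrix of the same shape, with the folded-away cells zero.
#' @export
foldSfs <- function(mat) {
  n1 <- nrow(mat) - 1L; n2 <- ncol(mat) - 1L
  out <- matrix(0, n1 + 1L, n2 + 1L)
  ntot <- n1 + n2
  for (i in 0:n1) for (j in 0:n2) {
    ci <- n1 - i; cj <- n2 - j
    tot <- i + j; ctot <- ci + cj
    keep <- tot < ctot || (tot == ctot && (i < ci || (i == ci && j <= cj)))
    if (keep) {
      v <- mat[i + 1, j + 1]
      if (!(i == ci && j == cj)) v <- v + mat[ci + 1, cj + 1]
      out[i + 1, j + 1] <- v
    }
  }
  out
}

## mask for a folded SFS: folded-away cells, minor-total <= maskMax, corners
.foldedMask <- function(n1, n2, maskMax) {
  m <- matrix(TRUE, n1 + 1L, n2 + 1L)
  ntot <- n1 + n2
  for (i in 0:n1) for (j in 0:n2) {
    ci <- n1 - i; cj <- n2 - j
    tot <- i + j; ctot <- ci + cj
    keep <- tot < ctot || (tot == ctot && (i < ci || (i == ci && j <= cj)))
    if (keep && tot > maskMax) m[i + 1, j + 1] <- FALSE
  }
  m[1, 1] <- TRUE
  m[n1 + 1, n2 + 1] <- TRUE
  m
}

#' Build a folded, masked joint SFS for a population pair
#'
#' Subsets the counts to the two populations, keeps SNPs whose coverage
#' lies within the interquartile range in both pools (homogenising the
#' allele-frequency estimation error between them), drops excluded SNPs
#' (e.g. scan outliers), projects read counts to the declared haploid
#' sample sizes by hypergeometric downsampling, removes SNPs fixed or lost
#' in both samples, optionally thins to a target SNP count, folds, and
#' masks low-frequency cells.
#'
#' @param pc a \linkS4class{PoolCounts} covering the analysed sequence.
#' @param popPair indices or names of the two populations (refuge first,
#'   invaded second).
#' @param n1,n2 haploid sample sizes to project to (default 20 each).
#' @param excludeSnps integer site indices to drop (default none).
#' @param coverageQuartileFilter keep SNPs inside both pools' coverage IQR
#'   (default TRUE).
#' @param maskMax mask folded cells with minor-allele total at or below
#'   this count (default 5).
#' @param subsampleTo thin at random to about this many SNPs (default Inf).
#' @param totalLength total sequence length the SNPs derive from; default:
#'   the coordinate span summed over scaffolds.
#' @param seed integer seed for downsampling and thinning.
#' @return a \linkS4class{Folded2DSFS}.
#' @export
buildSfs <- function(pc, popPair, n1 = 20L, n2 = 20L, excludeSnps = NULL,
                     coverageQuartileFilter = TRUE, maskMax = 5L,
                     subsampleTo = Inf, totalLength = NULL, seed = 1L) {
  if (length(popPair) != 2) stop("popPair must select exactly two populations")
  if (is.character(popPair)) popPair <- match(popPair, popNames(pc))
  set.seed(seed)
  if (is.null(totalLength))
    totalLength <- sum(tapply(pc@position, pc@scaffold, max))
  snpsTotal <- length(pc)
  keep <- rep(TRUE, length(pc))
  if (!is.null(excludeSnps)) keep[excludeSnps] <- FALSE
  sub <- pc[which(keep), popPair]
  d <- depth(sub)
  if (coverageQuartileFilter) {
    qs <- apply(d, 2, quantile, probs = c(0.25, 0.75))
    ok <- d[, 1] >= qs[1, 1] & d[, 1] <= qs[2, 1] &
          d[, 2] >= qs[1, 2] & d[, 2] <= qs[2, 2]
    sub <- sub[which(ok), ]
    d <- depth(sub)
  }
  a <- altCount(sub)
  ok <- d[, 1] >= n1 & d[, 2] >= n2
  sub <- sub[which(ok), ]; d <- d[ok, , drop = FALSE]; a <- a[ok, , drop = FALSE]
  # hypergeometric projection of reads to n haploid draws
  i1 <- rhyper(nrow(d), a[, 1], d[, 1] - a[, 1], n1)
  i2 <- rhyper(nrow(d), a[, 2], d[, 2] - a[, 2], n2)
  informative <- !((i1 == 0 & i2 == 0) | (i1 == n1 & i2 == n2))
  i1 <- i1[informative]; i2 <- i2[informative]
  if (length(i1) > subsampleTo) {
    pick <- sample.int(length(i1), subsampleTo)
    i1 <- i1[pick]; i2 <- i2[pick]
  }
  counts <- matrix(0, n1 + 1L, n2 + 1L)
  for (s in seq_along(i1))
    counts[i1[s] + 1L, i2[s] + 1L] <- counts[i1[s] + 1L, i2[s] + 1L] + 1
  counts <- foldSfs(counts)
  if (all(counts[!.foldedMask(n1, n2, maskMax)] == 0) && length(i1) > 0)
    warning("all SNPs fall in masked cells")
  sfs <- new("Folded2DSFS", counts = counts,
             mask = .foldedMask(n1, n2, maskMax),
             sampleSizes = c(as.integer(n1), as.integer(n2)),
             totalLength = totalLength, snpsUsed = length(i1),
             snpsTotal = snpsTotal)
  if (sum(sfs@counts[!sfs@mask]) == 0) stop("SFS empty after masking")
  sfs
}

#' Effective sequence length for the mutation-scaled parameter theta
#'
#' L_eff = total analysed length x (SNPs used / SNPs total): the fraction
#' of the mutational target actually represented in the fitted SFS.
#'
#' @param totalLen total sequence length analysed (bp).
#' @param snpsUsed SNPs entering the SFS.
#' @param snpsTotal SNPs called on the analysed sequence.
#' @return effective length in bp.
#' @examples
#' effectiveLength(1e9, 1e6, 2e7)   # 5e7
#' @export
effectiveLength <- function(totalLen, snpsUsed, snpsTotal) {
  stopifnot(totalLen > 0, snpsUsed >= 0, snpsTotal > 0)
  totalLen * snpsUsed / snpsTotal
}

#' Expected folded joint SFS under a demographic model
#'
#' Monte-Carlo structured-coalescent expectation: n1 + n2 lineages are
#' traced backward through the model's epochs (exponential recovery phases
#' discretised into piecewise-constant slices); the expected branch length
#' E[t_ij] subtending i population-1 and j population-2 lineages is
#' averaged over \code{nReps} genealogies with a fixed seed, and the
#' expected SFS entry is (theta/2) E[t_ij], folded.  For bottleneck models
#' the fixed bottleneck age \code{gB} (generations) is converted to
#' coalescent time via the reference size N_ref = theta / (4 mu L_eff).
#'
#' @param model a model definition from [demographicModels()].
#' @param params named numeric vector of the model's free parameters.
#' @param n1,n2 haploid sample sizes.
#' @param nReps number of genealogies (default 5000).
#' @param seed integer seed (common random numbers).
#' @param Leff effective sequence length (needed by bottleneck models).
#' @param gB bottleneck age in generations (default 12).
#' @param mu mutation rate per site per generation (default 7.6e-9).
#' @param theta overrides the theta used to scale the spectrum (default:
#'   the explicit parameter, or 1 for profiled-theta models).
#' @return folded (n1+1) x (n2+1) expected-SFS matrix.
#' @export
expectedSfs <- function(model, params, n1, n2, nReps = 5000L, seed = 1L,
                        Leff = NULL, gB = 12, mu = 7.6e-9, theta = NULL) {
  p <- as.list(params)
  for (nm in model$params) {
    if (is.null(p[[nm]])) stop("missing parameter ", nm)
    b <- model$bounds[[nm]]
    if (p[[nm]] < b[1] || p[[nm]] > b[2])
      stop("parameter ", nm, " outside bounds [", b[1], ", ", b[2], "]")
  }
  TB <- NA_real_
  if (model$thetaMode == "explicit") {
    if (is.null(Leff)) stop("bottleneck models need Leff to place the bottleneck in time")
    Nref <- p[["theta"]] / (4 * mu * Leff)
    TB <- gB / (2 * Nref)
  }
  ep <- model$epochs(p, TB)
  res <- .coalBranchLengths(as.integer(n1), as.integer(n2),
                            ep$epochStart, ep$size1, ep$size2,
                            ep$mig12, ep$mig21, ep$merged,
                            .foldMap(n1, n2),
                            as.integer(nReps), as.integer(seed))
  if (is.null(theta))
    theta <- if (model$thetaMode == "explicit") p[["theta"]] else 1
  out <- theta / 2 * res$mean
  # Monte-Carlo variance of each cell's mean, on the same scale; consumed
  # by compositeLoglik's second-order bias correction
  attr(out, "mcVar") <- (theta / 2)^2 * res$var
  out
}

## 0-based column-major linear index of the folded target of every cell
.foldMap <- function(n1, n2) {
  keepCell <- function(i, j) {
    ci <- n1 - i; cj <- n2 - j
    (i + j) < (ci + cj) ||
      ((i + j) == (ci + cj) && (i < ci || (i == ci && j <= cj)))
  }
  fm <- matrix(0L, n1 + 1L, n2 + 1L)
  for (i in 0:n1) for (j in 0:n2) {
    if (keepCell(i, j)) fm[i + 1, j + 1] <- i + j * (n1 + 1L)
    else fm[i + 1, j + 1] <- (n1 - i) + (n2 - j) * (n1 + 1L)
  }
  fm
}

#' Poisson composite log-likelihood of a folded SFS
#'
#' Sum over unmasked cells of k log(mu) - mu - log(k!) with mu the model's
#' expected count.  With \code{thetaMode = "profiled"} the model SFS (built
#' at theta = 1) is scaled by the analytic maximiser
#' theta_hat = sum(k)/sum(mu) before evaluation.
#'
#' @param obs a \linkS4class{Folded2DSFS}.
#' @param modelSfs expected folded SFS matrix of matching shape.
#' @param thetaMode "explicit" (use the matrix as is) or "profiled".
#' @return log-likelihood; attribute \code{"theta"} carries the profiled
#'   theta-hat when applicable.  -Inf (with a diagnostic attribute) if an
#'   unmasked cell has zero expectation but positive count.
#' @export
compositeLoglik <- function(obs, modelSfs, thetaMode = c("explicit", "profiled")) {
  thetaMode <- match.arg(thetaMode)
  stopifnot(all(dim(modelSfs) == dim(obs@counts)))
  use <- !obs@mask
  k <- obs@counts[use]
  m <- modelSfs[use]
  th <- NA_real_
  if (thetaMode == "profiled") {
    th <- sum(k) / sum(m)
    m <- th * m
  }
  if (any(m <= 0 & k > 0)) {
    ll <- -Inf
    attr(ll, "zeroExpectation") <- sum(m <= 0 & k > 0)
    return(ll)
  }
  pos <- m > 0
  ll <- sum(k[pos] * log(m[pos]) - m[pos] - lgamma(k[pos] + 1)) - sum(m[!pos])
  # when the model SFS is a Monte-Carlo estimate, E[k log(mu-hat)] sits
  # below k log(mu) by ~ k Var(mu-hat)/(2 mu^2); without this second-order
  # correction the noisy likelihood systematically favours parameter
  # regions where the estimator happens to have low relative variance
  v <- attr(modelSfs, "mcVar")
  if (!is.null(v)) {
    v <- v[use]
    if (thetaMode == "profiled") v <- th^2 * v
    # the Taylor correction only holds for small relative variance; the cap
    # keeps regions where the Monte-Carlo estimate is unusable from being
    # rewarded for their own noise
    ll <- ll + sum(k[pos] * pmin(v[pos] / (2 * m[pos]^2), 0.1))
  }
  attr(ll, "theta") <- th
  ll
}

#' Fit a demographic model to a folded SFS by maximum composite likelihood
#'
#' Repeated derivative-free optimisation in log-parameter space: a coarse
#' random-search stage scores dispersed candidates, then up to
#' \code{maxRuns} local runs (Hooke-Jeeves pattern search followed by a
#' Nelder-Mead refinement) start from perturbations of the best point or
#' from the next-best global candidate.  Every run's endpoint is re-scored
#' at \code{nRepsPolish} genealogies — the working-precision surface is
#' cheap but its Monte-Carlo error can reorder nearby optima — and the fit
#' is declared converged when at least \code{minRuns} runs end within 1\%
#' of the best re-scored log-likelihood.  The expected SFS uses common
#' random numbers, so each run optimises a deterministic surface.
#'
#' @param obs a \linkS4class{Folded2DSFS}.
#' @param model model definition from [demographicModels()] or its name.
#' @param nReps genealogies per likelihood evaluation during the local
#'   runs (default 6000).
#' @param nRepsPolish genealogies for endpoint re-scoring and the final
#'   polish (default 5 x nReps).
#' @param seed integer seed (shared by the SFS engine and the start
#'   perturbations).
#' @param maxRuns optimisation-run cap (default 30).
#' @param minRuns runs within 1\% of the best needed for convergence
#'   (default 3).
#' @param start optional named starting values (default: the null history
#'   — all sizes, times and migration rates 1).
#' @param Leff,gB,mu see [expectedSfs()]; Leff defaults to the observed
#'   SFS's own effective length.
#' @param maxit function-evaluation budget per pattern-search run
#'   (default 800).
#' @return list of class \code{"DemographicFit"}: model name, best
#'   parameters, logLik, theta, converged flag, per-run trace, and scaled
#'   migration summaries 2Nm per direction.
#' @export
fitModel <- function(obs, model, nReps = 6000L, nRepsPolish = 5L * nReps,
                     seed = 1L, maxRuns = 30L, minRuns = 3L, start = NULL,
                     Leff = NULL, gB = 12, mu = 7.6e-9, maxit = 800L) {
  if (is.character(model)) model <- demographicModels(TRUE)[[model]]
  if (is.null(model)) stop("unknown model")
  if (is.null(Leff))
    Leff <- effectiveLength(obs@totalLength, obs@snpsUsed, obs@snpsTotal)
  n1 <- obs@sampleSizes[1]; n2 <- obs@sampleSizes[2]
  lo <- vapply(model$bounds[model$params], `[`, 0, 1)
  hi <- vapply(model$bounds[model$params], `[`, 0, 2)
  # optimisation floor: in log space a parameter that reaches ~0 freezes
  # (multiplicative steps cannot leave it), so rates are floored at 1e-3 —
  # indistinguishable from zero at any realistic data size
  lo <- pmax(lo, 1e-3)
  objFor <- function(nr) function(logp) {
    p <- exp(logp)
    p <- pmin(pmax(p, lo), hi)
    names(p) <- model$params
    ms <- expectedSfs(model, p, n1, n2, nReps = nr, seed = seed,
                      Leff = Leff, gB = gB, mu = mu,
                      theta = if (model$thetaMode == "profiled") 1 else NULL)
    # Monte-Carlo zeros in sparsely visited cells are floored so the
    # surface stays finite; the floor is far below any data-supported mu
    ms[] <- pmax(ms, 1e-12)
    ll <- compositeLoglik(obs, ms, model$thetaMode)
    if (!is.finite(ll)) return(1e12)
    -as.numeric(ll)
  }
  objExplore <- objFor(max(1500L, nReps %/% 3))
  objRun <- objFor(nReps)
  objPolish <- objFor(nRepsPolish)
  if (is.null(start)) {
    # the null history (no size change, time and migration at 1) is the
    # standard neutral starting point
    start <- setNames(rep(1, length(model$params)), model$params)
    if ("theta" %in% model$params)
      start[["theta"]] <- max(sum(obs@counts[!obs@mask]), 2)
  }
  start <- pmin(pmax(start[model$params], lo), hi)
  names(start) <- model$params
  set.seed(seed)
  # coarse global stage: the starting point, a star design around it (each
  # parameter in turn moved toward its bounds), and random log-uniform
  # draws, all scored cheaply; local runs launch from the start first and
  # then work through the ranked candidates
  logLo <- log(pmax(lo, 1e-3)); logHi <- log(hi)
  star <- do.call(rbind, lapply(seq_along(start), function(kk) {
    t(vapply(c(0.15, 0.85), function(q) {
      s <- log(start); s[kk] <- logLo[kk] + q * (logHi[kk] - logLo[kk]); s
    }, numeric(length(start))))
  }))
  nCand <- 40L
  cand <- matrix(runif(nCand * length(start)), nCand)
  cand <- t(logLo + t(cand) * (logHi - logLo))
  candPool <- rbind(star, cand)
  candScore <- apply(candPool, 1, objExplore)
  ord <- order(candScore)
  runs <- list()
  best <- list(params = start, logLik = -objPolish(log(start)))
  converged <- FALSE
  for (r in seq_len(maxRuns)) {
    # restart scheme: the supplied start first, then cycle between the
    # ranked global candidates, light perturbations of the best point, and
    # a coordinate kick — the best point with one parameter redrawn from
    # its bounds — which walks along ridges a local search cannot cross
    if (r == 1) {
      s0 <- log(start)
    } else if (r %% 3 == 2) {
      s0 <- candPool[ord[min(r %/% 3 + 1, length(ord))], ]
    } else if (r %% 3 == 0) {
      s0 <- log(best$params)
      kick <- sample.int(length(start), 1)
      s0[kick] <- logLo[kick] + runif(1) * (logHi[kick] - logLo[kick])
    } else {
      s0 <- log(best$params) + rnorm(length(start), 0, 0.5)
    }
    s0 <- pmin(pmax(s0, log(lo)), log(hi))
    hj <- pracma::hooke_jeeves(s0, objRun, tol = 1e-6, maxfeval = maxit)
    nm <- optim(hj$xmin, objRun, method = "Nelder-Mead",
                control = list(maxit = max(200L, maxit %/% 3),
                               reltol = 1e-9))
    pars <- pmin(pmax(exp(nm$par), lo), hi)
    names(pars) <- model$params
    # re-score at polish precision: working-precision optima can be
    # reordered by Monte-Carlo error
    runs[[r]] <- list(logLik = -objPolish(log(pars)), params = pars)
    if (runs[[r]]$logLik > best$logLik) best <- runs[[r]]
    lls <- vapply(runs, `[[`, 0, "logLik")
    near <- sum(lls >= best$logLik - 0.01 * abs(best$logLik))
    if (r >= minRuns && near >= minRuns) { converged <- TRUE; break }
  }
  # final polish on the high-precision surface
  hj <- pracma::hooke_jeeves(log(best$params), objPolish, tol = 1e-7,
                             maxfeval = max(200L, maxit %/% 2))
  bestPar <- setNames(pmin(pmax(exp(hj$xmin), lo), hi), model$params)
  if (-hj$fmin >= best$logLik) {
    best <- list(logLik = -hj$fmin, params = bestPar)
  }
  ms <- expectedSfs(model, best$params, n1, n2, nReps = nRepsPolish,
                    seed = seed, Leff = Leff, gB = gB, mu = mu,
                    theta = if (model$thetaMode == "profiled") 1 else NULL)
  ms[] <- pmax(ms, 1e-12)
  ll <- compositeLoglik(obs, ms, model$thetaMode)
  theta <- if (model$thetaMode == "profiled") attr(ll, "theta") else
    best$params[["theta"]]
  twoNem <- c(
    IR = if ("mIR" %in% model$params) best$params[["mIR"]] / 2 else
      if ("mSym" %in% model$params) best$params[["mSym"]] / 2 else 0,
    RI = if ("mRI" %in% model$params) best$params[["mRI"]] / 2 else
      if ("mSym" %in% model$params) best$params[["mSym"]] / 2 else 0)
  out <- list(model = model$name, params = best$params,
              logLik = as.numeric(ll), theta = theta, converged = converged,
              runs = length(runs),
              trace = vapply(runs, `[[`, 0, "logLik"),
              twoNem = twoNem, nReps = nReps, nRepsPolish = nRepsPolish,
              seed = seed, Leff = Leff)
  class(out) <- "DemographicFit"
  out
}

#' @export
print.DemographicFit <- function(x, ...) {
  cat("Demographic fit:", x$model, "\n",
      " composite logLik:", format(x$logLik, digits = 8), "\n",
      " converged:", x$converged, "(", x$runs, "runs )\n",
      " parameters:\n")
  print(round(x$params, 4))
  invisible(x)
}

#' Rank demographic fits by composite log-likelihood
#'
#' Composite likelihoods of linked SNPs cannot be compared through AIC;
#' models are ranked strictly by log-likelihood, and ties within
#' \code{tieTol} are reported as ties rather than broken arbitrarily.
#'
#' @param fits list of \code{DemographicFit} objects.
#' @param tieTol absolute log-likelihood difference treated as a tie
#'   (default 1e-6).
#' @return data.frame sorted by decreasing logLik with columns model,
#'   logLik, k, converged, rank (ties share a rank).
#' @export
compareModels <- function(fits, tieTol = 1e-6) {
  reg <- demographicModels(TRUE)
  df <- data.frame(
    model = vapply(fits, `[[`, "", "model"),
    logLik = vapply(fits, `[[`, 0, "logLik"),
    k = vapply(fits, function(f) reg[[f$model]]$k, 0L),
    converged = vapply(fits, `[[`, TRUE, "converged"))
  df <- df[order(-df$logLik, df$model), ]
  rk <- integer(nrow(df)); rk[1] <- 1L
  if (nrow(df) > 1) for (i in 2:nrow(df)) {
    rk[i] <- if (df$logLik[i - 1] - df$logLik[i] <= tieTol) rk[i - 1] else i
  }
  df$rank <- rk
  rownames(df) <- NULL
  df
}

#' Classify a scaled migration rate
#'
#' @param twoNem scaled migration rate(s) 2 N_e m.
#' @return "negligible" below 0.05, "low" in [0.05, 5.5], "high" above
#'   (boundaries inclusive on the side of the lower class at 0.05 and of
#'   "low" at 5.5).
#' @export
classifyGeneFlow <- function(twoNem) {
  ifelse(twoNem < 0.05, "negligible", ifelse(twoNem <= 5.5, "low", "high"))
}

#' Block bootstrap confidence intervals for demographic parameters
#'
#' Partitions the genome into fixed-length chunks, resamples chunks with
#' replacement to the original number, rebuilds the SFS and refits the
#' model with a reduced optimiser budget starting from the full-data
#' estimate, and reports 2.5/97.5 percentile intervals.
#'
#' @param pc the \linkS4class{PoolCounts} the SFS was built from.
#' @param popPair,sfsArgs population pair and extra arguments forwarded to
#'   [buildSfs()].
#' @param fit the full-data \code{DemographicFit} to bootstrap.
#' @param chunkSize chunk length in bp (default 1e5).
#' @param B bootstrap replicates (default 100).
#' @param refitRuns optimiser runs per replicate (default 2).
#' @param seed integer seed.
#' @return list with \code{ci} (2 x k matrix of percentile bounds),
#'   \code{estimates} (B x k matrix) and \code{B}.
#' @export
blockBootstrap <- function(pc, popPair, fit, sfsArgs = list(),
                           chunkSize = 1e5, B = 100L, refitRuns = 2L,
                           seed = 1L) {
  chunk <- paste(pc@scaffold, (pc@position - 1) %/% chunkSize)
  uch <- unique(chunk)
  if (length(uch) < 10) stop("fewer than 10 chunks: block bootstrap meaningless")
  idxByChunk <- split(seq_len(length(pc)), factor(chunk, levels = uch))
  set.seed(seed)
  est <- matrix(NA_real_, B, length(fit$params),
                dimnames = list(NULL, names(fit$params)))
  for (b in seq_len(B)) {
    draw <- sample.int(length(uch), length(uch), replace = TRUE)
    idx <- unlist(idxByChunk[draw], use.names = FALSE)
    # resampled chunks can repeat sites; lay them out on fresh coordinates
    sub <- PoolCounts(rep("boot", length(idx)), seq_along(idx),
                      refCount(pc)[idx, , drop = FALSE],
                      altCount(pc)[idx, , drop = FALSE],
                      poolHaploids = poolHaploids(pc),
                      popNames = popNames(pc))
    sfs <- do.call(buildSfs, c(list(pc = sub, popPair = popPair,
                                    seed = seed + b), sfsArgs))
    rf <- fitModel(sfs, fit$model, nReps = fit$nReps, seed = fit$seed,
                   maxRuns = refitRuns, minRuns = 1L,
                   start = fit$params, Leff = fit$Leff, maxit = 150L)
    est[b, ] <- rf$params
  }
  ci <- apply(est, 2, quantile, probs = c(0.025, 0.975), na.rm = TRUE)
  list(ci = ci, estimates = est, B = B)
}
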