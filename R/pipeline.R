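#' Default pipeline configuration
#'
#' All stage thresholds in one validated list, defaulting to the standard
#' analysis settings: SNP filters (min count 2, coverage 5-300, MAF
#' 0.0125), XtX outlier p < 0.001, FDR 0.01 for the association scans,
#' 100 kb diversity windows (min coverage 20, 13 for Tajima's D, min
#' fraction 0.05), 1000 tree bootstraps, 9999 Mantel permutations, SFS mask
#' at minor-allele total 5, bottleneck age 12 generations, mutation rate
#' 7.6e-9 per site per generation, and 100 demographic block bootstraps of
#' 1e5 bp.  Unknown keys are rejected.
#'
#' @param ... overrides for any default entry.
#' @return named list of class \code{"RunConfig"}.
#' @export
runConfig <- function(...) {
  cfg <- list(
    seed = 1L,
    sim = list(),                 # overrides for simConfig()
    coverageMean = 35, errorRate = 0.001, nPoolDiploid = 40L,
    minCount = 2L, minCov = 5L, maxCov = 300L, minMaf = 0.0125,
    xtxP = 0.001, fdr = 0.01, omegaFdr = 0.001,
    windowSize = 1e5, divMinCov = 20L, divMinCovD = 13L, divMinFraction = 0.05,
    nBootTree = 1000L, nPermMantel = 9999L,
    sfsMaskMax = 5L, sfsN1 = 20L, sfsN2 = 20L,
    gB = 12, mu = 7.6e-9,
    demoModels = c("split_no_mig", "split_even_mig", "split_uneven_mig"),
    demoNReps = 2000L, demoMaxRuns = 8L,
    demoBootstrapB = 0L, demoBootstrapChunk = 1e5)
  ov <- list(...)
  bad <- setdiff(names(ov), names(cfg))
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  cfg[names(ov)] <- ov
  class(cfg) <- "RunConfig"
  cfg
}

## stable config hash for caching / provenance (no digest dependency)
.configHash <- function(x) {
  raw <- serialize(x, NULL, version = 2)
  sprintf("%08x", sum(as.integer(raw) * (seq_along(raw) %% 97 + 1)) %%
            .Machine$integer.max)
}

#' Run the full synthetic analysis pipeline
#'
#' Executes the stages in dependency order: synthetic metapopulation and
#' pooled reads, SNP filtering, Omega estimation and the four selection
#' scans with genomic-control recalibration and candidate intersection,
#' windowed diversity with habitat effect sizes, population structure
#' (FST, UPGMA bootstrap, isolation by distance and environment), and
#' demographic model fitting for one refuge/invaded pair.  Scan outliers
#' are excluded from the FST matrix and the SFS.  Every stage draws its
#' seed deterministically from \code{config$seed}; the summary embeds the
#' config hash so reruns are byte-identical.
#'
#' @param config a \code{RunConfig} from [runConfig()].
#' @param outDir optional directory: tab-separated stage outputs and a
#'   markdown report are written there.
#' @param verbose log stage progression to stderr (default TRUE).
#' @return list with the per-stage results and a \code{summary} list
#'   (candidate counts, FST matrix, effect sizes, model ranking, seeds,
#'   config hash).
#' @export
runPipeline <- function(config = runConfig(), outDir = NULL, verbose = TRUE) {
  stopifnot(inherits(config, "RunConfig"))
  say <- function(...) if (verbose) message("[poolscape] ", ...)
  hash <- .configHash(unclass(config))
  seed <- as.integer(config$seed)

  say("stage 1/6: synthetic metapopulation")
  sc <- do.call(simConfig, c(config$sim, list(seed = seed)))
  sim <- simulateMetapopulation(sc)
  pc <- simulatePoolReads(sim$freqs, nPool = config$nPoolDiploid,
                          coverageMean = config$coverageMean,
                          errorRate = config$errorRate, seed = seed + 1L)
  covars <- covariateTable(sc)

  say("stage 2/6: SNP filtering")
  pcf <- filterSnps(pc, minCount = config$minCount, minCov = config$minCov,
                    maxCov = config$maxCov, minMaf = config$minMaf)
  filterLog <- attr(pcf, "filterLog")

  say("stage 3/6: genome scans")
  omega <- estimateOmega(pcf)
  xtx <- xtxScan(pcf, omega, pOutlier = config$xtxP)
  c2 <- c2Scan(pcf, omega, covars$goby)
  reg <- omegaRegression(pcf, omega, covars$calcium_mgL)
  calBin <- as.integer(covars$calcium_mgL > median(covars$calcium_mgL))
  glmCal <- quasibinomialScan(pcf, calBin)
  glmGoby <- quasibinomialScan(pcf, covars$goby)
  gcCal <- genomicControl(glmCal$p)
  gcGoby <- genomicControl(glmGoby$p)
  glmCal$q <- storeyQvalues(gcCal$pRecal)
  glmGoby$q <- storeyQvalues(gcGoby$pRecal)
  cands <- candidateIntersection(
    omegaHits = list(calcium = reg, goby = c2),
    glmHits = list(calcium = glmCal, goby = glmGoby),
    pc = pcf, groups = list(calcium = calBin, goby = covars$goby),
    fdr = config$fdr, omegaFdr = config$omegaFdr,
    omegaIsRegression = c(calcium = TRUE, goby = FALSE))
  outliers <- sort(unique(c(
    xtx$snp[xtx$outlier],
    c2$snp[!is.na(c2$q) & c2$q < config$fdr],
    reg$snp[!is.na(reg$q) & reg$q < config$omegaFdr],
    glmCal$snp[!is.na(glmCal$q) & glmCal$q < config$fdr],
    glmGoby$snp[!is.na(glmGoby$q) & glmGoby$q < config$fdr])))

  say("stage 4/6: diversity")
  div <- windowStats(pcf, windowSize = config$windowSize,
                     minCov = config$divMinCov, minCovD = config$divMinCovD,
                     minFraction = config$divMinFraction)
  hetero <- observedHeterozygosity(pcf)
  perPopPi <- tapply(div$pi, div$pop, mean, na.rm = TRUE)[popNames(pcf)]
  effects <- list(
    pi = compareGroups(perPopPi, covars$goby),
    heterozygosity = compareGroups(hetero, covars$goby))

  say("stage 5/6: population structure")
  neutral <- setdiff(seq_len(length(pcf)), outliers)
  fst <- pairwiseFst(pcf, neutral)
  tree <- bootstrapSupport(pcf, neutral, nBoot = config$nBootTree,
                           seed = seed + 2L)
  dgeo <- attr(covars, "riverDistance")
  ibd <- mantelTest(ibdTransform(fst), log(dgeo + diag(nrow(dgeo))),
                    nPerm = config$nPermMantel, seed = seed + 3L)
  denv <- envDistance(covars[, c("calcium_mgL", "goby")])
  ibe <- mantelTest(ibdTransform(fst), denv,
                    nPerm = config$nPermMantel, seed = seed + 4L)

  say("stage 6/6: demography")
  refuge <- which(covars$goby == 0)[1]
  invaded <- which(covars$goby == 1)[1]
  sfs <- buildSfs(pcf, c(refuge, invaded), n1 = config$sfsN1,
                  n2 = config$sfsN2, excludeSnps = outliers,
                  maskMax = config$sfsMaskMax, seed = seed + 5L)
  fits <- lapply(config$demoModels, function(mn) {
    say("  fitting ", mn)
    fitModel(sfs, mn, nReps = config$demoNReps, seed = seed + 6L,
             maxRuns = config$demoMaxRuns, gB = config$gB, mu = config$mu)
  })
  ranking <- compareModels(fits)
  boot <- NULL
  if (config$demoBootstrapB > 0) {
    bestFit <- fits[[which.max(vapply(fits, `[[`, 0, "logLik"))]]
    boot <- blockBootstrap(pcf, c(refuge, invaded), bestFit,
                           sfsArgs = list(n1 = config$sfsN1, n2 = config$sfsN2,
                                          maskMax = config$sfsMaskMax),
                           chunkSize = config$demoBootstrapChunk,
                           B = config$demoBootstrapB, seed = seed + 7L)
  }

  summary <- list(
    configHash = hash, seed = seed,
    nSitesSimulated = length(pc), nSnpsRetained = length(pcf),
    filterLog = filterLog,
    lambda = c(calcium = gcCal$lambda, goby = gcGoby$lambda),
    nOutliersXtx = sum(xtx$outlier, na.rm = TRUE),
    nCandidates = vapply(cands, nrow, 0L),
    fst = fst, ibd = ibd, ibe = ibe,
    effectSizes = lapply(effects, function(e)
      c(g = e$hedgesG, lo = e$ciLower, hi = e$ciUpper, p = e$p)),
    modelRanking = ranking)

  res <- list(config = config, truth = sim$truth, poolCounts = pcf,
              covariates = covars, omega = omega,
              scans = list(xtx = xtx, c2 = c2, omegaReg = reg,
                           glmCalcium = glmCal, glmGoby = glmGoby),
              candidates = cands, outliers = outliers,
              diversity = div, heterozygosity = hetero, effects = effects,
              tree = tree, sfs = sfs, fits = fits, bootstrap = boot,
              summary = summary)
  if (!is.null(outDir)) .writePipelineOutputs(res, outDir)
  res
}

.writePipelineOutputs <- function(res, outDir) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  tsv <- function(x, f) write.table(x, file.path(outDir, f), sep = "\t",
                                    quote = FALSE, row.names = FALSE)
  tsv(res$scans$xtx, "scan_xtx.tsv")
  tsv(res$scans$c2, "scan_c2.tsv")
  tsv(res$scans$omegaReg, "scan_omega_regression.tsv")
  tsv(res$diversity, "diversity_windows.tsv")
  tsv(res$summary$modelRanking, "model_ranking.tsv")
  write.table(res$summary$fst, file.path(outDir, "fst_matrix.tsv"),
              sep = "\t", quote = FALSE)
  ape::write.tree(res$tree$tree, file.path(outDir, "upgma.nwk"))
  s <- res$summary
  rep <- c(
    "# poolscape pipeline report", "",
    paste0("- config hash: ", s$configHash, "; seed: ", s$seed),
    paste0("- sites simulated: ", s$nSitesSimulated,
           "; SNPs retained: ", s$nSnpsRetained),
    paste0("- XtX outliers (p < ", res$config$xtxP, "): ", s$nOutliersXtx),
    paste0("- candidates: ",
           paste(names(s$nCandidates), s$nCandidates, sep = "=",
                 collapse = ", ")),
    paste0("- genomic inflation lambda: calcium=",
           round(s$lambda["calcium"], 3), ", goby=",
           round(s$lambda["goby"], 3)),
    paste0("- IBD Mantel: r2=", round(s$ibd$r2, 3), ", p=", s$ibd$p),
    paste0("- IBE Mantel: r2=", round(s$ibe$r2, 3), ", p=", s$ibe$p),
    paste0("- best demographic model: ",
           s$modelRanking$model[1], " (logLik ",
           round(s$modelRanking$logLik[1], 1), ")"))
  writeLines(rep, file.path(outDir, "report.md"))
  invisible(outDir)
}

#' Load a pipeline configuration from a YAML file
#'
#' @param path YAML file whose top-level keys match [runConfig()] entries.
#' @return a \code{RunConfig}.
#' @export
readRunConfig <- function(path) {
  do.call(runConfig, yaml::read_yaml(path))
}
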