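#' Bonferroni-corrected significance threshold
#'
#' @param alpha family-wise error target in (0, 1).
#' @param nTests number of tests performed.
#' @return alpha / nTests.
#' @examples
#' bonferroniThreshold(0.05, 152337)  # 3.28e-7
#' @export
bonferroniThreshold <- function(alpha, nTests) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  if (nTests < 1) stop("nTests must be >= 1")
  alpha / nTests
}

#' Run the multivariate and univariate tests over a set of regions
#'
#' For each region: the univariate test per phenotype, the
#' minimum-p (Bonferroni over phenotypes) adjustment, and the
#' data-adaptive multivariate test. Inputs must be preprocessed:
#' complete-case phenotypes, carrier-filtered and imputed genotypes,
#' samples aligned (\code{\link{alignSamples}}). Regions whose genotype
#' submatrix has no variation left after residualization are flagged
#' (\code{NA} p-values), not fatal.
#'
#' @param gm a \linkS4class{GenotypeMatrix} (imputed).
#' @param block a \linkS4class{PhenotypeBlock} (complete cases), same
#'   samples in the same order as \code{gm}.
#' @param regions a GRanges of regions (\code{\link{geneRegions}},
#'   \code{\link{windowRegions}} or \code{\link{singleVariantRegions}}).
#' @param spec an \linkS4class{EffectCovarianceSpec}.
#' @param resamples resampling depth for the multivariate grid
#'   combination.
#' @param seed integer seed controlling all resampling draws.
#' @param alpha family-wise error target for the Bonferroni threshold.
#' @param verbose report progress every 200 regions.
#' @return a \linkS4class{ScanReport}; rows sorted by the multivariate p
#'   ascending, with columns chromosome, region, start, end, nSnps, maf
#'   (single-variant rows only), one \code{p_<phenotype>} column per
#'   phenotype, \code{p_skat_adjusted} and \code{p_murat}.
#' @export
runScan <- function(gm, block, regions, spec = EffectCovarianceSpec(),
                    resamples = 1000L, seed = 1L, alpha = 0.05,
                    verbose = FALSE) {
  if (length(regions) == 0L)
    stop("no regions to test")
  if (!identical(sampleIds(gm), sampleIds(block)))
    stop("samples of gm and block differ; run alignSamples() first")
  if (any(block@incomplete))
    stop("phenotype block has incomplete samples; run ",
         "dropIncompleteSamples() first")
  D <- dosages(gm)
  if (anyNA(D))
    stop("genotypes contain missing calls; run imputeGenotypes() first")
  Y <- phenotypes(block)
  X <- if (ncol(covariates(block))) covariates(block) else NULL
  K <- ncol(Y)
  fitMulti <- fitNull(Y, X)
  fitsUni <- lapply(seq_len(K), function(k)
    fitNull(Y[, k, drop = FALSE], X))
  mafAll <- mcols(rowRanges(gm))$maf
  idx <- mcols(regions)$variantIndices
  nm <- mcols(regions)$name
  pheno <- colnames(Y)
  nR <- length(regions)
  pUni <- matrix(NA_real_, nR, K, dimnames = list(NULL, paste0("p_", pheno)))
  pAdj <- pMur <- rep(NA_real_, nR)
  nSnps <- lengths(idx)
  flagged <- character(0)
  set.seed(seed)
  regionSeeds <- sample.int(.Machine$integer.max - 1L, nR)
  for (i in seq_len(nR)) {
    vi <- idx[[i]]
    G <- D[, vi, drop = FALSE]
    mafs <- mafAll[vi]
    ok <- tryCatch({
      for (k in seq_len(K))
        pUni[i, k] <- skatPvalueFit(fitsUni[[k]], G, mafs, spec)
      pAdj[i] <- adjustedMinP(pUni[i, ])
      res <- muratPvalue(fitMulti, G, mafs, spec, resamples = resamples,
                         seed = regionSeeds[i])
      pMur[i] <- finalP(res)
      TRUE
    }, error = function(e) {
      flagged <<- c(flagged, paste0(nm[i], ": ", conditionMessage(e)))
      FALSE
    })
    if (verbose && i %% 200L == 0L)
      message("tested ", i, "/", nR, " regions")
  }
  if (length(flagged))
    message(length(flagged), " region(s) skipped: ",
            paste(utils::head(flagged, 3L), collapse = "; "))
  rows <- data.frame(
    chromosome = as.character(seqnames(regions)),
    region = nm,
    start = start(regions),
    end = end(regions),
    nSnps = as.integer(nSnps),
    maf = ifelse(nSnps == 1L, mafAll[vapply(idx, `[`, integer(1), 1L)],
                 NA_real_),
    stringsAsFactors = FALSE)
  rows <- cbind(rows, as.data.frame(pUni))
  rows$p_skat_adjusted <- pAdj
  rows$p_murat <- pMur
  rows <- rows[order(rows$p_murat), , drop = FALSE]
  rownames(rows) <- NULL
  new("ScanReport", rows = rows, nTests = nR, alpha = alpha,
      bonferroniThreshold = bonferroniThreshold(alpha, nR))
}

#' Expected-vs-observed quantile pairs for a Q-Q plot
#'
#' Observed p-values are sorted ascending; the expected uniform quantile
#' for rank i of N is i/(N+1); both are returned on the -log10 scale.
#' Input order is irrelevant.
#'
#' @param pValues p-values in (0, 1].
#' @return data.frame with columns \code{expected} and \code{observed}
#'   (-log10 scale), one row per p-value.
#' @export
qqData <- function(pValues) {
  pValues <- pValues[!is.na(pValues)]
  if (length(pValues) == 0L) stop("no p-values supplied")
  if (any(pValues <= 0 | pValues > 1))
    stop("p-values must lie in (0, 1]")
  n <- length(pValues)
  data.frame(expected = -log10(seq_len(n) / (n + 1)),
             observed = -log10(sort(pValues)))
}
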