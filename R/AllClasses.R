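#' @import methods
#' @import S4Vectors
#' @import IRanges
#' @import GenomicRanges
#' @import SummarizedExperiment
NULL

#' GenotypeMatrix: sample-by-variant dosage container
#'
#' Holds alt-allele dosages (0--2, possibly fractional after imputation,
#' \code{NA} for missing calls) for n samples at v variants, together with
#' per-variant metadata: minor allele frequency computed on observed
#' genotypes, carrier count (individuals with observed minor-allele dosage
#' greater than zero) and missing-call count. Extends
#' \linkS4class{RangedSummarizedExperiment}; the single assay
#' \code{"dosage"} is stored variants-by-samples following Bioconductor
#' convention, and \code{\link{dosages}} returns the transposed
#' samples-by-variants matrix used by the association machinery.
#'
#' @export
setClass("GenotypeMatrix", contains = "RangedSummarizedExperiment")

setValidity("GenotypeMatrix", function(object) {
  if (!"dosage" %in% assayNames(object))
    return("assay 'dosage' is required")
  d <- assay(object, "dosage")
  bad <- !is.na(d) & (d < 0 | d > 2)
  if (any(bad))
    return("non-missing dosages must lie in [0, 2]")
  need <- c("maf", "nCarriers", "nMissing")
  if (!all(need %in% colnames(mcols(rowRanges(object)))))
    return(paste("rowData must contain:", paste(need, collapse = ", ")))
  maf <- mcols(rowRanges(object))$maf
  if (any(!is.na(maf) & (maf < 0 | maf > 0.5)))
    return("maf must lie in [0, 0.5] (minor-allele scale)")
  if (anyDuplicated(colnames(object)))
    return("duplicate sample ids")
  TRUE
})

#' Construct a GenotypeMatrix from a samples-by-variants dosage matrix
#'
#' Per-variant MAF, carrier and missing counts are computed from the observed
#' (non-\code{NA}) entries of \code{dosages}; MAF is folded onto the minor
#' allele, so it never exceeds 0.5 even when the stored alt allele is the
#' major one.
#'
#' @param dosages numeric matrix, samples in rows (rownames = sample ids),
#'   variants in columns; entries in \code{[0, 2]} or \code{NA}.
#' @param chromosome,position per-variant chromosome labels and 1-based
#'   positions, recycled to the number of variants.
#' @param variantId per-variant identifiers; defaults to
#'   \code{colnames(dosages)} or \code{chr_pos} labels.
#' @param ref,alt optional allele labels.
#' @return a \linkS4class{GenotypeMatrix}.
#' @examples
#' d <- matrix(c(0, 1, 2, 0, 0, 1), nrow = 3,
#'             dimnames = list(c("s1", "s2", "s3"), c("v1", "v2")))
#' gm <- GenotypeMatrix(d, chromosome = "1", position = c(100, 200))
#' variantInfo(gm)$maf
#' @export
GenotypeMatrix <- function(dosages, chromosome, position,
                           variantId = NULL, ref = NA_character_,
                           alt = NA_character_) {
  dosages <- as.matrix(dosages)
  if (is.null(rownames(dosages)))
    rownames(dosages) <- paste0("sample", seq_len(nrow(dosages)))
  if (anyDuplicated(rownames(dosages)))
    stop("duplicate sample id: ",
         rownames(dosages)[duplicated(rownames(dosages))][1L])
  v <- ncol(dosages)
  chromosome <- rep_len(as.character(chromosome), v)
  position <- rep_len(as.integer(position), v)
  if (is.null(variantId))
    variantId <- colnames(dosages)
  if (is.null(variantId))
    variantId <- paste(chromosome, position, sep = "_")
  maf <- apply(dosages, 2L, function(x)
    if (all(is.na(x))) NA_real_ else computeMaf(x))
  nCarriers <- apply(dosages, 2L, function(x) sum(!is.na(x) & x > 0))
  nMissing <- apply(dosages, 2L, function(x) sum(is.na(x)))
  rr <- GRanges(chromosome, IRanges(position, width = 1L))
  names(rr) <- variantId
  mcols(rr) <- DataFrame(ref = rep_len(ref, v), alt = rep_len(alt, v),
                         maf = maf, nCarriers = as.integer(nCarriers),
                         nMissing = as.integer(nMissing))
  se <- SummarizedExperiment(
    assays = list(dosage = t(dosages)),
    rowRanges = rr,
    colData = DataFrame(row.names = rownames(dosages)))
  new("GenotypeMatrix", se)
}

#' PhenotypeBlock: aligned phenotypes and covariates
#'
#' n samples by K continuous phenotypes plus an n-by-m covariate matrix,
#' aligned by sample id. Rows with any missing phenotype or covariate are
#' flagged on construction and removed by
#' \code{\link{dropIncompleteSamples}} before model fitting.
#'
#' @slot samples character vector of sample ids.
#' @slot Y numeric n-by-K phenotype matrix (named columns).
#' @slot X numeric n-by-m covariate matrix (m may be 0).
#' @slot incomplete logical flag per sample.
#' @export
setClass("PhenotypeBlock",
         representation(samples = "character", Y = "matrix", X = "matrix",
                        incomplete = "logical"))

setValidity("PhenotypeBlock", function(object) {
  n <- length(object@samples)
  if (nrow(object@Y) != n || nrow(object@X) != n)
    return("Y and X must have one row per sample")
  if (length(object@incomplete) != n)
    return("incomplete flag must have one entry per sample")
  if (anyDuplicated(object@samples))
    return("duplicate sample ids")
  if (is.null(colnames(object@Y)))
    return("phenotype columns must be named")
  TRUE
})

#' @param samples,Y,X,incomplete see the class slots.
#' @rdname PhenotypeBlock-class
#' @export
PhenotypeBlock <- function(samples, Y, X = NULL,
                           incomplete = NULL) {
  Y <- as.matrix(Y)
  if (is.null(X))
    X <- matrix(numeric(0), nrow = nrow(Y), ncol = 0)
  X <- as.matrix(X)
  if (is.null(incomplete))
    incomplete <- rowSums(is.na(Y)) > 0 | rowSums(is.na(X)) > 0
  new("PhenotypeBlock", samples = as.character(samples), Y = Y, X = X,
      incomplete = incomplete)
}

#' NullFit: covariate-only multivariate least-squares fit
#'
#' Per-phenotype ordinary least squares against the shared design
#' \code{[1, X]}, with the K-by-K residual covariance (denominator
#' n - m - 1) needed by the score tests.
#'
#' @slot alpha0 length-K intercepts.
#' @slot alpha m-by-K covariate coefficients.
#' @slot residuals n-by-K residual matrix.
#' @slot sigmaEps K-by-K residual covariance.
#' @slot design the n-by-(1+m) design matrix.
#' @slot qr QR decomposition of the design (reused for projections).
#' @export
setClass("NullFit",
         representation(alpha0 = "numeric", alpha = "matrix",
                        residuals = "matrix", sigmaEps = "matrix",
                        design = "matrix", qr = "ANY"))

#' ChiSquareMixture: weights of a chi-square(1) mixture
#'
#' Positive eigenvalue weights, sorted descending, of the null law
#' \eqn{\sum_l \lambda_l \chi^2_1} of a score-test quadratic form.
#' Weights below \code{truncationTol} times the largest are dropped.
#'
#' @export
setClass("ChiSquareMixture",
         representation(lambdas = "numeric", truncationTol = "numeric"))

setValidity("ChiSquareMixture", function(object) {
  l <- object@lambdas
  if (length(l) == 0L) return("empty mixture after truncation")
  if (any(l <= 0)) return("retained lambdas must be positive")
  if (is.unsorted(rev(l))) return("lambdas must be sorted descending")
  TRUE
})

#' @param lambdas numeric eigenvalue weights (any order; small and
#'   numerically negative values are truncated).
#' @param truncationTol relative truncation threshold.
#' @rdname ChiSquareMixture-class
#' @export
ChiSquareMixture <- function(lambdas, truncationTol = 1e-10) {
  lambdas <- as.numeric(lambdas)
  if (length(lambdas) == 0L || all(!is.finite(lambdas)))
    stop("empty mixture")
  mx <- max(lambdas)
  if (mx <= 0) stop("mixture has no positive weight")
  neg <- lambdas < -truncationTol * mx
  if (any(neg))
    warning(sum(neg), " negative eigenvalue(s) clipped from mixture")
  keep <- lambdas > truncationTol * mx
  new("ChiSquareMixture", lambdas = sort(lambdas[keep], decreasing = TRUE),
      truncationTol = truncationTol)
}

#' EffectCovarianceSpec: the variant-effect covariance model
#'
#' The multivariate test assumes variant effects are random with a common
#' cross-phenotype correlation \eqn{\rho} (scanned over \code{rhoGrid}) and
#' per-variant weights \eqn{w_j} given by the Beta density evaluated at the
#' MAF (\code{weightBetaParams}; \code{c(1, 1)} means unweighted, the
#' default \code{c(1, 25)} up-weights rarer variants).
#'
#' @export
setClass("EffectCovarianceSpec",
         representation(rhoGrid = "numeric", weightBetaParams = "numeric"))

setValidity("EffectCovarianceSpec", function(object) {
  g <- object@rhoGrid
  if (length(g) == 0L) return("rho grid is empty")
  if (any(g < 0 | g >= 1)) return("rho values must lie in [0, 1)")
  if (anyDuplicated(g)) return("rho values must be distinct")
  if (is.unsorted(g)) return("rho values must be sorted ascending")
  if (length(object@weightBetaParams) != 2L ||
      any(object@weightBetaParams <= 0))
    return("weightBetaParams must be two positive reals")
  TRUE
})

#' @param rhoGrid ascending effect-correlation grid in [0, 1).
#' @param weightBetaParams Beta-density shape parameters for MAF weights.
#' @rdname EffectCovarianceSpec-class
#' @export
EffectCovarianceSpec <- function(rhoGrid = c(seq(0, 0.9, by = 0.1), 0.99),
                                 weightBetaParams = c(1, 25)) {
  new("EffectCovarianceSpec", rhoGrid = rhoGrid,
      weightBetaParams = weightBetaParams)
}

#' MuratResult: outcome of the data-adaptive multivariate test
#'
#' @slot perRho data.frame with columns rho, Q, p.
#' @slot minP minimum p over the rho grid.
#' @slot finalP grid-adjusted p (resampling combination).
#' @slot bonferroniP conservative grid-size times minP bound, capped at 1.
#' @slot nVariants number of variants tested.
#' @slot flags character labels, e.g. "liu_fallback".
#' @export
setClass("MuratResult",
         representation(perRho = "data.frame", minP = "numeric",
                        finalP = "numeric", bonferroniP = "numeric",
                        nVariants = "integer", flags = "character"))

setValidity("MuratResult", function(object) {
  if (object@finalP < object@minP - 1e-12)
    return("finalP cannot undercut minP")
  p <- object@perRho$p
  if (any(p <= 0 | p > 1)) return("per-rho p-values must lie in (0, 1]")
  TRUE
})

#' SkatResult: per-phenotype univariate p-values with minimum-p adjustment
#'
#' @slot pPerPhenotype named length-K p-values.
#' @slot adjustedMinP min(1, K * min(p)).
#' @export
setClass("SkatResult",
         representation(pPerPhenotype = "numeric", adjustedMinP = "numeric"))

#' ScanReport: one row per tested region plus multiple-testing metadata
#'
#' @slot rows data.frame sorted by the multivariate p, ascending.
#' @slot nTests number of regions tested.
#' @slot alpha family-wise error target.
#' @slot bonferroniThreshold alpha / nTests.
#' @export
setClass("ScanReport",
         representation(rows = "data.frame", nTests = "integer",
                        alpha = "numeric", bonferroniThreshold = "numeric"))

#' QcConfig: genotype and phenotype quality-control settings
#'
#' @slot minCarriers variants with fewer observed carriers are excluded
#'   (carriers are individuals, counted before imputation).
#' @slot mafUpper optional upper MAF bound for a rare-only analysis.
#' @slot logTransform names of phenotypes to natural-log transform.
#' @export
setClass("QcConfig",
         representation(minCarriers = "integer", mafUpper = "numeric",
                        logTransform = "character"))

setValidity("QcConfig", function(object) {
  if (object@minCarriers < 1L) return("minCarriers must be >= 1")
  if (length(object@mafUpper) &&
      (object@mafUpper <= 0 || object@mafUpper > 0.5))
    return("mafUpper must lie in (0, 0.5]")
  TRUE
})

#' @param minCarriers,mafUpper,logTransform see slots.
#' @rdname QcConfig-class
#' @export
QcConfig <- function(minCarriers = 4L, mafUpper = numeric(0),
                     logTransform = character(0)) {
  new("QcConfig", minCarriers = as.integer(minCarriers),
      mafUpper = mafUpper, logTransform = logTransform)
}
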