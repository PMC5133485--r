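#' Minor allele frequency of a dosage vector
#'
#' Allele frequency of the less-common allele among observed (non-missing)
#' genotypes; always in [0, 0.5]. When the stored alt allele is the major
#' allele the frequency is folded onto the ref allele.
#'
#' @param dosages numeric vector of alt-allele dosages in [0, 2], NA for
#'   missing.
#' @return the minor allele frequency.
#' @examples
#' computeMaf(c(0, 0, 1, 2))  # 3/8
#' computeMaf(c(2, 2, 2, 1))  # folded: 1/8
#' @export
computeMaf <- function(dosages) {
  obs <- dosages[!is.na(dosages)]
  if (length(obs) == 0L)
    stop("cannot compute MAF: all genotypes missing")
  p <- mean(obs) / 2
  min(p, 1 - p)
}

#' Mean-impute missing genotypes, preserving the allele frequency
#'
#' Missing entries are replaced by the expected dosage 2*MAF on the minor
#' allele scale, folded back to the stored alt-allele scale when the alt
#' allele is the major one. The allele frequency recomputed over all
#' entries (observed plus imputed) equals the pre-imputation frequency, so
#' imputation never shifts the MAF.
#'
#' @param dosages dosage vector with possible NA entries.
#' @param maf minor allele frequency of the observed entries (defaults to
#'   \code{computeMaf(dosages)}).
#' @return the dosage vector with NA entries filled.
#' @export
imputeMissing <- function(dosages, maf = computeMaf(dosages)) {
  miss <- is.na(dosages)
  if (!any(miss)) return(dosages)
  altFreq <- mean(dosages[!miss]) / 2
  fill <- if (altFreq > 0.5) 2 * (1 - maf) else 2 * maf
  dosages[miss] <- fill
  dosages
}

#' Carrier-count filter for a single variant
#'
#' A carrier is an individual whose observed (pre-imputation) minor-allele
#' dosage is positive; a homozygote counts once. Returns TRUE when the
#' variant has at least \code{minCarriers} carriers.
#'
#' @param dosages dosage vector (NA = missing).
#' @param minCarriers minimum number of carrier individuals (default 4).
#' @export
carrierFilter <- function(dosages, minCarriers = 4L) {
  obs <- dosages[!is.na(dosages)]
  altFreq <- if (length(obs)) mean(obs) / 2 else 0
  # carrier status is defined on the minor allele: fold when alt is major
  carrier <- if (altFreq > 0.5) obs < 2 else obs > 0
  sum(carrier) >= minCarriers
}

#' Natural-log transform selected phenotypes
#'
#' Blood-pressure-style phenotypes are right-skewed; the scan protocol
#' works on their natural logarithms. Values must be strictly positive.
#'
#' @param block a \linkS4class{PhenotypeBlock}.
#' @param which names of phenotype columns to transform.
#' @return the block with the selected columns replaced by their logs.
#' @export
logTransformPhenotypes <- function(block, which) {
  Y <- block@Y
  missing <- setdiff(which, colnames(Y))
  if (length(missing))
    stop("unknown phenotype(s): ", paste(missing, collapse = ", "))
  for (ph in which) {
    bad <- which(!is.na(Y[, ph]) & Y[, ph] <= 0)
    if (length(bad))
      stop("non-positive value for phenotype '", ph, "' at sample ",
           block@samples[bad[1L]])
    Y[, ph] <- log(Y[, ph])
  }
  initialize(block, Y = Y)
}

#' Drop samples with any missing phenotype or covariate
#'
#' Complete-case filtering: the shared-design null regression needs every
#' phenotype and covariate observed for each retained sample.
#'
#' @param block a \linkS4class{PhenotypeBlock}.
#' @return the block restricted to complete cases.
#' @export
dropIncompleteSamples <- function(block) {
  drop <- block@incomplete
  if (!any(drop)) return(block)
  if (all(drop))
    stop("no samples remain after removing incomplete cases")
  message("dropping ", sum(drop), " sample(s) with missing phenotype ",
          "or covariate values")
  new("PhenotypeBlock", samples = block@samples[!drop],
      Y = block@Y[!drop, , drop = FALSE],
      X = block@X[!drop, , drop = FALSE],
      incomplete = rep(FALSE, sum(!drop)))
}

#' Pearson correlation between two phenotypes
#'
#' @param block a \linkS4class{PhenotypeBlock} (complete cases).
#' @param a,b phenotype column names.
#' @export
phenotypeCorrelation <- function(block, a, b) {
  Y <- block@Y
  for (ph in c(a, b))
    if (!ph %in% colnames(Y)) stop("unknown phenotype: ", ph)
  ya <- Y[!block@incomplete, a]
  yb <- Y[!block@incomplete, b]
  if (length(ya) < 3L) stop("need at least 3 complete samples")
  if (stats::sd(ya) == 0 || stats::sd(yb) == 0)
    stop("correlation undefined: zero variance in '",
         if (stats::sd(ya) == 0) a else b, "'")
  stats::cor(ya, yb)
}

#' Impute all missing genotypes in a GenotypeMatrix
#'
#' Applies \code{\link{imputeMissing}} column-wise using the stored
#' per-variant MAF; carrier and missing counts in the metadata keep their
#' pre-imputation values.
#'
#' @param gm a \linkS4class{GenotypeMatrix}.
#' @export
imputeGenotypes <- function(gm) {
  d <- assay(gm, "dosage")  # variants x samples
  miss <- rowSums(is.na(d)) > 0
  if (any(miss)) {
    maf <- mcols(rowRanges(gm))$maf
    for (j in which(miss))
      d[j, ] <- imputeMissing(d[j, ], maf[j])
    assay(gm, "dosage") <- d
  }
  gm
}

#' Filter variants by carrier count and (optionally) MAF
#'
#' @param gm a \linkS4class{GenotypeMatrix}.
#' @param minCarriers keep variants with at least this many carriers
#'   (individuals with an observed minor allele).
#' @param mafUpper optional: additionally require MAF <= mafUpper
#'   (rare-only analysis).
#' @return the filtered \linkS4class{GenotypeMatrix}.
#' @export
filterVariants <- function(gm, minCarriers = 4L, mafUpper = NULL) {
  info <- mcols(rowRanges(gm))
  keep <- info$nCarriers >= minCarriers
  if (!is.null(mafUpper) && length(mafUpper))
    keep <- keep & info$maf <= mafUpper
  dropped <- sum(!keep)
  if (dropped)
    message(dropped, " variant(s) removed by QC filter")
  gm[keep, ]
}

#' Align a genotype matrix and phenotype block on shared samples
#'
#' Takes the intersection of sample ids, in genotype-file order, and
#' reports how many samples each side loses.
#'
#' @param gm a \linkS4class{GenotypeMatrix}.
#' @param block a \linkS4class{PhenotypeBlock}.
#' @return list with elements \code{gm} and \code{block}, sample-aligned.
#' @export
alignSamples <- function(gm, block) {
  shared <- intersect(sampleIds(gm), sampleIds(block))
  if (length(shared) == 0L)
    stop("no samples shared between genotypes and phenotypes")
  lostG <- nSamples(gm) - length(shared)
  lostP <- nSamples(block) - length(shared)
  if (lostG || lostP)
    message("sample alignment: ", length(shared), " shared; dropped ",
            lostG, " genotype-only and ", lostP, " phenotype-only sample(s)")
  idx <- match(shared, sampleIds(block))
  blk <- new("PhenotypeBlock", samples = block@samples[idx],
             Y = block@Y[idx, , drop = FALSE],
             X = block@X[idx, , drop = FALSE],
             incomplete = block@incomplete[idx])
  list(gm = gm[, shared], block = blk)
}
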