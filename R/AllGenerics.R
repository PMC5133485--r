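#' Accessors for murat classes
#'
#' @param x,object an object of the documented class.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("dosages", function(x) standardGeneric("dosages"))

#' @describeIn accessors samples-by-variants dosage matrix.
#' @export
setMethod("dosages", "GenotypeMatrix", function(x) t(assay(x, "dosage")))

#' @rdname accessors
#' @export
setGeneric("variantInfo", function(x) standardGeneric("variantInfo"))

#' @describeIn accessors per-variant metadata as a GRanges (id, ref, alt,
#'   maf, nCarriers, nMissing).
#' @export
setMethod("variantInfo", "GenotypeMatrix", function(x) rowRanges(x))

#' @rdname accessors
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' @export
setMethod("sampleIds", "GenotypeMatrix", function(x) colnames(x))

#' @export
setMethod("sampleIds", "PhenotypeBlock", function(x) x@samples)

#' @rdname accessors
#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))

#' @export
setMethod("nSamples", "GenotypeMatrix", function(x) ncol(x))

#' @export
setMethod("nSamples", "PhenotypeBlock", function(x) length(x@samples))

#' @rdname accessors
#' @export
setGeneric("nVariants", function(x) standardGeneric("nVariants"))

#' @export
setMethod("nVariants", "GenotypeMatrix", function(x) nrow(x))

#' @rdname accessors
#' @export
setGeneric("phenotypes", function(x) standardGeneric("phenotypes"))

#' @describeIn accessors n-by-K phenotype matrix.
#' @export
setMethod("phenotypes", "PhenotypeBlock", function(x) x@Y)

#' @rdname accessors
#' @export
setGeneric("covariates", function(x) standardGeneric("covariates"))

#' @describeIn accessors n-by-m covariate matrix.
#' @export
setMethod("covariates", "PhenotypeBlock", function(x) x@X)

#' @rdname accessors
#' @export
setGeneric("phenotypeNames", function(x) standardGeneric("phenotypeNames"))

#' @export
setMethod("phenotypeNames", "PhenotypeBlock", function(x) colnames(x@Y))

#' @rdname accessors
#' @export
setGeneric("incompleteSamples", function(x)
  standardGeneric("incompleteSamples"))

#' @describeIn accessors logical flag: sample has a missing phenotype or
#'   covariate.
#' @export
setMethod("incompleteSamples", "PhenotypeBlock", function(x) x@incomplete)

#' @rdname accessors
#' @export
setGeneric("sigmaEps", function(x) standardGeneric("sigmaEps"))

#' @describeIn accessors K-by-K residual covariance of the null fit.
#' @export
setMethod("sigmaEps", "NullFit", function(x) x@sigmaEps)

#' @describeIn accessors n-by-K null-model residual matrix.
#' @export
setMethod("residuals", "NullFit", function(object) object@residuals)

#' @rdname accessors
#' @export
setGeneric("mixtureWeights", function(x) standardGeneric("mixtureWeights"))

#' @describeIn accessors descending chi-square(1) mixture weights.
#' @export
setMethod("mixtureWeights", "ChiSquareMixture", function(x) x@lambdas)

#' @rdname accessors
#' @export
setGeneric("rhoGrid", function(x) standardGeneric("rhoGrid"))

#' @export
setMethod("rhoGrid", "EffectCovarianceSpec", function(x) x@rhoGrid)

#' @rdname accessors
#' @export
setGeneric("perRho", function(x) standardGeneric("perRho"))

#' @describeIn accessors data.frame of (rho, Q, p) over the grid.
#' @export
setMethod("perRho", "MuratResult", function(x) x@perRho)

#' @rdname accessors
#' @export
setGeneric("minP", function(x) standardGeneric("minP"))

#' @export
setMethod("minP", "MuratResult", function(x) x@minP)

#' @rdname accessors
#' @export
setGeneric("finalP", function(x) standardGeneric("finalP"))

#' @export
setMethod("finalP", "MuratResult", function(x) x@finalP)

#' @rdname accessors
#' @export
setGeneric("scanRows", function(x) standardGeneric("scanRows"))

#' @describeIn accessors result table of a scan, sorted by multivariate p.
#' @export
setMethod("scanRows", "ScanReport", function(x) x@rows)

#' @rdname accessors
#' @export
setGeneric("bonferroniThresholdOf", function(x)
  standardGeneric("bonferroniThresholdOf"))

#' @export
setMethod("bonferroniThresholdOf", "ScanReport",
          function(x) x@bonferroniThreshold)

setMethod("show", "GenotypeMatrix", function(object) {
  cat("GenotypeMatrix:", ncol(object), "samples x", nrow(object),
      "variants\n")
  maf <- mcols(rowRanges(object))$maf
  if (length(maf))
    cat("  MAF range:", signif(min(maf, na.rm = TRUE), 3), "-",
        signif(max(maf, na.rm = TRUE), 3), "| missing calls:",
        sum(mcols(rowRanges(object))$nMissing), "\n")
  invisible(object)
})

setMethod("show", "PhenotypeBlock", function(object) {
  cat("PhenotypeBlock:", nSamples(object), "samples,",
      ncol(object@Y), "phenotype(s) [",
      paste(colnames(object@Y), collapse = ", "), "],",
      ncol(object@X), "covariate(s)\n")
  if (any(object@incomplete))
    cat("  incomplete samples flagged:", sum(object@incomplete), "\n")
  invisible(object)
})

setMethod("show", "NullFit", function(object) {
  cat("NullFit:", nrow(object@residuals), "samples,",
      ncol(object@residuals), "phenotype(s),",
      ncol(object@design) - 1L, "covariate(s)\n")
  cat("  residual covariance:\n")
  print(signif(object@sigmaEps, 4))
  invisible(object)
})

setMethod("show", "MuratResult", function(object) {
  cat("MuratResult over", nrow(object@perRho), "rho value(s),",
      object@nVariants, "variant(s)\n")
  cat("  min p over grid:", format(object@minP, digits = 4),
      " final p:", format(object@finalP, digits = 4), "\n")
  if (length(object@flags))
    cat("  flags:", paste(object@flags, collapse = ", "), "\n")
  invisible(object)
})

setMethod("show", "ScanReport", function(object) {
  cat("ScanReport:", object@nTests, "region(s) tested; alpha =",
      object@alpha, "; Bonferroni threshold =",
      format(object@bonferroniThreshold, digits = 3), "\n")
  print(utils::head(object@rows, 5L))
  if (nrow(object@rows) > 5L) cat("  ...\n")
  invisible(object)
})
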