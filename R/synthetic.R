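#' SimConfig: synthetic-data generator settings
#'
#' Defaults emulate the study conditions of a cohort of unrelated
#' individuals with two log-scale blood-pressure phenotypes: n = 1851
#' samples, K = 2 phenotypes with residual Pearson correlation 0.542,
#' age ~ Normal(40, 10^2) and sex ~ Bernoulli(0.5) covariates, and rare
#' exomic variants with MAF drawn uniformly on [0.001, 0.05] (so many
#' singletons and doubletons appear at this sample size, exercising the
#' carrier filter).
#'
#' @slot nSamples number of individuals.
#' @slot nVariants variants per simulated region.
#' @slot mafRange MAF range, within (0, 0.5].
#' @slot K number of phenotypes.
#' @slot phenotypeCorr residual correlation between phenotype pairs
#'   (|r| < 1; unit error variances).
#' @slot errorSd residual standard deviation (0 allowed, for exact
#'   covariate-only checks).
#' @slot ageMean,ageSd,sexProb covariate distributions.
#' @slot alpha0 length-K intercepts.
#' @slot ageEffect,sexEffect covariate coefficients (recycled to K).
#' @slot causalFraction fraction of variants with nonzero effects.
#' @slot effectSize per-variant per-phenotype effect scale (effects are
#'   drawn N(0, effectSize^2) with cross-phenotype correlation
#'   \code{effectCorr}).
#' @slot effectCorr true effect correlation across phenotypes.
#' @slot affectedPhenotypes indices of phenotypes receiving genetic
#'   effects (empty = all K; a single index gives a single-trait
#'   alternative).
#' @slot missingRate fraction of genotype calls set missing.
#' @slot seed integer seed; regeneration with the same config is
#'   identical.
#' @export
setClass("SimConfig",
         representation(nSamples = "integer", nVariants = "integer",
                        mafRange = "numeric", K = "integer",
                        phenotypeCorr = "numeric", errorSd = "numeric",
                        ageMean = "numeric", ageSd = "numeric",
                        sexProb = "numeric", alpha0 = "numeric",
                        ageEffect = "numeric", sexEffect = "numeric",
                        causalFraction = "numeric", effectSize = "numeric",
                        effectCorr = "numeric",
                        affectedPhenotypes = "integer",
                        missingRate = "numeric", seed = "integer"))

setValidity("SimConfig", function(object) {
  if (any(object@mafRange <= 0) || any(object@mafRange > 0.5) ||
      object@mafRange[1L] > object@mafRange[2L])
    return("mafRange must be an increasing pair within (0, 0.5]")
  if (abs(object@phenotypeCorr) >= 1)
    return("|phenotypeCorr| must be < 1")
  if (object@causalFraction < 0 || object@causalFraction > 1)
    return("causalFraction must lie in [0, 1]")
  if (object@missingRate < 0 || object@missingRate >= 1)
    return("missingRate must lie in [0, 1)")
  if (abs(object@effectCorr) > 1)
    return("|effectCorr| must be <= 1")
  TRUE
})

#' @param nSamples,nVariants,mafRange,K,phenotypeCorr,errorSd,ageMean,ageSd,sexProb,alpha0,ageEffect,sexEffect,causalFraction,effectSize,effectCorr,affectedPhenotypes,missingRate,seed see slots.
#' @rdname SimConfig-class
#' @export
SimConfig <- function(nSamples = 1851L, nVariants = 10L,
                      mafRange = c(0.001, 0.05), K = 2L,
                      phenotypeCorr = 0.542, errorSd = 1,
                      ageMean = 40, ageSd = 10, sexProb = 0.5,
                      alpha0 = NULL, ageEffect = 0.003, sexEffect = 0.02,
                      causalFraction = 0, effectSize = 0.25,
                      effectCorr = 0.9, affectedPhenotypes = integer(0),
                      missingRate = 0, seed = 1L) {
  if (is.null(alpha0))
    alpha0 <- rep_len(c(4.7, 4.3), K)
  new("SimConfig", nSamples = as.integer(nSamples),
      nVariants = as.integer(nVariants), mafRange = mafRange,
      K = as.integer(K), phenotypeCorr = phenotypeCorr, errorSd = errorSd,
      ageMean = ageMean, ageSd = ageSd, sexProb = sexProb,
      alpha0 = rep_len(alpha0, K), ageEffect = ageEffect,
      sexEffect = sexEffect, causalFraction = causalFraction,
      effectSize = effectSize, effectCorr = effectCorr,
      affectedPhenotypes = as.integer(affectedPhenotypes),
      missingRate = missingRate, seed = as.integer(seed))
}

# K x K correlation matrix with common off-diagonal r, scaled by sd^2.
.exchangeableCov <- function(K, r, sd = 1) {
  sd^2 * ((1 - r) * diag(K) + r * matrix(1, K, K))
}

# Symmetric PSD square root (handles the singular r = 1 case chol cannot).
.matSqrt <- function(S) {
  e <- eigen((S + t(S)) / 2, symmetric = TRUE)
  e$vectors %*% (t(e$vectors) * sqrt(pmax(e$values, 0)))
}

.withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}

#' Simulate a region of rare-variant genotypes
#'
#' Per variant a MAF is drawn uniformly on \code{mafRange} and genotypes
#' are Binomial(2, MAF), independent across samples and variants (no
#' linkage disequilibrium). A \code{missingRate} fraction of calls is set
#' missing. Variants sit 100 bp apart on chromosome "1".
#'
#' @param cfg a \linkS4class{SimConfig}.
#' @return a \linkS4class{GenotypeMatrix}.
#' @export
simulateGenotypes <- function(cfg) {
  .withSeed(cfg@seed, {
    n <- cfg@nSamples
    v <- cfg@nVariants
    mafs <- stats::runif(v, cfg@mafRange[1L], cfg@mafRange[2L])
    d <- vapply(mafs, function(p) stats::rbinom(n, 2L, p), numeric(n))
    if (cfg@missingRate > 0) {
      miss <- matrix(stats::runif(n * v) < cfg@missingRate, n, v)
      # keep at least one observed call per variant
      full <- colSums(!miss) == 0L
      miss[1L, full] <- FALSE
      d[miss] <- NA_real_
    }
    pos <- seq_len(v) * 100L
    rownames(d) <- sprintf("S%04d", seq_len(n))
    colnames(d) <- sprintf("var_1_%d", pos)
    GenotypeMatrix(d, chromosome = "1", position = pos)
  })
}

#' Simulate phenotypes from genotypes under the multivariate linear model
#'
#' Y_i = alpha0 + covariate effects + G_i' beta + eps_i, with causal
#' variants chosen at \code{causalFraction}, per-variant effect vectors
#' across phenotypes drawn multivariate normal with scale
#' \code{effectSize} and common correlation \code{effectCorr}, and error
#' rows multivariate normal with standard deviation \code{errorSd} and
#' common correlation \code{phenotypeCorr}. With
#' \code{affectedPhenotypes} set, effects on the other phenotypes are
#' zeroed (a single-trait alternative).
#'
#' @param gm a \linkS4class{GenotypeMatrix} from
#'   \code{\link{simulateGenotypes}} (or compatible).
#' @param cfg a \linkS4class{SimConfig}.
#' @return a \linkS4class{PhenotypeBlock} with phenotypes P1..PK and
#'   covariates age, sex.
#' @export
simulatePhenotypes <- function(gm, cfg) {
  .withSeed(cfg@seed + 1L, {
    n <- nSamples(gm)
    K <- cfg@K
    v <- nVariants(gm)
    age <- stats::rnorm(n, cfg@ageMean, cfg@ageSd)
    sex <- stats::rbinom(n, 1L, cfg@sexProb)
    X <- cbind(age = age, sex = sex)
    alphaMat <- rbind(rep_len(cfg@ageEffect, K), rep_len(cfg@sexEffect, K))
    Y <- matrix(cfg@alpha0, n, K, byrow = TRUE) + X %*% alphaMat
    nCausal <- round(cfg@causalFraction * v)
    if (nCausal > 0) {
      causal <- sort(sample.int(v, nCausal))
      Rbeta <- .exchangeableCov(K, cfg@effectCorr)
      beta <- matrix(stats::rnorm(nCausal * K), nCausal, K) %*%
        .matSqrt(Rbeta) * cfg@effectSize
      if (length(cfg@affectedPhenotypes))
        beta[, setdiff(seq_len(K), cfg@affectedPhenotypes)] <- 0
      D <- dosages(gm)[, causal, drop = FALSE]
      if (anyNA(D))
        D <- apply(D, 2L, imputeMissing)
      Y <- Y + D %*% beta
    }
    if (cfg@errorSd > 0) {
      Sigma <- .exchangeableCov(K, cfg@phenotypeCorr, cfg@errorSd)
      Y <- Y + matrix(stats::rnorm(n * K), n, K) %*% .matSqrt(Sigma)
    }
    colnames(Y) <- paste0("P", seq_len(K))
    PhenotypeBlock(samples = sampleIds(gm), Y = Y, X = X)
  })
}

#' Empirical size / power harness
#'
#' Simulates \code{nReps} independent regions under \code{cfg} (each
#' replicate reseeded deterministically from \code{cfg@seed}), applies
#' carrier filtering and mean imputation, runs the multivariate test and
#' the per-phenotype univariate tests, and tabulates the fraction of
#' replicates with p <= alpha, with exact binomial 95\% confidence
#' intervals. With \code{causalFraction = 0} the fractions are empirical
#' type-I error rates; otherwise empirical power.
#'
#' @param cfg a \linkS4class{SimConfig}.
#' @param nReps number of replicate regions (>= 100 recommended).
#' @param alpha significance level (default 0.05).
#' @param spec an \linkS4class{EffectCovarianceSpec}.
#' @param resamples resampling depth for the multivariate grid
#'   combination.
#' @param minCarriers carrier filter applied per replicate (default 4).
#' @param keepP also return the matrix of per-replicate p-values.
#' @return data.frame with one row per method (murat, skat_P1..PK,
#'   skat_adjusted): rejection rate, exact binomial CI, replicate counts.
#'   With \code{keepP = TRUE}, the p-value matrix is attached as
#'   attribute \code{"pValues"}.
#' @export
sizePowerHarness <- function(cfg, nReps, alpha = 0.05,
                             spec = EffectCovarianceSpec(),
                             resamples = 1000L, minCarriers = 4L,
                             keepP = FALSE) {
  if (nReps < 1L) stop("nReps must be positive")
  K <- cfg@K
  methods <- c("murat", paste0("skat_P", seq_len(K)), "skat_adjusted")
  P <- matrix(NA_real_, nReps, length(methods),
              dimnames = list(NULL, methods))
  seeds <- .withSeed(cfg@seed,
                     matrix(sample.int(.Machine$integer.max - 1L,
                                       2L * nReps), ncol = 2L))
  for (r in seq_len(nReps)) {
    cfgR <- initialize(cfg, seed = seeds[r, 1L])
    gm <- simulateGenotypes(cfgR)
    gm <- tryCatch(suppressMessages(filterVariants(gm, minCarriers)),
                   error = function(e) NULL)
    if (is.null(gm) || nVariants(gm) == 0L) next
    block <- simulatePhenotypes(gm, cfgR)
    gm <- imputeGenotypes(gm)
    Y <- phenotypes(block)
    X <- covariates(block)
    G <- dosages(gm)
    mafs <- mcols(rowRanges(gm))$maf
    fit <- fitNull(Y, X)
    res <- muratPvalue(fit, G, mafs, spec, resamples = resamples,
                       seed = seeds[r, 2L])
    P[r, "murat"] <- finalP(res)
    for (k in seq_len(K))
      P[r, 1L + k] <- skatPvalue(Y[, k], X, G, mafs, spec)
    P[r, "skat_adjusted"] <- adjustedMinP(P[r, 1L + seq_len(K)])
  }
  out <- do.call(rbind, lapply(methods, function(mth) {
    p <- P[, mth]
    nValid <- sum(!is.na(p))
    hits <- sum(p <= alpha, na.rm = TRUE)
    ci <- stats::binom.test(hits, max(nValid, 1L))$conf.int
    data.frame(method = mth, rate = hits / nValid, lower = ci[1L],
               upper = ci[2L], nReps = nReps, nValid = nValid,
               stringsAsFactors = FALSE)
  }))
  if (keepP) attr(out, "pValues") <- P
  out
}
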