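#' MAF-based variant weights
#'
#' Beta-density weights \eqn{w_j = f_{Beta}(maf_j; a, b)}, the
#' SKAT-family convention: with the default (1, 25) rarer variants are
#' up-weighted; (1, 1) gives unit weights. Monomorphic variants (MAF 0)
#' are an error -- they should have been removed by the carrier filter.
#'
#' @param mafs minor allele frequencies in (0, 0.5].
#' @param params length-2 positive shape parameters (a, b).
#' @export
variantWeights <- function(mafs, params = c(1, 25)) {
  if (any(is.na(mafs)) || any(mafs <= 0))
    stop("weights require MAF > 0 for every variant ",
         "(monomorphic variants must be filtered out)")
  if (any(mafs > 0.5)) stop("MAF must be on the minor-allele scale (<= 0.5)")
  stats::dbeta(mafs, params[1L], params[2L])
}

# Common precomputation for the multivariate score statistic on one
# region: weighted, design-residualized genotype cross-products and the
# (inverse) residual covariance factors.
.scoreKernel <- function(fit, G, weights) {
  G <- as.matrix(G)
  n <- nrow(fit@residuals)
  if (nrow(G) != n) stop("G must have one row per fitted sample")
  v <- ncol(G)
  if (length(weights) != v) stop("one weight per variant required")
  sigInv <- .sigmaEpsInverse(fit)
  sigInvSqrt <- .sigmaEpsInvSqrt(fit)
  M <- fit@residuals %*% sigInv               # n x K
  Tmat <- weights * crossprod(G, M)           # v x K, = W^{1/2} G' V^{-1} r
  Gperp <- projectionApply(fit, G)
  Gw <- sweep(Gperp, 2L, weights, `*`)
  B <- crossprod(Gw)                          # W^{1/2} Gperp' Gperp W^{1/2}
  list(Tmat = Tmat, C = crossprod(Tmat), B = B,
       eigB = eigen(B, symmetric = TRUE, only.values = TRUE)$values,
       sigInv = sigInv, sigInvSqrt = sigInvSqrt,
       K = ncol(fit@residuals), v = v)
}

.rhoMatrix <- function(K, rho) {
  (1 - rho) * diag(K) + rho * matrix(1, K, K)
}

# Q statistic and null mixture at one rho, given the kernel precompute.
.statAtRho <- function(kern, rho) {
  R <- .rhoMatrix(kern$K, rho)
  Q <- sum(R * kern$C)
  A <- kern$sigInvSqrt %*% R %*% kern$sigInvSqrt
  eigA <- eigen((A + t(A)) / 2, symmetric = TRUE, only.values = TRUE)$values
  lambdas <- as.vector(outer(eigA, kern$eigB))
  list(Q = Q, mixture = ChiSquareMixture(lambdas))
}

#' Multivariate score statistic and its null mixture at a fixed rho
#'
#' For a region of v variants and K phenotypes, with stacked residual
#' vector r (phenotype-major), \eqn{V = \Sigma_\epsilon \otimes I_n},
#' effect-correlation matrix \eqn{R_\rho = (1-\rho)I_K + \rho J_K} and
#' weight matrix \eqn{W = diag(w_j^2)}, the score statistic is
#' \deqn{Q = r^T V^{-1} (R_\rho \otimes G W G^T) V^{-1} r,}
#' whose null law is the chi-square mixture with weights given by the
#' eigenvalues of
#' \eqn{(\Sigma_\epsilon^{-1/2} R_\rho \Sigma_\epsilon^{-1/2}) \otimes
#' (W^{1/2} G_\perp^T G_\perp W^{1/2})} -- a Kronecker product, so the
#' K-by-K and v-by-v factors are decomposed separately and their
#' eigenvalues multiplied.
#'
#' @param fit \linkS4class{NullFit} on the same samples as \code{G}.
#' @param G n-by-v dosage submatrix (complete, i.e. imputed).
#' @param weights per-variant weights \eqn{w_j} (see
#'   \code{\link{variantWeights}}).
#' @param rho effect correlation in [0, 1).
#' @return list with elements \code{Q} (numeric) and \code{mixture}
#'   (\linkS4class{ChiSquareMixture}).
#' @export
muratStatistic <- function(fit, G, weights, rho) {
  if (rho < 0 || rho >= 1) stop("rho must lie in [0, 1)")
  kern <- .scoreKernel(fit, G, weights)
  .statAtRho(kern, rho)
}

#' Data-adaptive multivariate rare-variant test for one region
#'
#' Computes the score statistic and its analytic p-value at every rho on
#' the grid, takes the minimum p, and calibrates that minimum by seeded
#' Gaussian score resampling: the v-by-K score cross-product
#' \eqn{T = W^{1/2} G_\perp^T E \Sigma_\epsilon^{-1}} is exactly
#' \eqn{N(0, \Sigma_\epsilon^{-1} \otimes W^{1/2}G_\perp^TG_\perp W^{1/2})}
#' under the null (conditioning on the nuisance estimates), so surrogate
#' score stacks are drawn from that law, each surrogate's minimum
#' grid p is compared with the observed minimum, and
#' \code{finalP = (1 + #exceedances) / (resamples + 1)} (never reported
#' below \code{minP}: selecting the best rho cannot make the adjusted p
#' smaller than the unadjusted minimum). The conservative
#' Bonferroni-over-grid bound \code{min(1, gridSize * minP)} is reported
#' alongside.
#'
#' @param fit \linkS4class{NullFit}.
#' @param G n-by-v dosage submatrix (imputed; no missing values).
#' @param mafs per-variant minor allele frequencies in (0, 0.5].
#' @param spec an \linkS4class{EffectCovarianceSpec}.
#' @param resamples number of Gaussian surrogates for the grid
#'   combination (default 1000; a warning below 100).
#' @param seed optional integer seed for the resampling draws.
#' @return a \linkS4class{MuratResult}.
#' @export
muratPvalue <- function(fit, G, mafs, spec = EffectCovarianceSpec(),
                        resamples = 1000L, seed = NULL) {
  grid <- spec@rhoGrid
  if (length(grid) == 0L) stop("rho grid is empty")
  weights <- variantWeights(mafs, spec@weightBetaParams)
  kern <- .scoreKernel(fit, G, weights)
  if (max(kern$eigB) <= 0)
    stop("region is empty after residualization (rank-0 genotype matrix)")
  stats <- lapply(grid, function(rho) .statAtRho(kern, rho))
  ps <- lapply(seq_along(grid), function(i)
    qformPvalue(stats[[i]]$mixture, stats[[i]]$Q))
  flags <- character(0)
  if (any(vapply(ps, attr, "", which = "method") == "liu"))
    flags <- "liu_fallback"
  perRho <- data.frame(rho = grid,
                       Q = vapply(stats, `[[`, numeric(1), "Q"),
                       p = vapply(ps, as.numeric, numeric(1)))
  minIdx <- which.min(perRho$p)
  minP <- perRho$p[minIdx]
  bonfP <- min(1, length(grid) * minP)
  if (length(grid) == 1L || kern$K == 1L) {
    # a single grid point needs no adjustment; with one phenotype rho
    # never enters, so every grid point gives the same p
    finalP <- minP
  } else {
    if (resamples < 100L)
      warning("fewer than 100 resamples; the grid-adjusted p is coarse")
    finalP <- .resampleMinP(kern, stats, grid, minP, resamples, seed)
    finalP <- max(finalP, minP)
  }
  new("MuratResult", perRho = perRho, minP = minP, finalP = finalP,
      bonferroniP = min(1, bonfP), nVariants = ncol(as.matrix(G)),
      flags = flags)
}

# Monte Carlo tail of the minimum grid p. Rather than evaluating a
# quadratic-form p for every surrogate and rho, invert once per rho:
# surrogate min-p <= observed minP  iff  Q_b(rho) >= q_rho for some rho,
# where q_rho is the statistic threshold with p(q_rho) = minP.
.resampleMinP <- function(kern, stats, grid, minP, resamples, seed) {
  thresholds <- vapply(stats, function(s)
    .qformQuantile(s$mixture, minP), numeric(1))
  eB <- eigen(kern$B, symmetric = TRUE)
  Bhalf <- eB$vectors %*% (t(eB$vectors) * sqrt(pmax(eB$values, 0)))
  Shalf <- kern$sigInvSqrt
  Rs <- lapply(grid, .rhoMatrix, K = kern$K)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                        globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  hits <- 0L
  for (b in seq_len(resamples)) {
    Z <- Bhalf %*% matrix(stats::rnorm(kern$v * kern$K), kern$v) %*% Shalf
    Cb <- crossprod(Z)
    for (i in seq_along(grid)) {
      if (sum(Rs[[i]] * Cb) >= thresholds[i]) {
        hits <- hits + 1L
        break
      }
    }
  }
  (1 + hits) / (resamples + 1)
}

#' Univariate SKAT p-value for one phenotype and one region
#'
#' The weighted-linear-kernel variance-component score test: with null
#' residuals r and estimated error variance \eqn{\hat\sigma^2},
#' \eqn{Q = r^T G W G^T r / \hat\sigma^2} is referred to the chi-square
#' mixture with weights the eigenvalues of
#' \eqn{W^{1/2} G_\perp^T G_\perp W^{1/2}}. This is exactly the K = 1
#' specialization of \code{\link{muratPvalue}} (rho plays no role), and
#' the two agree to numerical accuracy.
#'
#' @param y length-n phenotype vector.
#' @param X covariate matrix or NULL.
#' @param G n-by-v dosage submatrix.
#' @param mafs per-variant MAFs.
#' @param spec an \linkS4class{EffectCovarianceSpec} (weights only).
#' @return p-value in (0, 1].
#' @export
skatPvalue <- function(y, X, G, mafs, spec = EffectCovarianceSpec()) {
  fit <- fitNull(matrix(y, ncol = 1, dimnames = list(NULL, "y")), X)
  skatPvalueFit(fit, G, mafs, spec)
}

#' @rdname skatPvalue
#' @param fit a K = 1 \linkS4class{NullFit} (avoids refitting in scans).
#' @export
skatPvalueFit <- function(fit, G, mafs, spec = EffectCovarianceSpec()) {
  if (ncol(fit@residuals) != 1L)
    stop("skatPvalueFit needs a single-phenotype null fit")
  G <- as.matrix(G)
  if (all(G == 0))
    stop("monomorphic region: all dosages zero")
  weights <- variantWeights(mafs, spec@weightBetaParams)
  st <- muratStatistic(fit, G, weights, rho = 0)
  as.numeric(qformPvalue(st$mixture, st$Q))
}

#' Minimum-p adjustment across K phenotypes
#'
#' Bonferroni over phenotypes: min(1, K * min(p)). For K = 2 this is the
#' "twice the minimum" rule used when comparing per-phenotype univariate
#' tests with a joint test.
#'
#' @param pValues length-K vector of p-values in (0, 1].
#' @export
adjustedMinP <- function(pValues) {
  if (length(pValues) == 0L) stop("empty p-value list")
  if (any(is.na(pValues) | pValues <= 0 | pValues > 1))
    stop("p-values must lie in (0, 1]")
  min(1, length(pValues) * min(pValues))
}
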