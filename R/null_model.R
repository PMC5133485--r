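#' Fit the covariate-only multivariate null model
#'
#' Each of the K phenotypes is regressed on the shared design [1, X] by
#' ordinary least squares (with an identical design across phenotypes,
#' OLS coincides with GLS, so a single QR factorization serves all
#' phenotypes). The residual covariance is the cross-product of the
#' residual columns divided by n - m - 1, the unbiased denominator under
#' the null. This fit is all the score tests need: no genotype enters.
#'
#' @param Y numeric n-by-K phenotype matrix (a vector is treated as K = 1).
#' @param X numeric n-by-m covariate matrix, or NULL for intercept-only.
#' @return a \linkS4class{NullFit}.
#' @examples
#' x <- rnorm(50)
#' Y <- cbind(a = 1 + 2 * x + rnorm(50), b = -x + rnorm(50))
#' fit <- fitNull(Y, cbind(x = x))
#' sigmaEps(fit)
#' @export
fitNull <- function(Y, X = NULL) {
  Y <- as.matrix(Y)
  if (is.null(colnames(Y)))
    colnames(Y) <- paste0("phenotype", seq_len(ncol(Y)))
  n <- nrow(Y)
  if (anyNA(Y)) stop("phenotypes contain missing values; run ",
                     "dropIncompleteSamples() first")
  if (is.null(X)) X <- matrix(numeric(0), nrow = n, ncol = 0)
  X <- as.matrix(X)
  if (ncol(X) && anyNA(X)) stop("covariates contain missing values")
  m <- ncol(X)
  if (n <= m + 1L)
    stop("need n > m + 1 samples to fit the null model")
  design <- cbind(`(Intercept)` = rep(1, n), X)
  qrD <- qr(design)
  if (qrD$rank < ncol(design)) {
    dropped <- colnames(design)[qrD$pivot[-seq_len(qrD$rank)]]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(dropped, collapse = ", "))
  }
  coefs <- qr.coef(qrD, Y)
  res <- qr.resid(qrD, Y)
  sig <- crossprod(res) / (n - m - 1)
  sig <- (sig + t(sig)) / 2
  new("NullFit",
      alpha0 = coefs[1L, ],
      alpha = coefs[-1L, , drop = FALSE],
      residuals = res,
      sigmaEps = sig,
      design = design,
      qr = qrD)
}

#' Residualize a matrix against the null design
#'
#' Returns M minus its least-squares projection onto the columns of the
#' null design; the output is orthogonal to every design column. Used to
#' project genotype columns before forming the score-statistic
#' eigenvalues.
#'
#' @param fit a \linkS4class{NullFit}.
#' @param M numeric matrix with one row per sample.
#' @export
projectionApply <- function(fit, M) {
  M <- as.matrix(M)
  if (nrow(M) != nrow(fit@design))
    stop("M must have one row per sample of the null fit")
  qr.resid(fit@qr, M)
}

# Inverse of the residual covariance, with a soft ridge when the
# phenotype pair is numerically degenerate (condition number > 1e12).
.sigmaEpsInverse <- function(fit) {
  sig <- fit@sigmaEps
  ev <- eigen(sig, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0 || max(ev) / min(ev) > 1e12)
    diag(sig) <- diag(sig) + 1e-8 * mean(diag(sig))
  solve(sig)
}

# Symmetric square root of the inverse residual covariance.
.sigmaEpsInvSqrt <- function(fit) {
  sig <- fit@sigmaEps
  e <- eigen(sig, symmetric = TRUE)
  ev <- e$values
  if (min(ev) <= 0 || max(ev) / min(ev) > 1e12) {
    diag(sig) <- diag(sig) + 1e-8 * mean(diag(sig))
    e <- eigen(sig, symmetric = TRUE)
    ev <- e$values
  }
  if (any(ev <= 0))
    stop("residual covariance is singular even after regularization")
  e$vectors %*% (t(e$vectors) / sqrt(ev))
}
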