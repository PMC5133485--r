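#' Tail probability of a weighted sum of chi-square(1) variables
#'
#' Computes \eqn{P(\sum_l \lambda_l \chi^2_1 > q)} -- the null law of the
#' score-test quadratic forms -- by numerical inversion of the
#' characteristic function (the Davies/Imhof scheme),
#' \deqn{P(Q > q) = 1/2 + \frac{1}{\pi}\int_0^\infty
#'   \frac{\sin\theta(u)}{u\,\rho(u)}\,du,}
#' with \eqn{\theta(u) = \frac12\sum_l \arctan(\lambda_l u) - qu/2} and
#' \eqn{\rho(u) = \prod_l (1+\lambda_l^2u^2)^{1/4}}, evaluated as a
#' midpoint sum whose grid spacing controls the aliasing error and whose
#' truncation point is set from the decay of the integrand envelope. If
#' the inversion fails or lands outside (0, 1] (deep tails suffer
#' cancellation at absolute accuracy), the moment-matching approximation
#' of Liu, Tang and Zhang (match mean, variance and skewness to a scaled
#' noncentral chi-square) is used instead and the result carries
#' \code{attr(, "method") == "liu"}.
#'
#' @param mix a \linkS4class{ChiSquareMixture}.
#' @param q non-negative quantile.
#' @param accuracy target absolute accuracy of the inversion.
#' @return p in (0, 1], floored at \code{1e-300}; attribute
#'   \code{"method"} records \code{"davies"} or \code{"liu"}.
#' @examples
#' qformPvalue(ChiSquareMixture(1), qchisq(0.95, df = 1))  # 0.05
#' @export
qformPvalue <- function(mix, q, accuracy = 1e-6) {
  if (length(q) != 1L || is.na(q) || q < 0)
    stop("q must be a single non-negative number")
  lambda <- mix@lambdas
  if (q == 0) {
    p <- 1
    attr(p, "method") <- "exact"
    return(p)
  }
  # the tail is invariant under joint rescaling of (lambda, q); normalize
  # by the largest weight for numerical uniformity
  s <- lambda[1L]
  p <- .daviesTail(lambda / s, q / s, accuracy)
  method <- "davies"
  # below the absolute accuracy of the inversion the result is
  # cancellation noise; the moment-matched tail is more trustworthy there
  if (is.na(p) || p <= accuracy || p > 1) {
    p <- .liuTail(lambda, q)
    method <- "liu"
  }
  p <- min(max(p, 1e-300), 1)
  attr(p, "method") <- method
  p
}

# Gil-Pelaez inversion of the characteristic function by a midpoint sum,
# Davies-style: with grid u_k = (k + 1/2) * delta,
#   P(Q > q) ~ 1/2 + (delta/pi) * sum_k sin(theta(u_k)) / (u_k rho(u_k)),
# theta(u) = 0.5 sum_l atan(lambda_l u) - q u / 2,
# rho(u) = prod_l (1 + lambda_l^2 u^2)^(1/4).
# Aliasing error is bounded by the tail P(Q > 2 pi / delta - q), so delta
# is set from a point T beyond which the (moment-matched) tail is far
# below `accuracy`; the k-sum is truncated once the oscillation-cancelled
# remainder bound 4 * envelope(U) / q drops below the budget.
.daviesTail <- function(lambda, q, accuracy) {
  tailSmall <- function(t) .liuTail(lambda, t) < accuracy / 20
  T <- sum(lambda) + 10 * sqrt(2 * sum(lambda^2))
  while (!tailSmall(T)) {
    T <- T * 2
    if (T > 1e9) return(NA_real_)
  }
  delta <- 2 * pi / (q + T)
  envelope <- function(u)
    exp(-log(u) - 0.25 * sum(log1p(lambda^2 * u^2)))
  budget <- accuracy * pi / 4
  U <- delta * 64
  while (4 * envelope(U) / q > budget) {
    U <- U * 2
    if (U / delta > 6e6) return(NA_real_)
  }
  nTerms <- ceiling(U / delta)
  total <- 0
  for (chunk in split(seq_len(nTerms) - 1L,
                      (seq_len(nTerms) - 1L) %/% 200000L)) {
    u <- (chunk + 0.5) * delta
    lu <- outer(lambda, u)
    theta <- 0.5 * colSums(atan(lu)) - 0.5 * q * u
    logrho <- 0.25 * colSums(log1p(lu * lu))
    total <- total + sum(sin(theta) / (u * exp(logrho)))
  }
  0.5 + total * delta / pi
}

# Liu-Tang-Zhang moment matching: central chi-square mixture mapped to a
# (possibly noncentral) chi-square by matching mean, variance, skewness.
.liuTail <- function(lambda, q) {
  c1 <- sum(lambda)
  c2 <- sum(lambda^2)
  c3 <- sum(lambda^3)
  c4 <- sum(lambda^4)
  s1 <- c3 / c2^1.5
  s2 <- c4 / c2^2
  if (s1^2 > s2) {
    a <- 1 / (s1 - sqrt(s1^2 - s2))
    delta <- s1 * a^3 - a^2
    l <- a^2 - 2 * delta
  } else {
    a <- 1 / s1
    delta <- 0
    l <- c2^3 / c3^2
  }
  muQ <- c1
  sigmaQ <- sqrt(2 * c2)
  tstar <- (q - muQ) / sigmaQ
  muX <- l + delta
  sigmaX <- sqrt(2) * a
  stats::pchisq(tstar * sigmaX + muX, df = l, ncp = delta,
                lower.tail = FALSE)
}

#' Chi-square mixture weights from a symmetric matrix
#'
#' Eigen-decomposes a symmetric PSD matrix into the weights of the
#' corresponding quadratic form's null mixture. Eigenvalues more negative
#' than the truncation threshold are clipped with a warning (numerical
#' null space of projected kernels); before clipping, the weights sum to
#' the trace.
#'
#' @param A symmetric matrix (checked to 1e-8 relative).
#' @param truncationTol relative truncation threshold (default 1e-10).
#' @return a \linkS4class{ChiSquareMixture}.
#' @export
mixtureFromMatrix <- function(A, truncationTol = 1e-10) {
  A <- as.matrix(A)
  if (nrow(A) != ncol(A) ||
      max(abs(A - t(A))) > 1e-8 * max(1, max(abs(A))))
    stop("A must be symmetric")
  ev <- eigen((A + t(A)) / 2, symmetric = TRUE, only.values = TRUE)$values
  ChiSquareMixture(ev, truncationTol = truncationTol)
}

# Smallest q with qformPvalue(mix, q) <= target, by bracketed root search.
# Used to turn an observed minimum p over the rho grid into per-rho
# statistic thresholds for the resampling combination.
.qformQuantile <- function(mix, target) {
  acc <- max(1e-10, min(1e-6, target / 50))
  f <- function(q) as.numeric(qformPvalue(mix, q, accuracy = acc)) - target
  lo <- 0
  hi <- sum(mix@lambdas) + 1
  while (f(hi) > 0) {
    lo <- hi
    hi <- hi * 2
    if (hi > 1e12) return(hi)
  }
  stats::uniroot(f, c(lo, hi), tol = 1e-9 * max(1, hi))$root
}
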