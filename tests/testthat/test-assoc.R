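test_that("Beta-density weights follow the MAF in the expected direction", {
  expect_equal(variantWeights(c(0.01, 0.3, 0.5), c(1, 1)), c(1, 1, 1))
  w <- variantWeights(c(0.01, 0.05), c(1, 25))
  expect_gt(w[1], w[2])  # rarer variant up-weighted
  expect_equal(variantWeights(0.5, c(1, 25)), 25 * 0.5^24)
  expect_error(variantWeights(c(0.1, 0), c(1, 25)), "monomorphic")
})

test_that("single-variant single-phenotype case equals the hand-computed score test", {
  # fixed 8-sample toy, no covariates, unit weight
  y <- c(2.1, 3.4, 1.9, 4.2, 2.8, 3.1, 2.2, 3.9)
  g <- c(0, 1, 0, 2, 0, 1, 0, 0)
  n <- 8
  r <- y - mean(y)
  s2 <- sum(r^2) / (n - 1)
  gp <- g - mean(g)
  # two-sided normal score test recomputed by hand
  z <- sum(gp * y) / sqrt(s2 * sum(gp^2))
  pHand <- 2 * pnorm(-abs(z))
  fit <- fitNull(cbind(y = y))
  st <- muratStatistic(fit, cbind(g), weights = 1, rho = 0)
  expect_equal(st$Q, sum(g * r)^2 / s2^2, tolerance = 1e-10)
  expect_equal(mixtureWeights(st$mixture), sum(gp^2) / s2,
               tolerance = 1e-10)
  expect_equal(as.numeric(qformPvalue(st$mixture, st$Q)), pHand,
               tolerance = 1e-6)
  # and the exported univariate test agrees
  expect_equal(skatPvalue(y, NULL, cbind(g), mafs = computeMaf(g),
                          spec = EffectCovarianceSpec(
                            weightBetaParams = c(1, 1))),
               pHand, tolerance = 1e-6)
})

test_that("with one phenotype the multivariate test reduces to the univariate test", {
  set.seed(41)
  spec <- EffectCovarianceSpec()
  for (v in c(1L, 5L, 20L)) {
    mafs <- runif(v, 0.02, 0.2)
    G <- randomGenotypes(300, mafs)
    X <- cbind(age = rnorm(300, 40, 10))
    y <- rnorm(300) + 0.1 * G[, 1]
    fit <- fitNull(cbind(y = y), X)
    res <- muratPvalue(fit, G, colMeans(G) / 2, spec, resamples = 200,
                       seed = 5)
    pSkat <- skatPvalue(y, X, G, colMeans(G) / 2, spec)
    expect_equal(finalP(res), pSkat, tolerance = 1e-8)
    expect_equal(minP(res), pSkat, tolerance = 1e-8)
  }
})

test_that("at rho 0 with diagonal error covariance Q decomposes per phenotype", {
  set.seed(42)
  n <- 150
  G <- randomGenotypes(n, c(0.1, 0.2, 0.3))
  mafs <- colMeans(G) / 2
  w <- variantWeights(mafs)
  X <- cbind(x = rnorm(n))
  Y <- cbind(P1 = rnorm(n), P2 = rnorm(n))
  fit <- fitNull(Y, X)
  fitDiag <- fit
  fitDiag@sigmaEps <- diag(diag(fit@sigmaEps))
  Qjoint <- muratStatistic(fitDiag, G, w, rho = 0)$Q
  Qparts <- vapply(1:2, function(k) {
    fk <- fitNull(Y[, k, drop = FALSE], X)
    fk@sigmaEps <- fit@sigmaEps[k, k, drop = FALSE] * diag(1)
    muratStatistic(fk, G, w, rho = 0)$Q
  }, numeric(1))
  expect_equal(Qjoint, sum(Qparts), tolerance = 1e-8)
})

test_that("mixture weights sum to the analytic trace of the defining matrix", {
  set.seed(43)
  n <- 100
  G <- randomGenotypes(n, c(0.05, 0.15, 0.3, 0.4))
  w <- variantWeights(colMeans(G) / 2)
  X <- cbind(x = rnorm(n))
  Y <- randomPhenotypes(n)
  fit <- fitNull(Y, X)
  Gp <- projectionApply(fit, G)
  B <- crossprod(sweep(Gp, 2, w, `*`))
  Sinv <- solve(sigmaEps(fit))
  for (rho in c(0, 0.3, 0.7, 0.99)) {
    st <- muratStatistic(fit, G, w, rho)
    R <- (1 - rho) * diag(2) + rho
    traceExpected <- sum(diag(Sinv %*% R)) * sum(diag(B))
    expect_equal(sum(mixtureWeights(st$mixture)), traceExpected,
                 tolerance = 1e-6)
  }
})

test_that("the grid-adjusted p never undercuts the minimum and collapses on a point grid", {
  set.seed(44)
  n <- 120
  G <- randomGenotypes(n, c(0.1, 0.25))
  mafs <- colMeans(G) / 2
  Y <- randomPhenotypes(n)
  fit <- fitNull(Y)
  onePoint <- EffectCovarianceSpec(rhoGrid = 0.3)
  r1 <- muratPvalue(fit, G, mafs, onePoint, seed = 1)
  expect_equal(finalP(r1), perRho(r1)$p[1])
  spec <- EffectCovarianceSpec()
  for (s in 1:8) {
    Y2 <- randomPhenotypes(n)
    f2 <- fitNull(Y2)
    r <- muratPvalue(f2, G, mafs, spec, resamples = 300, seed = s)
    expect_gte(finalP(r), minP(r))
    expect_true(all(perRho(r)$p > 0 & perRho(r)$p <= 1))
    expect_lte(minP(r), r@bonferroniP)
  }
})

test_that("monomorphic regions and empty inputs are rejected", {
  set.seed(45)
  y <- rnorm(20)
  G0 <- matrix(0, 20, 2)
  expect_error(skatPvalue(y, NULL, G0, mafs = c(0.1, 0.1)), "monomorphic")
  expect_error(adjustedMinP(numeric(0)), "empty")
})

test_that("minimum-p adjustment is Bonferroni over phenotypes", {
  expect_equal(adjustedMinP(c(0.03, 0.2)), 0.06)
  expect_equal(adjustedMinP(c(0.9, 0.8)), 1.0)  # capped
  expect_equal(adjustedMinP(c(0.5, 0.2, 0.1)), 0.3)  # K = 3
})
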