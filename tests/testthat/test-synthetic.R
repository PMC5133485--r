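test_that("genotype simulation is deterministic and respects the MAF range", {
  cfg <- SimConfig(nSamples = 200L, nVariants = 8L, seed = 61L)
  g1 <- simulateGenotypes(cfg)
  g2 <- simulateGenotypes(cfg)
  expect_identical(dosages(g1), dosages(g2))
  expect_identical(variantInfo(g1), variantInfo(g2))
  maf <- S4Vectors::mcols(variantInfo(g1))$maf
  expect_true(all(maf >= 0 & maf <= 0.5))
})

test_that("boundary MAF 0.5 folds and common variants carry many carriers", {
  cfg <- SimConfig(nSamples = 400L, nVariants = 5L,
                   mafRange = c(0.5, 0.5), seed = 62L)
  gm <- simulateGenotypes(cfg)
  expect_true(all(S4Vectors::mcols(variantInfo(gm))$maf <= 0.5))
  # expected dosage sum per variant = n at maf 0.5
  expect_equal(mean(colSums(dosages(gm))), 400, tolerance = 0.1)
})

test_that("very rare variants produce sub-threshold carrier counts", {
  # at maf 0.001, carriers per variant ~ Binomial(1851, ~0.002):
  # P(< 4 carriers) ~ 0.5, so among 40 variants some must fail the filter
  cfg <- SimConfig(nSamples = 1851L, nVariants = 40L,
                   mafRange = c(0.001, 0.001), seed = 63L)
  gm <- simulateGenotypes(cfg)
  nc <- S4Vectors::mcols(variantInfo(gm))$nCarriers
  expect_gt(sum(nc < 4L), 0L)
  expect_gt(sum(nc >= 4L), 0L)
  filtered <- suppressMessages(filterVariants(gm, minCarriers = 4L))
  expect_equal(nVariants(filtered), sum(nc >= 4L))
})

test_that("missing-call injection keeps at least one observed call per variant", {
  cfg <- SimConfig(nSamples = 60L, nVariants = 10L, missingRate = 0.3,
                   seed = 64L)
  gm <- simulateGenotypes(cfg)
  d <- dosages(gm)
  expect_gt(sum(is.na(d)), 0L)
  expect_true(all(colSums(!is.na(d)) >= 1L))
})

test_that("with no causal variants and no noise the phenotypes are the covariate part", {
  cfg <- SimConfig(nSamples = 50L, nVariants = 4L, causalFraction = 0,
                   errorSd = 0, seed = 65L)
  gm <- simulateGenotypes(cfg)
  blk <- simulatePhenotypes(gm, cfg)
  X <- covariates(blk)
  expected <- cbind(4.7 + 0.003 * X[, "age"] + 0.02 * X[, "sex"],
                    4.3 + 0.003 * X[, "age"] + 0.02 * X[, "sex"])
  expect_equal(unname(phenotypes(blk)), expected, tolerance = 1e-12)
})

test_that("the simulated phenotype correlation matches its target at n = 1851", {
  cfg <- SimConfig(seed = 66L)  # defaults: n 1851, corr 0.542
  gm <- simulateGenotypes(cfg)
  blk <- simulatePhenotypes(gm, cfg)
  r <- phenotypeCorrelation(blk, "P1", "P2")
  expect_lt(abs(r - 0.542), 0.04)  # Fisher-z band at this n
})

test_that("perfect effect correlation gives identical genetic components", {
  base <- SimConfig(nSamples = 300L, nVariants = 6L, causalFraction = 1,
                    effectCorr = 1, effectSize = 0.5, errorSd = 0,
                    ageEffect = 0, sexEffect = 0, alpha0 = c(0, 0),
                    seed = 67L)
  gm <- simulateGenotypes(base)
  blk <- simulatePhenotypes(gm, base)
  expect_equal(phenotypes(blk)[, 1], phenotypes(blk)[, 2],
               tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("a single-trait alternative leaves the other phenotype unaffected", {
  cfg <- SimConfig(nSamples = 200L, nVariants = 6L, causalFraction = 1,
                   affectedPhenotypes = 1L, effectSize = 0.6,
                   errorSd = 0, ageEffect = 0, sexEffect = 0,
                   alpha0 = c(0, 0), seed = 68L)
  gm <- simulateGenotypes(cfg)
  blk <- simulatePhenotypes(gm, cfg)
  expect_gt(stats::var(phenotypes(blk)[, 1]), 0)
  expect_equal(stats::var(phenotypes(blk)[, 2]), 0)
})

test_that("the harness tabulates rejection rates with binomial intervals", {
  cfg <- SimConfig(nSamples = 150L, nVariants = 6L,
                   mafRange = c(0.05, 0.2), causalFraction = 0,
                   seed = 69L)
  tab <- sizePowerHarness(cfg, nReps = 30, resamples = 150)
  expect_setequal(tab$method,
                  c("murat", "skat_P1", "skat_P2", "skat_adjusted"))
  expect_true(all(tab$rate >= 0 & tab$rate <= 1))
  expect_true(all(tab$lower <= tab$rate & tab$rate <= tab$upper))
  expect_true(all(tab$nValid <= 30))
  # deterministic regeneration
  tab2 <- sizePowerHarness(cfg, nReps = 30, resamples = 150)
  expect_identical(tab, tab2)
})
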