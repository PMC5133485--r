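test_that("log transform hits the usual anchors and round-trips", {
  block <- PhenotypeBlock(samples = c("a", "b", "c"),
                          Y = cbind(SBP = c(exp(1), 1, 100),
                                    DBP = c(80, 85, 90)))
  out <- logTransformPhenotypes(block, "SBP")
  expect_equal(phenotypes(out)[, "SBP"], c(1, 0, log(100)))
  expect_equal(phenotypes(out)[, "DBP"], c(80, 85, 90))  # untouched
  # round trip within floating tolerance
  set.seed(1)
  vals <- runif(200, 50, 250)
  b2 <- PhenotypeBlock(samples = paste0("s", 1:200), Y = cbind(SBP = vals))
  back <- exp(phenotypes(logTransformPhenotypes(b2, "SBP"))[, "SBP"])
  expect_equal(back, vals, tolerance = 1e-12)
  # constant column keeps zero variance
  b3 <- PhenotypeBlock(samples = c("a", "b", "c"),
                       Y = cbind(SBP = c(100, 100, 100)))
  expect_equal(var(phenotypes(logTransformPhenotypes(b3, "SBP"))[, "SBP"]),
               0)
  bad <- PhenotypeBlock(samples = c("a", "b"), Y = cbind(SBP = c(120, -3)))
  expect_error(logTransformPhenotypes(bad, "SBP"), "non-positive.*b")
})

test_that("complete-case filtering removes phenotype- or covariate-missing rows", {
  Y <- cbind(SBP = c(1, 2, 3, 4, 5), DBP = c(1, NA, 3, 4, 5))
  X <- cbind(age = c(40, 41, NA, 43, 44))
  block <- PhenotypeBlock(samples = paste0("s", 1:5), Y = Y, X = X)
  expect_message(out <- dropIncompleteSamples(block), "2 sample")
  expect_equal(nSamples(out), 3L)
  expect_equal(sampleIds(out), c("s1", "s4", "s5"))
  # identity when complete
  full <- PhenotypeBlock(samples = c("a", "b"), Y = cbind(P = c(1, 2)))
  expect_identical(dropIncompleteSamples(full), full)
  allBad <- PhenotypeBlock(samples = "a", Y = cbind(P = NA_real_))
  expect_error(dropIncompleteSamples(allBad), "no samples remain")
})

test_that("phenotype correlation matches closed forms and a seeded target", {
  Y <- cbind(A = c(1, 2, 3, 5), B = c(1, 2, 3, 5), C = -c(1, 2, 3, 5),
             D = c(1, 1, 1, 1))
  block <- PhenotypeBlock(samples = paste0("s", 1:4), Y = Y)
  expect_equal(phenotypeCorrelation(block, "A", "B"), 1)
  expect_equal(phenotypeCorrelation(block, "A", "C"), -1)
  expect_error(phenotypeCorrelation(block, "A", "D"), "zero variance.*D")
  # at n = 1851 the Fisher-z 95% sampling band around 0.542 is ~ +/- 0.033
  set.seed(542)
  Yc <- randomPhenotypes(1851, corr = 0.542)
  bc <- PhenotypeBlock(samples = paste0("s", 1:1851), Y = Yc)
  expect_lt(abs(phenotypeCorrelation(bc, "P1", "P2") - 0.542), 0.04)
})

test_that("MAF is the folded observed allele frequency", {
  expect_equal(computeMaf(c(0, 0, 1, 2)), 3 / 8)
  expect_equal(computeMaf(c(0, 0, 0, 0)), 0)
  expect_equal(computeMaf(c(2, 2, 2, 1)), 1 / 8)  # alt is the major allele
  expect_equal(computeMaf(c(NA, 0, 1)), 0.25)     # observed entries only
  expect_error(computeMaf(c(NA_real_, NA_real_)), "missing")
})

test_that("mean imputation preserves the MAF and folds correctly", {
  expect_equal(imputeMissing(c(0, 1, NA), maf = 0.25), c(0, 1, 0.5))
  x <- c(0, 1, NA)
  expect_equal(computeMaf(imputeMissing(x)), computeMaf(x))
  expect_identical(imputeMissing(c(0, 1, 2)), c(0, 1, 2))  # no-op
  expect_equal(imputeMissing(c(0, 0, NA), maf = 0), c(0, 0, 0))
  # alt-major variant: missing entries filled on the stored alt scale
  y <- c(2, 2, 1, NA)
  yi <- imputeMissing(y)
  expect_equal(yi[4], 2 * (5 / 6))  # expected alt dosage, not 2*maf
  expect_equal(computeMaf(yi), computeMaf(y))
})

test_that("imputation conserves MAF across randomized missingness patterns", {
  set.seed(8)
  for (i in 1:50) {
    n <- sample(20:200, 1)
    p <- runif(1, 0.01, 0.5)
    x <- rbinom(n, 2, p)
    x[sample(n, floor(runif(1, 0, 0.3) * n))] <- NA
    if (all(is.na(x))) next
    expect_equal(computeMaf(imputeMissing(x)), computeMaf(x),
                 tolerance = 1e-15)
  }
})

test_that("carrier filter counts individuals before imputation and is monotone", {
  expect_true(carrierFilter(c(0, 1, 1, 1, 1, 0), 4))
  expect_false(carrierFilter(c(0, 1, 1, 1, 0, 0), 4))
  expect_false(carrierFilter(c(2, 0, 0, 0), 4))  # one homozygous carrier
  expect_true(carrierFilter(c(2, 0, 0, 0), 1))
  expect_false(carrierFilter(c(NA, 1, 1, 1, NA), 4))  # missing not carriers
  set.seed(9)
  for (i in 1:20) {
    x <- rbinom(50, 2, runif(1, 0.02, 0.3))
    passes <- vapply(1:10, function(m) carrierFilter(x, m), logical(1))
    expect_true(all(diff(as.integer(passes)) <= 0))  # loosening never drops
  }
})

test_that("GenotypeMatrix-level QC: imputation, filtering, alignment", {
  set.seed(10)
  d <- randomGenotypes(40, c(0.2, 0.01, 0.3))
  d[1:5, 1] <- NA
  gm <- GenotypeMatrix(d, chromosome = "1", position = c(100, 200, 300))
  gi <- imputeGenotypes(gm)
  expect_false(anyNA(dosages(gi)))
  expect_equal(S4Vectors::mcols(variantInfo(gi))$maf,
               S4Vectors::mcols(variantInfo(gm))$maf)
  expect_equal(apply(dosages(gi), 2, computeMaf),
               S4Vectors::mcols(variantInfo(gm))$maf,
               tolerance = 1e-15, ignore_attr = TRUE)
  block <- PhenotypeBlock(samples = rev(rownames(d))[1:30],
                          Y = cbind(P = rnorm(30)))
  al <- suppressMessages(alignSamples(gm, block))
  expect_equal(sampleIds(al$gm), sampleIds(al$block))
  expect_equal(nSamples(al$gm), 30L)
  # genotype-file order wins
  expect_equal(sampleIds(al$gm),
               intersect(rownames(d), sampleIds(block)))
})
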