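makeGm <- function(pos, chr = "1") {
  set.seed(3)
  d <- matrix(rbinom(20 * length(pos), 2, 0.3), nrow = 20)
  colnames(d) <- paste0("v", seq_along(pos))
  GenotypeMatrix(d, chromosome = chr, position = pos)
}

test_that("gene regions use inclusive bounds and drop empty genes", {
  gm <- makeGm(c(10L, 20L, 21L))
  genes <- GenomicRanges::GRanges("1", IRanges::IRanges(c(10, 500),
                                                        c(20, 600)))
  S4Vectors::mcols(genes)$name <- c("GENEA", "GENEB")
  regs <- suppressMessages(geneRegions(genes, gm))
  expect_equal(length(regs), 1L)  # GENEB has no variants
  expect_equal(S4Vectors::mcols(regs)$name, "GENEA")
  expect_equal(S4Vectors::mcols(regs)$variantIndices[[1]], c(1L, 2L))
})

test_that("a variant shared by overlapping genes appears in both regions", {
  gm <- makeGm(c(150L, 250L))
  genes <- GenomicRanges::GRanges("1", IRanges::IRanges(c(100, 140),
                                                        c(200, 300)))
  S4Vectors::mcols(genes)$name <- c("G1", "G2")
  regs <- geneRegions(genes, gm)
  expect_equal(length(regs), 2L)
  expect_true(1L %in% S4Vectors::mcols(regs)$variantIndices[[1]])
  expect_true(1L %in% S4Vectors::mcols(regs)$variantIndices[[2]])
  # invariant to gene input order
  regs2 <- geneRegions(rev(genes), gm)
  ord <- match(S4Vectors::mcols(regs)$name, S4Vectors::mcols(regs2)$name)
  expect_equal(unname(as.list(S4Vectors::mcols(regs2)$variantIndices[ord])),
               unname(as.list(S4Vectors::mcols(regs)$variantIndices)))
})

test_that("windows tile the occupied genome from coordinate 1", {
  gm <- makeGm(c(100L, 29999L, 30050L))
  regs <- windowRegions(gm, width = 30000L)
  expect_equal(length(regs), 2L)
  expect_equal(GenomicRanges::start(regs), c(1L, 30001L))
  expect_equal(GenomicRanges::end(regs), c(30000L, 60000L))
  expect_equal(S4Vectors::mcols(regs)$variantIndices[[1]], c(1L, 2L))
  expect_equal(S4Vectors::mcols(regs)$variantIndices[[2]], 3L)
  # single variant at position 1
  g1 <- makeGm(1L)
  r1 <- windowRegions(g1, width = 30000L)
  expect_equal(GenomicRanges::start(r1), 1L)
  expect_equal(GenomicRanges::end(r1), 30000L)
})

test_that("windows partition variants: each assigned exactly once", {
  set.seed(11)
  pos <- sort(sample.int(2e5, 60))
  gm <- makeGm(as.integer(pos))
  for (w in c(1L, 7L, 30000L)) {
    regs <- windowRegions(gm, width = w)
    members <- unlist(S4Vectors::mcols(regs)$variantIndices)
    expect_equal(sort(members), seq_len(60))        # cover, no duplicates
    expect_false(any(GenomicRanges::countOverlaps(regs, regs) > 1L))
    # members lie within their window bounds
    for (i in seq_along(regs)) {
      p <- pos[S4Vectors::mcols(regs)$variantIndices[[i]]]
      expect_true(all(p >= GenomicRanges::start(regs)[i] &
                        p <= GenomicRanges::end(regs)[i]))
    }
  }
})

test_that("window width 1 degenerates to one window per occupied position", {
  gm <- makeGm(c(5L, 9L, 9L))
  regs <- windowRegions(gm, width = 1L)
  expect_equal(length(regs), 2L)
  expect_equal(lengths(S4Vectors::mcols(regs)$variantIndices), c(1L, 2L))
})

test_that("anchoring at the first variant shifts the grid", {
  gm <- makeGm(c(1000L, 1500L))
  regs <- windowRegions(gm, width = 600L, anchor = "first-variant")
  expect_equal(GenomicRanges::start(regs)[1], 1000L)
})

test_that("single-variant regions honour the carrier filter", {
  d <- cbind(v1 = c(1, 1, 1, 1, 0, 0), v2 = c(1, 0, 0, 0, 0, 0),
             v3 = c(2, 1, 1, 2, 0, 0))
  rownames(d) <- paste0("s", 1:6)
  gm <- GenotypeMatrix(d, chromosome = "1", position = c(10, 20, 30))
  regs <- singleVariantRegions(gm, minCarriers = 4L)
  expect_equal(S4Vectors::mcols(regs)$name, c("v1", "v3"))
  expect_equal(lengths(S4Vectors::mcols(regs)$variantIndices),
               c(1L, 1L))
  none <- singleVariantRegions(gm, minCarriers = 10L)
  expect_equal(length(none), 0L)
})
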