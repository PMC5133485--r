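# Regions are plain GRanges with two metadata columns: `name` and
# `variantIndices` (an IntegerList of column indices into the
# GenotypeMatrix). All three scan designs produce this shape.

.stripChr <- function(x) sub("^chr", "", as.character(x))

.variantPositions <- function(gm) {
  rr <- rowRanges(gm)
  list(chr = .stripChr(seqnames(rr)), pos = start(rr))
}

#' Gene-based variant sets
#'
#' One region per annotated gene containing at least one variant with
#' position inside the gene's (1-based, inclusive) bounds; genes without
#' variants are dropped with a message. A variant inside two overlapping
#' genes appears in both regions. Chromosome labels are compared after
#' stripping any leading "chr".
#'
#' @param genes a GRanges of gene bounds with a \code{name} metadata
#'   column (see \code{\link{readGeneList}}).
#' @param gm a \linkS4class{GenotypeMatrix}.
#' @return a GRanges of regions with \code{name} and
#'   \code{variantIndices} metadata columns.
#' @export
geneRegions <- function(genes, gm) {
  vp <- .variantPositions(gm)
  vgr <- GRanges(vp$chr, IRanges(vp$pos, width = 1L))
  ggr <- GRanges(.stripChr(seqnames(genes)), ranges(genes))
  hits <- findOverlaps(ggr, vgr, ignore.strand = TRUE)
  idxList <- split(subjectHits(hits), factor(queryHits(hits),
                                             levels = seq_along(genes)))
  nVar <- lengths(idxList)
  keep <- nVar > 0L
  if (any(!keep))
    message(sum(!keep), " gene(s) without variants excluded")
  out <- ggr[keep]
  mcols(out)$name <- mcols(genes)$name[keep]
  mcols(out)$variantIndices <- IntegerList(lapply(idxList[keep], sort))
  out
}

#' Fixed-width non-overlapping window variant sets
#'
#' Per chromosome, windows of \code{width} base pairs tile the genome on
#' a grid anchored either at coordinate 1 (window w covers
#' \code{[(w-1)*width + 1, w*width]}; the default) or at the first
#' variant's position. Only occupied windows are returned, and every
#' variant belongs to exactly one window.
#'
#' @param gm a \linkS4class{GenotypeMatrix}.
#' @param width window width in base pairs (default 30000, i.e. 30 kb).
#' @param anchor "one" for the coordinate-1 grid, "first-variant" to
#'   start the grid at the first variant per chromosome.
#' @return a GRanges of regions with \code{name} and
#'   \code{variantIndices} metadata columns.
#' @export
windowRegions <- function(gm, width = 30000L,
                          anchor = c("one", "first-variant")) {
  anchor <- match.arg(anchor)
  if (width < 1L) stop("width must be >= 1")
  vp <- .variantPositions(gm)
  out <- list()
  for (chr in unique(vp$chr)) {
    onChr <- which(vp$chr == chr)
    pos <- vp$pos[onChr]
    offset <- if (anchor == "one") 0L else min(pos) - 1L
    widx <- (pos - offset - 1L) %/% width
    for (w in sort(unique(widx))) {
      s <- offset + w * width + 1L
      members <- onChr[widx == w]
      out[[length(out) + 1L]] <- GRanges(
        chr, IRanges(s, s + width - 1L),
        name = sprintf("%s:%d-%d", chr, s, s + width - 1L),
        variantIndices = IntegerList(list(sort(members))))
    }
  }
  if (length(out) == 0L)
    return(GRanges(name = character(0),
                   variantIndices = IntegerList()))
  do.call(c, out)
}

#' Single-variant "regions"
#'
#' One singleton region per variant passing the carrier filter, so the
#' region-based machinery doubles as a single-variant scan.
#'
#' @param gm a \linkS4class{GenotypeMatrix}.
#' @param minCarriers carrier-count filter (default 4).
#' @return a GRanges of singleton regions.
#' @export
singleVariantRegions <- function(gm, minCarriers = 4L) {
  info <- mcols(rowRanges(gm))
  keep <- which(info$nCarriers >= minCarriers)
  if (length(keep) == 0L)
    return(GRanges(name = character(0), variantIndices = IntegerList()))
  vp <- .variantPositions(gm)
  out <- GRanges(vp$chr[keep], IRanges(vp$pos[keep], width = 1L))
  mcols(out)$name <- names(rowRanges(gm))[keep]
  mcols(out)$variantIndices <- IntegerList(as.list(keep))
  out
}
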