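#' Read genotype dosages from VCF or a dosage table
#'
#' VCF (v4.x, plain text or bgzipped) is read through
#' \code{VariantAnnotation::readVcf}; GT calls are converted to alt-allele
#' dosages 0/1/2 and missing calls (\code{./.} or \code{.}) to \code{NA} --
#' never to 0, imputation is a separate explicit step
#' (\code{\link{imputeGenotypes}}). Multi-allelic records are rejected by
#' default; with \code{splitMultiallelic = TRUE} each alt allele becomes
#' its own bi-allelic record whose dosage counts that allele.
#'
#' The dosage-table alternative is tab-separated: first column sample id,
#' one numeric column per variant, header row of variant ids. Ids of the
#' form \code{chr_pos}, \code{chr:pos} or \code{var_chr_pos} are parsed
#' for coordinates; otherwise the chromosome is "un" and the position is
#' the column index.
#'
#' @param path file path.
#' @param format "vcf", "dosage", or "auto" (by file extension).
#' @param splitMultiallelic split multi-allelic VCF records instead of
#'   raising an error.
#' @return a \linkS4class{GenotypeMatrix} with per-variant MAF, carrier
#'   and missing-call counts computed on observed genotypes.
#' @export
readGenotypes <- function(path, format = c("auto", "vcf", "dosage"),
                          splitMultiallelic = FALSE) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.vcf(\\.b?gz)?$", path)) "vcf" else "dosage"
  if (format == "vcf")
    .readVcfDosages(path, splitMultiallelic)
  else
    .readDosageTable(path)
}

.gtToDosage <- function(gt, altIndex, id) {
  # gt: character vector of GT calls for one record
  alleles <- strsplit(gt, "[/|]")
  vapply(seq_along(alleles), function(i) {
    a <- alleles[[i]]
    if (all(a == ".")) return(NA_real_)
    if (!all(grepl("^[0-9]+$", a)))
      stop("malformed genotype call '", gt[i], "' at record ", id)
    sum(as.integer(a) == altIndex)
  }, numeric(1))
}

.readVcfDosages <- function(path, splitMultiallelic) {
  # check the sample header up front: htslib cannot even parse a VCF with
  # duplicated sample columns, and its message would not name the cause
  con <- file(path, "r")
  on.exit(close(con))
  repeat {
    line <- readLines(con, n = 1L)
    if (length(line) == 0L)
      stop("no #CHROM header line found in ", path)
    if (startsWith(line, "#CHROM")) break
  }
  samples <- strsplit(line, "\t", fixed = TRUE)[[1L]][-(1:9)]
  if (anyDuplicated(samples))
    stop("duplicate sample id in VCF: ",
         samples[duplicated(samples)][1L])
  vcf <- tryCatch(VariantAnnotation::readVcf(path),
                  error = function(e)
                    stop("malformed VCF ", path, ": ",
                         conditionMessage(e)))
  gt <- VariantAnnotation::geno(vcf)$GT
  if (is.null(gt))
    stop("VCF has no GT field: ", path)
  altList <- VariantAnnotation::alt(vcf)
  nAlt <- S4Vectors::elementNROWS(altList)
  multi <- nAlt > 1L
  if (any(multi) && !splitMultiallelic)
    stop("multi-allelic record(s) at ",
         paste(utils::head(rownames(gt)[multi], 3L), collapse = ", "),
         "; set splitMultiallelic = TRUE to expand them")
  rr <- SummarizedExperiment::rowRanges(vcf)
  recIdx <- rep(seq_len(nrow(gt)), nAlt)
  altIdx <- unlist(lapply(nAlt, seq_len), use.names = FALSE)
  ids <- rownames(gt)[recIdx]
  ids[nAlt[recIdx] > 1L] <- paste0(ids[nAlt[recIdx] > 1L], "_alt",
                                   altIdx[nAlt[recIdx] > 1L])
  dos <- matrix(NA_real_, nrow = ncol(gt), ncol = length(recIdx),
                dimnames = list(colnames(gt), ids))
  altChar <- as.character(unlist(altList, use.names = FALSE))
  for (j in seq_along(recIdx))
    dos[, j] <- .gtToDosage(gt[recIdx[j], ], altIdx[j], ids[j])
  GenotypeMatrix(dos,
                 chromosome = as.character(GenomicRanges::seqnames(rr))[recIdx],
                 position = GenomicRanges::start(rr)[recIdx],
                 variantId = ids,
                 ref = as.character(VariantAnnotation::ref(vcf))[recIdx],
                 alt = altChar)
}

.parseVariantIds <- function(ids) {
  m <- regmatches(ids, regexec("^(?:var[_:])?(\\w+?)[_:](\\d+)$", ids))
  chr <- vapply(m, function(x) if (length(x) == 3L) x[2L] else NA_character_,
                character(1))
  pos <- vapply(m, function(x) if (length(x) == 3L) as.numeric(x[3L])
                else NA_real_, numeric(1))
  miss <- is.na(pos)
  chr[miss] <- "un"
  pos[miss] <- which(miss)
  list(chromosome = chr, position = as.integer(pos))
}

.readDosageTable <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (ncol(tab) < 2L)
    stop("dosage table needs a sample-id column plus >= 1 variant column: ",
         path)
  ids <- as.character(tab[[1L]])
  if (anyDuplicated(ids))
    stop("duplicate sample id in dosage table: ",
         ids[duplicated(ids)][1L])
  d <- as.matrix(tab[, -1L, drop = FALSE])
  if (!is.numeric(d))
    stop("non-numeric dosage value in ", path)
  rownames(d) <- ids
  coords <- .parseVariantIds(colnames(d))
  GenotypeMatrix(d, chromosome = coords$chromosome,
                 position = coords$position, variantId = colnames(d))
}

#' Write a GenotypeMatrix as a tab-separated dosage table
#'
#' Full-precision output; reading it back with \code{\link{readGenotypes}}
#' reproduces the dosages and derived MAF/carrier counts exactly.
#'
#' @param gm a \linkS4class{GenotypeMatrix}.
#' @param path output file path.
#' @export
writeDosages <- function(gm, path) {
  d <- dosages(gm)
  tab <- data.frame(sample = rownames(d), check.names = FALSE)
  tab[colnames(d)] <- as.data.frame(d, check.names = FALSE)
  utils::write.table(format(tab, digits = 17, trim = TRUE, scientific = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a phenotype/covariate table
#'
#' Tab-separated, one row per sample. Samples with any missing requested
#' phenotype or covariate are flagged (and removed downstream by
#' \code{\link{dropIncompleteSamples}}).
#'
#' @param path file path.
#' @param phenotypeCols names of the phenotype columns (K of them).
#' @param covariateCols names of the covariate columns (may be empty for
#'   an intercept-only null model).
#' @param idCol name of the sample-id column (default: first column).
#' @return a \linkS4class{PhenotypeBlock}.
#' @export
readPhenotypes <- function(path, phenotypeCols, covariateCols = character(0),
                           idCol = NULL) {
  tab <- utils::read.delim(path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (is.null(idCol)) idCol <- names(tab)[1L]
  missing <- setdiff(c(idCol, phenotypeCols, covariateCols), names(tab))
  if (length(missing))
    stop("column(s) not found in ", path, ": ",
         paste(missing, collapse = ", "))
  Y <- as.matrix(tab[phenotypeCols])
  X <- if (length(covariateCols))
    as.matrix(tab[covariateCols])
  else matrix(numeric(0), nrow = nrow(tab), ncol = 0)
  storage.mode(Y) <- "double"
  if (ncol(X)) storage.mode(X) <- "double"
  PhenotypeBlock(samples = as.character(tab[[idCol]]), Y = Y, X = X)
}

#' Read a gene annotation list (glist format)
#'
#' Whitespace-delimited lines: chromosome, start, end, gene name; 1-based
#' inclusive bounds. Overlapping genes are allowed and all retained.
#'
#' @param path file path.
#' @param stripChr normalize chromosome labels by stripping a leading
#'   "chr" (default TRUE).
#' @return a \code{GRanges} with a \code{name} metadata column.
#' @export
readGeneList <- function(path, stripChr = TRUE) {
  tab <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                           col.names = c("chromosome", "start", "end",
                                         "name"),
                           colClasses = c("character", "character",
                                          "character", "character"))
  for (col in c("start", "end"))
    if (any(!grepl("^[0-9]+$", tab[[col]])))
      stop("non-integer ", col, " bound for gene ",
           tab$name[!grepl("^[0-9]+$", tab[[col]])][1L])
  start <- as.integer(tab$start)
  end <- as.integer(tab$end)
  if (any(start > end))
    stop("start > end for gene ", tab$name[start > end][1L])
  chr <- if (stripChr) sub("^chr", "", tab$chromosome) else tab$chromosome
  gr <- GRanges(chr, IRanges(start, end))
  mcols(gr)$name <- tab$name
  gr
}

#' Write scan results as a tab-separated table
#'
#' Header plus one line per region; p-value columns (names starting
#' \code{p_}) are written in scientific notation. Column layout mirrors
#' the association-table convention: chromosome, region id, variant
#' count/MAF, per-phenotype univariate p, adjusted minimum p,
#' multivariate p.
#'
#' @param rows a data.frame of result records (e.g. \code{scanRows} of a
#'   \linkS4class{ScanReport}).
#' @param path output file path.
#' @export
writeResults <- function(rows, path) {
  rows <- as.data.frame(rows)
  for (col in grep("^p_", names(rows), value = TRUE))
    rows[[col]] <- ifelse(is.na(rows[[col]]), "NA",
                          sprintf("%.6e", rows[[col]]))
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
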