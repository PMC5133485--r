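# Shared fixture builders. Everything is generated in code; the only
# on-disk fixtures are the tiny examples under inst/extdata.

extfile <- function(name) system.file("extdata", name, package = "murat")

# Binomial(2, maf) genotype matrix, samples x variants
randomGenotypes <- function(n, mafs) {
  d <- vapply(mafs, function(p) stats::rbinom(n, 2L, p), numeric(n))
  colnames(d) <- sprintf("var_1_%d", seq_along(mafs) * 100L)
  rownames(d) <- sprintf("S%04d", seq_len(n))
  d
}

# Correlated bivariate normal phenotypes with given correlation
randomPhenotypes <- function(n, corr = 0.542, K = 2L) {
  S <- (1 - corr) * diag(K) + corr * matrix(1, K, K)
  e <- eigen(S, symmetric = TRUE)
  Y <- matrix(stats::rnorm(n * K), n, K) %*%
    (e$vectors %*% (t(e$vectors) * sqrt(e$values)))
  colnames(Y) <- paste0("P", seq_len(K))
  Y
}

# Write a small VCF from genotype strings: gtRows is a list of character
# vectors (one per record), meta a data.frame with chrom/pos/id/ref/alt.
writeTestVcf <- function(path, meta, gtRows, samples) {
  header <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
            "INFO", "FORMAT", samples), collapse = "\t"))
  body <- vapply(seq_len(nrow(meta)), function(i)
    paste(c(meta$chrom[i], meta$pos[i], meta$id[i], meta$ref[i],
            meta$alt[i], ".", "PASS", ".", "GT", gtRows[[i]]),
          collapse = "\t"), character(1))
  writeLines(c(header, body), path)
  path
}
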