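# Shared fixture builders: everything is generated in code at test time.

toyVariants <- function(n = 3L, chrom = "1", posStart = 1000L) {
  k <- max(n, 1L)
  df <- data.frame(
    snp_id = sprintf("rs%d", seq_len(k)),
    chrom = chrom,
    pos = posStart + (seq_len(k) - 1L) * 100L,
    a1 = rep(c("A", "C", "G"), length.out = k),
    a2 = rep(c("G", "T", "A"), length.out = k),
    p = seq(0.1, 0.9, length.out = k),
    stringsAsFactors = FALSE
  )
  df[seq_len(n), , drop = FALSE]
}

writeToySumstats <- function(df, path = tempfile(fileext = ".tsv")) {
  names(df) <- toupper(names(df))
  names(df)[names(df) == "SNP_ID"] <- "SNP"
  names(df)[names(df) == "CHROM"] <- "CHR"
  names(df)[names(df) == "POS"] <- "BP"
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# Reference panel with exact dosage columns supplied by the caller.
manualPanel <- function(dosages, chrom = "1", posStart = 1000L,
                        spacing = 100L) {
  colnames(dosages) <- sprintf("rs%d", seq_len(ncol(dosages)))
  new("ReferencePanel",
      variants = data.frame(
        snp_id = colnames(dosages), chrom = chrom,
        pos = posStart + (seq_len(ncol(dosages)) - 1L) * spacing,
        stringsAsFactors = FALSE),
      dosages = dosages, nDropped = 0L)
}

# Analytic LD structures used for calibration checks.
ar1Matrix <- function(m, rho) rho^abs(outer(seq_len(m), seq_len(m), "-"))
blockMatrix <- function(m, size, rho) {
  blk <- rep(seq_len(ceiling(m / size)), each = size)[1:m]
  R <- outer(blk, blk, function(a, b) ifelse(a == b, rho, 0))
  diag(R) <- 1
  R
}

# Draw SNP Z under MVN(mu, R) from a pre-computed Cholesky factor.
drawZ <- function(L, mu = 0) as.numeric(L %*% rnorm(nrow(L))) + mu

twoSidedP <- function(z) 2 * pnorm(abs(z), lower.tail = FALSE)

# GRanges gene helper
toyGenes <- function(chrom, start, end, strand = "+",
                     ids = sprintf("G%d", seq_along(start))) {
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end),
                               strand = strand)
  S4Vectors::mcols(gr)$gene_id <- ids
  S4Vectors::mcols(gr)$symbol <- ids
  gr
}
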