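#' Write an annotation to TSV
#'
#' One row per annotated gene: \code{gene_id}, \code{n_snps}, \code{mac}
#' and the comma-joined SNP identifiers.
#'
#' @param ann a \code{\linkS4class{GeneAnnotation}}.
#' @param ss the \code{\linkS4class{SumStats}} the annotation indexes.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeAnnotation <- function(ann, ss, path) {
  g <- annotatedGenes(ann)
  v <- variants(ss)
  out <- data.frame(
    gene_id = g$gene_id, n_snps = g$n_snps, mac = g$mac,
    snp_ids = vapply(snpIndex(ann), function(ix)
      paste(v$snp_id[ix], collapse = ","), ""),
    stringsAsFactors = FALSE
  )
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gene-location file
#'
#' TSV with header columns \code{gene_id}, \code{chrom}, \code{start},
#' \code{end}, \code{strand}, \code{symbol} (hg19-style, 1-based inclusive
#' coordinates). Only autosomal genes (chromosomes 1-22) are retained,
#' matching the analysis of autosomal protein-coding genes; unknown strand
#' may be encoded as \code{"*"} or \code{"."}.
#'
#' @param path file path.
#' @return A \code{\link[GenomicRanges]{GRanges}} with metadata columns
#'   \code{gene_id} and \code{symbol}.
#' @export
readGeneLoc <- function(path) {
  g <- data.table::fread(path, header = TRUE, data.table = FALSE)
  need <- c("gene_id", "chrom", "start", "end", "strand", "symbol")
  if (!all(need %in% names(g)))
    stop("gene-location file needs columns: ", paste(need, collapse = ", "))
  g$chrom <- sub("^chr", "", as.character(g$chrom), ignore.case = TRUE)
  auto <- g$chrom %in% as.character(1:22)
  if (any(!auto))
    warning(sum(!auto), " non-autosomal gene(s) dropped")
  g <- g[auto, , drop = FALSE]
  if (any(g$start > g$end)) stop("gene(s) with start > end")
  st <- ifelse(g$strand %in% c("+", "-"), g$strand, "*")
  gr <- GenomicRanges::GRanges(
    seqnames = g$chrom,
    ranges = IRanges::IRanges(start = g$start, end = g$end),
    strand = st
  )
  S4Vectors::mcols(gr)$gene_id <- as.character(g$gene_id)
  S4Vectors::mcols(gr)$symbol <- as.character(g$symbol)
  gr
}

#' Extend gene boundaries with a regulatory window
#'
#' Gene coordinates are extended upstream and downstream (defaults 5 kb and
#' 1.5 kb) to capture potential regulatory variation; the extension is
#' strand-aware, so for a minus-strand gene "upstream" lies beyond the 3'
#' coordinate end. Unknown strand is treated as plus. Intervals are 1-based
#' inclusive and the lower bound is floored at 1.
#'
#' @param genes a \code{GRanges} of gene bodies (see
#'   \code{\link{readGeneLoc}}).
#' @param up upstream extension in bp (default 5000).
#' @param down downstream extension in bp (default 1500).
#' @return A \code{GRanges} with the extended windows (same metadata).
#' @export
extendWindow <- function(genes, up = 5000, down = 1500) {
  stopifnot(up >= 0, down >= 0)
  st <- as.character(GenomicRanges::strand(genes))
  minus <- st == "-"
  newStart <- GenomicRanges::start(genes) - ifelse(minus, down, up)
  newEnd <- GenomicRanges::end(genes) + ifelse(minus, up, down)
  out <- genes
  IRanges::ranges(out) <- IRanges::IRanges(start = pmax(newStart, 1),
                                           end = newEnd)
  out
}

#' Exclude genes overlapping the extended MHC
#'
#' Removes any gene whose (extended) window overlaps the extended major
#' histocompatibility complex region, excluded because of its complex LD.
#' Default region: chr6:28477797-33448354 (hg19), 1-based inclusive.
#'
#' @param genes a \code{GRanges} (typically already window-extended).
#' @param chrom,start,end the region to mask.
#' @return The filtered \code{GRanges}; the number removed is reported via
#'   a message.
#' @export
excludeMhc <- function(genes, chrom = "6", start = 28477797, end = 33448354) {
  mhc <- GenomicRanges::GRanges(sub("^chr", "", as.character(chrom)),
                                IRanges::IRanges(start, end))
  # suppress the Seqinfo merge note when the gene set spans chromosomes
  # the mask region does not
  hit <- suppressWarnings(
    GenomicRanges::findOverlaps(genes, mhc, ignore.strand = TRUE))
  drop <- unique(S4Vectors::queryHits(hit))
  message(length(drop), " gene(s) removed for MHC overlap")
  if (length(drop)) genes[-drop] else genes
}

#' Map variants to genes
#'
#' Assigns each variant to every gene whose extended window contains its
#' position (1-based inclusive bounds; a variant inside k overlapping
#' windows is assigned to all k genes). Genes with no assigned variant are
#' absent from the map. The genic minor allele count (MAC) is computed from
#' the reference panel as the sum over the gene's SNPs of
#' \code{min(ac, 2n - ac)} where \code{ac} is the panel allele-dosage sum;
#' variants absent from the panel contribute 0 and are counted.
#'
#' @param ss a munged \code{\linkS4class{SumStats}}.
#' @param genes extended, MHC-filtered gene windows (\code{GRanges} with
#'   \code{gene_id}, \code{symbol}).
#' @param panel a \code{\linkS4class{ReferencePanel}} (may be \code{NULL}:
#'   MAC is then \code{NA}).
#' @param up,down window extensions recorded for provenance only (the
#'   \code{genes} input is assumed already extended).
#' @return A \code{\linkS4class{GeneAnnotation}}.
#' @export
annotateGenes <- function(ss, genes, panel = NULL, up = 5000, down = 1500) {
  stopifnot(is(ss, "SumStats"))
  if (length(genes) == 0L) stop("empty gene list")
  v <- variants(ss)
  vgr <- GenomicRanges::GRanges(v$chrom, IRanges::IRanges(v$pos, v$pos))
  hits <- suppressWarnings(
    GenomicRanges::findOverlaps(genes, vgr, ignore.strand = TRUE))
  byGene <- split(S4Vectors::subjectHits(hits),
                  S4Vectors::queryHits(hits))
  if (!length(byGene)) warning("no variant falls in any gene window")

  gi <- as.integer(names(byGene))
  ids <- S4Vectors::mcols(genes)$gene_id[gi]
  snpIdx <- lapply(byGene, function(ix) sort(unname(ix)))
  names(snpIdx) <- ids

  nMissing <- 0L
  mac <- rep(NA_real_, length(gi))
  if (!is.null(panel)) {
    pv <- variants(panel)
    dos <- dosages(panel)
    n2 <- 2 * nrow(dos)
    ac <- colSums(dos)
    macSnp <- pmin(ac, n2 - ac)
    names(macSnp) <- pv$snp_id
    mac <- vapply(snpIdx, function(ix) {
      ids <- v$snp_id[ix]
      found <- ids %in% names(macSnp)
      nMissing <<- nMissing + sum(!found)
      sum(macSnp[ids[found]])
    }, 1.0)
  }

  gdf <- data.frame(
    gene_id = ids,
    symbol = S4Vectors::mcols(genes)$symbol[gi],
    chrom = as.character(GenomicRanges::seqnames(genes))[gi],
    start = GenomicRanges::start(genes)[gi],
    end = GenomicRanges::end(genes)[gi],
    strand = as.character(GenomicRanges::strand(genes))[gi],
    wstart = GenomicRanges::start(genes)[gi],
    wend = GenomicRanges::end(genes)[gi],
    n_snps = vapply(snpIdx, length, 1L),
    mac = as.numeric(mac),
    stringsAsFactors = FALSE
  )
  rownames(gdf) <- NULL
  new("GeneAnnotation", genes = gdf, snpIndex = snpIdx,
      nMissingPanel = as.integer(nMissing))
}
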