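#' Construct a SumStats object from a variant table
#'
#' Low-level constructor used by \code{\link{readSumstats}} and by the
#' synthetic-data generator.
#'
#' @param variants data.frame with at least \code{snp_id}, \code{chrom},
#'   \code{pos}, \code{a1}, \code{a2}, \code{p}; optionally \code{z},
#'   \code{n}, \code{info}.
#' @param disorder phenotype label.
#' @param totalN total GWAS sample size (meta-analysis weight).
#' @param log named list of QC counters.
#' @return A \code{\linkS4class{SumStats}}.
#' @export
SumStats <- function(variants, disorder = NA_character_, totalN = NA_real_,
                     log = list()) {
  variants$chrom <- as.character(variants$chrom)
  variants$snp_id <- as.character(variants$snp_id)
  if (is.null(variants$ambiguous))
    variants$ambiguous <- isStrandAmbiguous(variants$a1, variants$a2)
  rownames(variants) <- NULL
  new("SumStats", disorder = disorder, totalN = as.numeric(totalN),
      variants = variants, log = log)
}

isStrandAmbiguous <- function(a1, a2) {
  pair <- paste0(toupper(a1), toupper(a2))
  pair %in% c("AT", "TA", "CG", "GC")
}

#' Read GWAS summary statistics
#'
#' Reads a tab/whitespace-delimited summary-statistics file with a header.
#' Column names are configurable through \code{columnMap}; \code{SNP},
#' \code{CHR}, \code{BP}, \code{A1}, \code{A2} and \code{P} are mandatory,
#' \code{N}, \code{INFO} and \code{Z} are used when present. Rows whose
#' p-value or position cannot be parsed are skipped and counted; p-values of
#' exactly zero are clamped to \code{1e-300} (needed by the probit transform
#' downstream) with the clamp count logged. Chromosome labels are normalised
#' by stripping a \code{"chr"} prefix; non-autosomal records (X/Y/MT) are
#' dropped, as only autosomal protein-coding genes are analysed.
#'
#' @param path file path.
#' @param columnMap named character vector mapping the canonical names
#'   \code{SNP, CHR, BP, A1, A2, P, N, INFO, Z} to the file's header names.
#' @param disorder phenotype label attached to the result.
#' @param totalN total GWAS sample size; when \code{NULL}, the maximum of
#'   the \code{N} column is used (NA if absent).
#' @return A \code{\linkS4class{SumStats}} with raw (unfiltered) records;
#'   QC counters are available via \code{\link{qcLog}}.
#' @export
readSumstats <- function(path,
                         columnMap = c(SNP = "SNP", CHR = "CHR", BP = "BP",
                                       A1 = "A1", A2 = "A2", P = "P",
                                       N = "N", INFO = "INFO", Z = "Z"),
                         disorder = NA_character_, totalN = NULL) {
  if (!file.exists(path)) stop("summary-statistics file not found: ", path)
  defaults <- c(SNP = "SNP", CHR = "CHR", BP = "BP", A1 = "A1", A2 = "A2",
                P = "P", N = "N", INFO = "INFO", Z = "Z")
  cm <- defaults
  cm[names(columnMap)] <- columnMap
  dt <- data.table::fread(path, header = TRUE, data.table = FALSE)
  mandatory <- c("SNP", "CHR", "BP", "A1", "A2", "P")
  miss <- mandatory[!cm[mandatory] %in% names(dt)]
  if (length(miss))
    stop("mandatory column(s) missing from ", path, ": ",
         paste(cm[miss], collapse = ", "))

  getcol <- function(key) if (cm[key] %in% names(dt)) dt[[cm[key]]] else NULL
  n0 <- nrow(dt)
  v <- data.frame(
    snp_id = as.character(getcol("SNP")),
    chrom = sub("^chr", "", as.character(getcol("CHR")), ignore.case = TRUE),
    pos = suppressWarnings(as.numeric(getcol("BP"))),
    a1 = toupper(as.character(getcol("A1"))),
    a2 = toupper(as.character(getcol("A2"))),
    p = suppressWarnings(as.numeric(getcol("P"))),
    stringsAsFactors = FALSE
  )
  for (opt in c("Z", "N", "INFO")) {
    col <- getcol(opt)
    if (!is.null(col))
      v[[tolower(sub("INFO", "info", opt))]] <-
        suppressWarnings(as.numeric(col))
  }
  names(v) <- sub("^z$", "z", names(v))

  log <- list()
  bad <- is.na(v$p) | v$p < 0 | v$p > 1 | is.na(v$pos) | v$pos < 1 |
    !nzchar(v$a1) | !nzchar(v$a2)
  log$skipped_unparseable <- sum(bad)
  v <- v[!bad, , drop = FALSE]
  clamp <- !is.na(v$p) & v$p == 0
  v$p[clamp] <- 1e-300
  log$clamped_p_zero <- sum(clamp)
  auto <- v$chrom %in% as.character(1:22)
  log$dropped_non_autosomal <- sum(!auto)
  v <- v[auto, , drop = FALSE]
  if (!nrow(v)) warning("no usable records parsed from ", path)
  if (is.null(totalN))
    totalN <- if (!is.null(v$n) && any(!is.na(v$n))) max(v$n, na.rm = TRUE)
              else NA_real_
  SumStats(v, disorder = disorder, totalN = totalN, log = log)
}

#' QC-filter summary statistics (munge)
#'
#' Applies the standard pre-TWAS munge filters: imputation
#' \code{INFO >= infoMin} (records lacking INFO are retained), both alleles
#' single nucleotides in \{A,C,G,T\} (indels and multi-allelic codes
#' removed), p-value in (0, 1], and removal of \emph{all} copies of any
#' duplicated SNP identifier. Strand-ambiguous (A/T, C/G) SNPs are retained
#' and flagged by default; set \code{dropAmbiguous = TRUE} to remove them.
#' Filters are applied in the order above and each removed record is
#' attributed to the first rule that rejects it, so the per-rule counts in
#' \code{\link{qcLog}} sum with the retained count to the input count.
#' The operation is idempotent.
#'
#' @param ss a \code{\linkS4class{SumStats}}.
#' @param infoMin minimum imputation INFO score (default 0.9).
#' @param dropAmbiguous remove strand-ambiguous SNPs (default \code{FALSE}).
#' @return A filtered \code{\linkS4class{SumStats}}.
#' @export
mungeSumstats <- function(ss, infoMin = 0.9, dropAmbiguous = FALSE) {
  stopifnot(is(ss, "SumStats"))
  v <- variants(ss)
  log <- qcLog(ss)
  nIn <- nrow(v)

  keepInfo <- if (is.null(v$info)) rep(TRUE, nIn)
              else is.na(v$info) | v$info >= infoMin
  if (is.null(v$info)) log$info_column_absent <- TRUE
  log$removed_low_info <- sum(!keepInfo)
  v <- v[keepInfo, , drop = FALSE]

  isSnp <- v$a1 %in% c("A", "C", "G", "T") & v$a2 %in% c("A", "C", "G", "T")
  log$removed_not_snp <- sum(!isSnp)
  v <- v[isSnp, , drop = FALSE]

  okP <- !is.na(v$p) & v$p > 0 & v$p <= 1
  log$removed_bad_p <- sum(!okP)
  v <- v[okP, , drop = FALSE]

  if (dropAmbiguous) {
    amb <- isStrandAmbiguous(v$a1, v$a2)
    log$removed_ambiguous <- sum(amb)
    v <- v[!amb, , drop = FALSE]
  }

  dup <- v$snp_id %in% v$snp_id[duplicated(v$snp_id)]
  log$removed_duplicate_id <- sum(dup)
  v <- v[!dup, , drop = FALSE]

  log$retained <- nrow(v)
  if (!nrow(v)) warning("munge removed every record for ", ss@disorder)
  SumStats(v, disorder = ss@disorder, totalN = ss@totalN, log = log)
}

#' Write summary statistics to TSV
#'
#' Columns are written in the fixed order SNP, CHR, BP, A1, A2, P
#' (then Z, N, INFO when present) with enough digits that
#' \code{readSumstats(writeSumstats(x))} reproduces the numeric fields
#' bit-identically.
#'
#' @param ss a \code{\linkS4class{SumStats}}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeSumstats <- function(ss, path) {
  v <- variants(ss)
  out <- data.frame(SNP = v$snp_id, CHR = v$chrom, BP = v$pos,
                    A1 = v$a1, A2 = v$a2,
                    P = formatC(v$p, digits = 17, format = "g"),
                    stringsAsFactors = FALSE)
  if (!is.null(v$z)) out$Z <- formatC(v$z, digits = 17, format = "g")
  if (!is.null(v$n)) out$N <- v$n
  if (!is.null(v$info)) out$INFO <- formatC(v$info, digits = 17, format = "g")
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a GMT gene-set file
#'
#' One set per line: name, description, then member gene identifiers,
#' tab-separated. Set names must be unique and member lists non-empty.
#'
#' @param path GMT file path.
#' @return Named list of character vectors of member gene IDs, with the
#'   per-set descriptions in \code{attr(, "description")}.
#' @export
readGmt <- function(path) {
  if (!file.exists(path)) stop("GMT file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- vapply(fields, length, 1L)
  if (any(nf < 3L))
    stop("GMT line(s) with fewer than 3 fields: line ",
         paste(which(nf < 3L), collapse = ", "))
  nm <- vapply(fields, `[[`, "", 1L)
  if (anyDuplicated(nm))
    stop("duplicate gene-set name(s): ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  sets <- lapply(fields, function(f) unique(f[-(1:2)][nzchar(f[-(1:2)])]))
  if (any(vapply(sets, length, 1L) == 0L))
    stop("gene set(s) with empty member list: ",
         paste(nm[vapply(sets, length, 1L) == 0L], collapse = ", "))
  names(sets) <- nm
  attr(sets, "description") <- setNames(vapply(fields, `[[`, "", 2L), nm)
  sets
}

#' Read an LD reference panel
#'
#' Accepts either a VCF (plain or bgzipped; hard genotypes or a DS dosage
#' field) or a TSV dosage matrix (individuals x variants, header = SNP ids)
#' with a variant-list sidecar (TSV: snp_id, chrom, pos). Monomorphic
#' variants are dropped with the count logged in the returned object. The
#' optional \code{region} (\code{list(chrom=, start=, end=)}) is applied
#' half-open on 1-based coordinates: \code{start <= pos < end}.
#'
#' @param path VCF or dosage-matrix path.
#' @param region optional region filter.
#' @param variantFile sidecar variant list for the TSV form; defaults to
#'   \code{paste0(path, ".variants.tsv")}.
#' @return A \code{\linkS4class{ReferencePanel}}.
#' @export
readPanel <- function(path, region = NULL, variantFile = NULL) {
  if (!file.exists(path)) stop("panel file not found: ", path)
  isVcf <- grepl("\\.vcf(\\.gz)?$", path)
  if (isVcf) {
    vcf <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
    vt <- data.frame(
      snp_id = fix$ID,
      chrom = sub("^chr", "", fix$CHROM, ignore.case = TRUE),
      pos = as.numeric(fix$POS),
      stringsAsFactors = FALSE
    )
    fmt <- unique(unlist(strsplit(vcf@gt[, 1L], ":", fixed = TRUE)))
    if ("DS" %in% fmt) {
      ds <- vcfR::extract.gt(vcf, element = "DS", as.numeric = TRUE)
    } else {
      gt <- vcfR::extract.gt(vcf, element = "GT")
      ds <- apply(gt, c(1, 2), function(g) {
        if (is.na(g)) return(NA_real_)
        sum(as.numeric(strsplit(g, "[/|]")[[1]]) > 0)
      })
    }
    dos <- t(ds)  # individuals x variants
  } else {
    variantFile <- variantFile %||% paste0(path, ".variants.tsv")
    if (!file.exists(variantFile))
      stop("variant-list sidecar not found: ", variantFile)
    dos <- as.matrix(data.table::fread(path, header = TRUE,
                                       data.table = FALSE))
    vt <- data.table::fread(variantFile, header = TRUE, data.table = FALSE)
    vt$chrom <- sub("^chr", "", as.character(vt$chrom), ignore.case = TRUE)
    if (!all(c("snp_id", "chrom", "pos") %in% names(vt)))
      stop("variant sidecar needs snp_id, chrom, pos columns")
    if (ncol(dos) != nrow(vt))
      stop("dosage matrix columns do not match the variant list")
    colnames(dos) <- vt$snp_id
  }
  storage.mode(dos) <- "double"
  if (any(is.na(dos))) stop("panel contains missing genotypes")

  if (!is.null(region)) {
    keep <- vt$chrom == sub("^chr", "", as.character(region$chrom)) &
      vt$pos >= region$start & vt$pos < region$end
    if (!any(keep)) stop("no panel variants overlap the requested region")
    vt <- vt[keep, , drop = FALSE]
    dos <- dos[, keep, drop = FALSE]
  }
  colVar <- apply(dos, 2L, stats::var)
  mono <- colVar < .Machine$double.eps
  if (all(mono)) stop("all panel variants are monomorphic")
  vt <- vt[!mono, , drop = FALSE]
  dos <- dos[, !mono, drop = FALSE]
  rownames(vt) <- NULL
  colnames(dos) <- vt$snp_id
  new("ReferencePanel", variants = vt, dosages = dos,
      nDropped = sum(mono))
}

#' Read a gene-wise expression covariate table
#'
#' TSV with columns \code{gene_id} and \code{median_tpm} (median transcript
#' per million, e.g. cortical expression), used as an optional covariate in
#' the competitive gene-set model.
#'
#' @param path file path.
#' @return data.frame with \code{gene_id}, \code{median_tpm}.
#' @export
readExpression <- function(path) {
  x <- data.table::fread(path, header = TRUE, data.table = FALSE)
  if (!all(c("gene_id", "median_tpm") %in% names(x)))
    stop("expression file needs gene_id and median_tpm columns")
  x$gene_id <- as.character(x$gene_id)
  x
}

#' Read eQTL SNP-weight models
#'
#' Long-format TSV with columns \code{gene_id}, \code{tissue},
#' \code{snp_id}, \code{weight}; one row per (gene, SNP) weight. Models
#' with all-zero weights are rejected.
#'
#' @param path file path.
#' @return data.frame of weights (one row per gene/SNP pair).
#' @export
readWeights <- function(path) {
  w <- data.table::fread(path, header = TRUE, data.table = FALSE)
  need <- c("gene_id", "tissue", "snp_id", "weight")
  if (!all(need %in% names(w)))
    stop("weight file needs columns: ", paste(need, collapse = ", "))
  w$gene_id <- as.character(w$gene_id)
  w$snp_id <- as.character(w$snp_id)
  dup <- duplicated(w[, c("gene_id", "tissue", "snp_id")])
  if (any(dup)) stop("duplicated SNP within a weight model")
  tot <- tapply(abs(w$weight), paste(w$gene_id, w$tissue), sum)
  if (any(tot == 0)) stop("weight model(s) with all-zero weights")
  w
}
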