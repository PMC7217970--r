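#' @import methods
#' @importFrom stats qnorm pnorm qchisq pchisq pgamma integrate lm pt
#'   df.residual coef rnorm runif rbinom cor setNames complete.cases
#'   p.adjust uniroot dnorm
#' @importFrom utils read.table write.table head
NULL

setClassUnion("numericOrNULL", c("numeric", "NULL"))

#' GWAS summary statistics for one disorder
#'
#' Holds per-variant association evidence (p-value, optional signed Z,
#' sample size, imputation INFO, alleles, coordinates) for a single GWAS,
#' together with the total sample size used downstream as the
#' meta-analysis weight.
#'
#' @slot disorder single character label for the phenotype.
#' @slot totalN total GWAS sample size (the Stouffer weight \eqn{w_i}).
#' @slot variants data.frame with columns \code{snp_id}, \code{chrom},
#'   \code{pos}, \code{a1}, \code{a2}, \code{p}, and optionally
#'   \code{z}, \code{n}, \code{info}, \code{ambiguous}.
#' @slot log named list of row counts recorded by the reader and by
#'   \code{\link{mungeSumstats}} (rows skipped, clamped, filtered per rule).
#'
#' @seealso \code{\link{readSumstats}}, \code{\link{mungeSumstats}}
#' @export
setClass("SumStats",
  representation(
    disorder = "character",
    totalN = "numeric",
    variants = "data.frame",
    log = "list"
  ),
  prototype(disorder = NA_character_, totalN = NA_real_, log = list())
)

setValidity("SumStats", function(object) {
  msg <- character()
  v <- object@variants
  need <- c("snp_id", "chrom", "pos", "a1", "a2", "p")
  miss <- setdiff(need, names(v))
  if (length(miss))
    msg <- c(msg, paste0("variants lacks column(s): ",
                         paste(miss, collapse = ", ")))
  if (length(object@disorder) != 1L)
    msg <- c(msg, "disorder must be a single string")
  if (length(object@totalN) != 1L ||
      (!is.na(object@totalN) && object@totalN <= 0))
    msg <- c(msg, "totalN must be a single positive number")
  if (!length(miss) && nrow(v)) {
    if (any(!is.na(v$p) & (v$p <= 0 | v$p > 1)))
      msg <- c(msg, "p-values must lie in (0, 1]")
    if (any(!is.na(v$pos) & v$pos < 1))
      msg <- c(msg, "positions must be >= 1")
  }
  if (length(msg)) msg else TRUE
})

#' Reference LD panel
#'
#' Genotype dosages (individuals x variants, values in [0, 2]) used to
#' derive variant-wise linkage disequilibrium. Monomorphic variants are
#' dropped at construction.
#'
#' @slot variants data.frame with \code{snp_id}, \code{chrom}, \code{pos}.
#' @slot dosages numeric matrix, individuals in rows, variants in columns;
#'   column order matches \code{variants}.
#' @slot nDropped number of monomorphic variants removed.
#' @export
setClass("ReferencePanel",
  representation(
    variants = "data.frame",
    dosages = "matrix",
    nDropped = "integer"
  ),
  prototype(nDropped = 0L)
)

setValidity("ReferencePanel", function(object) {
  msg <- character()
  if (ncol(object@dosages) != nrow(object@variants))
    msg <- c(msg, "dosage columns must match the variant table")
  if (!all(c("snp_id", "chrom", "pos") %in% names(object@variants)))
    msg <- c(msg, "variant table needs snp_id, chrom, pos")
  if (ncol(object@dosages)) {
    if (!is.null(colnames(object@dosages)) &&
        !identical(colnames(object@dosages), object@variants$snp_id))
      msg <- c(msg, "dosage column names must match variant snp_ids")
    rng <- range(object@dosages)
    if (rng[1] < 0 || rng[2] > 2)
      msg <- c(msg, "dosages must lie in [0, 2]")
    v <- apply(object@dosages, 2L, stats::var)
    if (any(v < .Machine$double.eps))
      msg <- c(msg, "monomorphic variants must not be retained")
  }
  if (length(msg)) msg else TRUE
})

#' SNP-to-gene annotation
#'
#' The variant-to-gene map after window extension and MHC masking, plus the
#' gene-wise covariates used by the competitive gene-set model (SNP count,
#' genic minor allele count, gene length).
#'
#' @slot genes data.frame with \code{gene_id}, \code{symbol}, \code{chrom},
#'   \code{start}, \code{end}, \code{strand}, \code{wstart}, \code{wend},
#'   \code{n_snps}, \code{mac}.
#' @slot snpIndex named list (by gene_id) of integer indices into the
#'   annotated \code{SumStats} variant table.
#' @slot nMissingPanel variants assigned to genes but absent from the panel
#'   (they contribute 0 to the genic minor allele count).
#' @export
setClass("GeneAnnotation",
  representation(
    genes = "data.frame",
    snpIndex = "list",
    nMissingPanel = "integer"
  ),
  prototype(nMissingPanel = 0L)
)

setValidity("GeneAnnotation", function(object) {
  msg <- character()
  if (!identical(names(object@snpIndex), object@genes$gene_id))
    msg <- c(msg, "snpIndex names must match genes$gene_id in order")
  if (length(object@snpIndex) &&
      any(vapply(object@snpIndex, length, 1L) == 0L))
    msg <- c(msg, "genes with zero SNPs must be absent from the map")
  if (length(msg)) msg else TRUE
})

## ---- accessors -----------------------------------------------------------

#' @describeIn SumStats-class variant table accessor
#' @param x a \code{SumStats}, \code{ReferencePanel} or \code{GeneAnnotation}.
#' @export
setGeneric("variants", function(x) standardGeneric("variants"))

#' @export
setMethod("variants", "SumStats", function(x) x@variants)

#' @export
setMethod("variants", "ReferencePanel", function(x) x@variants)

#' @rdname SumStats-class
#' @export
setGeneric("disorderLabel", function(x) standardGeneric("disorderLabel"))

#' @export
setMethod("disorderLabel", "SumStats", function(x) x@disorder)

#' @rdname SumStats-class
#' @export
setGeneric("totalN", function(x) standardGeneric("totalN"))

#' @export
setMethod("totalN", "SumStats", function(x) x@totalN)

#' @rdname SumStats-class
#' @export
setGeneric("qcLog", function(x) standardGeneric("qcLog"))

#' @export
setMethod("qcLog", "SumStats", function(x) x@log)

#' @rdname ReferencePanel-class
#' @param x a \code{ReferencePanel}.
#' @export
setGeneric("dosages", function(x) standardGeneric("dosages"))

#' @export
setMethod("dosages", "ReferencePanel", function(x) x@dosages)

#' @rdname GeneAnnotation-class
#' @param x a \code{GeneAnnotation}.
#' @export
setGeneric("annotatedGenes", function(x) standardGeneric("annotatedGenes"))

#' @export
setMethod("annotatedGenes", "GeneAnnotation", function(x) x@genes)

#' @rdname GeneAnnotation-class
#' @export
setGeneric("snpIndex", function(x) standardGeneric("snpIndex"))

#' @export
setMethod("snpIndex", "GeneAnnotation", function(x) x@snpIndex)

## ---- show ----------------------------------------------------------------

setMethod("show", "SumStats", function(object) {
  cat("SumStats for", object@disorder,
      sprintf("(N = %s)\n", format(object@totalN, big.mark = ",")))
  cat(" ", nrow(object@variants), "variants on",
      length(unique(object@variants$chrom)), "chromosome(s)\n")
  lg <- object@log
  if (length(lg))
    cat("  QC log:", paste(names(lg), unlist(lg), sep = "=",
                           collapse = ", "), "\n")
})

setMethod("show", "ReferencePanel", function(object) {
  cat("ReferencePanel:", nrow(object@dosages), "individuals x",
      ncol(object@dosages), "variants")
  if (object@nDropped)
    cat(" (", object@nDropped, " monomorphic dropped)", sep = "")
  cat("\n")
})

setMethod("show", "GeneAnnotation", function(object) {
  cat("GeneAnnotation:", nrow(object@genes), "genes;",
      sum(object@genes$n_snps), "SNP assignments\n")
  if (object@nMissingPanel)
    cat(" ", object@nMissingPanel,
        "assigned variants missing from the panel (MAC contribution 0)\n")
})
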