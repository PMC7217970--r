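#' Classify genes shared with comparison disorders
#'
#' A gene is \emph{shared} when it survives Bonferroni correction in the
#' focal GWAS and in at least one comparison GWAS. The sharing disorders
#' are recorded per gene.
#'
#' @param focal data.frame with \code{gene_id}, \code{p} for the focal
#'   disorder.
#' @param comparisons named list of such data.frames, one per comparison
#'   disorder.
#' @param bonf Bonferroni threshold (default \code{2.7e-6}, i.e.
#'   0.05 over 18297 genes).
#' @return data.frame with \code{gene_id}, \code{shared} (logical) and
#'   \code{sharing_disorders} (comma-joined labels, "" when none).
#' @export
classifyShared <- function(focal, comparisons, bonf = 2.7e-6) {
  sig <- focal$p < bonf
  sharing <- vapply(focal$gene_id, function(g) {
    hits <- names(comparisons)[vapply(comparisons, function(cc) {
      i <- match(g, cc$gene_id)
      !is.na(i) && cc$p[i] < bonf
    }, TRUE)]
    paste(hits, collapse = ",")
  }, "")
  data.frame(gene_id = focal$gene_id,
             shared = sig & nzchar(sharing),
             sharing_disorders = ifelse(sig, sharing, ""),
             stringsAsFactors = FALSE)
}

#' Classify focal-disorder-specific genes
#'
#' A gene is \emph{specific} when it survives Bonferroni correction in the
#' focal GWAS and is not even nominally significant in any comparison GWAS
#' (strictly \code{p > nominal} in every one). A gene must be testable
#' (present) in every comparison GWAS to be eligible — absence of evidence
#' is not evidence of absence; untestable Bonferroni-significant genes are
#' reported separately.
#'
#' @inheritParams classifyShared
#' @param nominal nominal significance level (default 0.05).
#' @return data.frame with \code{gene_id}, \code{specific},
#'   \code{untestable} (focal-significant but absent from some comparison).
#' @export
classifySpecific <- function(focal, comparisons, bonf = 2.7e-6,
                             nominal = 0.05) {
  sig <- focal$p < bonf
  status <- vapply(focal$gene_id, function(g) {
    ps <- vapply(comparisons, function(cc) {
      i <- match(g, cc$gene_id)
      if (is.na(i)) NA_real_ else cc$p[i]
    }, 1.0)
    if (anyNA(ps)) return("untestable")
    if (all(ps > nominal)) "clear" else "nominal"
  }, "")
  data.frame(gene_id = focal$gene_id,
             specific = sig & status == "clear",
             untestable = sig & status == "untestable",
             stringsAsFactors = FALSE)
}

#' Classify novel genes from a pairwise meta-analysis
#'
#' Under the interval rule a gene is \emph{novel} for a disorder pair when
#' its meta-analysis p survives Bonferroni correction while both individual
#' GWAS p-values lie strictly inside the open interval
#' \code{(bonf, nominal)} — significant only once the disorders are
#' combined. A looser rule (\code{rule = "nominal"}) requires only that
#' both individual p-values are below \code{nominal} (no lower bound).
#'
#' @param meta output of \code{\link{pairwiseMeta}} (needs \code{gene_id},
#'   \code{p_meta}, \code{p1}, \code{p2}).
#' @param bonf Bonferroni threshold.
#' @param nominal nominal significance level.
#' @param rule \code{"interval"} (default) or \code{"nominal"}.
#' @return data.frame with \code{gene_id}, \code{novel}.
#' @export
classifyNovelMeta <- function(meta, bonf = 2.7e-6, nominal = 0.05,
                              rule = c("interval", "nominal")) {
  rule <- match.arg(rule)
  inWindow <- switch(rule,
    interval = meta$p1 > bonf & meta$p1 < nominal &
               meta$p2 > bonf & meta$p2 < nominal,
    nominal = meta$p1 < nominal & meta$p2 < nominal
  )
  data.frame(gene_id = meta$gene_id,
             novel = meta$p_meta < bonf & inWindow,
             stringsAsFactors = FALSE)
}

#' Full pleiotropy classification report
#'
#' Applies the shared, specific and novel-on-meta rules across a focal
#' disorder, its comparison disorders and the pairwise meta-analyses, and
#' assembles one wide per-gene table plus per-class counts. Shared and
#' specific are mutually exclusive by construction.
#'
#' @param focal focal-disorder gene results (\code{gene_id}, \code{p}).
#' @param comparisons named list of comparison gene results.
#' @param metas optional named list (by comparison label) of
#'   \code{\link{pairwiseMeta}} outputs.
#' @param bonf,nominal thresholds (defaults \code{2.7e-6}, 0.05).
#' @param novelRule passed to \code{\link{classifyNovelMeta}}.
#' @return list with \code{genes} (wide data.frame: focal p, per-comparison
#'   p, labels) and \code{counts} (named list: \code{n_focal_significant},
#'   \code{n_shared}, \code{n_specific}, \code{n_untestable},
#'   \code{n_novel_total}, and \code{n_novel_<pair>} per pair).
#' @export
classifyGenes <- function(focal, comparisons, metas = NULL,
                          bonf = 2.7e-6, nominal = 0.05,
                          novelRule = "interval") {
  sh <- classifyShared(focal, comparisons, bonf)
  sp <- classifySpecific(focal, comparisons, bonf, nominal)
  wide <- data.frame(gene_id = focal$gene_id, p_focal = focal$p,
                     stringsAsFactors = FALSE)
  for (nm in names(comparisons)) {
    i <- match(wide$gene_id, comparisons[[nm]]$gene_id)
    wide[[paste0("p_", nm)]] <- comparisons[[nm]]$p[i]
  }
  wide$shared <- sh$shared
  wide$sharing_disorders <- sh$sharing_disorders
  wide$specific <- sp$specific
  wide$untestable <- sp$untestable

  counts <- list(
    n_focal_significant = sum(focal$p < bonf),
    n_shared = sum(sh$shared),
    n_specific = sum(sp$specific),
    n_untestable = sum(sp$untestable)
  )
  novelTotal <- character()
  if (!is.null(metas)) {
    for (nm in names(metas)) {
      nv <- classifyNovelMeta(metas[[nm]], bonf, nominal, novelRule)
      col <- paste0("novel_", nm)
      wide[[col]] <- nv$novel[match(wide$gene_id, nv$gene_id)]
      wide[[col]][is.na(wide[[col]])] <- FALSE
      counts[[paste0("n_novel_", nm)]] <- sum(nv$novel)
      novelTotal <- union(novelTotal, nv$gene_id[nv$novel])
    }
  }
  counts$n_novel_total <- length(novelTotal)
  stopifnot(!any(wide$shared & wide$specific))  # partition sanity
  list(genes = wide, counts = counts)
}
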