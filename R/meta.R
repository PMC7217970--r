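#' Stouffer's weighted-Z combination
#'
#' \deqn{Z_{meta} = \frac{\sum_i w_i Z_i}{\sqrt{\sum_i w_i^2}}}
#' with weights \eqn{w_i} the GWAS sample sizes. Invariant to rescaling all
#' weights by a positive constant and symmetric in its arguments.
#'
#' @param z numeric vector of Z-scores (length >= 2).
#' @param w positive weights, same length.
#' @return The combined Z.
#' @export
stoufferZ <- function(z, w) {
  if (length(z) < 2L || length(z) != length(w))
    stop("need matched z and weight vectors of length >= 2")
  if (any(w <= 0)) stop("weights must be positive")
  sum(w * z) / sqrt(sum(w^2))
}

#' Upper-tail p for a meta Z
#'
#' The combined statistic follows a standard normal under the null;
#' the p-value is the upper tail \eqn{1 - \Phi(z)}, matching the one-sided
#' construction of the gene Z-scores.
#'
#' @param zMeta finite Z value(s).
#' @return p-value(s) in (0, 1].
#' @export
metaPvalue <- function(zMeta) {
  stopifnot(all(is.finite(zMeta)))
  pmax(pnorm(zMeta, lower.tail = FALSE), 1e-300)
}

#' Pairwise gene-level meta-analysis of two disorders
#'
#' Combines per-gene Z-scores from two gene-based analyses with Stouffer's
#' method, weighting each disorder by its GWAS sample size. Only genes
#' present in both analyses are combined; genes unique to one side are
#' dropped and reported. Overlap of control samples between the two GWAS is
#' not modelled — a warning reminds the user that the combination is
#' intended for gene discovery, not effect estimation.
#'
#' @param res1,res2 gene-result data.frames (from \code{\link{geneTest}})
#'   with \code{gene_id}, \code{z}, \code{p}.
#' @param n1,n2 GWAS sample sizes used as weights.
#' @param alpha family-wise error rate for the recomputed Bonferroni
#'   threshold over the combined gene count.
#' @return data.frame with \code{gene_id}, \code{z1}, \code{z2},
#'   \code{z_meta}, \code{p_meta}, \code{p1}, \code{p2}; the dropped gene
#'   IDs in \code{attr(, "dropped")} and the Bonferroni threshold in
#'   \code{attr(, "bonferroni")}.
#' @export
pairwiseMeta <- function(res1, res2, n1, n2, alpha = 0.05) {
  stopifnot(n1 > 0, n2 > 0)
  common <- intersect(res1$gene_id, res2$gene_id)
  if (!length(common)) stop("no gene shared between the two analyses")
  warning("possible sample overlap between GWAS is ignored; ",
          "meta-analysis intended for gene discovery", call. = FALSE)
  i1 <- match(common, res1$gene_id)
  i2 <- match(common, res2$gene_id)
  w <- c(n1, n2); denom <- sqrt(sum(w^2))
  zMeta <- (n1 * res1$z[i1] + n2 * res2$z[i2]) / denom
  out <- data.frame(
    gene_id = common,
    z1 = res1$z[i1], z2 = res2$z[i2],
    z_meta = zMeta, p_meta = metaPvalue(zMeta),
    p1 = res1$p[i1], p2 = res2$p[i2],
    stringsAsFactors = FALSE
  )
  attr(out, "dropped") <- list(
    only_in_1 = setdiff(res1$gene_id, common),
    only_in_2 = setdiff(res2$gene_id, common)
  )
  attr(out, "bonferroni") <- bonferroniThreshold(alpha, nrow(out))
  out
}

#' Gene-set association on meta-analysis Z-scores
#'
#' Runs the competitive gene-set model with the pairwise meta Z as the
#' response variable.
#'
#' @param metaResults output of \code{\link{pairwiseMeta}}.
#' @param sets named list of gene sets.
#' @param covariates covariate data.frame aligned with \code{metaResults}
#'   rows (meta results carry no gene coordinates, so covariates must be
#'   supplied explicitly or omitted).
#' @param ... passed to \code{\link{runGenesetAssociation}}.
#' @return Per-set results as \code{\link{runGenesetAssociation}}.
#' @export
metaGenesetTest <- function(metaResults, sets, covariates = NULL, ...) {
  res <- data.frame(gene_id = metaResults$gene_id,
                    z = metaResults$z_meta, stringsAsFactors = FALSE)
  runGenesetAssociation(res, sets, covariates = covariates, ...)
}
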